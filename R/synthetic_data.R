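# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes - a proteome, multinomial
# injection/growth/sequencing bottlenecks with clonal-fraction-gated
# antigen-specific depletion, two-color mixture experiments, and
# error-bearing amplicon reads. All generators are reproducible under a
# seed. Effect sizes are generator parameters, not biological claims.

#' Simulate a proteome
#'
#' Proteins with i.i.d. residues from a configurable composition and
#' Poisson-distributed lengths. A stand-in for a real proteome FASTA: it
#' reproduces the combinatorial structure the design pipeline needs (many
#' unique k-mers, occasional repeats) but none of the biology (no motifs,
#' no homology, no amino-acid autocorrelation).
#'
#' @param n_proteins Number of proteins (default 60).
#' @param mean_length Mean protein length in residues (default 300).
#' @param composition Named probability vector over the 20 canonical
#'   residues (default uniform). Residues given zero weight never occur.
#' @param seed Seed.
#' @return Named character vector of protein sequences (ids `SYNP...`).
#' @export
simulate_proteome <- function(n_proteins = 60L, mean_length = 300,
                              composition = NULL, seed = NULL) {
  stopifnot(n_proteins >= 1, mean_length >= 1)
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20L), AA20)
  }
  stopifnot(all(names(composition) %in% AA20), all(composition >= 0),
            sum(composition) > 0)
  .with_seed(seed, {
    lens <- pmax(8L, rpois(n_proteins, mean_length))
    seqs <- vapply(lens, function(n) {
      paste(sample(names(composition), n, replace = TRUE,
                   prob = composition), collapse = "")
    }, character(1))
    setNames(seqs, sprintf("SYNP%04d", seq_len(n_proteins)))
  })
}

#' Write a proteome as FASTA
#'
#' @param proteome Named character vector of protein sequences.
#' @param path Output path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Expected multi-integration fraction at a given MOI
#'
#' Under Poisson integrations with mean `moi`, the fraction of *transduced*
#' cells carrying more than one integration:
#' `(1 - e^-m - m e^-m) / (1 - e^-m)`. At the conventional library MOI of
#' 0.3 this is 0.1425, which is why transduction is done at MOI < 0.3 -
#' few cells receive more than one minigene, so the barcode faithfully
#' labels the cell.
#'
#' @param moi Multiplicity of infection (> 0).
#' @return Fraction in `[0, 1)`.
#' @export
multi_integration_fraction <- function(moi) {
  stopifnot(all(moi > 0))
  (1 - exp(-moi) - moi * exp(-moi)) / (1 - exp(-moi))
}

#' Simulate library transduction
#'
#' Integrations per cell are Poisson(`moi`); transduced cells receive
#' uniformly sampled minigenes.
#'
#' @param n_cells Number of cells exposed.
#' @param moi Multiplicity of infection (default 0.3).
#' @param library_size If given, transduced cells are assigned minigene
#'   indices uniformly from `1:library_size`.
#' @param seed Seed.
#' @return List: `integrations` (per-cell counts), `n_transduced`,
#'   `observed_multi_fraction` (among transduced; NA if none),
#'   `expected_multi_fraction` (closed form), `assignments` (list of
#'   minigene indices per transduced cell, if `library_size` given).
#' @export
simulate_transduction <- function(n_cells, moi = 0.3, library_size = NULL,
                                  seed = NULL) {
  stopifnot(moi > 0, n_cells >= 0)
  .with_seed(seed, {
    integrations <- if (n_cells == 0) integer() else rpois(n_cells, moi)
    transduced <- which(integrations > 0)
    assignments <- NULL
    if (!is.null(library_size) && length(transduced)) {
      assignments <- lapply(integrations[transduced], function(k) {
        sample.int(library_size, k, replace = TRUE)
      })
    }
    list(
      integrations = integrations,
      n_transduced = length(transduced),
      observed_multi_fraction = if (length(transduced)) {
        mean(integrations[transduced] > 1)
      } else NA_real_,
      expected_multi_fraction = multi_integration_fraction(moi),
      assignments = assignments
    )
  })
}

#' Simulate a pooled drop-out screen through its bottlenecks
#'
#' The generative pipeline is a chain of multinomial bottlenecks:
#'
#' 1. **Injection**: the inoculum is a multinomial draw from the pretumor
#'    abundances, so minigenes rarer than ~1/inoculum drop out
#'    stochastically with no explicit rule.
#' 2. **Selection**: minigene i's survival multiplier `s_i` is applied only
#'    if its *realized* inoculum fraction is at least its clonal-fraction
#'    threshold; below the threshold the immune system does not act and
#'    `s_i` is replaced by 1.
#' 3. **Growth**: deterministic expansion by `growth_factor` (proportions
#'    unchanged).
#' 4. **Sequencing**: reads are a multinomial draw of size `depth` from the
#'    surviving cell frequencies.
#'
#' Pretumor replicate samples are sequencing draws from the pretumor
#' abundances directly; each tumor replicate runs its own injection
#' bottleneck (one animal each).
#'
#' @param library Minigene ids (character vector), or an integer count (ids
#'   are generated).
#' @param pre_abundance Pretumor abundance vector (summing to 1); default a
#'   normalized log-uniform draw over `[2e-7, 5e-3]`, the 4-plus orders of
#'   magnitude such libraries span in practice (1 cell per 5e6 up to
#'   ~0.5%).
#' @param survival Per-minigene survival multiplier in `[0, 1]` (scalar
#'   recycled; default 1 = no selection).
#' @param clonal_fraction_threshold Per-minigene fraction below which
#'   selection is suppressed (scalar recycled; default 0 = always acts).
#' @param inoculum Injected cells (default 5e6).
#' @param growth_factor Expansion during tumor growth (default 100).
#' @param depth Sequencing depth per sample (default 1e6).
#' @param n_pre,n_post Number of pretumor / tumor replicates (defaults 3
#'   and 5).
#' @param seed Seed.
#' @return List of class `simulated_screen`: `library`, `pre_abundance`,
#'   `survival`, `threshold`, `pre_counts` and `post_counts` (lists of
#'   `count_table`), `true_post_cells` (per replicate), `config`.
#' @export
simulate_screen <- function(library, pre_abundance = NULL, survival = 1,
                            clonal_fraction_threshold = 0, inoculum = 5e6,
                            growth_factor = 100, depth = 1e6, n_pre = 3L,
                            n_post = 5L, seed = NULL) {
  if (is.numeric(library) && length(library) == 1L) {
    library <- sprintf("mg%05d", seq_len(library))
  }
  n <- length(library)
  stopifnot(n >= 2, depth >= 1, inoculum >= 1, n_pre >= 1, n_post >= 1)
  survival <- rep_len(survival, n)
  thr <- rep_len(clonal_fraction_threshold, n)
  stopifnot(all(survival >= 0 & survival <= 1), all(thr >= 0 & thr < 1))
  .with_seed(seed, {
    if (is.null(pre_abundance)) {
      raw <- 10^runif(n, log10(2e-7), log10(5e-3))
      pre_abundance <- raw / sum(raw)
    }
    stopifnot(length(pre_abundance) == n, all(pre_abundance >= 0))
    if (abs(sum(pre_abundance) - 1) > 1e-9) {
      stop("pre_abundance must sum to 1")
    }
    pre_counts <- lapply(seq_len(n_pre), function(r) {
      as_count_table(setNames(rmultinom(1L, depth, pre_abundance)[, 1L],
                              library),
                     sample_id = sprintf("pretumor_%d", r))
    })
    true_post <- vector("list", n_post)
    post_counts <- lapply(seq_len(n_post), function(r) {
      cells <- rmultinom(1L, inoculum, pre_abundance)[, 1L]
      frac <- cells / inoculum
      s_eff <- ifelse(frac >= thr, survival, 1)
      surv_cells <- cells * s_eff * growth_factor
      if (sum(surv_cells) <= 0) stop("tumor fully rejected in simulation")
      true_post[[r]] <<- surv_cells
      as_count_table(setNames(rmultinom(1L, depth,
                                        surv_cells / sum(surv_cells))[, 1L],
                              library),
                     sample_id = sprintf("tumor_%d", r))
    })
    structure(list(
      library = library, pre_abundance = setNames(pre_abundance, library),
      survival = setNames(survival, library),
      threshold = setNames(thr, library),
      pre_counts = pre_counts, post_counts = post_counts,
      true_post_cells = true_post,
      config = list(inoculum = inoculum, growth_factor = growth_factor,
                    depth = depth, n_pre = n_pre, n_post = n_post,
                    seed = seed)
    ), class = "simulated_screen")
  })
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf(
    "<simulated_screen> %d minigenes; %d pretumor + %d tumor samples at depth %g\n",
    length(x$library), length(x$pre_counts), length(x$post_counts),
    x$config$depth))
  invisible(x)
}

#' Simulate a two-color mixture experiment
#'
#' One record per mouse per intended eGFP (immunogenic) fraction. The
#' measured per-mouse log10 fold change is drawn as
#' `Normal(kill_log10fc * 1[fraction >= threshold], mouse_noise_sd^2)`:
#' clonal-fraction gating is modelled as a hard threshold on the intended
#' fraction - the minimal generative mechanism consistent with
#' antigen-specific detection limits, stated as an assumption, not biology.
#' Emitted flow percentages are scaled by `fluorescent_fraction` (the
#' remainder emulating non-fluorescent events, which the analysis must
#' ignore) and normalization recovers the generative fold change exactly.
#' A tumor whose surviving-cell percentage falls below `reject_floor_pct`
#' of the injected mixture is emitted as rejected (no cells recovered).
#'
#' @param fractions Intended eGFP percentages (default
#'   `c(50, 10, 1, 0.1)`, the classic 2-log dilution ladder).
#' @param threshold Generative clonal-fraction gating threshold, percent
#'   (default 1).
#' @param kill_log10fc Mean log10 fold change when gating is exceeded
#'   (default -1.5, a strong antigen; use ~-1 for a weak one).
#' @param mouse_noise_sd Per-mouse SD of the log10 fold change
#'   (default 0.2).
#' @param n_mice Mice per fraction group (default 4).
#' @param reject_floor_pct Rejection rule: tumor rejected when surviving
#'   cells fall below this percent of the injected mixture (default 1).
#' @param fluorescent_fraction Fraction of tumor events that are
#'   fluorescent (default 0.85).
#' @param antigen Antigen label.
#' @param seed Seed.
#' @return Data frame with columns `antigen`, `mouse`, `fraction_d0_pct`,
#'   `egfp_d0`, `mcherry_d0`, `egfp_tumor`, `mcherry_tumor`, `rejected`;
#'   feeds [analyze_mixture_experiment()] unchanged.
#' @export
simulate_two_color <- function(fractions = c(50, 10, 1, 0.1), threshold = 1,
                               kill_log10fc = -1.5, mouse_noise_sd = 0.2,
                               n_mice = 4L, reject_floor_pct = 1,
                               fluorescent_fraction = 0.85,
                               antigen = "synthetic_antigen", seed = NULL) {
  stopifnot(all(fractions > 0 & fractions < 100), n_mice >= 1,
            mouse_noise_sd >= 0, fluorescent_fraction > 0,
            fluorescent_fraction <= 1)
  .with_seed(seed, {
    grid <- expand.grid(mouse = seq_len(n_mice), fraction = fractions)
    g <- rnorm(nrow(grid),
               mean = kill_log10fc * (grid$fraction >= threshold),
               sd = mouse_noise_sd)
    f <- grid$fraction
    egfp_norm <- pmin(f * 10^g, 99.9)      # measured, already normalized
    survivors_pct <- (100 - f) + f * 10^g  # of the injected mixture
    rejected <- survivors_pct < reject_floor_pct
    data.frame(
      antigen = antigen,
      mouse = sprintf("m%02d_f%g", grid$mouse, f),
      fraction_d0_pct = f,
      egfp_d0 = f * fluorescent_fraction,
      mcherry_d0 = (100 - f) * fluorescent_fraction,
      egfp_tumor = ifelse(rejected, 0, egfp_norm * fluorescent_fraction),
      mcherry_tumor = ifelse(rejected, 0,
                             (100 - egfp_norm) * fluorescent_fraction),
      rejected = rejected,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate amplicon reads for a minigene pool
#'
#' Emits exactly `sum(counts)` reads, each covering the epitope window from
#' its first base (continuing into the downstream flank of the oligo, or
#' A-padding, out to `read_length`), with i.i.d. per-base substitution
#' errors at `error_rate` and constant placeholder Phred qualities.
#'
#' @param pool [build_oligo_pool()] data frame, or a named character vector
#'   of epitope encodings.
#' @param counts Named read counts per minigene (names must be pool
#'   members; missing minigenes get 0).
#' @param error_rate Per-base substitution probability (default 0).
#' @param read_length Read length (default: longest epitope).
#' @param seed Seed.
#' @param path If given, a FASTQ file is written there.
#' @return Data frame (`id`, `minigene`, `read`), invisibly when `path` is
#'   given.
#' @export
simulate_reads <- function(pool, counts, error_rate = 0, read_length = NULL,
                           seed = NULL, path = NULL) {
  if (is.data.frame(pool)) {
    epitopes <- setNames(pool$epitope_dna, pool$peptide)
    downstream <- vapply(seq_len(nrow(pool)), function(i) {
      at <- regexpr(pool$epitope_dna[i], pool$oligo[i], fixed = TRUE)
      substr(pool$oligo[i], at + nchar(pool$epitope_dna[i]),
             nchar(pool$oligo[i]))
    }, character(1))
  } else {
    stopifnot(!is.null(names(pool)))
    epitopes <- pool
    downstream <- rep("", length(pool))
  }
  stopifnot(!is.null(names(counts)), all(counts >= 0),
            all(names(counts) %in% names(epitopes)))
  counts <- counts[counts > 0]
  if (!length(counts)) {
    out <- data.frame(id = character(), minigene = character(),
                      read = character())
    if (!is.null(path)) {
      writeLines(character(), path)
      return(invisible(out))
    }
    return(out)
  }
  L <- read_length %||% max(nchar(epitopes))
  j <- match(names(counts), names(epitopes))
  templates <- substr(paste0(epitopes[j], downstream[j],
                             strrep("A", L)), 1L, L)
  reads <- rep(templates, times = counts)
  origin <- rep(names(counts), times = counts)
  .with_seed(seed, {
    if (error_rate > 0) {
      n_err <- rbinom(length(reads), L, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(L, n_err[i])
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
        reads[i] <- paste(chars, collapse = "")
      }
    }
  })
  out <- data.frame(
    id = sprintf("read%07d:%s", seq_along(reads), origin),
    minigene = origin, read = reads, stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    qual <- strrep("I", L)
    writeLines(paste0("@", out$id, "\n", out$read, "\n+\n", qual), path)
    return(invisible(out))
  }
  out
}
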