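# Screen deconvolution: amplicon reads -> per-minigene counts -> relative
# abundances -> pretumor/tumor comparison with pseudocounted log2 fold
# changes, a LOESS trend in log10 space, and guarded depletion calls.

#' Count minigenes in amplicon reads
#'
#' Bespoke anchored-window matching in place of a general-purpose aligner:
#' each read's leading window (the epitope occupies a fixed position in the
#' amplicon) is compared to every reference epitope encoding at Hamming
#' distance up to `max_mismatch`. A read is assigned to the unique reference
#' at minimal distance; reads tied between two or more references at the
#' best distance are discarded as ambiguous, and reads matching nothing are
#' unmapped. Deterministic.
#'
#' @param reads FASTQ path (optionally gzipped), a character vector of read
#'   sequences, or a `DNAStringSet`.
#' @param reference Named character vector of epitope encodings (names are
#'   minigene ids), or an [build_oligo_pool()] data frame (uses
#'   `epitope_dna` named by `peptide`). Encodings must be unique.
#' @param max_mismatch 0 (exact) or 1.
#' @param sample_id Optional sample label carried in the result.
#' @return Data frame of class `count_table` (`minigene`, `count`) with
#'   attributes `sample_id`, `total_reads`, `mapped`, `unmapped`,
#'   `ambiguous`.
#' @export
count_minigenes <- function(reads, reference, max_mismatch = 0L,
                            sample_id = NULL) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  if (is.data.frame(reference)) {
    reference <- setNames(reference$epitope_dna, reference$peptide)
  }
  if (!length(reference)) stop("empty reference")
  if (is.null(names(reference)) || anyDuplicated(names(reference)) ||
      anyDuplicated(reference)) {
    stop("reference encodings must be uniquely named and mutually unique")
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(
      Biostrings::readDNAStringSet(reads, format = "fastq")
    )
  } else {
    reads <- as.character(reads)
  }
  n <- length(reads)
  if (n == 0L) {
    warning("no reads; returning an all-zero count table")
    return(as_count_table(setNames(rep(0L, length(reference)),
                                   names(reference)),
                          sample_id = sample_id, total_reads = 0L,
                          ambiguous = 0L))
  }
  rl <- nchar(reads)
  L_all <- nchar(reference)
  best_d <- rep(Inf, n)
  best_ref <- rep(NA_integer_, n)
  ambig <- rep(FALSE, n)
  # pass 1: exact window matches (distance 0)
  for (L in sort(unique(L_all))) {
    idx <- which(L_all == L)
    w <- substr(reads, 1L, L)
    m <- match(w, reference[idx])
    hit <- which(rl >= L & !is.na(m))
    tie <- hit[best_d[hit] == 0]
    ambig[tie] <- TRUE
    new <- hit[best_d[hit] > 0]
    best_d[new] <- 0
    best_ref[new] <- idx[m[new]]
    ambig[new] <- FALSE
    ambig[tie] <- TRUE
  }
  # pass 2: distance-1 matches for reads with no exact hit
  if (max_mismatch >= 1L) {
    todo <- which(best_d > 0)
    for (L in sort(unique(L_all))) {
      idx <- which(L_all == L)
      sub <- todo[rl[todo] >= L]
      if (!length(sub)) next
      w <- substr(reads[sub], 1L, L)
      uw <- unique(w)
      pos <- match(w, uw)
      mat <- matrix(utf8ToInt(paste(uw, collapse = "")), nrow = L)
      ubest <- rep(Inf, length(uw))
      uref <- rep(NA_integer_, length(uw))
      uamb <- rep(FALSE, length(uw))
      for (j in seq_along(idx)) {
        d <- colSums(mat != utf8ToInt(reference[idx[j]]))
        tie <- which(d == ubest & is.finite(d))
        better <- which(d < ubest)
        uamb[tie] <- TRUE
        ubest[better] <- d[better]
        uref[better] <- idx[j]
        uamb[better] <- FALSE
      }
      d <- ubest[pos]; r <- uref[pos]; a <- uamb[pos]
      tie <- which(d == best_d[sub] & is.finite(d))
      better <- which(d < best_d[sub])
      ambig[sub[tie]] <- TRUE
      best_d[sub[better]] <- d[better]
      best_ref[sub[better]] <- r[better]
      ambig[sub[better]] <- a[better]
    }
  }
  mapped <- is.finite(best_d) & best_d <= max_mismatch & !ambig
  counts <- tabulate(best_ref[mapped], nbins = length(reference))
  n_ambig <- sum(ambig & is.finite(best_d) & best_d <= max_mismatch)
  as_count_table(setNames(counts, names(reference)), sample_id = sample_id,
                 total_reads = n, ambiguous = n_ambig)
}

#' Construct a count table from named counts
#'
#' @param counts Named non-negative numeric vector (names are minigene ids).
#' @param sample_id Optional sample label.
#' @param total_reads Total reads in the sample including unmapped; defaults
#'   to `sum(counts)`.
#' @param ambiguous Number of reads discarded as ambiguous (informational).
#' @return `count_table` data frame.
#' @export
as_count_table <- function(counts, sample_id = NULL, total_reads = NULL,
                           ambiguous = 0L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  out <- data.frame(minigene = names(counts), count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  mapped <- sum(out$count)
  total_reads <- total_reads %||% mapped
  structure(out, sample_id = sample_id, total_reads = total_reads,
            mapped = mapped, unmapped = total_reads - mapped,
            ambiguous = ambiguous,
            class = c("count_table", "data.frame"))
}

#' Read / write a count table TSV (`minigene  count`)
#'
#' @param path File path.
#' @param sample_id Optional sample label.
#' @return `count_table` data frame.
#' @export
read_count_tsv <- function(path, sample_id = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("minigene", "count") %in% names(tab)))
  as_count_table(setNames(tab$count, tab$minigene), sample_id = sample_id)
}

#' @rdname read_count_tsv
#' @param counts `count_table` to write.
#' @export
write_count_tsv <- function(counts, path) {
  write.table(counts[, c("minigene", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative abundance of each minigene
#'
#' Each minigene's mapped read count divided by the total mapped reads of
#' the sample; abundances sum to 1.
#'
#' @param counts `count_table` (or named numeric vector of counts).
#' @return Data frame of class `abundance_table` (`minigene`, `abundance`)
#'   with attributes `sample_id` and `total_mapped`.
#' @export
relative_abundance <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- as_count_table(counts)
  }
  total <- sum(counts$count)
  if (total <= 0) stop("zero mapped reads: cannot normalise")
  structure(
    data.frame(minigene = counts$minigene,
               abundance = counts$count / total,
               stringsAsFactors = FALSE),
    sample_id = attr(counts, "sample_id"), total_mapped = total,
    class = c("abundance_table", "data.frame")
  )
}

#' Library representation QC
#'
#' Pass iff the observed number of independent events (transformants,
#' transduced cells, template genome equivalents...) is at least `min_fold`
#' times the library size; e.g. a 5000-member library at 1000x requires
#' 5,000,000 colonies.
#'
#' @param n_observed Observed count.
#' @param library_size Number of library members.
#' @param min_fold Required fold representation (default 1000).
#' @return List of class `qc_representation`: `required`, `observed`,
#'   `pass`.
#' @export
qc_representation <- function(n_observed, library_size, min_fold = 1000L) {
  stopifnot(library_size >= 1, min_fold >= 1)
  required <- min_fold * library_size
  structure(list(required = required, observed = n_observed,
                 pass = n_observed >= required),
            class = "qc_representation")
}

#' @export
print.qc_representation <- function(x, ...) {
  cat(sprintf("<qc_representation> observed %g / required %g: %s\n",
              x$observed, x$required, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Cells at injection implied by a relative abundance
#'
#' The absolute number of cells carrying a minigene at the time of injection
#' is its relative abundance times the inoculum; e.g. 0.005% of a 5e6-cell
#' inoculum is 250 cells.
#'
#' @param abundance Relative abundance as a fraction in `[0, 1]`.
#' @param inoculum Injected cell count (default 5e6).
#' @return Data frame: `abundance`, `cells` (unrounded), `cells_nearest`.
#' @export
estimate_cells_at_injection <- function(abundance, inoculum = 5e6) {
  stopifnot(all(abundance >= 0 & abundance <= 1), inoculum > 0)
  cells <- abundance * inoculum
  data.frame(abundance = abundance, cells = cells,
             cells_nearest = round(cells))
}

#' Compare pretumor and tumor screens
#'
#' Per minigene: the arithmetic mean abundance over pretumor replicates and
#' over tumor replicates, the pseudocounted log2 fold change
#' `log2((post + eps) / (pre + eps))`, a LOESS trend of log10(post) on
#' log10(pre), and a guarded call. A minigene is called depleted only when
#' its fold change is at or below `-lfc_threshold` *and* its pretumor
#' abundance is at least `floor`: minigenes rarer than ~1/10,000 at
#' injection are lost to stochastic drop-out through the engraftment
#' bottleneck, so their disappearance carries no immunological signal.
#'
#' @param pre,post `abundance_table` or list of replicate tables; all tables
#'   must cover the same minigene set.
#' @param pseudocount Pseudocount `eps`; default `1 / (2 * max total mapped
#'   reads across samples)` (scale-aware; falls back to half the smallest
#'   non-zero abundance when read totals are unavailable).
#' @param floor Pretumor abundance floor for depletion calls (default 1e-4).
#' @param lfc_threshold Absolute log2 fold-change call threshold (default 1,
#'   i.e. 2-fold). No formal call rule is implied by the screen itself; the
#'   threshold is a reported parameter, never silently applied.
#' @param span,degree LOESS parameters (defaults 0.5 and 1); the trend is
#'   skipped (NA) for fewer than 10 minigenes.
#' @param per_animal If `TRUE`, return one comparison per tumor replicate
#'   (each vs the pretumor mean) instead of the replicate-averaged one.
#' @return Data frame of class `screen_comparison` (`minigene`, `pre`,
#'   `post`, `lfc`, `fitted`, `residual`, `call`) with a `params` attribute;
#'   or a list of them when `per_animal = TRUE`.
#' @export
compare_screens <- function(pre, post, pseudocount = NULL, floor = 1e-4,
                            lfc_threshold = 1, span = 0.5, degree = 1,
                            per_animal = FALSE) {
  as_list <- function(x) {
    if (is.data.frame(x)) list(x) else as.list(x)
  }
  pre <- as_list(pre)
  post <- as_list(post)
  stopifnot(length(pre) >= 1, length(post) >= 1)
  ids <- pre[[1L]]$minigene
  all_tabs <- c(pre, post)
  for (tab in all_tabs) {
    if (!setequal(tab$minigene, ids) || nrow(tab) != length(ids)) {
      stop("all samples must cover the same minigene library")
    }
  }
  if (is.null(pseudocount)) {
    totals <- unlist(lapply(all_tabs, attr, "total_mapped"))
    if (length(totals) == length(all_tabs)) {
      pseudocount <- 1 / (2 * max(totals))
    } else {
      ab <- unlist(lapply(all_tabs, `[[`, "abundance"))
      pseudocount <- min(ab[ab > 0]) / 2
      message("read totals unavailable; pseudocount set to half the ",
              "smallest non-zero abundance (", signif(pseudocount, 3), ")")
    }
  }
  if (per_animal) {
    return(lapply(post, function(p) {
      compare_screens(pre, p, pseudocount = pseudocount, floor = floor,
                      lfc_threshold = lfc_threshold, span = span,
                      degree = degree, per_animal = FALSE)
    }))
  }
  mat_of <- function(tabs) {
    vapply(tabs, function(tab) {
      tab$abundance[match(ids, tab$minigene)]
    }, numeric(length(ids)))
  }
  pre_mean <- rowMeans(mat_of(pre))
  post_mean <- rowMeans(mat_of(post))
  eps <- pseudocount
  lfc <- log2((post_mean + eps) / (pre_mean + eps))
  lx <- log10(pre_mean + eps)
  ly <- log10(post_mean + eps)
  # the trend needs enough distinct pretumor abundances to be identifiable;
  # toy tables get NA rather than a degenerate fit
  if (length(unique(signif(lx, 10))) >= 10L) {
    fit <- loess(ly ~ lx, span = span, degree = degree)
    fitted <- predict(fit, lx)
  } else {
    fitted <- rep(NA_real_, length(ids))
  }
  residual <- ly - fitted
  call <- rep("neutral", length(ids))
  call[lfc >= lfc_threshold] <- "enriched"
  call[lfc <= -lfc_threshold & pre_mean >= floor] <- "depleted"
  structure(
    data.frame(minigene = ids, pre = pre_mean, post = post_mean, lfc = lfc,
               fitted = fitted, residual = residual, call = call,
               stringsAsFactors = FALSE),
    params = list(pseudocount = eps, floor = floor,
                  lfc_threshold = lfc_threshold, span = span,
                  degree = degree, n_pre = length(pre),
                  n_post = length(post)),
    class = c("screen_comparison", "data.frame")
  )
}

#' Write a screen comparison TSV
#'
#' Columns `minigene pre post lfc residual call`.
#'
#' @param comparison `screen_comparison` data frame.
#' @param path Output path.
#' @export
write_comparison_tsv <- function(comparison, path) {
  write.table(comparison[, c("minigene", "pre", "post", "lfc", "residual",
                             "call")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
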