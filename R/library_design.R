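# Library design: proteome k-mer enumeration, wild-type binder selection,
# constrained single-residue mutagenesis, controls, and the three
# characterization statistics (affinity shift, mutated position,
# substitution class).

#' Enumerate unique k-mers of a proteome
#'
#' Collects every unique length-`k` substring over all proteins, excluding
#' k-mers containing non-canonical residues. Provenance records the first
#' occurrence (protein id and 0-based start) in the order proteins are given.
#'
#' @param proteome A named character vector of protein sequences, a
#'   `Biostrings::AAStringSet`, or a path to a protein FASTA file.
#' @param k Peptide length (default 8, the modal H-2Kb ligand length).
#' @return Data frame with columns `peptide`, `protein_id`, `start`
#'   (0-based), one row per unique peptide.
#' @examples
#' enumerate_kmers(c(p1 = "SIINFEKLA"), k = 8)
#' @export
enumerate_kmers <- function(proteome, k = 8L) {
  stopifnot(k >= 2)
  k <- as.integer(k)
  if (is.character(proteome) && length(proteome) == 1L &&
      is.null(names(proteome)) && file.exists(proteome)) {
    proteome <- Biostrings::readAAStringSet(proteome)
  }
  if (methods::is(proteome, "XStringSet")) {
    proteome <- setNames(as.character(proteome), names(proteome))
  }
  proteome <- proteome[nchar(proteome) > 0]
  if (!length(proteome)) stop("empty proteome")
  if (is.null(names(proteome)) || anyDuplicated(names(proteome))) {
    stop("proteome sequences must carry unique ids")
  }
  lens <- nchar(proteome)
  keep <- lens >= k
  if (!any(keep)) stop("no protein is at least ", k, " residues long")
  seqs <- proteome[keep]
  lens <- lens[keep]
  n_win <- lens - k + 1L
  starts <- unlist(lapply(n_win, function(m) seq_len(m) - 1L))
  pep <- unlist(mapply(function(s, m) {
    substring(s, seq_len(m), seq_len(m) + k - 1L)
  }, seqs, n_win, SIMPLIFY = FALSE), use.names = FALSE)
  out <- data.frame(
    peptide = pep,
    protein_id = rep(names(seqs), n_win),
    start = starts,
    stringsAsFactors = FALSE
  )
  out <- out[.is_canonical(out$peptide), , drop = FALSE]
  out <- out[!duplicated(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the wild-type peptide library
#'
#' Filters candidate peptides to predicted binders (IC50 strictly below
#' `ic50_threshold`) and samples `n_select` of them uniformly without
#' replacement. Deterministic under `seed` and invariant to the input order
#' (candidates are sorted before sampling).
#'
#' @param peptides Candidate peptides: a character vector or the data frame
#'   from [enumerate_kmers()] (provenance columns are carried through).
#' @param affinity Affinity source: an `affinity_model`, a prediction data
#'   frame from [load_prediction_table()], or a named numeric IC50 vector.
#' @param n_select Library size (default 5000).
#' @param ic50_threshold Binder cut in nM (default 500, strict `<`).
#' @param seed Sampling seed.
#' @return Data frame of `PeptideRecord`s: `peptide`, `ic50`, `role`
#'   (`"wild_type"`), `partner` (NA), `mutated_position` (NA), plus any
#'   provenance columns.
#' @export
select_wildtype_library <- function(peptides, affinity, n_select = 5000L,
                                    ic50_threshold = 500, seed = NULL) {
  stopifnot(n_select >= 1, ic50_threshold > 0)
  prov <- NULL
  if (is.data.frame(peptides)) {
    prov <- peptides
    peptides <- peptides$peptide
  }
  stopifnot(!anyDuplicated(peptides))
  ic50 <- .ic50_of(peptides, affinity)
  binder <- !is.na(ic50) & ic50 < ic50_threshold
  n_binders <- sum(binder)
  if (n_binders < n_select) {
    stop(sprintf("only %d peptides pass the %g nM binder filter; %d requested",
                 n_binders, ic50_threshold, n_select))
  }
  cand <- data.frame(peptide = peptides[binder], ic50 = ic50[binder],
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$peptide), , drop = FALSE]
  pick <- .with_seed(seed, sample.int(nrow(cand), n_select))
  out <- cand[sort(pick), , drop = FALSE]
  out$role <- "wild_type"
  out$partner <- NA_character_
  out$mutated_position <- NA_integer_
  if (!is.null(prov)) {
    j <- match(out$peptide, prov$peptide)
    for (col in setdiff(names(prov), names(out))) out[[col]] <- prov[[col]][j]
  }
  rownames(out) <- NULL
  out
}

#' Mutate one peptide by a single random residue substitution
#'
#' Draws a position (1..k) and one of the 19 alternative residues uniformly
#' and accepts the first candidate that is not in `forbidden` and passes the
#' binder filter. `method = "sample"` uses rejection resampling with at most
#' `max_attempts` draws (the candidate space for an 8-mer is 8 x 19 = 152);
#' `method = "enumerate"` enumerates all admissible neighbours and picks one
#' uniformly, which cannot miss an admissible mutant by chance.
#'
#' @param wild_type A single peptide.
#' @param forbidden Peptides the mutant must not equal (typically all
#'   proteome k-mers, so a "mutant" is never a self peptide elsewhere in the
#'   proteome). A character vector, or an environment whose names are the
#'   forbidden peptides (constant-time lookup for large sets).
#' @param affinity Affinity source (see [select_wildtype_library()]); the
#'   mutant must itself satisfy `ic50 < ic50_threshold`, i.e. the
#'   substitution must not eliminate predicted MHC-I binding.
#' @param ic50_threshold Binder cut in nM (default 500).
#' @param max_attempts Rejection-sampling budget (default 200).
#' @param method `"sample"` (default) or `"enumerate"`.
#' @param seed Seed.
#' @return One-row data frame (`peptide`, `ic50`, `role = "mutant"`,
#'   `partner`, `mutated_position`), or `NULL` if no admissible mutant was
#'   found (the wild type is unmutable under the constraints).
#' @export
mutate_peptide <- function(wild_type, forbidden = character(), affinity,
                           ic50_threshold = 500, max_attempts = 200L,
                           method = c("sample", "enumerate"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(wild_type) == 1L, .is_canonical(wild_type))
  k <- nchar(wild_type)
  chars <- strsplit(wild_type, "", fixed = TRUE)[[1L]]
  mk <- function(pos, res) {
    x <- chars; x[pos] <- res
    paste(x, collapse = "")
  }
  is_forbidden <- if (is.environment(forbidden)) {
    function(p) exists(p, envir = forbidden, inherits = FALSE)
  } else {
    function(p) p %in% forbidden
  }
  admissible <- function(p) {
    if (is_forbidden(p)) return(NA_real_)
    ic <- .ic50_of(p, affinity)
    if (is.na(ic) || ic >= ic50_threshold) return(NA_real_)
    ic
  }
  result <- .with_seed(seed, {
    if (method == "sample") {
      found <- NULL
      for (i in seq_len(max_attempts)) {
        pos <- sample.int(k, 1L)
        res <- sample(setdiff(AA20, chars[pos]), 1L)
        p <- mk(pos, res)
        ic <- admissible(p)
        if (!is.na(ic)) {
          found <- list(peptide = p, pos = pos, ic50 = ic)
          break
        }
      }
      found
    } else {
      grid <- expand.grid(pos = seq_len(k), res = AA20,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$res != chars[grid$pos], , drop = FALSE]
      grid$peptide <- mapply(mk, grid$pos, grid$res)
      grid$ic50 <- vapply(grid$peptide, admissible, numeric(1))
      grid <- grid[!is.na(grid$ic50), , drop = FALSE]
      if (nrow(grid)) {
        j <- grid[sample.int(nrow(grid), 1L), ]
        list(peptide = j$peptide, pos = j$pos, ic50 = j$ic50)
      } else {
        NULL
      }
    }
  })
  if (is.null(result)) return(NULL)
  data.frame(peptide = result$peptide, ic50 = result$ic50, role = "mutant",
             partner = wild_type, mutated_position = as.integer(result$pos),
             stringsAsFactors = FALSE)
}

#' Build the mutant library paired to a wild-type library
#'
#' One single-residue mutant per wild-type peptide, each absent from the
#' proteome k-mer set (so no mutant is a self peptide; set
#' `exclude_scope = "library"` for the narrower library-only check), absent
#' from the library built so far, and itself passing the binder filter.
#' Wild types with no admissible mutant are excluded and reported. Processing
#' order and per-peptide seeds are derived from the sorted wild-type
#' peptides, so the result is reproducible under `seed` and invariant to
#' input order.
#'
#' @param wildtype_library Data frame from [select_wildtype_library()] (or
#'   any data frame with a `peptide` column).
#' @param proteome_kmers Character vector of all unique proteome k-mers (or
#'   the data frame from [enumerate_kmers()]).
#' @param affinity,ic50_threshold,max_attempts,method,seed As in
#'   [mutate_peptide()].
#' @param exclude_scope `"proteome"` (default): mutants must not equal any
#'   proteome k-mer; `"library"`: only the wild-type library is forbidden.
#' @return Data frame of mutant `PeptideRecord`s with attribute
#'   `"unmutable"`: the wild-type peptides for which no admissible mutant
#'   exists.
#' @export
build_mutant_library <- function(wildtype_library, proteome_kmers = NULL,
                                 affinity, ic50_threshold = 500,
                                 max_attempts = 200L,
                                 method = c("sample", "enumerate"),
                                 exclude_scope = c("proteome", "library"),
                                 seed = NULL) {
  method <- match.arg(method)
  exclude_scope <- match.arg(exclude_scope)
  wt <- if (is.data.frame(wildtype_library)) wildtype_library$peptide
        else as.character(wildtype_library)
  stopifnot(length(wt) > 0, !anyDuplicated(wt))
  if (is.data.frame(proteome_kmers)) proteome_kmers <- proteome_kmers$peptide
  base_forbidden <- if (exclude_scope == "proteome") {
    if (is.null(proteome_kmers)) {
      stop("proteome_kmers is required when exclude_scope = \"proteome\"")
    }
    unique(c(proteome_kmers, wt))
  } else {
    wt
  }
  wt <- sort(wt)
  forbidden <- new.env(parent = emptyenv())
  for (p in base_forbidden) assign(p, TRUE, envir = forbidden)
  rows <- vector("list", length(wt))
  unmutable <- character()
  for (i in seq_along(wt)) {
    m <- mutate_peptide(
      wt[i], forbidden = forbidden,
      affinity = affinity, ic50_threshold = ic50_threshold,
      max_attempts = max_attempts, method = method,
      seed = .derive_seed(seed, wt[i])
    )
    if (is.null(m)) {
      unmutable <- c(unmutable, wt[i])
    } else {
      rows[[i]] <- m
      assign(m$peptide, TRUE, envir = forbidden)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(peptide = character(), ic50 = numeric(),
                      role = character(), partner = character(),
                      mutated_position = integer())
  }
  rownames(out) <- NULL
  if (length(unmutable)) {
    message(length(unmutable),
            " wild-type peptide(s) had no admissible mutant and were excluded")
  }
  attr(out, "unmutable") <- unmutable
  out
}

#' Default control peptides
#'
#' The known immunogenic (SIINFEKL, SNFVFAGI, VTFVFAGL) and known
#' non-immunogenic (MSIIFFLPL, FEKIILSN, EQYKFYSV, SNFVSAGI, TWHRYHLL)
#' control antigens spiked into each library. Controls may differ in length
#' from the library peptides (MSIIFFLPL is a 9-mer).
#'
#' @return Data frame with `peptide` and `role` columns.
#' @export
default_control_peptides <- function() {
  data.frame(
    peptide = c("SIINFEKL", "SNFVFAGI", "VTFVFAGL",
                "MSIIFFLPL", "FEKIILSN", "EQYKFYSV", "SNFVSAGI", "TWHRYHLL"),
    role = c(rep("control_immunogenic", 3L),
             rep("control_nonimmunogenic", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Append control peptides to a library
#'
#' @param library Data frame with at least `peptide` and `role` columns.
#' @param controls Data frame with `peptide` and `role`
#'   (`control_immunogenic` or `control_nonimmunogenic`); defaults to
#'   [default_control_peptides()].
#' @return The library with controls appended. A control equal to an
#'   existing library peptide is an error.
#' @export
add_controls <- function(library, controls = default_control_peptides()) {
  stopifnot(all(c("peptide", "role") %in% names(controls)))
  ok_roles <- c("control_immunogenic", "control_nonimmunogenic")
  if (!all(controls$role %in% ok_roles)) {
    stop("control roles must be one of: ", paste(ok_roles, collapse = ", "))
  }
  dup <- intersect(controls$peptide, library$peptide)
  if (length(dup)) {
    stop("control peptide(s) already in the library: ",
         paste(dup, collapse = ", "))
  }
  if (anyDuplicated(controls$peptide)) stop("duplicated control peptides")
  add <- data.frame(peptide = controls$peptide, role = controls$role,
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(library), names(add))) add[[col]] <- NA
  rbind(library, add[names(library)])
}

#' Characterize a paired wild-type/mutant library
#'
#' Three statistics over the mutant pairs: the absolute predicted-affinity
#' shift `|ic50(mutant) - ic50(wild type)|` binned with a dedicated
#' "within 100 nM" first bin; the histogram of mutated positions 1..k; and
#' the 3 x 3 substitution-class matrix over hydrophobic / polar / charged
#' (fixed convention: hydrophobic A,C,F,I,L,M,P,V,W; polar G,H,N,Q,S,T,Y;
#' charged D,E,K,R). All three totals equal the number of mutants.
#'
#' @param wildtype_library,mutant_library Data frames from
#'   [select_wildtype_library()] and [build_mutant_library()]. Every mutant's
#'   `partner` must be present in the wild-type library.
#' @param delta_breaks Right-closed bin edges for the affinity shift
#'   (default `c(0, 100, 250, 500, 1000, Inf)`).
#' @return List of class `library_characterization` with
#'   `affinity_delta_histogram`, `position_histogram`,
#'   `substitution_class_matrix` and `n_mutants`.
#' @export
characterize_library <- function(wildtype_library, mutant_library,
                                 delta_breaks = c(0, 100, 250, 500, 1000,
                                                  Inf)) {
  wt <- wildtype_library
  mut <- mutant_library
  k <- if (nrow(wt)) max(nchar(wt$peptide)) else 8L
  orphan <- setdiff(mut$partner, wt$peptide)
  if (length(orphan)) {
    stop("mutant(s) with no wild-type partner in the library: ",
         paste(head(orphan, 5L), collapse = ", "))
  }
  labels <- paste0("(", delta_breaks[-length(delta_breaks)], ",",
                   delta_breaks[-1L], "]")
  labels[1L] <- sprintf("within %g nM", delta_breaks[2L])
  classes <- c("hydrophobic", "polar", "charged")
  cls_mat <- matrix(0L, 3L, 3L, dimnames = list(from = classes, to = classes))
  if (nrow(mut) == 0) {
    return(structure(list(
      affinity_delta_histogram = setNames(rep(0L, length(labels)), labels),
      position_histogram = setNames(rep(0L, k), seq_len(k)),
      substitution_class_matrix = cls_mat,
      n_mutants = 0L
    ), class = "library_characterization"))
  }
  j <- match(mut$partner, wt$peptide)
  delta <- abs(mut$ic50 - wt$ic50[j])
  hist_delta <- table(cut(delta, breaks = delta_breaks,
                          include.lowest = TRUE, labels = labels))
  pos_hist <- tabulate(mut$mutated_position, nbins = k)
  names(pos_hist) <- seq_len(k)
  from_res <- substr(mut$partner, mut$mutated_position, mut$mutated_position)
  to_res <- substr(mut$peptide, mut$mutated_position, mut$mutated_position)
  tab <- table(factor(RESIDUE_CLASS[from_res], levels = classes),
               factor(RESIDUE_CLASS[to_res], levels = classes))
  cls_mat[] <- as.integer(tab)
  structure(list(
    affinity_delta_histogram = setNames(as.integer(hist_delta), labels),
    position_histogram = pos_hist,
    substitution_class_matrix = cls_mat,
    n_mutants = nrow(mut)
  ), class = "library_characterization")
}

#' @export
print.library_characterization <- function(x, ...) {
  cat(sprintf("<library_characterization> %d mutant pairs\n", x$n_mutants))
  cat("affinity shift |ic50(mut) - ic50(wt)|:\n")
  print(x$affinity_delta_histogram)
  cat("mutated position:\n")
  print(x$position_histogram)
  cat("substitution class (from x to):\n")
  print(x$substitution_class_matrix)
  invisible(x)
}

#' Write a peptide library as TSV
#'
#' Columns `peptide role partner mutated_position ic50_nM protein_id start`
#' (provenance columns NA where unknown).
#'
#' @param library Library data frame.
#' @param path Output path.
#' @export
write_library_tsv <- function(library, path) {
  cols <- c("peptide", "role", "partner", "mutated_position")
  stopifnot(all(c("peptide", "role") %in% names(library)))
  out <- data.frame(
    peptide = library$peptide,
    role = library$role,
    partner = if ("partner" %in% names(library)) library$partner else NA,
    mutated_position = if ("mutated_position" %in% names(library))
      library$mutated_position else NA,
    ic50_nM = if ("ic50" %in% names(library)) library$ic50 else NA,
    protein_id = if ("protein_id" %in% names(library))
      library$protein_id else NA,
    start = if ("start" %in% names(library)) library$start else NA
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write peptides as a one-record-per-peptide FASTA
#'
#' For hand-off to an external affinity predictor.
#'
#' @param peptides Character vector (or data frame with a `peptide` column).
#' @param path Output path.
#' @export
write_peptides_fasta <- function(peptides, path) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  x <- Biostrings::AAStringSet(setNames(peptides, peptides))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
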