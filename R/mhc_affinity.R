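# MHC-I binding affinity scoring: external prediction tables plus a bundled
# position-weight model so the pipeline can run without a network predictor.

#' Bundled position-weight affinity model
#'
#' A seeded random position-weight matrix over the 20 canonical residues with
#' the strictly decreasing calibration `ic50 = ic50_scale * exp(-score)`,
#' where `score` is the sum of per-position weights. This is a *test double*
#' for an external MHC-I predictor: it has the right shape (deterministic,
#' length-k, canonical-residue-only, monotone calibration) but no scientific
#' content. With the defaults roughly half of random 8-mers score below the
#' conventional 500 nM binder cut, which is convenient for exercising the
#' design pipeline.
#'
#' @param allele MHC allele label attached to predictions (default `"H-2Kb"`,
#'   the C57BL/6 mouse class I allele that binds mostly 8-mers).
#' @param k Peptide length the model scores (default 8).
#' @param seed Seed for the random weight matrix.
#' @param ic50_scale Calibration scale in nM: the IC50 assigned to a
#'   zero-score peptide.
#' @param weight_mean,weight_sd Normal parameters for the weights.
#' @return An object of class `affinity_model`: list with `allele`, `k`,
#'   `weights` (20 x k matrix, rows named by residue) and `calibration`
#'   (strictly decreasing function score -> nM).
#' @examples
#' m <- toy_affinity_model(seed = 1)
#' predict_ic50("SIINFEKL", m)
#' @export
toy_affinity_model <- function(allele = "H-2Kb", k = 8L, seed = 1L,
                               ic50_scale = 50000, weight_mean = 0.6,
                               weight_sd = 0.5) {
  stopifnot(k >= 2, ic50_scale > 0, weight_sd >= 0)
  weights <- .with_seed(seed, matrix(
    rnorm(20L * k, mean = weight_mean, sd = weight_sd),
    nrow = 20L, dimnames = list(AA20, NULL)
  ))
  structure(
    list(
      allele = allele, k = as.integer(k), weights = weights,
      calibration = function(score) ic50_scale * exp(-score),
      ic50_scale = ic50_scale
    ),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model> allele %s, length-%d position-weight matrix\n",
              x$allele, x$k))
  cat(sprintf("  calibration: ic50 = %g * exp(-score) nM (test double)\n",
              x$ic50_scale))
  invisible(x)
}

#' Predict IC50 for peptides under a position-weight model
#'
#' Deterministic: the calibration applied to the summed per-position weights
#' of each peptide's residues.
#'
#' @param peptide Character vector of amino-acid strings, all of the model's
#'   length and using canonical residues only.
#' @param model An [toy_affinity_model()]-style `affinity_model`.
#' @return Numeric vector of predicted IC50 in nM.
#' @export
predict_ic50 <- function(peptide, model) {
  stopifnot(inherits(model, "affinity_model"))
  peptide <- as.character(peptide)
  if (any(nchar(peptide) != model$k)) {
    stop("all peptides must have length ", model$k)
  }
  if (!all(.is_canonical(peptide))) {
    stop("peptides must use only the 20 canonical residues")
  }
  chars <- matrix(unlist(strsplit(peptide, "", fixed = TRUE)),
                  nrow = model$k)
  idx <- cbind(match(chars, AA20), rep(seq_len(model$k), length(peptide)))
  scores <- colSums(matrix(model$weights[idx], nrow = model$k))
  model$calibration(scores)
}

#' Binder classification at an IC50 threshold
#'
#' Strict inequality: a peptide is a binder iff its predicted IC50 is
#' *below* the threshold (so exactly 500 nM is not a binder at the default
#' cut).
#'
#' @param ic50 Numeric vector of predicted IC50 (nM), or a data frame with an
#'   `ic50` column as returned by [load_prediction_table()].
#' @param threshold Binder cut in nM (default 500).
#' @return Logical vector.
#' @export
is_binder <- function(ic50, threshold = 500) {
  stopifnot(threshold > 0)
  if (is.data.frame(ic50)) ic50 <- ic50$ic50
  as.numeric(ic50) < threshold
}

#' Read a peptide-affinity prediction table
#'
#' Reads a delimited table with peptide, allele and IC50 columns. Rows with a
#' non-canonical peptide or a missing/non-positive IC50 are skipped with a
#' message; duplicated (peptide, allele) pairs are resolved by keeping the
#' minimum IC50 (the most optimistic binding call, which is conservative for
#' downstream binder filtering).
#'
#' @param path Path to the table.
#' @param sep Field separator (default tab).
#' @param peptide_col,allele_col,ic50_col Column names (defaults `peptide`,
#'   `allele`, `ic50_nM`).
#' @return Data frame with columns `peptide`, `allele`, `ic50` (nM), one row
#'   per (peptide, allele).
#' @seealso [read_netmhcpan()] for the long-format predictor output dialect.
#' @export
load_prediction_table <- function(path, sep = "\t", peptide_col = "peptide",
                                  allele_col = "allele",
                                  ic50_col = "ic50_nM") {
  tab <- tryCatch(
    read.delim(path, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) {
      warning("empty or unreadable prediction table: ", conditionMessage(e))
      data.frame(peptide = character(), allele = character(),
                 ic50 = numeric())
    }
  )
  if (nrow(tab) == 0 && ncol(tab) == 3 &&
      identical(names(tab), c("peptide", "allele", "ic50"))) {
    return(tab)
  }
  missing <- setdiff(c(peptide_col, allele_col, ic50_col), names(tab))
  if (length(missing)) {
    stop("prediction table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    peptide = as.character(tab[[peptide_col]]),
    allele = as.character(tab[[allele_col]]),
    ic50 = suppressWarnings(as.numeric(tab[[ic50_col]])),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    warning("prediction table has no data rows")
    return(out)
  }
  bad_pep <- !.is_canonical(out$peptide)
  bad_ic <- is.na(out$ic50) | out$ic50 <= 0
  if (any(bad_pep)) {
    message(sum(bad_pep), " row(s) skipped: non-canonical residues")
  }
  if (any(bad_ic)) {
    message(sum(bad_ic), " row(s) skipped: missing or non-positive ic50")
  }
  out <- out[!(bad_pep | bad_ic), , drop = FALSE]
  # duplicates: keep minimum ic50 per (peptide, allele)
  key <- paste(out$peptide, out$allele, sep = "\r")
  out <- out[order(key, out$ic50), , drop = FALSE]
  out <- out[!duplicated(paste(out$peptide, out$allele, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prediction table in the package's exchange format
#'
#' Tab-separated with header `peptide allele ic50_nM`; the inverse of
#' [load_prediction_table()] with default arguments.
#'
#' @param predictions Data frame with `peptide`, `allele`, `ic50`.
#' @param path Output path.
#' @export
write_prediction_table <- function(predictions, path) {
  stopifnot(all(c("peptide", "allele", "ic50") %in% names(predictions)))
  out <- data.frame(peptide = predictions$peptide,
                    allele = predictions$allele,
                    ic50_nM = predictions$ic50)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read NetMHCpan v4 long-format output
#'
#' Adapter for the whitespace-aligned long format: the header row is located
#' by the `Peptide` column name and columns are identified by name, not
#' position. The affinity column (`Aff(nM)`) is taken as the IC50; runs that
#' were produced without `-BA` (no affinity column) are rejected.
#'
#' @param path Path to the predictor output.
#' @return Data frame as from [load_prediction_table()].
#' @export
read_netmhcpan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- grep("\\bPeptide\\b", lines)
  if (!length(hdr_i)) stop("no header row with a 'Peptide' column found")
  hdr_i <- hdr_i[[1L]]
  split_ws <- function(x) strsplit(trimws(x), "[[:space:]]+")[[1L]]
  hdr <- split_ws(lines[hdr_i])
  pep_j <- match("Peptide", hdr)
  all_j <- match(c("MHC", "HLA", "Allele"), hdr)
  all_j <- all_j[!is.na(all_j)][1L]
  aff_j <- grep("^Aff", hdr)[1L]
  if (is.na(aff_j) || !length(aff_j)) {
    stop("no affinity column (Aff(nM)) in predictor output; ",
         "re-run the predictor with binding-affinity output enabled")
  }
  body <- lines[-seq_len(hdr_i)]
  body <- body[!grepl("^[[:space:]]*([-#=]|$)", body)]
  fields <- lapply(body, split_ws)
  fields <- fields[vapply(fields, length, 1L) >= max(pep_j, aff_j)]
  if (!length(fields)) {
    warning("predictor output has no data rows")
    return(data.frame(peptide = character(), allele = character(),
                      ic50 = numeric()))
  }
  pick <- function(j) vapply(fields, `[[`, character(1), j)
  out <- data.frame(
    peptide = pick(pep_j),
    allele = if (is.na(all_j)) NA_character_ else pick(all_j),
    ic50 = suppressWarnings(as.numeric(pick(aff_j))),
    stringsAsFactors = FALSE
  )
  out <- out[.is_canonical(out$peptide) & !is.na(out$ic50) & out$ic50 > 0, ,
             drop = FALSE]
  key <- paste(out$peptide, out$allele, sep = "\r")
  out <- out[order(key, out$ic50), , drop = FALSE]
  out <- out[!duplicated(paste(out$peptide, out$allele, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Resolve an "affinity source" (model, prediction data frame, or named
# numeric vector) into per-peptide IC50s; NA for peptides the source cannot
# score.
.ic50_of <- function(peptides, affinity) {
  if (inherits(affinity, "affinity_model")) {
    ok <- nchar(peptides) == affinity$k & .is_canonical(peptides)
    out <- rep(NA_real_, length(peptides))
    if (any(ok)) out[ok] <- predict_ic50(peptides[ok], affinity)
    return(out)
  }
  if (is.data.frame(affinity)) {
    stopifnot(all(c("peptide", "ic50") %in% names(affinity)))
    affinity <- affinity[order(affinity$peptide, affinity$ic50), ]
    affinity <- affinity[!duplicated(affinity$peptide), ]
    return(affinity$ic50[match(peptides, affinity$peptide)])
  }
  if (is.numeric(affinity) && !is.null(names(affinity))) {
    return(unname(affinity[match(peptides, names(affinity))]))
  }
  stop("affinity must be an affinity_model, a prediction data frame, ",
       "or a named numeric vector of IC50s")
}
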