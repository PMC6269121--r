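# Two-color mixture analysis: normalization, per-tumor fold change, the
# one-sample t-test on log10 fold changes per fraction group, and the
# minimal clonal fraction at which antigen-specific depletion is detected.

#' Normalize two-color tumor percentages to sum to 100
#'
#' Non-fluorescent events (host infiltrate, marker-silenced cells) are
#' ignored by construction: only the eGFP and mCherry percentages enter, and
#' they are rescaled to sum to 100. A tumor in which neither color is
#' recovered cannot be normalized and is flagged rejected.
#'
#' @param egfp_pct,mcherry_pct Percent eGFP+ / mCherry+ events (vectorised).
#' @return Data frame: `egfp_norm`, `mcherry_norm` (NA when rejected),
#'   `rejected`.
#' @export
normalize_two_color <- function(egfp_pct, mcherry_pct) {
  stopifnot(length(egfp_pct) == length(mcherry_pct),
            all(egfp_pct >= 0), all(mcherry_pct >= 0))
  tot <- egfp_pct + mcherry_pct
  rejected <- !(tot > 0)
  egfp_norm <- ifelse(rejected, NA_real_, 100 * egfp_pct / tot)
  data.frame(egfp_norm = egfp_norm,
             mcherry_norm = ifelse(rejected, NA_real_, 100 - egfp_norm),
             rejected = rejected)
}

#' Fold change of an antigen-bearing subclone
#'
#' `FC = (normalized eGFP percent in tumor) / (eGFP percent at day 0)`, with
#' the log10 fold change alongside.
#'
#' @param egfp_norm_tumor Normalized eGFP percent in the tumor.
#' @param egfp_pct_d0 eGFP percent at day 0 (must be positive).
#' @return Data frame: `fc`, `log10_fc`.
#' @export
fold_change <- function(egfp_norm_tumor, egfp_pct_d0) {
  if (any(egfp_pct_d0 <= 0)) stop("day-0 eGFP percentage must be positive")
  fc <- egfp_norm_tumor / egfp_pct_d0
  data.frame(fc = fc, log10_fc = log10(fc))
}

#' One-sample t-test for depletion of a fraction group
#'
#' Tests the per-tumor log10 fold changes against the null of no change
#' (mean 0). The default alternative is one-sided in the depletion
#' direction (`mean < 0`): the screen's question is whether the subclone
#' was lost, and at the small group sizes typical of these experiments
#' (3-4 tumors) a two-sided test at stringent alpha has too little power to
#' detect even 10-fold depletion. A two-sided test (with a direction guard
#' so enrichment is never labelled depletion) is available via
#' `alternative = "two.sided"`.
#'
#' With zero variance no t-statistic exists; the group is reported
#' sign-based: significant only when all (identical) values are negative,
#' with `t` and `p` NA.
#'
#' @param log10_fcs Numeric vector of per-tumor log10 fold changes (n >= 2;
#'   a warning is issued below n = 3, the reporting standard for these
#'   experiments).
#' @param alpha Significance level (default 0.001, mirroring the four-star
#'   reporting convention).
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return List of class `depletion_test`: `n`, `mean_log10fc`,
#'   `sd_log10fc`, `t`, `df`, `p`, `alpha`, `alternative`, `significant`.
#' @examples
#' test_depletion(c(-1.0, -1.2, -0.8))
#' @export
test_depletion <- function(log10_fcs, alpha = 0.001,
                           alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- log10_fcs[!is.na(log10_fcs)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations for a t-test (got ", n, ")")
  if (n < 3L) {
    warning("fewer than 3 tumors in group; below the reporting standard")
  }
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(structure(list(
      n = n, mean_log10fc = m, sd_log10fc = 0, t = NA_real_,
      df = n - 1L, p = NA_real_, alpha = alpha, alternative = alternative,
      significant = m < 0,
      note = "zero variance: sign-based report, no t-statistic"
    ), class = "depletion_test"))
  }
  tstat <- m / (s / sqrt(n))
  df <- n - 1L
  p <- switch(alternative,
              less = pt(tstat, df),
              two.sided = 2 * pt(-abs(tstat), df))
  structure(list(
    n = n, mean_log10fc = m, sd_log10fc = s, t = tstat, df = df, p = p,
    alpha = alpha, alternative = alternative,
    significant = (p < alpha) && (m < 0)
  ), class = "depletion_test")
}

#' @export
print.depletion_test <- function(x, ...) {
  cat(sprintf(
    "<depletion_test> n=%d mean log10FC=%.3f t=%s p=%s (%s, alpha=%g): %s\n",
    x$n, x$mean_log10fc,
    if (is.na(x$t)) "NA" else sprintf("%.3f", x$t),
    if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3),
    x$alternative, x$alpha,
    if (isTRUE(x$significant)) "DEPLETED" else "not significant"))
  invisible(x)
}

#' Per-fraction depletion tests for a two-color mixture experiment
#'
#' Normalizes day-0 and tumor percentages, computes per-tumor fold changes,
#' excludes rejected tumors (flagged, or with no fluorescent cells
#' recovered), and runs [test_depletion()] within each intended day-0
#' fraction group. Groups with fewer than 2 analyzable tumors are reported
#' untested (NA).
#'
#' @param experiment Data frame with columns `fraction_d0_pct`, `egfp_d0`,
#'   `mcherry_d0`, `egfp_tumor`, `mcherry_tumor` and optionally `rejected`
#'   and `antigen`/`mouse` (as produced by [simulate_two_color()] or read
#'   from a TSV of the same layout).
#' @param alpha,alternative Passed to [test_depletion()].
#' @return Data frame of class `mixture_tests`, one row per fraction group
#'   in decreasing fraction order: `fraction_d0_pct`, `n`, `n_rejected`,
#'   `mean_log10fc`, `t`, `p`, `significant`.
#' @export
analyze_mixture_experiment <- function(experiment, alpha = 0.001,
                                       alternative = c("less",
                                                       "two.sided")) {
  alternative <- match.arg(alternative)
  need <- c("fraction_d0_pct", "egfp_d0", "mcherry_d0", "egfp_tumor",
            "mcherry_tumor")
  missing <- setdiff(need, names(experiment))
  if (length(missing)) {
    stop("experiment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tum <- normalize_two_color(experiment$egfp_tumor, experiment$mcherry_tumor)
  d0 <- normalize_two_color(experiment$egfp_d0, experiment$mcherry_d0)
  if (any(d0$rejected)) stop("day-0 percentages must not both be zero")
  rejected <- tum$rejected
  if ("rejected" %in% names(experiment)) {
    rejected <- rejected | as.logical(experiment$rejected)
  }
  lfc <- rep(NA_real_, nrow(experiment))
  ok <- !rejected
  lfc[ok] <- fold_change(tum$egfp_norm[ok], d0$egfp_norm[ok])$log10_fc
  fractions <- sort(unique(experiment$fraction_d0_pct), decreasing = TRUE)
  rows <- lapply(fractions, function(f) {
    in_grp <- experiment$fraction_d0_pct == f
    x <- lfc[in_grp & !rejected]
    n_rej <- sum(in_grp & rejected)
    if (length(x) < 2L) {
      return(data.frame(fraction_d0_pct = f, n = length(x),
                        n_rejected = n_rej, mean_log10fc = NA_real_,
                        t = NA_real_, p = NA_real_, significant = NA))
    }
    tst <- suppressWarnings(
      test_depletion(x, alpha = alpha, alternative = alternative)
    )
    data.frame(fraction_d0_pct = f, n = tst$n, n_rejected = n_rej,
               mean_log10fc = tst$mean_log10fc, t = tst$t, p = tst$p,
               significant = tst$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mixture_tests", class(out))
  out
}

#' Minimal clonal fraction with detectable depletion
#'
#' The antigen-specific immunogenicity threshold: the smallest intended
#' day-0 fraction whose group test is significant. By default the monotone
#' frontier rule is applied - every larger tested fraction must also be
#' significant - because the quantity of interest is a detection limit, not
#' an isolated significance; `frontier = FALSE` returns the smallest
#' significant fraction regardless of larger groups.
#'
#' @param experiment A mixture experiment table (see
#'   [analyze_mixture_experiment()]) or an already-computed `mixture_tests`
#'   table.
#' @param alpha,alternative Passed to [analyze_mixture_experiment()] when a
#'   raw experiment is supplied.
#' @param frontier Apply the monotone-frontier rule (default `TRUE`).
#' @return The minimal fraction in percent (`NA` if no group is
#'   significant), with the per-group test table as attribute `"tests"`.
#' @export
detect_threshold <- function(experiment, alpha = 0.001,
                             alternative = c("less", "two.sided"),
                             frontier = TRUE) {
  alternative <- match.arg(alternative)
  tests <- if (inherits(experiment, "mixture_tests")) {
    experiment
  } else {
    analyze_mixture_experiment(experiment, alpha = alpha,
                               alternative = alternative)
  }
  tested <- tests[!is.na(tests$significant), , drop = FALSE]
  if (!nrow(tested)) stop("no fraction group has enough analyzable tumors")
  tested <- tested[order(tested$fraction_d0_pct, decreasing = TRUE), ,
                   drop = FALSE]
  sig <- tested$significant
  detected <- NA_real_
  if (frontier) {
    run <- cumsum(!sig) == 0  # prefix of all-significant groups
    if (any(run)) detected <- min(tested$fraction_d0_pct[run])
  } else {
    if (any(sig)) detected <- min(tested$fraction_d0_pct[sig])
  }
  structure(detected, tests = tests)
}

#' Caliper tumor volume (modified ellipsoid)
#'
#' `volume = L x W^2 x 0.52` with L the longest diameter and W the
#' perpendicular width, in mm. Inputs with W > L are swapped with a warning.
#'
#' @param L,W Caliper measurements in mm (vectorised, positive).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 10) # 520
#' @export
tumor_volume <- function(L, W) {
  stopifnot(all(L > 0), all(W > 0))
  swap <- W > L
  if (any(swap)) {
    warning("W > L for ", sum(swap), " measurement(s); inputs swapped")
    tmp <- L[swap]
    L[swap] <- W[swap]
    W[swap] <- tmp
  }
  L * W^2 * 0.52
}

#' Read / write mixture experiment TSV
#'
#' Layout: `antigen mouse fraction_d0_pct egfp_d0 mcherry_d0 egfp_tumor
#' mcherry_tumor rejected`.
#'
#' @param path File path.
#' @return Experiment data frame.
#' @export
read_mixture_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("fraction_d0_pct", "egfp_d0", "mcherry_d0", "egfp_tumor",
            "mcherry_tumor")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("mixture table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_mixture_tsv
#' @param experiment Experiment data frame to write.
#' @export
write_mixture_tsv <- function(experiment, path) {
  write.table(experiment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
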