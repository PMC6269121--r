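# Shared fixtures built in code: small affinity models, toy libraries, and
# the independent brute-force counting oracle.

# A model with all-zero weights: every peptide scores 0, so
# ic50 = ic50_scale for all of them.
flat_model <- function(k = 8L, ic50_scale = 500) {
  m <- toy_affinity_model(k = k, seed = 1L, ic50_scale = ic50_scale)
  m$weights[] <- 0
  m$calibration <- function(score) ic50_scale * exp(-score)
  m
}

# Hand-built 2-position model: weight A@1 = 1, K@2 = 2, everything else 0,
# calibration 1000 / (1 + score). "AK" scores 3 -> 250 nM.
ak_model <- function() {
  m <- toy_affinity_model(k = 2L, seed = 1L)
  m$weights[] <- 0
  m$weights["A", 1L] <- 1
  m$weights["K", 2L] <- 2
  m$calibration <- function(score) 1000 / (1 + score)
  m
}

# A model under which *every* canonical peptide of length k is a binder at
# 500 nM (constant strong score), so mutagenesis constraints reduce to the
# forbidden set alone.
permissive_model <- function(k = 8L) {
  m <- toy_affinity_model(k = k, seed = 1L)
  m$weights[] <- 8 / k  # constant score 8 -> 50000 * e^-8 = 16.8 nM
  m$calibration <- function(score) 50000 * exp(-score)
  m
}

# Independent counting oracle: all-pairs Hamming scan of each read's
# leading window against every reference; unique best within max_mismatch
# wins, ties are discarded.
brute_force_count <- function(reads, reference, max_mismatch = 0L) {
  counts <- setNames(rep(0L, length(reference)), names(reference))
  for (rd in reads) {
    best <- Inf
    best_ref <- NA_character_
    n_best <- 0L
    for (id in names(reference)) {
      ref <- reference[[id]]
      L <- nchar(ref)
      if (nchar(rd) < L) next
      d <- sum(utf8ToInt(substr(rd, 1L, L)) != utf8ToInt(ref))
      if (d < best) {
        best <- d
        best_ref <- id
        n_best <- 1L
      } else if (d == best) {
        n_best <- n_best + 1L
      }
    }
    if (is.finite(best) && best <= max_mismatch && n_best == 1L) {
      counts[best_ref] <- counts[best_ref] + 1L
    }
  }
  counts
}

# Abundance tables from named count vectors.
abundance_of <- function(counts, sample_id = NULL) {
  relative_abundance(as_count_table(counts, sample_id = sample_id))
}

# Deterministic per-replicate seed derivation used by stochastic suites;
# kept below 2^31.
rep_seed <- function(base, r) {
  as.integer((as.numeric(base) * 7919 + r * 104729) %% 2147483647)
}
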