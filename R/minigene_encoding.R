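# Minigene encoding: peptide -> codon-optimised epitope DNA -> full oligo
# (adapter + SfiI flank + signal + epitope + stop + SfiI flank + adapter),
# with motif avoidance so each oligo carries exactly the two intended SfiI
# sites and the epitope DNA is a unique, self-barcoding sequence.

# SfiI recognition site: GGCC NNNNN GGCC (13 bp, degenerate core). The
# pattern class is its own reverse complement, so single-strand matching
# covers both strands. Top-strand cut after GGCCNNNN (offset 8), leaving
# 3-nt 3' overhangs.
SFII_REGEX <- "GGCC.{5}GGCC"
SFII_CUT_OFFSET <- 8L

.find_sfii <- function(dna) {
  # overlap-aware: zero-width lookahead
  m <- gregexpr(paste0("(?=", SFII_REGEX, ")"), dna, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Mouse-preferred codon table
#'
#' For each residue, synonymous codons ordered by mouse codon-usage
#' preference (most frequent first). The first codon is the default
#' encoding; the alternatives are the fallback pool when a forbidden motif
#' must be avoided.
#'
#' @return Named list of codon character vectors.
#' @export
mouse_codon_table <- function() {
  list(
    A = c("GCC", "GCT", "GCA", "GCG"),
    C = c("TGC", "TGT"),
    D = c("GAC", "GAT"),
    E = c("GAG", "GAA"),
    F = c("TTC", "TTT"),
    G = c("GGC", "GGA", "GGG", "GGT"),
    H = c("CAC", "CAT"),
    I = c("ATC", "ATT", "ATA"),
    K = c("AAG", "AAA"),
    L = c("CTG", "CTC", "TTG", "CTT", "CTA", "TTA"),
    M = "ATG",
    N = c("AAC", "AAT"),
    P = c("CCC", "CCT", "CCA", "CCG"),
    Q = c("CAG", "CAA"),
    R = c("AGG", "AGA", "CGG", "CGC", "CGA", "CGT"),
    S = c("AGC", "TCC", "TCT", "TCA", "AGT", "TCG"),
    T = c("ACC", "ACA", "ACT", "ACG"),
    V = c("GTG", "GTC", "GTT", "GTA"),
    W = "TGG",
    Y = c("TAC", "TAT")
  )
}

#' Placeholder ER signal-sequence DNA
#'
#' A synthetic, ATG-initiated, GGCC-free coding placeholder with a
#' signal-peptide-like hydrophobic core (translation MKTIIFFLLLSLSLTET).
#' The construct's real signal sequence is not printed in this package's
#' sources; users reproducing a published construct should supply the exact
#' sequence via the `signal_dna` argument of [build_minigene()].
#'
#' @return A single DNA string.
#' @export
presenter_signal_sequence <- function() {
  "ATGAAGACCATCATCTTCTTTCTGCTGCTGAGCCTGAGCCTGACCGAAACC"
}

#' Default amplification adapters (generic T3/T7 promoter primers)
#'
#' @return Named character vector with `adapter_5p` and `adapter_3p`.
#' @export
default_adapters <- function() {
  c(adapter_5p = "ATTAACCCTCACTAAAGGGA",  # T3
    adapter_3p = "TAATACGACTCACTATAGGG") # T7
}

#' Reverse-translate a peptide into motif-free epitope DNA
#'
#' Encodes each residue with the mouse-preferred codon, then (if the result,
#' in its junction context `flank5 + dna + flank3`, contains a forbidden
#' motif) deterministically resamples synonymous codons under `seed` until a
#' motif-free encoding is found or the attempt budget is exhausted.
#'
#' @param peptide A single peptide (canonical residues only).
#' @param codon_table Named list of synonymous codons per residue, preferred
#'   first (default [mouse_codon_table()]).
#' @param forbidden_motifs Character vector of regular expressions the
#'   encoding (with flanks) must not contain; default the degenerate SfiI
#'   site.
#' @param flank5,flank3 Fixed DNA context on either side, included in the
#'   motif check so no motif can arise across a junction (supply at least
#'   motif length - 1 characters of true context).
#' @param seed Seed for the codon resampling.
#' @param max_attempts Resampling budget (default 100).
#' @return Epitope DNA string; `translate(result) == peptide`.
#' @export
reverse_translate <- function(peptide, codon_table = mouse_codon_table(),
                              forbidden_motifs = SFII_REGEX,
                              flank5 = "", flank3 = "", seed = NULL,
                              max_attempts = 100L) {
  stopifnot(length(peptide) == 1L, .is_canonical(peptide))
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(codon_table))) {
    stop("codon table does not cover all residues of ", peptide)
  }
  clean <- function(dna) {
    ctx <- paste0(flank5, dna, flank3)
    !any(vapply(forbidden_motifs, function(mo) grepl(mo, ctx, perl = TRUE),
                logical(1)))
  }
  dna <- paste(vapply(chars, function(a) codon_table[[a]][1L], character(1)),
               collapse = "")
  if (clean(dna)) return(dna)
  found <- .with_seed(seed, {
    hit <- NULL
    for (i in seq_len(max_attempts)) {
      cand <- paste(vapply(chars, function(a) {
        cods <- codon_table[[a]]
        if (length(cods) == 1L) cods else sample(cods, 1L)
      }, character(1)), collapse = "")
      if (clean(cand)) {
        hit <- cand
        break
      }
    }
    hit
  })
  if (is.null(found)) {
    stop("no motif-free encoding found for peptide ", peptide,
         " within ", max_attempts, " attempts")
  }
  found
}

#' Build one minigene
#'
#' Assembles `full_insert = signal + epitope + stop` and
#' `oligo = adapter_5p + SfiI flank + full_insert + SfiI flank + adapter_3p`,
#' with the epitope encoded by [reverse_translate()] under junction-aware
#' motif avoidance. The finished oligo is checked to contain exactly the two
#' intended SfiI sites.
#'
#' @param peptide Peptide to encode.
#' @param signal_dna ER signal-sequence DNA; must start with ATG, be a whole
#'   number of codons and contain no internal stop.
#' @param stop_codon Stop codon appended after the epitope (default TAA).
#' @param adapter_5p,adapter_3p Amplification adapters (default generic
#'   T3/T7 promoter primers; override with construct-specific primers).
#' @param sfii_5p,sfii_3p The two intended SfiI sites (13-mers matching
#'   GGCCNNNNNGGCC).
#' @param codon_table,seed Passed to [reverse_translate()].
#' @return List of class `minigene`: `peptide`, `epitope_dna`,
#'   `full_insert`, `oligo`.
#' @export
build_minigene <- function(peptide, signal_dna = presenter_signal_sequence(),
                           stop_codon = "TAA",
                           adapter_5p = default_adapters()[["adapter_5p"]],
                           adapter_3p = default_adapters()[["adapter_3p"]],
                           sfii_5p = "GGCCTCAGTGGCC",
                           sfii_3p = "GGCCAGAGAGGCC",
                           codon_table = mouse_codon_table(), seed = NULL) {
  stopifnot(grepl("^ATG", signal_dna), nchar(signal_dna) %% 3 == 0)
  sig_aa <- .translate_dna(signal_dna)
  if (grepl("\\*", sig_aa)) stop("signal sequence contains a stop codon")
  for (s in c(sfii_5p, sfii_3p)) {
    if (!grepl(paste0("^", SFII_REGEX, "$"), s)) {
      stop("SfiI flank ", s, " does not match GGCCNNNNNGGCC")
    }
  }
  flank5 <- substr(paste0(sfii_5p, signal_dna),
                   nchar(sfii_5p) + nchar(signal_dna) - 11L,
                   nchar(sfii_5p) + nchar(signal_dna))
  flank3 <- substr(paste0(stop_codon, sfii_3p), 1L, 12L)
  epitope <- reverse_translate(peptide, codon_table = codon_table,
                               flank5 = flank5, flank3 = flank3, seed = seed)
  full_insert <- paste0(signal_dna, epitope, stop_codon)
  oligo <- paste0(adapter_5p, sfii_5p, full_insert, sfii_3p, adapter_3p)
  n_sites <- length(.find_sfii(oligo))
  if (n_sites != 2L) {
    stop("oligo for ", peptide, " carries ", n_sites,
         " SfiI sites (expected exactly the 2 intended flanks); ",
         "check signal/adapter sequences")
  }
  structure(list(peptide = peptide, epitope_dna = epitope,
                 full_insert = full_insert, oligo = oligo),
            class = "minigene")
}

#' @export
print.minigene <- function(x, ...) {
  cat(sprintf("<minigene> %s\n  epitope: %s\n  oligo (%d nt): %s...\n",
              x$peptide, x$epitope_dna, nchar(x$oligo),
              substr(x$oligo, 1, 40)))
  invisible(x)
}

#' Build an oligo pool for a peptide set
#'
#' One minigene per peptide. Per-peptide encoding seeds are derived from
#' `seed` and the peptide itself, so permuting the input permutes the output
#' identically. Epitope encodings are checked for uniqueness.
#'
#' @param peptides Character vector (or library data frame with a `peptide`
#'   column).
#' @param seed Base seed for codon fallback sampling.
#' @param ... Passed to [build_minigene()].
#' @return Data frame of class `oligo_pool` with columns `peptide`,
#'   `epitope_dna`, `full_insert`, `oligo`, `length`; adapters kept as
#'   attributes.
#' @export
build_oligo_pool <- function(peptides, seed = NULL, ...) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  stopifnot(length(peptides) > 0, !anyDuplicated(peptides))
  genes <- lapply(peptides, function(p) {
    build_minigene(p, seed = .derive_seed(seed, p), ...)
  })
  out <- data.frame(
    peptide = vapply(genes, `[[`, character(1), "peptide"),
    epitope_dna = vapply(genes, `[[`, character(1), "epitope_dna"),
    full_insert = vapply(genes, `[[`, character(1), "full_insert"),
    oligo = vapply(genes, `[[`, character(1), "oligo"),
    stringsAsFactors = FALSE
  )
  out$length <- nchar(out$oligo)
  dots <- list(...)
  attr(out, "adapter_5p") <- dots$adapter_5p %||%
    default_adapters()[["adapter_5p"]]
  attr(out, "adapter_3p") <- dots$adapter_3p %||%
    default_adapters()[["adapter_3p"]]
  class(out) <- c("oligo_pool", class(out))
  if (anyDuplicated(out$epitope_dna)) {
    warning("duplicate epitope encodings in pool; see validate_pool()")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' In-silico SfiI digestion
#'
#' Cuts the top strand after GGCCNNNN within each site (3-nt 3' overhangs;
#' fragment boundaries are reported in top-strand coordinates). For a
#' standard two-site oligo the middle fragment is the released insert
#' carrying the overhang remnants of both flanks.
#'
#' @param dna A single DNA string.
#' @return Character vector of fragments (length `n_sites + 1`).
#' @export
digest_sfii <- function(dna) {
  sites <- .find_sfii(dna)
  if (!length(sites)) return(dna)
  cuts <- sites + SFII_CUT_OFFSET - 1L
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(dna))
  substring(dna, starts, ends)
}

#' Validate an oligo pool
#'
#' Report-only QC: duplicate epitope encodings (hard violation), oligos
#' whose SfiI site count differs from the two intended flanks (hard
#' violation), the oligo length distribution, and the minimum pairwise
#' Hamming distance between equal-length epitope encodings (informational:
#' barcode confusability; distance 1 means a single sequencing error can
#' turn one barcode into another).
#'
#' @param pool An [build_oligo_pool()] data frame.
#' @param max_pairwise Largest group size for which the exact all-pairs
#'   minimum distance is computed; larger groups are subsampled to this size
#'   (default 500).
#' @return List of class `pool_qc`: `n`, `duplicate_epitopes`,
#'   `n_duplicates`, `bad_sfii` (peptides), `length_distribution`,
#'   `min_pairwise_hamming`, `hard_fail`.
#' @export
validate_pool <- function(pool, max_pairwise = 500L) {
  stopifnot(nrow(pool) > 0)
  dup <- unique(pool$epitope_dna[duplicated(pool$epitope_dna)])
  bad <- pool$peptide[vapply(pool$oligo,
                             function(o) length(.find_sfii(o)) != 2L,
                             logical(1))]
  min_d <- NA_integer_
  for (L in unique(nchar(pool$epitope_dna))) {
    grp <- unique(pool$epitope_dna[nchar(pool$epitope_dna) == L])
    if (length(grp) < 2L) next
    if (length(grp) > max_pairwise) {
      grp <- grp[seq_len(max_pairwise)]
    }
    mat <- matrix(utf8ToInt(paste(grp, collapse = "")), nrow = L)
    for (i in seq_len(length(grp) - 1L)) {
      d <- colSums(mat[, (i + 1L):length(grp), drop = FALSE] != mat[, i])
      m <- min(d)
      if (is.na(min_d) || m < min_d) min_d <- as.integer(m)
      if (min_d == 0L) break
    }
  }
  structure(list(
    n = nrow(pool),
    duplicate_epitopes = dup,
    n_duplicates = length(dup),
    bad_sfii = bad,
    length_distribution = table(pool$length),
    min_pairwise_hamming = min_d,
    hard_fail = length(dup) > 0L || length(bad) > 0L
  ), class = "pool_qc")
}

#' @export
print.pool_qc <- function(x, ...) {
  cat(sprintf("<pool_qc> %d minigenes; %d duplicate encodings; %d bad SfiI\n",
              x$n, x$n_duplicates, length(x$bad_sfii)))
  cat("min pairwise epitope Hamming distance:", x$min_pairwise_hamming, "\n")
  cat(if (x$hard_fail) "HARD VIOLATIONS PRESENT\n" else "clean\n")
  invisible(x)
}

#' Write an oligo pool FASTA and TSV manifest
#'
#' @param pool Oligo pool data frame.
#' @param fasta,tsv Output paths (either may be `NULL` to skip).
#' @export
write_pool <- function(pool, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(setNames(pool$oligo, pool$peptide))
    Biostrings::writeXStringSet(x, fasta)
  }
  if (!is.null(tsv)) {
    write.table(pool[, c("peptide", "epitope_dna", "oligo", "length")],
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(pool)
}
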