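# Shared internal helpers: residue alphabet, seeding, small string tools.

# The 20 canonical amino acids; affinity matrices and mutagenesis are defined
# over these only (B, J, O, U, X, Z are rejected upstream).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fixed residue-class convention used for the substitution-class matrix.
RESIDUE_CLASS <- c(
  A = "hydrophobic", C = "hydrophobic", F = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", P = "hydrophobic", V = "hydrophobic",
  W = "hydrophobic",
  G = "polar", H = "polar", N = "polar", Q = "polar", S = "polar",
  T = "polar", Y = "polar",
  D = "charged", E = "charged", K = "charged", R = "charged"
)

.is_canonical <- function(x) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

# Run `code` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; otherwise run as-is.
.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic small integer hash of a peptide, used to derive per-peptide
# seeds so that pooled operations are invariant to input order. Kept well
# below 2^31.
.peptide_hash <- function(x) {
  vapply(x, function(p) {
    h <- 0
    for (code in utf8ToInt(p)) h <- (h * 31 + code) %% 2147483629
    h
  }, numeric(1), USE.NAMES = FALSE)
}

.derive_seed <- function(seed, x) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + .peptide_hash(x)) %% 2147483629)
}

# Hamming distance between equal-length strings (vectorised over `a`).
.hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

.translate_dna <- function(dna) {
  n <- nchar(dna)
  stopifnot(n %% 3 == 0)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}
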