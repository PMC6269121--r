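test_that("enumerate_kmers collects unique canonical k-mers with provenance", {
  km <- enumerate_kmers(c(p1 = "SIINFEKLA"), k = 8)
  expect_setequal(km$peptide, c("SIINFEKL", "IINFEKLA"))
  expect_equal(km$start[km$peptide == "SIINFEKL"], 0L)  # 0-based
  # dedup: 9xA has a single unique 8-mer
  expect_equal(enumerate_kmers(c(p = "AAAAAAAAA"), 8)$peptide, "AAAAAAAA")
  # k-mers containing a non-canonical residue are excluded
  km2 <- enumerate_kmers(c(a = "MSIINFEKL", b = "XSIINFEKL"), 8)
  expect_setequal(km2$peptide, c("MSIINFEK", "SIINFEKL"))
  # provenance records the first occurrence
  km3 <- enumerate_kmers(c(a = "ASIINFEKL", b = "SIINFEKLW"), 8)
  expect_equal(km3$protein_id[km3$peptide == "SIINFEKL"], "a")
  expect_error(enumerate_kmers(character()), "empty")
})

test_that("wild-type selection filters to binders and samples reproducibly", {
  m <- flat_model(ic50_scale = 100)  # every 8-mer scores 100 nM
  km <- enumerate_kmers(simulate_proteome(5, 60, seed = 1), 8)
  # exhaustive case: n_select equals the binder count
  wt_all <- select_wildtype_library(km, m, n_select = nrow(km), seed = 1)
  expect_setequal(wt_all$peptide, km$peptide)
  # binders-only: mix strong binders with non-binders via a named table
  ic <- setNames(c(rep(100, 10), rep(2000, 5)), km$peptide[1:15])
  wt <- select_wildtype_library(km$peptide[1:15], ic, n_select = 10, seed = 9)
  expect_setequal(wt$peptide, names(ic)[1:10])
  expect_true(all(wt$ic50 < 500))
  # determinism and permutation invariance
  m2 <- toy_affinity_model(seed = 2)
  a <- select_wildtype_library(km, m2, n_select = 20, seed = 5)
  b <- select_wildtype_library(km[sample(nrow(km)), ], m2, n_select = 20,
                               seed = 5)
  expect_equal(a$peptide, b$peptide)
  # too few binders errors with both counts
  expect_error(
    select_wildtype_library(km$peptide[1:15], ic, n_select = 11, seed = 1),
    "only 10.*11"
  )
})

test_that("single-residue mutants respect distance, forbidden set and binding", {
  m <- permissive_model()
  wt <- "SNFVSAGI"
  mu <- mutate_peptide(wt, forbidden = wt, affinity = m, seed = 4)
  expect_equal(nchar(mu$peptide), 8L)
  diff_pos <- which(utf8ToInt(mu$peptide) != utf8ToInt(wt))
  expect_length(diff_pos, 1L)  # Hamming distance exactly 1
  expect_equal(mu$mutated_position, diff_pos)
  # candidate space for an 8-mer is 8 x 19 = 152; forbidding all of it
  # leaves the peptide unmutable
  neighbors <- unlist(lapply(1:8, function(i) {
    vapply(setdiff(rownames(m$weights), substr(wt, i, i)), function(a) {
      x <- strsplit(wt, "")[[1]]; x[i] <- a; paste(x, collapse = "")
    }, character(1))
  }))
  expect_length(neighbors, 152L)
  expect_null(mutate_peptide(wt, forbidden = neighbors, affinity = m,
                             method = "enumerate", seed = 1))
  expect_null(mutate_peptide(wt, forbidden = neighbors, affinity = m,
                             method = "sample", seed = 1))
})

test_that("mutant library pairing holds its invariants across seeds", {
  m <- toy_affinity_model(seed = 3)
  km <- enumerate_kmers(simulate_proteome(15, 150, seed = 6), 8)
  wt <- select_wildtype_library(km, m, n_select = 40, seed = 2)
  for (s in c(1, 2)) {
    for (meth in c("sample", "enumerate")) {
      mut <- build_mutant_library(wt, km, m, seed = s, method = meth)
      expect_equal(nrow(mut) + length(attr(mut, "unmutable")), nrow(wt))
      # Hamming distance exactly 1 from the partner
      d <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                  mut$peptide, mut$partner)
      expect_true(all(d == 1))
      # never a proteome k-mer, never a duplicate, always a binder
      expect_false(any(mut$peptide %in% km$peptide))
      expect_false(anyDuplicated(c(mut$peptide, wt$peptide)) > 0)
      expect_true(all(mut$ic50 < 500))
      # mutated_position is consistent with the observed difference
      pos <- mapply(function(a, b) which(utf8ToInt(a) != utf8ToInt(b)),
                    mut$peptide, mut$partner)
      expect_equal(unname(pos), mut$mutated_position)
    }
  }
  # reproducible and permutation-invariant
  a <- build_mutant_library(wt, km, m, seed = 11)
  b <- build_mutant_library(wt[sample(nrow(wt)), ], km, m, seed = 11)
  expect_identical(a, b)
})

test_that("a wild type whose admissible neighbours are all proteome k-mers is excluded", {
  m <- permissive_model(k = 2)
  # proteome containing every 2-mer neighbour of "AK"
  neighbors <- c(vapply(setdiff(rownames(m$weights), "A"),
                        function(a) paste0(a, "K"), character(1)),
                 vapply(setdiff(rownames(m$weights), "K"),
                        function(a) paste0("A", a), character(1)))
  suppressMessages(
    mut <- build_mutant_library(data.frame(peptide = "AK"),
                                proteome_kmers = c(neighbors, "AK"),
                                affinity = m, seed = 1)
  )
  expect_equal(nrow(mut), 0L)
  expect_equal(attr(mut, "unmutable"), "AK")
  # library-only scope is laxer: the same wild type becomes mutable
  mut2 <- build_mutant_library(data.frame(peptide = "AK"),
                               affinity = m, exclude_scope = "library",
                               seed = 1)
  expect_equal(nrow(mut2), 1L)
})

test_that("controls append with their roles and reject duplicates", {
  lib <- data.frame(peptide = c("AAAAAAAA", "CCCCCCCC"),
                    role = "wild_type", stringsAsFactors = FALSE)
  out <- add_controls(lib)
  expect_equal(nrow(out), 2 + 8)
  expect_true("SIINFEKL" %in% out$peptide)
  # controls may differ in length from the library (9-mer among 8-mers)
  expect_true("MSIIFFLPL" %in% out$peptide)
  expect_equal(sum(out$role == "control_immunogenic"), 3L)
  expect_equal(sum(out$role == "control_nonimmunogenic"), 5L)
  # duplicate control errors
  lib2 <- data.frame(peptide = "SIINFEKL", role = "wild_type")
  expect_error(add_controls(lib2), "already in the library")
  expect_error(
    add_controls(lib, data.frame(peptide = "AAAAAAAC", role = "wild_type")),
    "roles"
  )
})

test_that("library characterization bins shifts, positions and classes conservatively", {
  wt <- data.frame(peptide = c("SNFVSAGI", "AAAAAAAA"),
                   ic50 = c(200, 300), stringsAsFactors = FALSE)
  mut <- data.frame(peptide = c("SNFVFAGI", "AAAAKAAA"),
                    ic50 = c(260, 80), role = "mutant",
                    partner = c("SNFVSAGI", "AAAAAAAA"),
                    mutated_position = c(5L, 5L), stringsAsFactors = FALSE)
  ch <- characterize_library(wt, mut)
  # |260-200| = 60 within 100 nM; |80-300| = 220 in (100,250]
  expect_equal(unname(ch$affinity_delta_histogram[1]), 1L)
  expect_equal(unname(ch$affinity_delta_histogram[2]), 1L)
  expect_equal(unname(ch$position_histogram["5"]), 2L)
  # S->F is polar->hydrophobic; A->K is hydrophobic->charged
  expect_equal(ch$substitution_class_matrix["polar", "hydrophobic"], 1L)
  expect_equal(ch$substitution_class_matrix["hydrophobic", "charged"], 1L)
  # conservation: all three statistics total the mutant count
  expect_equal(sum(ch$affinity_delta_histogram), nrow(mut))
  expect_equal(sum(ch$position_histogram), nrow(mut))
  expect_equal(sum(ch$substitution_class_matrix), nrow(mut))
  # empty mutant library -> all-zero histograms
  ch0 <- characterize_library(wt, mut[0, ])
  expect_true(all(ch0$affinity_delta_histogram == 0))
  # orphan mutant errors
  expect_error(
    characterize_library(wt[1, ], mut),
    "no wild-type partner"
  )
})
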