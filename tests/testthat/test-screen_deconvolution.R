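test_that("counting matches the brute-force Hamming oracle on random pools", {
  withr::with_seed(42, {
    for (trial in 1:3) {
      n_ref <- sample(20:100, 1)
      L <- 24L
      refs <- unique(vapply(seq_len(n_ref), function(i) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
      }, character(1)))
      names(refs) <- sprintf("mg%03d", seq_along(refs))
      # reads: perfect copies plus mutated copies (0-2 errors)
      reads <- unlist(lapply(sample(names(refs), 200, replace = TRUE),
                             function(id) {
        rd <- refs[[id]]
        k <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
        if (k > 0) {
          pos <- sample.int(L, k)
          ch <- strsplit(rd, "")[[1]]
          ch[pos] <- vapply(ch[pos], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
          rd <- paste(ch, collapse = "")
        }
        rd
      }))
      for (mm in 0:1) {
        got <- count_minigenes(reads, refs, max_mismatch = mm)
        want <- brute_force_count(reads, refs, max_mismatch = mm)
        expect_equal(setNames(got$count, got$minigene), want + 0)
        # conservation: mapped + unmapped = total
        expect_equal(attr(got, "mapped") + attr(got, "unmapped"),
                     attr(got, "total_reads"))
      }
    }
  })
})

test_that("mismatch threshold and ambiguity discarding behave as specified", {
  refs <- c(a = "ACGTACGTACGT", b = "ACGTACGTACGA")
  # error-free reads of one minigene count only for it
  got <- count_minigenes(rep(refs[["a"]], 100), refs, max_mismatch = 0)
  expect_equal(setNames(got$count, got$minigene), c(a = 100, b = 0))
  # one substitution: unmapped at 0 mismatches, counted at 1
  rd <- "ACGTACGTACCT"  # distance 1 from a, distance 2 from b
  expect_equal(sum(count_minigenes(rd, refs, 0)$count), 0)
  got1 <- count_minigenes(rd, refs, 1)
  expect_equal(setNames(got1$count, got1$minigene), c(a = 1, b = 0))
  # equidistant read (distance 1 from both) is discarded as ambiguous
  amb <- "ACGTACGTACGG"
  got2 <- count_minigenes(amb, refs, 1)
  expect_equal(sum(got2$count), 0)
  expect_equal(attr(got2, "ambiguous"), 1L)
  expect_error(count_minigenes(rd, character()), "empty reference")
  expect_warning(z <- count_minigenes(character(), refs), "no reads")
  expect_equal(sum(z$count), 0)
})

test_that("FASTQ round trip recovers simulated counts exactly without errors", {
  pool <- build_oligo_pool(c("SIINFEKL", "FEKIILSN", "SNFVSAGI"), seed = 3)
  counts <- setNames(c(120, 40, 7), pool$peptide)
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(pool, counts, error_rate = 0, read_length = 30, seed = 1,
                 path = fq)
  got <- count_minigenes(fq, pool, max_mismatch = 0)
  expect_equal(setNames(got$count, got$minigene), counts + 0)
  # with substitution errors, 1-mismatch counting recovers within the
  # binomial bound on reads carrying >= 2 errors
  rd <- simulate_reads(pool, counts * 10, error_rate = 0.01,
                       read_length = 24, seed = 2)
  got1 <- count_minigenes(rd$read, pool, max_mismatch = 1)
  p2 <- 1 - (0.99^24 + 24 * 0.01 * 0.99^23)  # P(>=2 errors per read)
  lost <- sum(counts * 10) - sum(got1$count)
  expect_lte(lost, sum(counts * 10) * (p2 + 4 * sqrt(p2 / sum(counts))))
  expect_gte(lost, 0)
})

test_that("relative abundance normalises to 1 and is order-invariant", {
  ab <- relative_abundance(as_count_table(c(a = 1, b = 1)))
  expect_equal(ab$abundance, c(0.5, 0.5))
  ct <- as_count_table(c(x = 3, y = 1, z = 0))
  ab2 <- relative_abundance(ct)
  expect_equal(sum(ab2$abundance), 1, tolerance = 1e-12)
  perm <- as_count_table(c(z = 0, x = 3, y = 1))
  ab3 <- relative_abundance(perm)
  expect_equal(setNames(ab3$abundance, ab3$minigene)[c("x", "y", "z")],
               setNames(ab2$abundance, ab2$minigene)[c("x", "y", "z")])
  expect_error(relative_abundance(as_count_table(c(a = 0))), "zero mapped")
  # a single cell in a 5e6-cell-equivalent sample is 0.00002%
  one <- relative_abundance(as_count_table(c(rare = 1, rest = 5e6 - 1)))
  expect_equal(100 * one$abundance[one$minigene == "rare"], 2e-5)
})

test_that("representation QC enforces the fold-coverage minimum", {
  qc <- qc_representation(0, 5000, 1000)
  expect_equal(qc$required, 5e6)  # 1000x a 5000-member library
  expect_false(qc_representation(4999999, 5000, 1000)$pass)
  expect_true(qc_representation(5000000, 5000, 1000)$pass)
})

test_that("cells at injection scale abundance by the inoculum", {
  est <- estimate_cells_at_injection(c(5e-5, 1.3e-4, 0), 5e6)
  expect_equal(est$cells, c(250, 650, 0))
  expect_equal(est$cells_nearest, c(250, 650, 0))
})

test_that("comparing a screen against itself is all-neutral", {
  withr::with_seed(8, {
    counts <- setNames(rpois(50, 2000) + 1, sprintf("m%02d", 1:50))
  })
  x <- abundance_of(counts)
  cmp <- compare_screens(x, x)
  expect_true(all(cmp$lfc == 0))
  expect_true(all(cmp$call == "neutral"))
})

test_that("an induced 8-fold drop is called depleted on a toy table", {
  pre <- abundance_of(c(a = 250000, b = 250000, c = 500000))
  # a falls 8-fold, others rescale
  post <- abundance_of(c(a = 31250, b = 250000, c = 500000))
  cmp <- compare_screens(pre, post, lfc_threshold = 1)
  lfc_a <- cmp$lfc[cmp$minigene == "a"]
  # log2 of the renormalised ratio 0.04/0.25 = -2.64, within pseudocount
  expect_equal(lfc_a, log2(0.04 / 0.25), tolerance = 0.01)
  expect_equal(cmp$call[cmp$minigene == "a"], "depleted")
  expect_true(all(cmp$call[cmp$minigene != "a"] == "neutral"))
})

test_that("the abundance floor guards depletion calls for rare minigenes", {
  nm <- sprintf("m%03d", 1:20)
  pre_counts <- setNames(rep(5e4, 20), nm)
  pre_counts["m001"] <- 50       # 5e-5 < 1e-4 floor
  post_counts <- pre_counts
  post_counts["m001"] <- 0       # total drop-out of the rare minigene
  cmp <- compare_screens(abundance_of(pre_counts), abundance_of(post_counts))
  # below the floor: stochastic drop-out, not a depletion call
  expect_equal(cmp$call[cmp$minigene == "m001"], "neutral")
  # the same drop above the floor is called
  pre_counts["m001"] <- 5e4
  post_counts["m001"] <- 0
  cmp2 <- compare_screens(abundance_of(pre_counts), abundance_of(post_counts))
  expect_equal(cmp2$call[cmp2$minigene == "m001"], "depleted")
})

test_that("per-animal mode returns one comparison per tumor replicate", {
  withr::with_seed(3, {
    pre <- lapply(1:3, function(i) {
      abundance_of(setNames(rpois(30, 1000) + 1, sprintf("m%02d", 1:30)))
    })
    post <- lapply(1:2, function(i) {
      abundance_of(setNames(rpois(30, 1000) + 1, sprintf("m%02d", 1:30)))
    })
  })
  per <- compare_screens(pre, post, per_animal = TRUE)
  expect_length(per, 2L)
  avg <- compare_screens(pre, post)
  expect_s3_class(avg, "screen_comparison")
  # library mismatch errors
  bad <- abundance_of(setNames(1:5, paste0("x", 1:5)))
  expect_error(compare_screens(pre, bad), "same minigene library")
})
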