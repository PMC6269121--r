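test_that("simulated proteomes are reproducible and composition-faithful", {
  p1 <- simulate_proteome(5, 100, seed = 3)
  expect_identical(simulate_proteome(5, 100, seed = 3), p1)
  expect_false(identical(simulate_proteome(5, 100, seed = 4), p1))
  expect_length(p1, 5L)
  # zero weight on a residue excludes it entirely
  comp <- setNames(rep(1, 20), rownames(toy_affinity_model()$weights))
  comp["W"] <- 0
  p2 <- simulate_proteome(5, 200, composition = comp / sum(comp), seed = 1)
  expect_false(any(grepl("W", p2)))
  # FASTA round trip feeds the design pipeline
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(p1, path)
  km_file <- enumerate_kmers(path, 8)
  km_mem <- enumerate_kmers(p1, 8)
  expect_equal(km_file$peptide, km_mem$peptide)
})

test_that("transduction follows Poisson statistics with the closed-form multi fraction", {
  # closed form: (1 - e^-m - m e^-m) / (1 - e^-m), evaluated exactly
  expect_equal(multi_integration_fraction(0.3), 0.1425112, tolerance = 1e-6)
  # limit: vanishing MOI -> single integrations only
  expect_lt(multi_integration_fraction(1e-6), 1e-5)
  tr <- simulate_transduction(2e4, moi = 0.3, library_size = 100, seed = 9)
  expect_equal(tr$expected_multi_fraction, multi_integration_fraction(0.3))
  # observed fraction within 4 binomial SEs of the closed form
  se <- sqrt(0.1425 * 0.8575 / tr$n_transduced)
  expect_lt(abs(tr$observed_multi_fraction - 0.1425112), 4 * se)
  # empty assignment
  expect_equal(simulate_transduction(0, 0.3, seed = 1)$n_transduced, 0L)
})

test_that("null screens reproduce pre abundances within multinomial error", {
  sim <- simulate_screen(100, depth = 1e6, n_pre = 2, n_post = 2, seed = 21)
  expect_identical(
    simulate_screen(100, depth = 1e6, n_pre = 2, n_post = 2, seed = 21)$pre_counts,
    sim$pre_counts
  )
  ab <- relative_abundance(sim$pre_counts[[1]])
  p <- sim$pre_abundance
  # each abundance within 4 SEs of the generative frequency
  se <- sqrt(p * (1 - p) / 1e6)
  expect_true(all(abs(ab$abundance - p) < 4 * se + 1e-9))
})

test_that("clonal-fraction gating switches depletion on and off in expectation", {
  n <- 50
  pre <- rep(1, n)
  pre[1] <- 0.05 * (n - 2) / (1 - 0.05 - 0.001)  # abundant target
  pre[2] <- 0.001 * (n - 2) / (1 - 0.05 - 0.001) # rare target, below gate
  pre <- pre / sum(pre)
  surv <- rep(1, n); surv[1:2] <- 0.1
  sim <- simulate_screen(n, pre_abundance = pre, survival = surv,
                         clonal_fraction_threshold = 0.01, depth = 1e6,
                         seed = 31)
  cmp <- compare_screens(lapply(sim$pre_counts, relative_abundance),
                         lapply(sim$post_counts, relative_abundance))
  lfc1 <- cmp$lfc[cmp$minigene == sim$library[1]]
  lfc2 <- cmp$lfc[cmp$minigene == sim$library[2]]
  # above the gate: ~10-fold loss (renormalisation shifts it slightly)
  expect_lt(lfc1, -2.5)
  expect_equal(cmp$call[cmp$minigene == sim$library[1]], "depleted")
  # below the gate: no depletion in expectation
  expect_gt(lfc2, -0.5)
  expect_equal(cmp$call[cmp$minigene == sim$library[2]], "neutral")
})

test_that("depletion recovery on gated screens meets recall and false-call bounds", {
  n <- 300
  surv <- rep(1, n); surv[1:30] <- 0.1
  sim <- simulate_screen(n, survival = surv, depth = 1e6, seed = 5)
  cmp <- compare_screens(lapply(sim$pre_counts, relative_abundance),
                         lapply(sim$post_counts, relative_abundance))
  truth <- cmp$minigene %in% sim$library[1:30]
  eligible <- cmp$pre >= 1e-4
  expect_gte(mean(cmp$call[truth & eligible] == "depleted"), 0.9)
  expect_lte(mean(cmp$call[!truth & eligible] == "depleted"), 0.05)
})

test_that("two-color simulation encodes the generative fold change exactly", {
  # zero noise: the measured log10 FC is exactly the kill effect above the
  # gate and 0 below it
  tc <- simulate_two_color(threshold = 1, kill_log10fc = -1.5,
                           mouse_noise_sd = 0, seed = 2)
  res <- analyze_mixture_experiment(tc)
  above <- res$fraction_d0_pct >= 1
  expect_equal(res$mean_log10fc[above], rep(-1.5, sum(above)))
  expect_equal(res$mean_log10fc[!above], rep(0, sum(!above)))
  # kill 0: all fold changes centred at 1
  tc0 <- simulate_two_color(kill_log10fc = 0, mouse_noise_sd = 0.1,
                            n_mice = 50, seed = 3)
  res0 <- analyze_mixture_experiment(tc0)
  expect_true(all(abs(res0$mean_log10fc) < 0.1))
  # reproducibility
  expect_identical(simulate_two_color(seed = 4), simulate_two_color(seed = 4))
})

test_that("simulated reads round-trip through counting and abundance", {
  pool <- build_oligo_pool(c("SIINFEKL", "FEKIILSN", "SNFVSAGI",
                             "TWHRYHLL"), seed = 11)
  withr::with_seed(13, {
    freq <- c(0.5, 0.3, 0.15, 0.05)
    counts <- setNames(rmultinom(1, 2e4, freq)[, 1], pool$peptide)
  })
  rd <- simulate_reads(pool, counts, error_rate = 0, seed = 1)
  got <- count_minigenes(rd$read, pool, max_mismatch = 0)
  expect_equal(setNames(got$count, got$minigene), counts + 0)
  ab <- relative_abundance(got)
  # recovered frequencies within 3 multinomial SEs of the generative ones
  se <- sqrt(0.5 * 0.5 / 2e4)
  expect_true(all(abs(ab$abundance - c(0.5, 0.3, 0.15, 0.05)) < 3 * se))
  # zero counts -> empty read set
  expect_equal(nrow(simulate_reads(pool, setNames(0, "SIINFEKL"))), 0L)
})
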