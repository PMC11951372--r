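test_that("observed log-likelihood matches hand and brute-force values", {
  # unambiguous heterozygote, uniform frequencies: log(2 * 0.25)
  g <- gt(list(lc("A", "B")))
  pi <- hap_freq(c(A = 0.5, B = 0.5))
  expect_equal(observed_loglik(pi, g), log(0.5))

  # an individual compatible with every unordered diplotype: total mass 1
  g_all <- gt(list(lc(c("A", "B"), c("A", "B"))))
  expect_equal(observed_loglik(hap_freq(c(A = 0.3, B = 0.7)), g_all), 0)

  # three individuals, mixed ambiguity, against the brute-force oracle
  g3 <- gt(list(lc("A", "A")),
           list(lc(c("A", "B"), "B")),
           list(lc(c("A", "B"), c("A", "B"))))
  pi <- hap_freq(c(A = 0.3, B = 0.7))
  expect_equal(observed_loglik(pi, g3), brute_force_loglik(pi, g3))

  # zero support is reported with the individual
  expect_error(observed_loglik(hap_freq(c(A = 1, B = 0)),
                               gt(list(lc("B", "B")))),
               "zero support")
})

test_that("E-step counts match hand computation and conserve diploidy", {
  pi <- hap_freq(c(A = 0.5, C = 0.5))
  # unambiguous heterozygote: one count per haplotype
  A1 <- e_step_counts(pi, gt(list(lc("A", "C"))))
  expect_equal(as.numeric(A1), c(1, 1))

  # {A/C}+{A/C}: posterior 1/4, 1/2, 1/4 over AA, AC, CC gives doses (1, 1)
  A2 <- e_step_counts(pi, gt(list(lc(c("A", "C"), c("A", "C")))))
  expect_equal(as.numeric(A2), c(1, 1))

  # conservation on randomized instances
  set.seed(3)
  for (k in 1:10) {
    h <- sample(c("A", "B", "C"), 8, replace = TRUE)
    h2 <- sample(c("A", "B", "C"), 8, replace = TRUE)
    g <- geno_from_dips(h, h2)
    pi <- hap_freq(c(A = 0.2, B = 0.5, C = 0.3))
    A <- e_step_counts(pi, g)
    expect_equal(unname(rowSums(A)), rep(2, 8))
    expect_true(all(A >= 0))
  }
})

test_that("M-step profiles fixed frequencies and rescales the rest", {
  # complete data, no profiling: empirical relative frequencies
  counts <- matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B")))
  expect_equal(m_step_htf(counts), c(A = 0.75, B = 0.25))

  # profiled CLPS at 0.1 with raw free mass (0.6, 0.4) -> (0.54, 0.36, 0.10)
  counts <- matrix(c(1.2, 0.8, 0), 1, 3,
                   dimnames = list(NULL, c("h1", "h2", "CLPS")))
  out <- m_step_htf(counts, profiled = "CLPS",
                    pi_prev = c(h1 = 0.5, h2 = 0.4, CLPS = 0.1))
  expect_equal(out, c(h1 = 0.54, h2 = 0.36, CLPS = 0.10))

  # uniform counts, nothing profiled: uniform frequencies
  counts <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(m_step_htf(counts), c(A = 0.5, B = 0.5))

  expect_error(m_step_htf(counts, profiled = c("A", "B"),
                          pi_prev = c(A = 0.6, B = 0.4)),
               "entire probability mass")
})

test_that("rare-haplotype collapsing pools mass and honors protection", {
  cfg <- em_config(collapse_threshold = 1e-7)
  pi <- hap_freq(c(h1 = 0.6, h2 = 0.4))
  expect_identical(collapse_rare(pi, cfg), pi)

  pi <- hap_freq(c(h1 = 0.6, h2 = 0.4 - 2e-8, h3 = 2e-8))
  out <- collapse_rare(pi, cfg)
  expect_equal(names(out), c("h1", "h2", "CLPS"))
  expect_equal(as.numeric(out), c(0.6, 0.4 - 2e-8, 2e-8))
  expect_equal(attr(out, "clps_members"), c(h3 = 2e-8))
  expect_equal(sum(out), 1)

  cfg_p <- em_config(collapse_threshold = 1e-7,
                     protected_haplotypes = "h3")
  expect_identical(collapse_rare(pi, cfg_p), pi)
})

test_that("profile EM recovers empirical frequencies for unambiguous data", {
  # single-locus calls carry no phase ambiguity at all, so the EM must hit
  # the empirical allele frequencies immediately
  set.seed(5)
  h1 <- sample(c("A", "B", "C"), 40, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  h2 <- sample(c("A", "B", "C"), 40, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  g <- geno_from_dips(h1, h2)
  fit <- run_profile_em(g)
  emp <- table(factor(c(h1, h2)))
  expect_equal(as.numeric(fit$freq[names(emp)]),
               as.numeric(emp) / sum(emp), tolerance = 1e-12)
  expect_true(fit$converged)
  expect_lte(nrow(fit$trace), 3)
})

test_that("the observed log-likelihood is monotone when profiling is off", {
  set.seed(8)
  spec <- scenario_poc("A", ld_level = 0.4, ambiguity_level = 0.8, N = 120)
  dat <- simulate_dataset(spec, seed = 21)
  fit <- run_profile_em(dat$genotypes, em_config(collapse_threshold = 0,
                                                 max_iter = 2000))
  expect_true(all(diff(fit$trace$loglik) >= -1e-9))
})

test_that("profile EM matches an exhaustive simplex grid search", {
  g <- gt(list(lc("A", "A")), list(lc("A", "B")),
          list(lc(c("A", "B"), c("A", "B"))), list(lc("B", "B")),
          list(lc(c("A", "B"), "A")))
  fit <- run_profile_em(g, em_config(convergence_tol = 1e-12,
                                     max_iter = 5000))
  ll_em <- observed_loglik(fit$freq, g)
  ll_grid <- grid_search_loglik(g)
  expect_lt(abs(ll_em - ll_grid), 1e-6)
})

test_that("locus addition seeds the extended universe with product mass", {
  set.seed(9)
  # two independent loci, no ambiguity
  h1 <- paste(sample(c("A", "B"), 300, TRUE, c(0.6, 0.4)),
              sample(c("E", "F"), 300, TRUE, c(0.3, 0.7)), sep = "-")
  h2 <- paste(sample(c("A", "B"), 300, TRUE, c(0.6, 0.4)),
              sample(c("E", "F"), 300, TRUE, c(0.3, 0.7)), sep = "-")
  g <- geno_from_dips(h1, h2)
  cfg <- em_config()
  fit1 <- run_profile_em(subset_loci_for_test(g, 1), cfg)
  # single-locus start equals the allele-frequency EM on that locus
  emp1 <- table(factor(c(substr(h1, 1, 1), substr(h2, 1, 1))))
  expect_equal(as.numeric(fit1$freq[names(emp1)]),
               as.numeric(emp1) / sum(emp1), tolerance = 1e-9)

  fit2 <- add_locus(fit1, g, cfg)
  expect_equal(sum(fit2$freq), 1, tolerance = 1e-12)
  # double heterozygotes keep phase ambiguity, so the joint is estimated;
  # under independence it must sit close to the empirical joint
  emp2 <- table(factor(c(h1, h2)))
  expect_lt(max(abs(as.numeric(fit2$freq[names(emp2)]) -
                      as.numeric(emp2) / sum(emp2))), 0.03)
  # independence: joint close to the product of the margins (MC error)
  pA <- sum(fit2$freq[startsWith(names(fit2$freq), "A-")])
  pE <- sum(fit2$freq[endsWith(names(fit2$freq), "-E")])
  expect_lt(abs(fit2$freq[["A-E"]] - pA * pE), 0.05)
})

test_that("frequencies stay on the simplex at every iteration", {
  spec <- scenario_poc("A", ld_level = 0.4, ambiguity_level = 0.4, N = 100)
  dat <- simulate_dataset(spec, seed = 4)
  fit <- run_profile_em(dat$genotypes)
  for (p in fit$pi_history) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})
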