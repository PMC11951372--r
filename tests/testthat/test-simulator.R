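test_that("the true haplotype distribution preserves every per-locus marginal", {
  specs <- list(scenario_main(1, 1), scenario_main(2, 2),
                scenario_poc("A"), scenario_poc("B"))
  for (base in specs) for (lv in c(0, 0.4, 0.8)) {
    sp <- base
    sp$ld_level <- lv
    htf <- build_true_htfs(sp)
    al <- do.call(rbind, strsplit(names(htf), "-", fixed = TRUE))
    for (l in seq_along(sp$af)) {
      marg <- tapply(as.numeric(htf), al[, l], sum)
      expect_equal(as.numeric(marg[names(sp$af[[l]])]),
                   as.numeric(sp$af[[l]]), tolerance = 1e-10)
    }
  }
})

test_that("zero LD gives the product distribution, full LD full coupling", {
  sp <- scenario_poc("A", ld_level = 0)
  htf <- build_true_htfs(sp)
  for (h in names(htf)) {
    al <- hap_alleles(h)
    expect_equal(htf[[h]],
                 sp$af$g1[[al[1]]] * sp$af$g2[[al[2]]] * sp$af$g3[[al[3]]],
                 tolerance = 1e-12)
  }
  # l = 1 with 0.5/0.5 margins: perfect coupling
  sp2 <- scenario_spec(af = list(g1 = c(A = 0.5, B = 0.5),
                                 g2 = c(E = 0.5, F = 0.5)),
                       effects = c(A = 0, B = 0, E = 0, F = 0),
                       ld_pairs = list(c("A", "E")), ld_level = 1)
  htf2 <- build_true_htfs(sp2)
  expect_equal(htf2[["A-E"]], 0.5, tolerance = 1e-12)
})

test_that("LD cells hit the standardized target exactly", {
  sp <- scenario_main(1, 1, ld_level = 0.4)
  htf <- build_true_htfs(sp)
  al <- do.call(rbind, strsplit(names(htf), "-", fixed = TRUE))
  # oracle: aggregate P(B at locus 1, F at locus 2) and compare with the
  # constrained-margin construction P(B)P(F) + 0.4 * Dmax
  pBF <- sum(htf[al[, 1] == "B" & al[, 2] == "F"])
  pB <- sp$af$g1[["B"]]
  pF <- sp$af$g2[["F"]]
  dmax <- min(pB * (1 - pF), (1 - pB) * pF)
  expect_equal(pBF, pB * pF + 0.4 * dmax, tolerance = 1e-10)
  # same for the cross-locus pairs D-G and E-H
  pDG <- sum(htf[al[, 1] == "D" & al[, 3] == "G"])
  pD <- sp$af$g1[["D"]]; pG <- sp$af$g3[["G"]]
  expect_equal(pDG, pD * pG + 0.4 * min(pD * (1 - pG), (1 - pD) * pG),
               tolerance = 1e-8)
  expect_error(build_true_htfs(
    scenario_spec(af = list(g1 = c(A = 1), g2 = c(E = 0.5, F = 0.5)),
                  effects = c(A = 0, E = 0, F = 0),
                  ld_pairs = list(c("A", "E")), ld_level = 0.5)),
    NA)  # degenerate margin is feasible (Dmax = 0)
})

test_that("diplotype draws are reproducible and match their distribution", {
  htf <- build_true_htfs(scenario_poc("A"))
  d1 <- draw_diplotypes(htf, 500, seed = 77)
  d2 <- draw_diplotypes(htf, 500, seed = 77)
  expect_identical(d1, d2)

  one <- hap_freq(c(`A-E-G` = 1))
  dp <- draw_diplotypes(one, 10, seed = 1)
  expect_true(all(dp$h1 == "A-E-G" & dp$h2 == "A-E-G"))

  big <- draw_diplotypes(htf, 2000, seed = 13)
  emp <- table(factor(c(big$h1, big$h2), levels = names(htf))) / 4000
  se <- sqrt(as.numeric(htf) * (1 - as.numeric(htf)) / 4000)
  expect_true(all(abs(as.numeric(emp) - as.numeric(htf)) <= 4 * se + 1e-12))
})

test_that("ambiguity injection is a sound MAR coarsening", {
  spec <- scenario_poc("A", ambiguity_level = 1)
  htf <- build_true_htfs(spec)
  dips <- draw_diplotypes(htf, 50, seed = 3)
  g <- inject_ambiguity(dips, spec, seed = 4)
  # saturation: every group-member call became its group's set
  for (i in seq_len(10)) for (l in 1:3) for (k in 1:2) {
    cp <- g$calls[[i]][[l]][[k]]
    a_true <- hap_alleles(if (k == 1) dips$h1[i] else dips$h2[i])[l]
    if (!allele_is_neg(a_true)) expect_gt(length(cp), 1)
    # the true allele always stays in the call's set
    expect_true(a_true %in% cp)
  }

  # level 0: only phase (and CNV) ambiguity remains
  spec0 <- scenario_poc("A", ambiguity_level = 0)
  g0 <- inject_ambiguity(dips, spec0, seed = 5)
  expect_true(all(vapply(g0$calls, function(ci)
    all(lengths(unlist(ci, recursive = FALSE)) == 1L), logical(1))))

  # the true diplotype is never removed from the compatibility set
  specm <- scenario_poc("A", ambiguity_level = 0.4)
  gm <- inject_ambiguity(dips, specm, seed = 6)
  for (i in seq_len(25)) {
    d <- enumerate_compatible_diplotypes(gm$calls[[i]])
    expect_true(any(d$h1 == dips$h1[i] & d$h2 == dips$h2[i]))
  }
})

test_that("the injected ambiguity rate matches its level", {
  spec <- scenario_poc("A", ambiguity_level = 0.4)
  htf <- build_true_htfs(spec)
  dips <- draw_diplotypes(htf, 2000, seed = 8)
  g <- inject_ambiguity(dips, spec, seed = 9)
  eligible <- 0L; ambiguous <- 0L
  for (i in seq_along(g$ids)) for (l in 1:3) for (k in 1:2) {
    a_true <- hap_alleles(if (k == 1) dips$h1[i] else dips$h2[i])[l]
    if (allele_is_neg(a_true)) next
    eligible <- eligible + 1L
    if (length(g$calls[[i]][[l]][[k]]) > 1) ambiguous <- ambiguous + 1L
  }
  rate <- ambiguous / eligible
  se <- sqrt(0.4 * 0.6 / eligible)
  expect_lt(abs(rate - 0.4), 4 * se)
})

test_that("outcome simulation obeys the stated generating models", {
  spec <- scenario_poc("A")
  spec$effects[] <- 0
  htf <- build_true_htfs(spec)
  dips <- draw_diplotypes(htf, 2000, seed = 11)
  out <- simulate_outcome(dips, spec, names(htf), seed = 12)
  expect_lt(abs(mean(out$y)), 4 / sqrt(2000))
  expect_lt(abs(sd(out$y) - 1), 0.06)

  # binomial null model: baseline event probability about 15%
  specb <- scenario_poc("A", family = "binomial")
  specb$effects[] <- 0
  outb <- simulate_outcome(dips, specb, names(htf), seed = 13)
  p0 <- plogis(-1.75)
  expect_lt(abs(mean(outb$y) - p0), 4 * sqrt(p0 * (1 - p0) / 2000))

  # a single allele effect is recovered by regression on the true design
  spec1 <- scenario_poc("A")
  spec1$effects[] <- 0
  spec1$effects[["A"]] <- 5
  out1 <- simulate_outcome(dips, spec1, names(htf), seed = 14)
  co <- lm.fit(out1$X, out1$y)$coefficients
  expect_equal(unname(co["A"]), 5, tolerance = 0.05)
})

test_that("haplotype effects double up on top of allele effects", {
  spec <- scenario_poc("B")
  htf <- build_true_htfs(spec)
  dips <- draw_diplotypes(htf, 50, seed = 15)
  out <- simulate_outcome(dips, spec, names(htf), seed = 16)
  expect_true(all(c("A-E", "F-H") %in% names(out$beta)))
  expect_equal(out$beta[["A-E"]],
               spec$effects[["A"]] + spec$effects[["E"]])
  expect_equal(out$beta[["F-H"]],
               spec$effects[["F"]] + spec$effects[["H"]])
})

test_that("the scenario grid reproduces the study's factor totals", {
  expect_equal(nrow(build_scenario_grid("x", factors = list(a = 1))), 1L)

  grid <- build_scenario_grid(default_base_scenarios())
  expect_equal(nrow(grid), 864L)
  expect_false(anyDuplicated(grid$scenario_id) > 0)

  poc_grid <- build_scenario_grid("A", factors = list(
    ld_level = c(0, 0.4, 0.8), ambiguity_level = c(0, 0.4, 0.8)))
  expect_equal(nrow(poc_grid), 9L)

  expect_error(build_scenario_grid(c("a", "a")), "duplicate")
})
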