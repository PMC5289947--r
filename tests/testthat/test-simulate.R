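test_that("parameter validation rejects out-of-range rates and concentrations", {
  expect_error(ensemble_params(a1 = 1.2), "a1")
  expect_error(ensemble_params(a1 = 0.4, kappa = 0), "kappa")
  expect_error(ensemble_params(a1 = 0.4, kappa = -3), "kappa")
  expect_error(ensemble_params(a1 = 0.4, n_neurons = 0), "n_neurons")
  expect_error(expected_category_probs(ensemble_params(a1 = 0.4), "A20A"),
               "requires parameter")
})

test_that("closed-form category probabilities match the forward model", {
  p <- expected_category_probs(
    ensemble_params(a1 = 0.4023, r = 0.8128, b = 0.0760), "A20A")
  expect_equal(unname(round(p, 4)),
               c(0.5523, 0.0454, 0.0753, 0.3270))
  expect_equal(sum(p), 1, tolerance = 1e-15)

  asac <- expected_category_probs(ensemble_params(a1 = 0.3905), "ASAC")
  expect_equal(unname(asac["beta"]), 0.3905)
  expect_equal(unname(asac[c("gamma", "delta")]), c(0, 0))

  cc <- expected_category_probs(ensemble_params(f0 = 0.0689), "CC")
  expect_equal(unname(cc["beta"]), 0.0689)

  silent <- expected_category_probs(
    ensemble_params(a1 = 0, r = 0.5, b = 0), "A20A")
  expect_equal(unname(silent), c(1, 0, 0, 0))
})

test_that("simulated counts are conserved, reproducible and hit deterministic limits", {
  p <- ensemble_params(a1 = 0.4, r = 0.8, b = 0.08, n_neurons = 250)
  set.seed(5)
  one <- simulate_animal(p, "A20A")
  expect_equal(one$alpha + one$beta + one$gamma + one$delta, 250)

  coh1 <- simulate_cohort(p, "A20A", n_animals = 4, seed = 99)
  coh2 <- simulate_cohort(p, "A20A", n_animals = 4, seed = 99)
  expect_identical(coh1, coh2)
  expect_equal(anyDuplicated(coh1$animal_id), 0L)

  all_delta <- simulate_cohort(ensemble_params(a1 = 1, r = 1, b = 0,
                                               n_neurons = 100),
                               "A20A", n_animals = 2, seed = 1)
  expect_true(all(all_delta$delta == 100))
})

test_that("empirical category fractions converge to the closed form at large n", {
  p <- ensemble_preset("WT_A20A", n_neurons = 1e6)
  # neutralise animal-level variability so the binomial SE is the right yardstick
  p$kappa <- 1e9
  set.seed(23)
  sim <- simulate_animal(p, "A20A")
  probs <- expected_category_probs(ensemble_preset("WT_A20A"), "A20A")
  frac <- unlist(sim[, c("alpha", "beta", "gamma", "delta")]) / 1e6
  se <- sqrt(probs * (1 - probs) / 1e6)
  expect_true(all(abs(frac - probs) < 4 * se + 1e-4))
})

test_that("cohort-mean epoch-1 fraction concentrates on the calibrated sparsity", {
  sim <- simulate_cohort("WT_A20A", n_animals = 200, seed = 31)
  e1 <- vapply(seq_len(nrow(sim)), function(i) e1_fraction(obs_counts(sim, i)),
               numeric(1))
  se <- stats::sd(e1) / sqrt(length(e1))
  expect_lt(abs(mean(e1) - 0.4023), 3 * se)
})

test_that("concentration calibration inverts the Beta variance formula", {
  k <- calibrate_concentration(target_sem = 2.16, n_animals = 4,
                               mean = 0.3905)
  sd2 <- (0.0216 * 2)^2
  expect_equal(k, 0.3905 * (1 - 0.3905) / sd2 - 1, tolerance = 1e-12)
  expect_equal(k, 126.5, tolerance = 1e-3)

  expect_error(calibrate_concentration(60, 4, 0.5), "infeasible")
  expect_error(calibrate_concentration(0, 4, 0.5), "positive")
  expect_error(calibrate_concentration(1, 1, 0.5), "n_animals")
})

test_that("presets carry provenance and reproduce the published regime", {
  ps <- ensemble_presets()
  expect_setequal(names(ps),
                  c("WT_A20A", "TS_A20A", "WT_ASAC", "TS_ASAC",
                    "WT_CC", "TS_CC", "WT_AX4_A20A", "TS_AX4_A20A"))
  for (p in ps) {
    expect_false(is.null(attr(p, "provenance")))
    expect_true(attr(p, "paradigm") %in% catfish_paradigms)
  }
  expect_match(attr(ps$WT_AX4_A20A, "provenance"), "subtraction")

  wt <- ps$WT_A20A
  expect_equal(c(wt$a1, wt$r, wt$b), c(0.4023, 0.8128, 0.0760))
  # preset rates are the 4-decimal print of the group-mean tally inversion
  fit <- ensemble_fit(reference_counts("WT", "A20A"))
  expect_equal(unname(round(coef(fit), 4)), c(wt$a1, wt$r, wt$b))
  expect_error(ensemble_preset("WT_B2B"), "unknown preset")
})

test_that("matching recruitment to fidelity decouples the two epochs", {
  p <- ensemble_params(a1 = 0.4, r = 0.4, b = 0.4, n_neurons = 1e5)
  set.seed(12)
  scores <- vapply(1:100, function(i) {
    similarity_score(obs_counts(simulate_animal(p, "A20A"), 1))
  }, numeric(1))
  expect_lt(abs(mean(scores, na.rm = TRUE)), 0.02)
})

test_that("perfect fidelity yields a score of exactly 1 in every simulated animal", {
  p <- ensemble_params(a1 = 0.3, r = 1, b = 0, n_neurons = 200)
  sim <- simulate_cohort(p, "A20A", n_animals = 20, seed = 8)
  sc <- per_animal_scores(sim)
  has_delta <- sim$delta > 0
  expect_true(all(sc$score[has_delta] == 1))
})
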