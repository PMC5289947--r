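test_that("group summaries give mean and SEM, excluding undefined values", {
  expect_equal(group_summary(c(0.4, 0.4, 0.4))[c("mean", "sem")],
               list(mean = 0.4, sem = 0))
  gs <- group_summary(c(0.3, 0.5))
  expect_equal(gs$mean, 0.4)
  expect_equal(gs$sem, 0.1, tolerance = 1e-12)

  expect_message(gs2 <- group_summary(c(0.2, NA, 0.4)), "excluded 1")
  expect_equal(gs2$n_used, 2L)
  expect_equal(gs2$n_excluded, 1L)
  expect_error(suppressMessages(group_summary(c(NA, NA))), "no finite values")

  sim <- simulate_cohort("WT_A20A", n_animals = 4, seed = 6)
  gs3 <- group_summary(per_animal_scores(sim)$score)
  expect_true(is.finite(gs3$mean) && is.finite(gs3$sem))
})

test_that("bootstrap difference straddles zero for identical groups and guards group size", {
  md <- mean_difference(c(1, 2, 3, 4), c(1, 2, 3, 4), n_boot = 2000, seed = 3)
  expect_equal(md$diff, 0)
  expect_lte(md$ci_low, 0)
  expect_gte(md$ci_high, 0)
  expect_error(mean_difference(39.05, c(1, 2)), "at least 2")
})

test_that("bootstrap CI brackets the point difference and is seed-reproducible", {
  a <- c(0.41, 0.38, 0.44, 0.40)
  b <- c(0.28, 0.30, 0.25, 0.31)
  m1 <- mean_difference(a, b, n_boot = 5000, seed = 10)
  m2 <- mean_difference(a, b, n_boot = 5000, seed = 10)
  expect_identical(m1, m2)
  expect_lte(m1$ci_low, m1$diff)
  expect_gte(m1$ci_high, m1$diff)
})

test_that("simulated preset cohorts reproduce the published double-positive gap", {
  set.seed(41)
  wt <- simulate_cohort(ensemble_preset("WT_A20A", n_neurons = 20000),
                        n_animals = 4)
  ts <- simulate_cohort(ensemble_preset("TS_A20A", n_neurons = 20000),
                        n_animals = 4, genotype = "TS65DN")
  dw <- wt$delta / 20000
  dt <- ts$delta / 20000
  diff <- mean(dw) - mean(dt)
  se <- sqrt(stats::var(dw) / 4 + stats::var(dt) / 4)
  # preset delta gap: 0.4023*0.8128 - 0.2820*0.7730 = 0.109 (10.9 points)
  expect_lt(abs(diff - 0.109), 3 * se)
})

test_that("permutation test enumerates exhaustively and matches the brute-force count", {
  pt <- permutation_test(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_identical(pt$method, "exhaustive")
  expect_equal(pt$n_perm, 70)
  expect_equal(pt$p, 2 / 70, tolerance = 1e-12)

  same <- permutation_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)

  a <- stats::rnorm(12); b <- stats::rnorm(12)  # 2704156 relabelings
  p1 <- permutation_test(a, b, n_perm = 500, seed = 9)
  p2 <- permutation_test(a, b, n_perm = 500, seed = 9)
  expect_identical(p1$method, "monte-carlo")
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 501)
  expect_lte(p1$p, 1)
})

test_that("combined contrast honours its invariants and labels", {
  set.seed(2)
  wt <- per_animal_scores(simulate_cohort("WT_A20A", n_animals = 4))$score
  ts <- per_animal_scores(simulate_cohort("TS_A20A", n_animals = 4,
                                          genotype = "TS65DN"))$score
  gc <- group_contrast(wt, ts, n_boot = 1000, n_perm = 1000, seed = 5,
                       labels = c("WT", "TS65DN"))
  expect_s3_class(gc, "group_contrast")
  expect_equal(gc$diff, mean(wt) - mean(ts), tolerance = 1e-12)
  expect_lte(gc$ci_low, gc$diff)
  expect_gte(gc$ci_high, gc$diff)
  expect_gt(gc$p_perm, 0)
  expect_lte(gc$p_perm, 1)
  expect_output(print(gc), "WT vs TS65DN")
})

test_that("bootstrap intervals show the expected small-sample coverage under the null", {
  # Percentile intervals from 4 animals per group undercover a nominal 95%
  # level (classic small-m behaviour); coverage sits in the high 80s and must
  # never be degenerate or anti-conservative beyond that.
  set.seed(91)
  n_cohorts <- 500
  covered <- vapply(seq_len(n_cohorts), function(i) {
    a <- simulate_cohort("WT_A20A", n_animals = 4)$delta / 200
    b <- simulate_cohort("WT_A20A", n_animals = 4)$delta / 200
    md <- mean_difference(a, b, n_boot = 1000)
    md$ci_low <= 0 && md$ci_high >= 0
  }, logical(1))
  cover <- mean(covered)
  expect_gte(cover, 0.83)
  expect_lte(cover, 0.99)
})

test_that("genotype_contrast extracts the requested measure from a mixed table", {
  set.seed(3)
  obs <- rbind(simulate_cohort("WT_A20A", n_animals = 4, id_prefix = "wt"),
               simulate_cohort("TS_A20A", n_animals = 4,
                               genotype = "TS65DN", id_prefix = "ts"))
  gc <- genotype_contrast(obs, "A20A", measure = "delta_fraction",
                          n_boot = 500, n_perm = 500, seed = 4)
  dw <- obs$delta[obs$genotype == "WT"] / 200
  dt <- obs$delta[obs$genotype == "TS65DN"] / 200
  expect_equal(gc$diff, mean(dw) - mean(dt), tolerance = 1e-12)
  expect_error(genotype_contrast(obs, "CC"), "no rows")
})
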