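test_that("epoch fractions match hand arithmetic on published group means", {
  x <- do.call(compartment_counts, as.list(wt_a20a_means))
  expect_equal(e1_fraction(x), 0.4023, tolerance = 1e-12)
  expect_equal(e2_fraction(x), 0.3724, tolerance = 1e-12)

  expect_equal(e1_fraction(compartment_counts(100, 0, 0, 0)), 0)
  expect_equal(e1_fraction(compartment_counts(0, 0, 0, 50)), 1)
  expect_equal(e2_fraction(compartment_counts(100, 0, 0, 0)), 0)
  expect_equal(e2_fraction(compartment_counts(0, 50, 0, 0)), 1)
})

test_that("similarity chain reproduces hand-computed group-mean scores", {
  wt <- similarity_components(do.call(compartment_counts,
                                      as.list(wt_a20a_means)))
  expect_equal(wt$p_ind, 0.4023 * 0.3724, tolerance = 1e-12)
  expect_equal(wt$p_overlap, 0.327 - 0.4023 * 0.3724, tolerance = 1e-12)
  expect_equal(wt$least, 0.3724, tolerance = 1e-12)
  expect_equal(wt$score, 0.7960, tolerance = 1e-4)

  ts <- similarity_components(do.call(compartment_counts,
                                      as.list(ts_a20a_means)))
  expect_equal(ts$score, 0.6621, tolerance = 1e-4)
})

test_that("perfect reactivation scores 1, exact independence scores 0", {
  expect_identical(similarity_score(compartment_counts(60, 0, 0, 40)), 1)
  expect_identical(similarity_score(compartment_counts(30, 20, 30, 20)), 0)
})

test_that("degenerate tallies are flagged undefined, not errors", {
  s <- similarity_components(compartment_counts(100, 0, 0, 0))
  expect_false(s$defined)
  expect_true(is.na(s$score))
  expect_match(s$reason, "degenerate")

  # caged-control-like: second epoch only
  s2 <- similarity_components(compartment_counts(93, 7, 0, 0))
  expect_false(s2$defined)
})

test_that("all components agree with the independent six-step oracle over every composition of n = 12", {
  comp <- compositions4(12)
  expect_equal(nrow(comp), 455L)
  for (i in seq_len(nrow(comp))) {
    q <- comp[i, ]
    if (sum(q) == 0) next
    got <- similarity_components(q)
    want <- oracle_similarity(q[1], q[2], q[3], q[4])
    expect_equal(got$e1, want$e1, tolerance = 1e-12)
    expect_equal(got$e2, want$e2, tolerance = 1e-12)
    expect_equal(got$p_ind, want$p_ind, tolerance = 1e-12)
    expect_equal(got$p_overlap, want$p_overlap, tolerance = 1e-12)
    expect_equal(got$least, want$least, tolerance = 1e-12)
    if (is.na(want$score)) {
      expect_true(is.na(got$score))
    } else {
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("every similarity component is invariant under uniform rescaling", {
  base <- c(55.23, 4.54, 7.53, 32.7)
  ref <- similarity_components(base)
  for (k in c(2, 10, 0.01)) {
    s <- similarity_components(base * k)
    for (f in c("e1", "e2", "p_ind", "p_overlap", "least", "score")) {
      expect_equal(s[[f]], ref[[f]], tolerance = 1e-12,
                   label = sprintf("%s at k=%g", f, k))
    }
  }
})

test_that("defined scores never exceed 1, with equality iff one ensemble nests in the other", {
  set.seed(4)
  for (i in 1:200) {
    q <- stats::runif(4, 0, 50)
    s <- similarity_components(q)
    if (!s$defined) next
    expect_lte(s$score, 1 + 1e-12)
    dn <- q[4] / sum(q)
    if (abs(s$score - 1) < 1e-12) {
      expect_equal(dn, min(s$e1, s$e2), tolerance = 1e-12)
    }
  }
  # nested construction: every epoch-2 cell also epoch-1 active
  nested <- similarity_components(compartment_counts(40, 0, 25, 35))
  expect_equal(nested$score, 1, tolerance = 1e-12)
})

test_that("tallies built to satisfy independence exactly score 0", {
  set.seed(7)
  for (i in 1:50) {
    e1 <- stats::runif(1, 0.1, 0.9)
    e2 <- stats::runif(1, 0.1, 0.9)
    d <- e1 * e2
    g <- e1 - d
    b <- e2 - d
    a <- 1 - b - g - d
    s <- similarity_components(c(a, b, g, d))
    expect_lt(abs(s$score), 1e-12)
  }
})

test_that("per-animal scores preserve order and carry undefined flags", {
  obs <- animal_observations(
    c("m1", "m2", "m3"), "WT", "A20A",
    alpha = c(60, 30, 100), beta = c(0, 20, 0),
    gamma = c(0, 30, 0), delta = c(40, 20, 0))
  sc <- per_animal_scores(obs)
  expect_equal(sc$animal_id, c("m1", "m2", "m3"))
  expect_identical(sc$score[1:2], c(1, 0))
  expect_true(is.na(sc$score[3]))
  expect_identical(sc$score_defined, c(TRUE, TRUE, FALSE))
})

test_that("simulated wild-type cohorts give finite scores in (0, 1]", {
  sim <- simulate_cohort("WT_A20A", n_animals = 4, seed = 11)
  sc <- per_animal_scores(sim)
  expect_equal(nrow(sc), 4L)
  expect_true(all(sc$score_defined))
  expect_true(all(sc$score > 0 & sc$score <= 1))
})
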