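#' Group mean and standard error
#'
#' Arithmetic mean and SEM (`sd / sqrt(m)`) of per-animal values. Undefined
#' entries (`NA`, e.g. similarity scores flagged undefined) are excluded with
#' a message recording the exclusion count; they are never imputed.
#'
#' @param values numeric vector of per-animal fractions or scores.
#' @return A list with `mean`, `sem`, `n_used`, `n_excluded`.
#' @examples
#' group_summary(c(0.3, 0.5))  # mean 0.4, sem 0.1
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  keep <- is.finite(values)
  n_excluded <- sum(!keep)
  values <- values[keep]
  if (length(values) == 0L) {
    stop("no finite values left after excluding undefined entries",
         call. = FALSE)
  }
  if (n_excluded > 0L) {
    message("group_summary: excluded ", n_excluded, " undefined value(s)")
  }
  m <- length(values)
  list(mean = mean(values),
       sem  = if (m > 1) stats::sd(values) / sqrt(m) else 0,
       n_used = m, n_excluded = n_excluded)
}

drop_undefined <- function(x, label) {
  x <- as.numeric(x)
  keep <- is.finite(x)
  if (any(!keep)) {
    message("excluded ", sum(!keep), " undefined value(s) from group ", label)
  }
  x[keep]
}

#' Bootstrap mean difference between two groups of animals
#'
#' Difference of group means with a percentile bootstrap confidence interval.
#' Animals (not neurons) are resampled with replacement within each group,
#' matching the animal as the experimental unit.
#'
#' @param group_a,group_b numeric vectors of per-animal values (>= 2 finite
#'   values each after excluding undefined entries).
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level of the percentile interval.
#' @param seed optional integer seed.
#' @return A list with `diff` (`mean(group_a) - mean(group_b)`), `ci_low`,
#'   `ci_high`, `n_boot`, `conf`.
#' @export
mean_difference <- function(group_a, group_b, n_boot = 10000, conf = 0.95,
                            seed = NULL) {
  a <- drop_undefined(group_a, "A")
  b <- drop_undefined(group_b, "B")
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(a, replace = TRUE)) - mean(sample(b, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(diff = mean(a) - mean(b), ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot, conf = conf)
}

#' Permutation test for a difference in group means
#'
#' Two-sided test of label exchangeability on the absolute difference of
#' means. When the number of distinct relabelings `choose(na + nb, na)` is at
#' most `exhaustive_limit` every relabeling is enumerated and the p-value is
#' the exact proportion with `|difference| >=` the observed one (the observed
#' labeling is part of the null set, so p >= 1/choose(na+nb, na)). Otherwise
#' `n_perm` Monte-Carlo relabelings are drawn and the add-one-corrected
#' estimate `(1 + #extreme) / (n_perm + 1)` is returned, so p >= 1/(n_perm+1).
#' If all values are equal the p-value is 1.
#'
#' @inheritParams mean_difference
#' @param n_perm Monte-Carlo relabelings when enumeration is infeasible
#'   (>= 99).
#' @param exhaustive_limit switch point between exact enumeration and
#'   Monte-Carlo sampling.
#' @return A list with `p` (in (0, 1\]), `method` (`"exhaustive"` or
#'   `"monte-carlo"`), `n_perm` (relabelings actually evaluated) and
#'   `diff_obs`.
#' @examples
#' permutation_test(c(0, 0, 0, 0), c(1, 1, 1, 1))$p  # 2/70 by enumeration
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000,
                             exhaustive_limit = 20000, seed = NULL) {
  a <- drop_undefined(group_a, "A")
  b <- drop_undefined(group_b, "B")
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  d_obs <- abs(mean(a) - mean(b))
  eps <- 1e-12 * max(1, d_obs)
  total <- choose(n, na)
  if (total <= exhaustive_limit) {
    idx <- utils::combn(n, na)
    sum_pool <- sum(pool)
    d_perm <- abs(apply(idx, 2, function(j) {
      mean(pool[j]) - (sum_pool - sum(pool[j])) / (n - na)
    }))
    p <- sum(d_perm >= d_obs - eps) / total
    method <- "exhaustive"
    n_eval <- total
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      j <- sample.int(n, na)
      abs(mean(pool[j]) - mean(pool[-j])) >= d_obs - eps
    }, logical(1)))
    p <- (1 + hits) / (n_perm + 1)
    method <- "monte-carlo"
    n_eval <- n_perm
  }
  list(p = p, method = method, n_perm = n_eval, diff_obs = mean(a) - mean(b))
}

#' Resampling contrast between two groups of animals
#'
#' Combines the bootstrap mean difference and the permutation test into one
#' genotype (or condition) contrast — the package's nonparametric analogue of
#' a post hoc group comparison. Works on any per-animal measure: an epoch
#' activation fraction, a category fraction, or the similarity score.
#'
#' @inheritParams mean_difference
#' @param n_perm relabelings for the permutation test.
#' @param labels length-2 character vector naming the groups.
#' @return An object of class `"group_contrast"`: a list with `mean_a`,
#'   `mean_b`, `diff`, `ci_low`, `ci_high`, `p_perm`, `perm_method`,
#'   `n_boot`, `n_perm`, `conf`, `seed`, `labels`.
#' @examples
#' set.seed(1)
#' wt <- per_animal_scores(simulate_cohort("WT_A20A", n_animals = 4))$score
#' ts <- per_animal_scores(simulate_cohort("TS_A20A", n_animals = 4,
#'                                         genotype = "TS65DN"))$score
#' group_contrast(wt, ts, n_boot = 500, seed = 7)
#' @export
group_contrast <- function(group_a, group_b, n_boot = 10000, n_perm = 10000,
                           conf = 0.95, seed = NULL,
                           labels = c("A", "B")) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- drop_undefined(group_a, labels[1])
  b <- drop_undefined(group_b, labels[2])
  bd <- mean_difference(a, b, n_boot = n_boot, conf = conf)
  pt <- permutation_test(a, b, n_perm = n_perm)
  structure(
    list(mean_a = mean(a), mean_b = mean(b), diff = bd$diff,
         ci_low = bd$ci_low, ci_high = bd$ci_high,
         p_perm = pt$p, perm_method = pt$method,
         n_boot = n_boot, n_perm = pt$n_perm, conf = conf,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         labels = labels),
    class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, digits = 4, ...) {
  cat(sprintf("Group contrast: %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  means: %s = %.*f, %s = %.*f\n",
              x$labels[1], digits, x$mean_a, x$labels[2], digits, x$mean_b))
  cat(sprintf("  difference = %.*f, %g%% bootstrap CI [%.*f, %.*f] (%d resamples)\n",
              digits, x$diff, 100 * x$conf, digits, x$ci_low,
              digits, x$ci_high, x$n_boot))
  cat(sprintf("  permutation p = %.4g (%s, %d relabelings)\n",
              x$p_perm, x$perm_method, x$n_perm))
  invisible(x)
}

#' Contrast two genotypes on a per-animal measure
#'
#' Convenience wrapper: selects one paradigm from an observation table,
#' computes a per-animal measure for each genotype, and runs
#' [group_contrast()] (WT minus TS65DN).
#'
#' @param obs observation table (see [animal_observations()]).
#' @param paradigm paradigm to analyse.
#' @param measure one of `"e1"`, `"e2"`, `"delta_fraction"`,
#'   `"beta_fraction"`, `"score"`.
#' @inheritParams group_contrast
#' @return A `"group_contrast"` object.
#' @export
genotype_contrast <- function(obs, paradigm, measure = c(
                                "score", "e1", "e2",
                                "delta_fraction", "beta_fraction"),
                              n_boot = 10000, n_perm = 10000, conf = 0.95,
                              seed = NULL) {
  measure <- match.arg(measure)
  paradigm <- match_vocab(paradigm, catfish_paradigms, "paradigm")
  obs <- validate_observations(obs)
  obs <- obs[obs$paradigm == paradigm, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no rows for paradigm ", paradigm, call. = FALSE)
  value_of <- function(rows) {
    switch(measure,
      score = per_animal_scores(rows)$score,
      e1    = vapply(seq_len(nrow(rows)),
                     function(i) e1_fraction(obs_counts(rows, i)), numeric(1)),
      e2    = vapply(seq_len(nrow(rows)),
                     function(i) e2_fraction(obs_counts(rows, i)), numeric(1)),
      delta_fraction = rows$delta /
        (rows$alpha + rows$beta + rows$gamma + rows$delta),
      beta_fraction  = rows$beta /
        (rows$alpha + rows$beta + rows$gamma + rows$delta))
  }
  wt <- value_of(obs[obs$genotype == "WT", , drop = FALSE])
  ts <- value_of(obs[obs$genotype == "TS65DN", , drop = FALSE])
  group_contrast(wt, ts, n_boot = n_boot, n_perm = n_perm, conf = conf,
                 seed = seed, labels = c("WT", "TS65DN"))
}
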