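#' Fit the two-epoch ensemble activation model to compartment counts
#'
#' Maximum-likelihood estimation of the forward model behind
#' [expected_category_probs()] from one compartment tally (or an observation
#' table, whose counts are pooled first). Under the multinomial likelihood of
#' the two-epoch model the MLE is closed form:
#' \deqn{\hat a_1 = (\gamma + \delta)/n, \quad
#'       \hat r = \delta/(\gamma + \delta), \quad
#'       \hat b = \beta/(\alpha + \beta).}
#' Standard errors are the usual binomial ones on each estimate's own
#' denominator (`r` and `b` are conditional rates). An estimate whose
#' denominator is zero is undefined and returned as `NA`.
#'
#' Fractional "counts" (group-mean percentages) are accepted; estimates are
#' scale-invariant, though standard errors are then only meaningful if the
#' scale equals the number of neurons scored.
#'
#' @param counts a [compartment_counts()] object, 4 numbers, or an
#'   observation table from a two-epoch paradigm (pooled before fitting).
#' @return An object of class `"ensemble_fit"` with components
#'   `coefficients` (named vector `a1`, `r`, `b`), `se`, `counts`, `n` and
#'   `undefined` (names of non-estimable parameters). Supports `coef()`,
#'   `print()`, `summary()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()`, `logLik()` and `plot()`.
#' @examples
#' fit <- ensemble_fit(compartment_counts(55.23, 4.54, 7.53, 32.7))
#' coef(fit)   # a1 = 0.4023, r = 0.8128, b = 0.0760
#' predict(fit)
#' @export
ensemble_fit <- function(counts) {
  if (is.data.frame(counts)) counts <- pooled_counts(counts)
  x <- validate_counts(counts)
  n <- sum(x)
  n1 <- unname(x["gamma"] + x["delta"])  # epoch-1 active
  n0 <- unname(x["alpha"] + x["beta"])   # epoch-1 silent
  a1 <- n1 / n
  r  <- if (n1 > 0) unname(x["delta"]) / n1 else NA_real_
  b  <- if (n0 > 0) unname(x["beta"])  / n0 else NA_real_
  se <- c(a1 = sqrt(a1 * (1 - a1) / n),
          r  = if (n1 > 0) sqrt(r * (1 - r) / n1) else NA_real_,
          b  = if (n0 > 0) sqrt(b * (1 - b) / n0) else NA_real_)
  est <- c(a1 = a1, r = r, b = b)
  structure(
    list(coefficients = est, se = se, counts = x, n = n,
         undefined = names(est)[is.na(est)]),
    class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, digits = 4, ...) {
  cat("Two-epoch ensemble activation model (closed-form multinomial MLE)\n")
  cat("n =", format(x$n), "cells\n")
  print(round(x$coefficients, digits))
  if (length(x$undefined)) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ensemble_fit <- function(object, ...) object$coefficients

#' @export
summary.ensemble_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  rownames(tab) <- c("sparsity a1", "fidelity r", "recruitment b")
  structure(list(table = tab, n = object$n, undefined = object$undefined,
                 similarity = asymptotic_similarity(fit_params(object))),
            class = "summary.ensemble_fit")
}

#' @export
print.summary.ensemble_fit <- function(x, digits = 4, ...) {
  cat("Two-epoch ensemble activation model\n")
  cat("n =", format(x$n), "cells\n\n")
  stats::printCoefmat(x$table, digits = digits, na.print = "undef")
  cat("\nasymptotic similarity score:",
      if (is.na(x$similarity)) "undefined" else format(round(x$similarity, digits)),
      "\n")
  invisible(x)
}

# ensemble_params built from a fit (NA-safe for degenerate fits)
fit_params <- function(object, kappa = 126, n_neurons = NULL) {
  if (is.null(n_neurons)) {
    n_neurons <- max(1L, as.integer(round(object$n)))
  }
  est <- object$coefficients
  ensemble_params(a1 = est["a1"], r = est["r"], b = est["b"],
                  kappa = kappa, n_neurons = n_neurons)
}

#' @export
#' @rdname ensemble_fit
#' @param object an `"ensemble_fit"` object.
#' @param type `"prob"` for category probabilities, `"counts"` for expected
#'   category counts at the fitted total `n`.
#' @param ... unused.
predict.ensemble_fit <- function(object, type = c("prob", "counts"), ...) {
  type <- match.arg(type)
  p <- expected_category_probs(fit_params(object), "A20A")
  if (type == "counts") p * object$n else p
}

#' @export
fitted.ensemble_fit <- function(object, ...) predict(object, type = "prob")

#' @export
residuals.ensemble_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  obs <- unclass(object$counts) / object$n
  exp <- predict(object, type = "prob")
  res <- obs - exp
  if (type == "pearson") {
    res <- res / sqrt(exp * (1 - exp) / object$n)
  }
  res
}

#' @export
logLik.ensemble_fit <- function(object, ...) {
  p <- predict(object, type = "prob")
  x <- unclass(object$counts)
  keep <- x > 0
  ll <- sum(x[keep] * log(p[keep]))
  structure(ll, df = 3 - length(object$undefined), nobs = object$n,
            class = "logLik")
}

#' @export
#' @rdname ensemble_fit
#' @param nsim number of animals to simulate.
#' @param seed optional RNG seed.
simulate.ensemble_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_cohort(fit_params(object), paradigm = "A20A", n_animals = nsim,
                  seed = seed, id_prefix = "fitsim")
}

#' @export
plot.ensemble_fit <- function(x, ...) {
  obs <- unclass(x$counts) / x$n
  exp <- predict(x, type = "prob")
  m <- rbind(observed = obs, fitted = exp)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "fraction of neurons",
                    names.arg = c("negative", "nucleus", "cytoplasm", "both"),
                    main = "Observed vs fitted compartment fractions", ...)
  invisible(x)
}

#' Similarity score implied by model parameters
#'
#' Plugs the closed-form category probabilities of a parameter set into the
#' similarity calculation — the score an infinitely large animal with those
#' rates would attain. Perfect fidelity (`r = 1`, `b = 0`) gives 1; setting
#' `b = r` makes the two epochs independent and gives 0.
#'
#' @param params an [ensemble_params()] object or preset name.
#' @param paradigm paradigm label (two-epoch); defaults to the preset's own
#'   paradigm or `"A20A"`.
#' @return The asymptotic score, or `NA` when degenerate (e.g. `a1 = 0`).
#' @examples
#' asymptotic_similarity(ensemble_params(a1 = 0.4, r = 1, b = 0))  # 1
#' asymptotic_similarity("WT_A20A")                                # ~0.796
#' @export
asymptotic_similarity <- function(params, paradigm = NULL) {
  if (is.character(params)) {
    p <- ensemble_preset(params)
    if (is.null(paradigm)) paradigm <- attr(p, "paradigm")
    params <- p
  }
  if (is.null(paradigm)) paradigm <- "A20A"
  if (anyNA(unlist(params[required_rates(
        match_vocab(paradigm, catfish_paradigms, "paradigm"))]))) {
    return(NA_real_)
  }
  probs <- expected_category_probs(params, paradigm)
  if (sum(probs) <= 0) return(NA_real_)
  similarity_score(probs)
}

#' Parameter-recovery study for the simulation/estimation pipeline
#'
#' Repeatedly simulates a cohort from known parameters, fits the pooled
#' closed-form MLE, and summarises bias and root-mean-square error per
#' parameter — the standard check that the estimator recovers the generative
#' rates at realistic cohort sizes.
#'
#' @param params true [ensemble_params()] (or preset name).
#' @param n_animals animals per simulated cohort.
#' @param n_neurons neurons per animal (overrides `params$n_neurons` if given).
#' @param reps number of simulation replicates.
#' @param paradigm two-epoch paradigm label.
#' @param seed optional RNG seed.
#' @return An object of class `"recovery_report"`: a `data.frame` with one
#'   row per parameter (`a1`, `r`, `b`) and columns `true`, `mean_est`,
#'   `bias`, `rmse`, `sd_est`, `n_defined`, plus attributes `reps`,
#'   `n_animals`, `n_neurons` and the matrix of per-replicate estimates in
#'   attribute `estimates`.
#' @export
parameter_recovery <- function(params, n_animals = 4, n_neurons = NULL,
                               reps = 100, paradigm = "A20A", seed = NULL) {
  if (is.character(params)) {
    p <- ensemble_preset(params)
    paradigm <- attr(p, "paradigm")
    params <- p
  }
  if (!is.null(n_neurons)) {
    params <- ensemble_params(a1 = params$a1, r = params$r, b = params$b,
                              f0 = params$f0, kappa = params$kappa,
                              n_neurons = n_neurons)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  est <- t(vapply(seq_len(reps), function(i) {
    cohort <- simulate_cohort(params, paradigm = paradigm,
                              n_animals = n_animals)
    coef(ensemble_fit(cohort))
  }, numeric(3)))
  true <- c(a1 = params$a1, r = params$r, b = params$b)
  out <- data.frame(
    parameter = colnames(est),
    true      = unname(true),
    mean_est  = colMeans(est, na.rm = TRUE),
    bias      = colMeans(est, na.rm = TRUE) - unname(true),
    rmse      = sqrt(colMeans((est - rep(true, each = nrow(est)))^2,
                              na.rm = TRUE)),
    sd_est    = apply(est, 2, stats::sd, na.rm = TRUE),
    n_defined = colSums(!is.na(est)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "reps") <- reps
  attr(out, "n_animals") <- n_animals
  attr(out, "n_neurons") <- params$n_neurons
  attr(out, "estimates") <- est
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery: %d reps of %d animals x %d neurons\n",
              attr(x, "reps"), attr(x, "n_animals"), attr(x, "n_neurons")))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
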