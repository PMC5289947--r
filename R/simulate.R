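#' Generative parameters for two-epoch ensemble activation
#'
#' The forward model assumes each scored neuron is activated independently in
#' epoch 1 with probability `a1` (the population sparsity), and in epoch 2
#' with probability `r` if it was active in epoch 1 (reactivation fidelity) or
#' `b` otherwise (de novo recruitment). Epoch-1 activity produces the
#' cytoplasmic label, epoch-2 activity the nuclear label, matching the ~20-min
#' nucleus-to-cytoplasm translocation of Arc mRNA. Caged controls transcribe
#' at a baseline rate `f0`. Animal-to-animal variability is modelled by
#' drawing each animal's rates from Beta distributions with the given means
#' and one shared concentration `kappa` (variance `m(1-m)/(kappa+1)`).
#'
#' Defaults: `kappa = 126` was calibrated so that 4-animal cohorts reproduce
#' the order of magnitude of reported group SEMs (see
#' [calibrate_concentration()]); `n_neurons = 200` matches reported totals of
#' roughly 340-900 neurons per 4-5-animal group.
#'
#' @param a1 epoch-1 activation probability (sparsity), in \[0, 1\].
#' @param r reactivation probability given epoch-1 activity.
#' @param b recruitment probability given epoch-1 silence.
#' @param f0 caged-control baseline transcription probability.
#' @param kappa Beta concentration for animal-level variability (> 0; larger
#'   means less variability).
#' @param n_neurons neurons scored per animal (>= 1).
#' @return An object of class `"ensemble_params"` (a named list).
#' @examples
#' ensemble_params(a1 = 0.40, r = 0.81, b = 0.08)
#' @export
ensemble_params <- function(a1 = NA_real_, r = NA_real_, b = NA_real_,
                            f0 = NA_real_, kappa = 126, n_neurons = 200) {
  p <- list(a1 = as.numeric(a1), r = as.numeric(r), b = as.numeric(b),
            f0 = as.numeric(f0), kappa = as.numeric(kappa),
            n_neurons = as.integer(n_neurons))
  for (nm in c("a1", "r", "b", "f0")) {
    v <- p[[nm]]
    if (!is.na(v) && (v < 0 || v > 1)) {
      stop("parameter ", nm, " must lie in [0, 1], got ", v, call. = FALSE)
    }
  }
  if (!is.finite(p$kappa) || p$kappa <= 0) {
    stop("kappa must be a positive finite number", call. = FALSE)
  }
  if (is.na(p$n_neurons) || p$n_neurons < 1L) {
    stop("n_neurons must be at least 1", call. = FALSE)
  }
  class(p) <- "ensemble_params"
  p
}

#' @export
print.ensemble_params <- function(x, ...) {
  cat("Two-epoch ensemble activation parameters\n")
  cat(sprintf("  sparsity a1 = %s, fidelity r = %s, recruitment b = %s, baseline f0 = %s\n",
              format(x$a1), format(x$r), format(x$b), format(x$f0)))
  cat(sprintf("  animal-level concentration kappa = %s; %d neurons/animal\n",
              format(x$kappa), x$n_neurons))
  invisible(x)
}

# which rate parameters a paradigm requires
required_rates <- function(paradigm) {
  switch(paradigm,
         CC = "f0", ASAC = "a1",
         A20A = c("a1", "r", "b"), AX4_A20A = c("a1", "r", "b"))
}

check_rates <- function(params, paradigm) {
  need <- required_rates(paradigm)
  have <- vapply(params[need], function(v) !is.na(v), logical(1))
  if (!all(have)) {
    stop("paradigm ", paradigm, " requires parameter(s) ",
         paste(need[!have], collapse = ", "), " to be set", call. = FALSE)
  }
  invisible(params)
}

#' Expected compartment-category probabilities
#'
#' Closed-form category probabilities of the forward model for one paradigm.
#' For two-epoch paradigms (`A20A`, `AX4_A20A`):
#' `p_delta = a1 * r`, `p_gamma = a1 * (1 - r)`, `p_beta = (1 - a1) * b`,
#' `p_alpha = (1 - a1) * (1 - b)`. Single-epoch paradigms place all activity
#' in the nuclear category: `ASAC` has `p_beta = a1`, `CC` has `p_beta = f0`,
#' with `p_gamma = p_delta = 0`. The quadruple always sums to 1.
#'
#' @param params an [ensemble_params()] object.
#' @param paradigm paradigm label (see [catfish_paradigms]).
#' @return Named numeric vector `(alpha, beta, gamma, delta)` summing to 1.
#' @examples
#' expected_category_probs(ensemble_params(a1 = 0.4023, r = 0.8128, b = 0.076),
#'                         "A20A")
#' @export
expected_category_probs <- function(params, paradigm) {
  stopifnot(inherits(params, "ensemble_params"))
  paradigm <- match_vocab(paradigm, catfish_paradigms, "paradigm")
  check_rates(params, paradigm)
  if (is_two_epoch(paradigm)) {
    a1 <- params$a1; r <- params$r; b <- params$b
    p <- c(alpha = (1 - a1) * (1 - b), beta = (1 - a1) * b,
           gamma = a1 * (1 - r), delta = a1 * r)
  } else {
    rate <- if (paradigm == "CC") params$f0 else params$a1
    p <- c(alpha = 1 - rate, beta = rate, gamma = 0, delta = 0)
  }
  p
}

# Beta draw parameterised by mean and concentration; degenerate means pass
# through exactly so presets with a rate of 0 or 1 stay deterministic.
rbeta_mean <- function(n, mean, kappa) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
}

# draw one animal's rate vector from the Beta hierarchy
draw_animal_rates <- function(params, paradigm) {
  p <- params
  for (nm in required_rates(paradigm)) {
    p[[nm]] <- rbeta_mean(1L, params[[nm]], params$kappa)
  }
  p
}

#' Simulate one animal's compartment counts
#'
#' Draws animal-level activation rates from the Beta hierarchy (means from
#' `params`, shared concentration `kappa`), then scores `n_neurons`
#' independent neurons under the two-epoch Bernoulli model and tallies the
#' four compartment categories: epoch-1-only activity gives cytoplasmic
#' signal (`gamma`), epoch-2-only gives nuclear (`beta`), both gives
#' double-positive (`delta`), neither gives `alpha`.
#'
#' Randomness comes from R's global RNG stream; call `set.seed()` (or use the
#' `seed` argument of [simulate_cohort()]) for reproducibility.
#'
#' @param params an [ensemble_params()] object.
#' @param paradigm paradigm label.
#' @param animal_id identifier for the returned row.
#' @param genotype genotype label for the returned row.
#' @return A one-row observation table (see [animal_observations()]) whose
#'   counts sum to `params$n_neurons`.
#' @export
simulate_animal <- function(params, paradigm, animal_id = "sim1",
                            genotype = "WT") {
  stopifnot(inherits(params, "ensemble_params"))
  paradigm <- match_vocab(paradigm, catfish_paradigms, "paradigm")
  check_rates(params, paradigm)
  rates <- draw_animal_rates(params, paradigm)
  probs <- expected_category_probs(rates, paradigm)
  tally <- as.vector(stats::rmultinom(1L, size = params$n_neurons, prob = probs))
  animal_observations(animal_id = animal_id, genotype = genotype,
                      paradigm = paradigm, alpha = tally[1], beta = tally[2],
                      gamma = tally[3], delta = tally[4])
}

#' Simulate a cohort of animals
#'
#' Repeated [simulate_animal()] draws with distinct animal identifiers.
#' Reproducible: the same `seed` yields identical counts.
#'
#' @param params an [ensemble_params()] object or preset name (string, see
#'   [ensemble_preset()]).
#' @param paradigm paradigm label; defaults to the preset's own paradigm when
#'   `params` is a preset name.
#' @param n_animals number of animals (>= 1).
#' @param genotype genotype label for all rows.
#' @param seed optional integer seed applied to R's RNG before simulation.
#' @param id_prefix prefix for generated animal identifiers.
#' @return An observation table with `n_animals` rows.
#' @examples
#' sim <- simulate_cohort("WT_A20A", n_animals = 4, seed = 17)
#' per_animal_scores(sim)
#' @export
simulate_cohort <- function(params, paradigm = NULL, n_animals = 4,
                            genotype = NULL, seed = NULL,
                            id_prefix = "sim") {
  if (is.character(params)) {
    params <- ensemble_preset(params)
  }
  if (is.null(paradigm)) paradigm <- attr(params, "paradigm")
  if (is.null(genotype)) genotype <- attr(params, "genotype")
  if (is.null(genotype)) genotype <- "WT"
  if (is.null(paradigm)) {
    stop("paradigm must be given when params is not a preset name",
         call. = FALSE)
  }
  if (n_animals < 1L) stop("n_animals must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_animals), function(i) {
    simulate_animal(params, paradigm,
                    animal_id = sprintf("%s%d", id_prefix, i),
                    genotype = genotype)
  })
  validate_observations(do.call(rbind, rows))
}

#' Calibrate the animal-level concentration from a reported SEM
#'
#' Given a reported group SEM (on the percentage scale), the group size and
#' the group mean fraction, returns the Beta concentration `kappa` for which
#' the animal-level SD matches the implied per-animal SD
#' (`SD = SEM * sqrt(n_animals)`, after converting the SEM to the fraction
#' scale): `kappa = mean * (1 - mean) / SD^2 - 1`.
#'
#' This attributes all between-animal variance to the Beta hierarchy (none to
#' finite neuron sampling), so it is a lower bound on the true concentration;
#' at the package defaults the neuron-sampling share is small.
#'
#' @param target_sem reported SEM in percentage points (> 0).
#' @param n_animals animals per group (>= 2).
#' @param mean group mean as a fraction, strictly inside (0, 1).
#' @return The concentration `kappa` (> 0).
#' @examples
#' calibrate_concentration(target_sem = 2.16, n_animals = 4, mean = 0.3905)
#' @export
calibrate_concentration <- function(target_sem, n_animals, mean) {
  if (!is.finite(target_sem) || target_sem <= 0) {
    stop("target_sem must be positive", call. = FALSE)
  }
  if (n_animals < 2) stop("n_animals must be at least 2", call. = FALSE)
  if (mean <= 0 || mean >= 1) {
    stop("mean must lie strictly inside (0, 1)", call. = FALSE)
  }
  sd_frac <- (target_sem / 100) * sqrt(n_animals)
  v <- sd_frac^2
  if (v >= mean * (1 - mean)) {
    stop("infeasible: implied animal-level variance ", format(v),
         " reaches the Bernoulli bound mean*(1-mean) = ",
         format(mean * (1 - mean)), call. = FALSE)
  }
  mean * (1 - mean) / v - 1
}

#' Calibrated parameter presets
#'
#' Named parameter sets obtained by closed-form inversion
#' ([ensemble_fit()] applied to group-mean percentages) of the published CA1
#' group values for wild-type and Ts65Dn mice under each behavioral paradigm.
#' Each preset carries its genotype, paradigm and a provenance note;
#' cytoplasm-only percentages that the source reports only via the total
#' Arc-positive percentage are marked as derived by subtraction. The repeated
#' exposure paradigm (`AX4_A20A`) uses the same forward model as `A20A` with
#' its own rates; no mechanistic model of training-dependent destabilisation
#' is attempted.
#'
#' `ensemble_presets()` returns all presets; `ensemble_preset(name)` returns
#' one as an [ensemble_params()] object with attributes `genotype`,
#' `paradigm` and `provenance`.
#'
#' @param name preset name, e.g. `"WT_A20A"`, `"TS_ASAC"`, `"WT_CC"`,
#'   `"TS_AX4_A20A"`.
#' @param kappa,n_neurons passed to [ensemble_params()].
#' @return For `ensemble_preset()`, an `"ensemble_params"` object; for
#'   `ensemble_presets()`, a named list of them.
#' @examples
#' ensemble_preset("WT_A20A")
#' names(ensemble_presets())
#' @export
ensemble_preset <- function(name, kappa = 126, n_neurons = 200) {
  raw <- preset_table()
  if (!name %in% names(raw)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  entry <- raw[[name]]
  grab <- function(f) if (is.null(entry[[f]])) NA_real_ else entry[[f]]
  p <- ensemble_params(a1 = grab("a1"), r = grab("r"), b = grab("b"),
                       f0 = grab("f0"), kappa = kappa, n_neurons = n_neurons)
  attr(p, "genotype")   <- entry$genotype
  attr(p, "paradigm")   <- entry$paradigm
  attr(p, "provenance") <- entry$provenance
  p
}

#' @rdname ensemble_preset
#' @export
ensemble_presets <- function(kappa = 126, n_neurons = 200) {
  nms <- names(preset_table())
  stats::setNames(
    lapply(nms, ensemble_preset, kappa = kappa, n_neurons = n_neurons), nms)
}

preset_table <- function() {
  path <- system.file("extdata", "presets.json", package = "catfishr",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
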