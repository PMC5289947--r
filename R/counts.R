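#' Compartmental Arc cell counts
#'
#' Constructs the four-category cell tally of a catFISH experiment for one
#' animal and condition: neurons with no Arc signal (`alpha`), intranuclear
#' foci only (`beta`), cytoplasmic/perinuclear signal only (`gamma`), and
#' signal in both compartments (`delta`). Cytoplasmic signal marks activity in
#' the first exploration epoch (transcribed ~25 min before sacrifice, mRNA has
#' translocated), nuclear foci mark the second epoch (transcribed within
#' minutes of sacrifice).
#'
#' Fields are non-negative reals, not necessarily integers: group-level
#' percentages (per 100 neurons) are accepted interchangeably with raw counts
#' because every derived fraction is invariant under uniform rescaling.
#' Values are never rounded.
#'
#' @param alpha Arc-negative neurons.
#' @param beta nucleus-only neurons.
#' @param gamma cytoplasm-only neurons.
#' @param delta double-positive (nucleus and cytoplasm) neurons.
#' @return An object of class `"compartment_counts"`: a named numeric vector
#'   with elements `alpha`, `beta`, `gamma`, `delta`.
#' @examples
#' compartment_counts(alpha = 30, beta = 20, gamma = 30, delta = 20)
#' # group-mean percentages work identically
#' compartment_counts(55.23, 4.54, 7.53, 32.7)
#' @seealso [similarity_components()], [ensemble_fit()]
#' @export
compartment_counts <- function(alpha, beta, gamma, delta) {
  x <- c(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta))
  class(x) <- "compartment_counts"
  validate_counts(x)
}

#' Validate a compartment-count tally
#'
#' Checks that all four categories are present, finite and non-negative and
#' that at least one neuron was scored. Returns its input unchanged so it can
#' be used as a pass-through guard.
#'
#' @param counts a [compartment_counts()] object or a numeric vector of length
#'   4 ordered `alpha, beta, gamma, delta`.
#' @return The validated `"compartment_counts"` object.
#' @export
validate_counts <- function(counts) {
  x <- as_counts(counts)
  bad <- !is.finite(unclass(x)) | unclass(x) < 0
  if (any(bad)) {
    stop("negative or non-finite compartment count in field(s): ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  }
  if (sum(x) <= 0) {
    stop("empty observation: total cell count must be positive", call. = FALSE)
  }
  x
}

# coerce numeric length-4 / list / counts object to compartment_counts
as_counts <- function(counts) {
  if (inherits(counts, "compartment_counts")) return(counts)
  x <- unlist(counts, use.names = FALSE)
  if (length(x) != 4L || !is.numeric(x)) {
    stop("counts must be a compartment_counts object or 4 numbers ",
         "(alpha, beta, gamma, delta)", call. = FALSE)
  }
  x <- as.numeric(x)
  names(x) <- c("alpha", "beta", "gamma", "delta")
  class(x) <- "compartment_counts"
  x
}

#' @export
print.compartment_counts <- function(x, ...) {
  cat("catFISH compartment counts (n =", format(sum(x)), "cells)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Controlled vocabularies for genotype and behavioral paradigm
#'
#' `catfish_genotypes` holds the two genotype labels (wild-type littermate
#' controls and the segmentally trisomic Ts65Dn model). `catfish_paradigms`
#' holds the four behavioral paradigms: caged control (`CC`), a single 5-min
#' exploration followed by immediate sacrifice (`ASAC`), two explorations of
#' the same environment 20 min apart (`A20A`), and four daily exposures
#' followed by the two-exploration probe (`AX4_A20A`).
#'
#' Single-epoch paradigms (`CC`, `ASAC`) carry nuclear signal only, so their
#' `gamma` and `delta` categories are zero by construction.
#' @format Character vectors.
#' @export
catfish_genotypes <- c("WT", "TS65DN")

#' @rdname catfish_genotypes
#' @export
catfish_paradigms <- c("CC", "ASAC", "A20A", "AX4_A20A")

#' Does a paradigm expose both activation epochs?
#'
#' @param paradigm paradigm label, one of [catfish_paradigms].
#' @return `TRUE` for the two-epoch paradigms (`A20A`, `AX4_A20A`),
#'   `FALSE` for `CC` and `ASAC`.
#' @export
is_two_epoch <- function(paradigm) {
  match_vocab(paradigm, catfish_paradigms, "paradigm") %in%
    c("A20A", "AX4_A20A")
}

match_vocab <- function(x, vocab, what) {
  x <- toupper(as.character(x))
  bad <- !(x %in% vocab)
  if (any(bad)) {
    stop("unknown ", what, " label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(vocab, collapse = ", "), ")",
         call. = FALSE)
  }
  x
}

#' Assemble a table of per-animal observations
#'
#' The unit of resampling throughout the package is the animal. An observation
#' table is a plain `data.frame` with one row per animal and condition and
#' columns `animal_id`, `genotype`, `paradigm`, `alpha`, `beta`, `gamma`,
#' `delta`. This constructor validates vocabularies, count positivity and the
#' uniqueness of `(animal_id, paradigm)` pairs.
#'
#' @param animal_id character or coercible identifiers.
#' @param genotype genotype labels, recycled (see [catfish_genotypes]).
#' @param paradigm paradigm labels, recycled (see [catfish_paradigms]).
#' @param alpha,beta,gamma,delta per-animal category counts (or percentages).
#' @return A `data.frame` of class `c("catfish_observations", "data.frame")`.
#' @examples
#' animal_observations(
#'   animal_id = c("m1", "m2"), genotype = "WT", paradigm = "A20A",
#'   alpha = c(120, 130), beta = c(10, 8), gamma = c(15, 12),
#'   delta = c(60, 55)
#' )
#' @export
animal_observations <- function(animal_id, genotype, paradigm,
                                alpha, beta, gamma, delta) {
  obs <- data.frame(
    animal_id = as.character(animal_id),
    genotype  = match_vocab(rep_len(genotype, length(animal_id)),
                            catfish_genotypes, "genotype"),
    paradigm  = match_vocab(rep_len(paradigm, length(animal_id)),
                            catfish_paradigms, "paradigm"),
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    gamma = as.numeric(gamma), delta = as.numeric(delta),
    stringsAsFactors = FALSE
  )
  validate_observations(obs)
}

validate_observations <- function(obs) {
  required <- c("animal_id", "genotype", "paradigm",
                "alpha", "beta", "gamma", "delta")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("observation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(obs$animal_id, obs$paradigm, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (animal_id, paradigm) pair(s): ",
         paste(unique(obs$animal_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(obs))) {
    validate_counts(obs[i, c("alpha", "beta", "gamma", "delta")])
  }
  single <- !is_two_epoch(obs$paradigm)
  leak <- single & (obs$gamma > 0 | obs$delta > 0)
  if (any(leak)) {
    warning("single-epoch rows with nonzero gamma/delta (kept as stored): ",
            paste(obs$animal_id[leak], collapse = ", "), call. = FALSE)
  }
  class(obs) <- unique(c("catfish_observations", class(obs)))
  obs
}

#' Extract one animal's compartment counts from an observation table
#'
#' @param obs observation table (see [animal_observations()]).
#' @param i row index or `animal_id`.
#' @return A `"compartment_counts"` object.
#' @export
obs_counts <- function(obs, i = 1L) {
  if (is.character(i)) i <- match(i, obs$animal_id)
  row <- obs[i, , drop = FALSE]
  compartment_counts(row$alpha, row$beta, row$gamma, row$delta)
}

#' Pool compartment counts across animals
#'
#' Field-wise sum of per-animal tallies. Pooling weights each neuron equally
#' and is offered as an explicit alternative to the default per-animal
#' analysis (see [per_animal_scores()]); the two give different group scores
#' whenever animals differ.
#'
#' @param obs observation table; all rows must share one paradigm.
#' @return A `"compartment_counts"` object with the summed tally.
#' @export
pooled_counts <- function(obs) {
  if (is.null(obs) || nrow(obs) == 0L) {
    stop("cannot pool an empty observation table", call. = FALSE)
  }
  if (length(unique(obs$paradigm)) != 1L) {
    stop("cannot pool across paradigms: found ",
         paste(unique(obs$paradigm), collapse = ", "), call. = FALSE)
  }
  compartment_counts(sum(obs$alpha), sum(obs$beta),
                     sum(obs$gamma), sum(obs$delta))
}
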