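# Tolerance below which the similarity denominator (least - p_ind) is treated
# as degenerate and the score flagged undefined (e.g. caged controls with no
# epoch-1 signal).
SCORE_DENOM_TOL <- 1e-12

#' Epoch activation fractions
#'
#' `e1_fraction()` is the fraction of scored neurons active in the first
#' exploration epoch (cytoplasmic signal): (gamma + delta) / n.
#' `e2_fraction()` is the fraction active in the second epoch (nuclear foci):
#' (beta + delta) / n. Both are invariant under uniform rescaling of the
#' counts, so percentages and raw tallies are interchangeable.
#'
#' @param counts a [compartment_counts()] object (or 4 numbers alpha, beta,
#'   gamma, delta).
#' @return A fraction in \[0, 1\].
#' @examples
#' e1_fraction(compartment_counts(55.23, 4.54, 7.53, 32.7)) # 0.4023
#' e2_fraction(compartment_counts(55.23, 4.54, 7.53, 32.7)) # 0.3724
#' @export
e1_fraction <- function(counts) {
  x <- validate_counts(counts)
  unname((x["gamma"] + x["delta"]) / sum(x))
}

#' @rdname e1_fraction
#' @export
e2_fraction <- function(counts) {
  x <- validate_counts(counts)
  unname((x["beta"] + x["delta"]) / sum(x))
}

#' Ensemble similarity score and its components
#'
#' Computes the full six-quantity similarity calculation on one compartment
#' tally:
#' \describe{
#'   \item{e1, e2}{activation fractions of the two epochs.}
#'   \item{p_ind}{`e1 * e2`, the expected double-positive fraction if the two
#'     ensembles were statistically independent.}
#'   \item{p_overlap}{`delta/n - p_ind`, the observed excess of double-positive
#'     neurons over the independence expectation (may be negative).}
#'   \item{least}{`min(e1, e2)`, the smaller of the two active populations —
#'     the most overlap geometrically possible.}
#'   \item{score}{`p_overlap / (least - p_ind)`, the excess overlap normalised
#'     so that perfect reactivation of the same ensemble (A/A) scores 1 and
#'     independent ensembles (A/B) score 0.}
#' }
#'
#' The score is at most 1 whenever defined and may be negative
#' (anti-correlated ensembles); negative values are returned, not clipped.
#' When `least - p_ind` is within `1e-12` of zero (no neurons active in one
#' epoch, or one epoch saturated) the score is undefined and returned as `NA`
#' with a `reason` string rather than an error, since caged-control data
#' legitimately produce such tallies.
#'
#' @param counts a [compartment_counts()] object or 4 numbers.
#' @return An object of class `"similarity_score"`: a list with elements
#'   `e1`, `e2`, `p_ind`, `p_overlap`, `least`, `score`, `defined`, `reason`.
#' @examples
#' # perfect A/A reactivation scores exactly 1
#' similarity_components(compartment_counts(60, 0, 0, 40))$score
#' # exact statistical independence scores exactly 0
#' similarity_components(compartment_counts(30, 20, 30, 20))$score
#' @references Vazdarjanova A, Guzowski JF (2004) J Neurosci 24:6489-6496.
#' @export
similarity_components <- function(counts) {
  x <- validate_counts(counts)
  n  <- sum(x)
  e1 <- unname((x["gamma"] + x["delta"]) / n)
  e2 <- unname((x["beta"] + x["delta"]) / n)
  p_ind     <- e1 * e2
  p_overlap <- unname(x["delta"] / n) - p_ind
  least     <- min(e1, e2)
  denom     <- least - p_ind
  if (denom <= SCORE_DENOM_TOL) {
    score   <- NA_real_
    defined <- FALSE
    reason  <- sprintf(
      "degenerate denominator: least (%.6g) - p_ind (%.6g) <= %.0e",
      least, p_ind, SCORE_DENOM_TOL)
  } else {
    score   <- p_overlap / denom
    defined <- TRUE
    reason  <- NA_character_
  }
  structure(
    list(e1 = e1, e2 = e2, p_ind = p_ind, p_overlap = p_overlap,
         least = least, score = score, defined = defined, reason = reason),
    class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, digits = 4, ...) {
  cat("Ensemble similarity (1 = perfect reactivation, 0 = independence)\n")
  cat(sprintf("  E1 = %.*f   E2 = %.*f   least = %.*f\n",
              digits, x$e1, digits, x$e2, digits, x$least))
  cat(sprintf("  p(E1E2) = %.*f   pO(E1E2) = %.*f\n",
              digits, x$p_ind, digits, x$p_overlap))
  if (x$defined) {
    cat(sprintf("  similarity score = %.*f\n", digits, x$score))
  } else {
    cat("  similarity score undefined:", x$reason, "\n")
  }
  invisible(x)
}

#' Similarity score as a bare number
#'
#' Convenience wrapper around [similarity_components()] returning only the
#' score (`NA` when undefined).
#'
#' @inheritParams similarity_components
#' @return A single numeric value.
#' @export
similarity_score <- function(counts) {
  similarity_components(counts)$score
}

#' Per-animal similarity scores
#'
#' Applies the similarity calculation to each row of an observation table.
#' Per-animal scores are the default reporting unit of this package (group
#' summaries are means of per-animal values, matching mean-plus-SEM
#' reporting); use [pooled_counts()] first for an explicit neuron-weighted
#' pooled score.
#'
#' @param obs observation table (see [animal_observations()]).
#' @return A `data.frame` with one row per input row and columns `animal_id`,
#'   `e1`, `e2`, `p_ind`, `p_overlap`, `least`, `score`, `score_defined`.
#'   Undefined scores are carried through as `NA` with `score_defined = FALSE`,
#'   never dropped.
#' @export
per_animal_scores <- function(obs) {
  obs <- validate_observations(obs)
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    s <- similarity_components(obs_counts(obs, i))
    data.frame(animal_id = obs$animal_id[i],
               e1 = s$e1, e2 = s$e2, p_ind = s$p_ind,
               p_overlap = s$p_overlap, least = s$least,
               score = s$score, score_defined = s$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
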