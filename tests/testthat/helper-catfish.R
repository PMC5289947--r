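# Independent transcription of the six-step similarity calculation, coded
# directly from the published definitions and kept separate from the package
# implementation so it can serve as an oracle.
oracle_similarity <- function(alpha, beta, gamma, delta) {
  n  <- alpha + beta + gamma + delta
  E1 <- (gamma + delta) / n
  E2 <- (beta + delta) / n
  p_ind <- E1 * E2
  pO <- delta / n - p_ind
  least <- min(E1, E2)
  score <- if (least - p_ind <= 1e-12) NA_real_ else pO / (least - p_ind)
  list(e1 = E1, e2 = E2, p_ind = p_ind, p_overlap = pO,
       least = least, score = score)
}

# all weak compositions of n into 4 non-negative parts
compositions4 <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (g in 0:(n - a - b)) {
    out[[length(out) + 1L]] <- c(a, b, g, n - a - b - g)
  }
  do.call(rbind, out)
}

# group-mean quadruples reassembled from the published percentages
wt_a20a_means <- c(alpha = 55.23, beta = 4.54, gamma = 7.53, delta = 32.7)
ts_a20a_means <- c(alpha = 60.77, beta = 11.03, gamma = 6.40, delta = 21.8)
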