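COUNTS_HEADER <- c("animal_id", "genotype", "paradigm",
                   "alpha", "beta", "gamma", "delta")

#' Read and write per-animal counts tables
#'
#' The on-disk dialect is a UTF-8 comma-separated file with exactly the header
#' `animal_id,genotype,paradigm,alpha,beta,gamma,delta` and one row per
#' animal and paradigm. Writing then reading reproduces the observation table
#' exactly for integer counts. Malformed headers, unknown genotype/paradigm
#' labels and negative counts raise parse errors naming the offending column
#' and line; single-epoch rows with nonzero `gamma`/`delta` are kept with a
#' warning (see [animal_observations()]).
#'
#' @param path file path.
#' @return `read_counts_csv()` returns an observation table (see
#'   [animal_observations()]); the writers return their input invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' sim <- simulate_cohort("WT_A20A", n_animals = 2, seed = 3)
#' write_counts_csv(sim, f)
#' read_counts_csv(f)
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), COUNTS_HEADER)) {
    stop("malformed header in ", path, ": expected '",
         paste(COUNTS_HEADER, collapse = ","), "' but found '",
         paste(names(raw), collapse = ","), "'", call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at line ", bad[1] + 1L,
           " of ", path, call. = FALSE)
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop("negative count in column '", col, "' at line ", neg[1] + 1L,
           " of ", path, call. = FALSE)
    }
    v
  }
  vocab <- function(col, allowed) {
    v <- toupper(raw[[col]])
    bad <- which(!(v %in% allowed))
    if (length(bad)) {
      stop("unknown ", col, " '", raw[[col]][bad[1]], "' at line ",
           bad[1] + 1L, " of ", path, call. = FALSE)
    }
    v
  }
  obs <- data.frame(
    animal_id = raw$animal_id,
    genotype  = vocab("genotype", catfish_genotypes),
    paradigm  = vocab("paradigm", catfish_paradigms),
    alpha = num("alpha"), beta = num("beta"),
    gamma = num("gamma"), delta = num("delta"),
    stringsAsFactors = FALSE
  )
  validate_observations(obs)
}

#' @rdname read_counts_csv
#' @param obs observation table to write.
#' @export
write_counts_csv <- function(obs, path) {
  obs <- validate_observations(obs)
  utils::write.csv(as.data.frame(obs)[, COUNTS_HEADER], path,
                   row.names = FALSE, quote = FALSE)
  invisible(obs)
}

#' @rdname read_counts_csv
#' @param scores a per-animal score table from [per_animal_scores()].
#' @export
write_scores_csv <- function(scores, path) {
  cols <- c("animal_id", "e1", "e2", "p_ind", "p_overlap", "least",
            "score", "score_defined")
  missing <- setdiff(cols, names(scores))
  if (length(missing)) {
    stop("score table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(scores[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(scores)
}
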