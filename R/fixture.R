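#' Published CA1 group values for wild-type and Ts65Dn mice
#'
#' The built-in table of group-level percentages, similarity scores and group
#' sizes reported for Arc catFISH in hippocampal CA1 of Ts65Dn mice and
#' wild-type littermates across the four behavioral paradigms. These are the
#' only quantitative inputs the source study publishes (no per-animal raw
#' data), so they drive the package's reproduction report and the simulator
#' presets.
#'
#' Every row carries a provenance tag: `"reported"` values appear verbatim in
#' the source's figure legends or results text (the `location` column says
#' where, descriptively); `"derived-by-subtraction"` values are cytoplasm-only
#' percentages recovered from a reported total Arc-positive percentage, with
#' the arithmetic spelled out in `note`.
#'
#' Measures: `nuclear_pct` (nucleus-only, category beta), `cyto_pct`
#' (cytoplasm-only, gamma), `double_pct` (double-positive, delta),
#' `total_arc_pct` (beta + gamma + delta as reported), `similarity_score`.
#' For the single-epoch paradigms (`CC`, `ASAC`) `nuclear_pct` is the only
#' activity measure.
#'
#' @return A `data.frame` with columns `genotype`, `paradigm`, `measure`,
#'   `value`, `sem`, `n_animals`, `n_neurons`, `provenance`, `location`,
#'   `note`.
#' @examples
#' ref <- reference_values()
#' subset(ref, paradigm == "ASAC" & measure == "nuclear_pct")
#' @export
reference_values <- function() {
  row <- function(genotype, paradigm, measure, value, sem, n_animals,
                  n_neurons, provenance, location, note = NA_character_) {
    data.frame(genotype = genotype, paradigm = paradigm, measure = measure,
               value = value, sem = sem, n_animals = n_animals,
               n_neurons = n_neurons, provenance = provenance,
               location = location, note = note, stringsAsFactors = FALSE)
  }
  leg1 <- "single-exploration figure legend"
  txt2 <- "two-exploration results text"
  leg2 <- "two-exploration figure legend"
  txt4 <- "repeated-exposure results text"
  leg5 <- "similarity-score figure and results text"
  rbind(
    row("WT",     "CC",   "nuclear_pct",  6.89, 1.35, 4, 900, "reported", leg1),
    row("TS65DN", "CC",   "nuclear_pct",  6.79, 2.57, 4, 340, "reported", leg1),
    row("WT",     "ASAC", "nuclear_pct", 39.05, 2.16, 4, 710, "reported", leg1),
    row("TS65DN", "ASAC", "nuclear_pct", 20.86, 1.79, 4, 767, "reported", leg1),
    row("WT",     "ASAC", "total_arc_pct", 44.1, NA, 4, 710, "reported", txt4,
        "composition of the total is not decomposable from reported parts"),
    row("WT", "A20A", "double_pct",  32.7, 2.18, 4, 583, "reported", txt2),
    row("WT", "A20A", "nuclear_pct",  4.54, 1.32, 4, 583, "reported", txt2),
    row("WT", "A20A", "cyto_pct",     7.53, 2.50, 4, 583, "reported", txt2),
    row("WT", "A20A", "total_arc_pct", 44.7,  NA, 4, 583, "reported", txt4),
    row("WT", "A20A", "similarity_score", 0.88, NA, 4, 583, "reported", leg5),
    row("TS65DN", "A20A", "double_pct",  21.8, 4.03, 4, 423, "reported", txt2),
    row("TS65DN", "A20A", "nuclear_pct", 11.03, 1.67, 4, 423, "reported", txt2),
    row("TS65DN", "A20A", "cyto_pct",     6.40, 2.65, 4, 423, "reported", txt2),
    row("TS65DN", "A20A", "total_arc_pct", 39.2, NA, 4, 423, "reported", txt4),
    row("TS65DN", "A20A", "similarity_score", 0.78, NA, 4, 423, "reported", leg5),
    row("WT", "AX4_A20A", "double_pct",  27.09, 3.68, 5, 656, "reported", txt4),
    row("WT", "AX4_A20A", "nuclear_pct",  6.98, 1.72, 5, 656, "reported", txt4),
    row("WT", "AX4_A20A", "cyto_pct",     5.53,   NA, 5, 656,
        "derived-by-subtraction", txt4, "39.6 - 27.09 - 6.98"),
    row("WT", "AX4_A20A", "total_arc_pct", 39.6,  NA, 5, 656, "reported", txt4),
    row("WT", "AX4_A20A", "similarity_score", 0.86, NA, 5, 656, "reported", leg5),
    row("TS65DN", "AX4_A20A", "double_pct",  13.95, 3.35, 4, 495, "reported", txt4),
    row("TS65DN", "AX4_A20A", "nuclear_pct", 17.22, 2.12, 4, 495, "reported", txt4),
    row("TS65DN", "AX4_A20A", "cyto_pct",     8.95,   NA, 4, 495,
        "derived-by-subtraction", txt4, "40.12 - 13.95 - 17.22"),
    row("TS65DN", "AX4_A20A", "total_arc_pct", 40.12, NA, 4, 495, "reported", txt4),
    row("TS65DN", "AX4_A20A", "similarity_score", 0.59, NA, 4, 495, "reported", leg5)
  )
}

#' Look up one reference value
#'
#' @param genotype,paradigm,measure row selectors (see [reference_values()]).
#' @param fixture a reference table; defaults to the built-in one.
#' @return The value, or `NA` if the row is absent.
#' @export
reference_value <- function(genotype, paradigm, measure,
                            fixture = reference_values()) {
  hit <- fixture$genotype == genotype & fixture$paradigm == paradigm &
    fixture$measure == measure
  if (!any(hit)) return(NA_real_)
  fixture$value[which(hit)[1]]
}

#' Group-mean compartment counts from the reference table
#'
#' Reassembles a per-100-neuron compartment tally from the published group
#' mean percentages: `beta` = nucleus-only, `gamma` = cytoplasm-only,
#' `delta` = double-positive, `alpha` = the remainder to 100. Single-epoch
#' paradigms get `gamma = delta = 0`. These group-mean tallies back the
#' simulator presets and the pooled-mean similarity scores.
#'
#' @inheritParams reference_value
#' @return A `"compartment_counts"` object on the per-100 scale.
#' @examples
#' reference_counts("WT", "A20A")
#' similarity_score(reference_counts("WT", "A20A"))  # ~0.796
#' @export
reference_counts <- function(genotype, paradigm,
                             fixture = reference_values()) {
  paradigm <- match_vocab(paradigm, catfish_paradigms, "paradigm")
  nuclear <- reference_value(genotype, paradigm, "nuclear_pct", fixture)
  if (!is_two_epoch(paradigm)) {
    return(compartment_counts(100 - nuclear, nuclear, 0, 0))
  }
  cyto   <- reference_value(genotype, paradigm, "cyto_pct", fixture)
  double <- reference_value(genotype, paradigm, "double_pct", fixture)
  compartment_counts(100 - nuclear - cyto - double, nuclear, cyto, double)
}
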