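#' Bundled reference cell counts
#'
#' Published cell counts from a 2-photon time-lapse study of tangentially
#' migrating midbrain dopaminergic neurons in organotypic slices of control
#' and Dab1-deficient (Reelin-signalling-null) mouse embryos, bundled as
#' plain-text tables so that bookkeeping identities can be checked against
#' the package's classification scheme. Three tables are available:
#'
#' * `"tracked_cells"`: per-genotype counts of tracked cells in each
#'   max-speed class (`n_cells`) together with the total number of tracked
#'   cells (`n_total`; 806 control, 844 mutant).
#' * `"morphology_subset"`: how many cells of each speed class were
#'   selected for frame-by-frame morphology annotation.
#' * `"morphology_categories"`: per-slice counts of annotated cells in each
#'   morphology category (constant bipolar, transitionary, constant
#'   multipolar), with the per-slice class denominator `n_total`.
#'
#' @param which Which table to return.
#' @return A tibble.
#' @export
reference_counts <- function(which = c("tracked_cells", "morphology_subset",
                                       "morphology_categories")) {
  which <- match.arg(which)
  file <- switch(which,
    tracked_cells = "tracked_cell_counts.csv",
    morphology_subset = "morphology_subset_counts.csv",
    morphology_categories = "morphology_category_table.csv"
  )
  path <- system.file("extdata", file, package = "saltatrack",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
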