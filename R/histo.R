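#' Mediolateral bin fractions in a fixed section
#'
#' Quantifies the mediolateral distribution of cells in a fixed section by
#' quadrisecting (by default) the line extending from the midline to the
#' most lateral marker-positive landmark cell. Each cell's position is
#' normalised to `u = (x - midline_x) / (landmark_x - midline_x)`; the
#' interval `[0, 1]` is split into `n_bins` equal bins, half-open `[lo,
#' hi)` except the most lateral bin which is closed at 1, and the fraction
#' of cells per bin is returned. Normalisation is per section: each
#' section's own midline and landmark define its grid. Cells falling
#' outside `[0, 1]` beyond the tolerance are excluded and reported.
#'
#' @param x Cell x-coordinates in micrometres.
#' @param midline_x Midline x-coordinate of this section.
#' @param landmark_x x-coordinate of the most lateral landmark cell; must
#'   differ from `midline_x`.
#' @param n_bins Number of bins (default 4, a quadrisection).
#' @param tol Tolerance on `u` outside `[0, 1]` before exclusion; small
#'   overshoots within the tolerance are clamped.
#' @return List with `fractions` (named numeric, sums to 1 over included
#'   cells), `n_used`, and `excluded` (tibble of the flagged cells with
#'   their `u`).
#' @export
mediolateral_fractions <- function(x, midline_x, landmark_x, n_bins = 4,
                                   tol = 1e-8) {
  if (length(x) < 1) abort("At least one cell is required.")
  if (landmark_x == midline_x) {
    abort("`landmark_x` must differ from `midline_x`.")
  }
  u <- (x - midline_x) / (landmark_x - midline_x)
  out_of_range <- u < -tol | u > 1 + tol
  excluded <- tibble(index = which(out_of_range), x = x[out_of_range],
                     u = u[out_of_range])
  u <- pmin(pmax(u[!out_of_range], 0), 1)
  if (length(u) == 0) {
    abort("All cells fall outside the midline-to-landmark span.")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(u, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  fr <- counts / length(u)
  names(fr) <- paste0("bin", seq_len(n_bins))
  list(fractions = fr, n_used = length(u), excluded = excluded)
}

#' SN/VTA region percentages
#'
#' Normalises per-region cell counts by the total number of cells in both
#' regions, as done when comparing the share of dopaminergic neurons in the
#' substantia nigra versus the ventral tegmental area.
#'
#' @param n_sn,n_vta Cell counts (non-negative, positive total).
#' @return Named numeric vector `c(SN = , VTA = )` in percent, summing to
#'   100.
#' @export
region_fractions <- function(n_sn, n_vta) {
  if (n_sn < 0 || n_vta < 0) abort("Counts must be non-negative.")
  total <- n_sn + n_vta
  if (total <= 0) abort("Total cell count must be positive.")
  c(SN = 100 * n_sn / total, VTA = 100 * n_vta / total)
}

#' Read a fixed-section cell coordinate table
#'
#' Expects columns `section_id`, `cell_id`, `x_um`, `midline_x_um`,
#' `landmark_x_um`, `group`, and optionally `region` (`SN` or `VTA`).
#'
#' @param path Path to the delimited file.
#' @return Tibble.
#' @export
read_section_cells <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("section_id", "cell_id", "x_um", "midline_x_um",
                "landmark_x_um", "group")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("'", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab
}
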