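#' Per-frame morphology state from process counts
#'
#' A neuron is `multipolar` at a frame when more than two processes arise
#' directly from the soma; otherwise it is bipolar, `bipolar_branched` if
#' the leading process is branched at that frame and `bipolar_unbranched`
#' if not.
#'
#' @param n_soma_processes Integer vector (>= 0): primary processes arising
#'   from the soma at each frame.
#' @param lp_branched Logical vector: is the leading process branched?
#' @return Factor with levels `bipolar_unbranched`, `bipolar_branched`,
#'   `multipolar`.
#' @export
morph_state <- function(n_soma_processes, lp_branched) {
  if (length(n_soma_processes) != length(lp_branched)) {
    abort("`n_soma_processes` and `lp_branched` must have equal length.")
  }
  if (any(n_soma_processes < 0) || anyNA(n_soma_processes)) {
    abort("`n_soma_processes` must be non-negative integers.")
  }
  out <- ifelse(n_soma_processes > 2, "multipolar",
                ifelse(lp_branched, "bipolar_branched", "bipolar_unbranched"))
  factor(out, levels = MORPH_STATES)
}

#' Morphology category of a cell over time
#'
#' `constant_bipolar` when every frame is bipolar (branched or unbranched
#' both count as bipolar), `constant_multipolar` when every frame is
#' multipolar, `transitionary` otherwise.
#'
#' @param states Non-empty factor/character vector of per-frame morphology
#'   states (levels as in [morph_state()]).
#' @return Factor with levels `constant_bipolar`, `constant_multipolar`,
#'   `transitionary`.
#' @export
categorize_cell <- function(states) {
  if (length(states) == 0) abort("`states` must be non-empty.")
  s <- as.character(states)
  if (!all(s %in% MORPH_STATES)) abort("Unknown morphology state.")
  multi <- s == "multipolar"
  out <- if (all(!multi)) "constant_bipolar"
         else if (all(multi)) "constant_multipolar"
         else "transitionary"
  factor(out, levels = MORPH_CATEGORIES)
}

#' Frequency of bipolar/multipolar transitions
#'
#' Counts the frames at which the cell switches polarity class (bipolar to
#' multipolar or back; branched/unbranched changes within the bipolar class
#' do not count) and divides by the elapsed time `(n - 1) * dt`.
#'
#' @param states Per-frame morphology states, at least 2 frames.
#' @param dt Frame interval in hours.
#' @return Transitions per hour.
#' @export
morph_transition_frequency <- function(states, dt) {
  if (length(states) < 2) abort("At least 2 frames are needed.")
  if (dt <= 0) abort("`dt` must be positive.")
  multi <- as.character(states) == "multipolar"
  sum(diff(multi) != 0) / ((length(states) - 1) * dt)
}

#' Branch transitions per hour
#'
#' Branch appearance/disappearance events are scored as the absolute change
#' in the total branch count between consecutive frames, summed over the
#' recording and divided by the elapsed time. Count differencing
#' undercounts a simultaneous appearance plus disappearance within one
#' interval; when an explicit per-event annotation is available it can be
#' passed as `events` (one row per appearance or disappearance) and is used
#' instead.
#'
#' @param branch_counts Integer vector of total branch counts per frame,
#'   at least 2 frames.
#' @param dt Frame interval in hours.
#' @param events Optional data frame of annotated events with a `frame`
#'   column; when given, the rate is `nrow(events)` over the elapsed time.
#' @return Branch transitions per hour.
#' @export
branch_transition_rate <- function(branch_counts, dt, events = NULL) {
  if (length(branch_counts) < 2) abort("At least 2 frames are needed.")
  if (dt <= 0) abort("`dt` must be positive.")
  if (any(branch_counts < 0)) abort("Branch counts must be >= 0.")
  elapsed <- (length(branch_counts) - 1) * dt
  n_events <- if (is.null(events)) {
    sum(abs(diff(branch_counts)))
  } else {
    nrow(events)
  }
  n_events / elapsed
}

#' Morphology composition of each speed band
#'
#' Pairs each frame's morphology state with the soma speed of the movement
#' from that frame to the next one (the forward convention used when
#' asking "how does a cell in this shape move?"), bands the speed, and
#' reports the morphology composition of every band. The backward
#' convention of [instantaneous_speeds()] is the per-timepoint velocity
#' definition; both are exposed via `convention`.
#'
#' @param pos Position matrix of the cell (frames x xyz).
#' @param states Per-frame morphology states covering at least the frames
#'   paired with a speed (all but the last frame under `"forward"`, all but
#'   the first under `"backward"`).
#' @param dt Frame interval in hours.
#' @param bands A [speed_bands()].
#' @param merge_bipolar Merge branched and unbranched bipolar states into
#'   one `bipolar` class (default `TRUE`).
#' @param convention `"forward"` (default) or `"backward"` speed pairing.
#' @return Tibble with `phase`, `state`, `n` and `fraction` (fractions sum
#'   to 1 within each occupied band).
#' @export
pair_speed_morphology <- function(pos, states, dt, bands = speed_bands(),
                                  merge_bipolar = TRUE,
                                  convention = c("forward", "backward")) {
  convention <- match.arg(convention)
  pos <- as.matrix(pos)
  speeds <- instantaneous_speeds(pos, dt)
  n_pairs <- length(speeds)
  s <- as.character(states)
  if (length(s) < n_pairs + ifelse(convention == "backward", 1L, 0L)) {
    abort("`states` does not cover the frames required for pairing.")
  }
  paired_states <- if (convention == "forward") s[seq_len(n_pairs)]
                   else s[seq_len(n_pairs) + 1L]
  if (merge_bipolar) {
    paired_states <- ifelse(paired_states == "multipolar",
                            "multipolar", "bipolar")
  }
  cuts <- c(bands$rest_max, bands$slow_max, bands$moderate_max)
  phase <- factor(PHASE_NAMES[findInterval(speeds, cuts) + 1L],
                  levels = PHASE_NAMES)
  tab <- as.data.frame(table(phase = phase, state = paired_states),
                       stringsAsFactors = FALSE)
  tab <- as_tibble(tab)
  names(tab)[names(tab) == "Freq"] <- "n"
  totals <- tapply(tab$n, tab$phase, sum)
  tab$fraction <- ifelse(totals[tab$phase] > 0,
                         tab$n / totals[tab$phase], NA_real_)
  tab[order(tab$phase, tab$state), ]
}

#' Spread of leading-process lengths across groups
#'
#' Summarises the per-group distribution of leading-process (plus soma)
#' lengths (median, IQR, range) and, for exactly two groups, compares their
#' dispersion with the ratio of IQRs and the Ansari-Bradley rank test for
#' differences in scale. This is a reproducible stand-in for the
#' qualitative observation that a perturbed population shows "very long and
#' very short" leading processes; no single canonical statistic exists for
#' that observation.
#'
#' @param lengths Numeric vector of lengths in micrometres (> 0).
#' @param group Group label per length; at least 2 values per group.
#' @return List with `summary` (tibble: group, n, median, iqr, min, max),
#'   and for two groups `iqr_ratio` (second / first, 1 when both are 0) and
#'   `dispersion_test` (the `htest` from [stats::ansari.test()]).
#' @export
lp_length_spread <- function(lengths, group) {
  if (length(lengths) != length(group)) {
    abort("`lengths` and `group` must have equal length.")
  }
  if (any(lengths <= 0) || anyNA(lengths)) abort("Lengths must be positive.")
  group <- as.character(group)
  sizes <- table(group)
  if (any(sizes < 2)) abort("Each group needs at least 2 lengths.")
  groups <- names(sizes)
  summary_tab <- dplyr::bind_rows(lapply(groups, function(g) {
    x <- lengths[group == g]
    tibble(group = g, n = length(x), median = median(x), iqr = IQR(x),
           min = min(x), max = max(x))
  }))
  out <- list(summary = summary_tab)
  if (length(groups) == 2) {
    i1 <- summary_tab$iqr[1]
    i2 <- summary_tab$iqr[2]
    out$iqr_ratio <- if (i1 == 0 && i2 == 0) 1 else i2 / i1
    out$dispersion_test <- suppressWarnings(
      stats::ansari.test(lengths[group == groups[1]],
                         lengths[group == groups[2]])
    )
  }
  out
}

#' Read per-frame morphology annotations
#'
#' Expects a comma-separated table with columns `cell_id`, `frame`,
#' `n_soma_processes`, `lp_branched`, `n_branches_total`.
#'
#' @param path Path to the delimited file.
#' @return Tibble of annotations ordered by cell and frame.
#' @export
read_morphology <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "frame", "n_soma_processes", "lp_branched",
                "n_branches_total")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("'", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(tab$n_branches_total < 0)) abort("`n_branches_total` must be >= 0.")
  tab$cell_id <- as.character(tab$cell_id)
  tab$lp_branched <- as.logical(tab$lp_branched)
  tab[order(tab$cell_id, tab$frame), ]
}
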