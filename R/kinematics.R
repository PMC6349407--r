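#' Speed-band cutoffs for migration classes
#'
#' The three cutoffs partition max-speeds (and instantaneous soma speeds)
#' into four half-open bands: rest/non-migratory `[0, rest_max)`, slow
#' `[rest_max, slow_max)`, moderate `[slow_max, moderate_max)` and fast
#' `[moderate_max, Inf)`. A value exactly on a cutoff belongs to the upper
#' band. The defaults (10, 30, 60 um/hr) follow the quartile-based
#' convention for tangentially migrating midbrain dopaminergic neurons: 10
#' and 30 um/hr are the lower and upper quartiles of a reference max-speed
#' distribution (see [derive_band_cutoffs()]); 60 um/hr is a fixed
#' constant separating moderate from fast movement.
#'
#' @param rest_max,slow_max,moderate_max Cutoffs in um/hr; must satisfy
#'   `0 < rest_max < slow_max < moderate_max`.
#' @return An object of class `speed_bands`.
#' @export
speed_bands <- function(rest_max = 10, slow_max = 30, moderate_max = 60) {
  v <- c(rest_max, slow_max, moderate_max)
  if (!is.numeric(v) || length(v) != 3 || anyNA(v)) {
    abort("Cutoffs must be single finite numbers.")
  }
  if (!(0 < rest_max && rest_max < slow_max && slow_max < moderate_max)) {
    abort("Cutoffs must satisfy 0 < rest_max < slow_max < moderate_max.")
  }
  structure(list(rest_max = rest_max, slow_max = slow_max,
                 moderate_max = moderate_max),
            class = "speed_bands")
}

#' @export
print.speed_bands <- function(x, ...) {
  cat("<speed_bands> rest < ", x$rest_max, " <= slow < ", x$slow_max,
      " <= moderate < ", x$moderate_max, " <= fast  (um/hr)\n", sep = "")
  invisible(x)
}

#' Instantaneous soma speeds
#'
#' The speed at frame k (k >= 1) is the 3D Euclidean displacement of the
#' soma from frame k-1 to frame k divided by the frame interval, i.e. the
#' backward difference used throughout the per-timepoint analysis.
#'
#' @param pos Numeric matrix (or data frame) of per-frame positions with
#'   columns x, y, z in micrometres; at least two rows.
#' @param dt Frame interval in hours.
#' @return Numeric vector of length `nrow(pos) - 1`, in um/hr.
#' @export
#' @examples
#' instantaneous_speeds(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)), dt = 1 / 6)
instantaneous_speeds <- function(pos, dt) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2) abort("At least two frames are needed to compute speeds.")
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive.")
  steps <- diff(pos[, 1:3, drop = FALSE])
  sqrt(rowSums(steps^2)) / dt
}

#' Per-cell kinematic summary
#'
#' Computes the quantities that characterise one cell's movement: average
#' and maximum instantaneous speed, total displacement (3D, start to end),
#' path length (sum of per-frame 3D steps), and directionality (total
#' displacement / path length, in `[0, 1]`). The directionality of a cell
#' that never moved (`path_length == 0`) is undefined and reported as `NA`
#' rather than 0; such cells are non-migratory and excluded from
#' displacement analyses downstream.
#'
#' @inheritParams instantaneous_speeds
#' @return One-row tibble with `n_frames`, `avg_speed`, `max_speed`,
#'   `total_displacement`, `path_length`, `directionality`.
#' @export
summarize_kinematics <- function(pos, dt) {
  pos <- as.matrix(pos)
  speeds <- instantaneous_speeds(pos, dt)
  path <- sum(speeds) * dt
  disp <- sqrt(sum((pos[nrow(pos), 1:3] - pos[1, 1:3])^2))
  tibble(
    n_frames = nrow(pos),
    avg_speed = mean(speeds),
    max_speed = max(speeds),
    total_displacement = disp,
    path_length = path,
    directionality = if (path > 0) disp / path else NA_real_
  )
}

#' Classify cells by their maximum soma speed
#'
#' @param max_speed Numeric vector of max-speeds in um/hr (>= 0).
#' @param bands A [speed_bands()].
#' @return Factor with levels `non_migratory`, `slow`, `moderate`, `fast`.
#' @export
#' @examples
#' classify_by_max_speed(c(0, 15, 45, 183))
classify_by_max_speed <- function(max_speed, bands = speed_bands()) {
  if (any(!is.finite(max_speed)) || any(max_speed < 0)) {
    abort("`max_speed` must be finite and non-negative.")
  }
  cuts <- c(bands$rest_max, bands$slow_max, bands$moderate_max)
  idx <- findInterval(max_speed, cuts) + 1L
  factor(SPEED_CLASSES[idx], levels = SPEED_CLASSES)
}

#' Fraction of time points spent in each speed band
#'
#' Applies the same half-open band convention as [classify_by_max_speed()]
#' to a cell's per-frame speed series, yielding the fraction of time points
#' spent at rest (< rest_max), in slow, moderate and fast migratory phases.
#'
#' @param speeds Non-empty numeric vector of instantaneous speeds (um/hr).
#' @param bands A [speed_bands()].
#' @return Named numeric vector (`rest`, `slow`, `moderate`, `fast`)
#'   summing to 1.
#' @export
phase_occupancy <- function(speeds, bands = speed_bands()) {
  if (length(speeds) == 0) abort("`speeds` must be non-empty.")
  if (any(!is.finite(speeds)) || any(speeds < 0)) {
    abort("`speeds` must be finite and non-negative.")
  }
  cuts <- c(bands$rest_max, bands$slow_max, bands$moderate_max)
  idx <- findInterval(speeds, cuts) + 1L
  counts <- tabulate(idx, nbins = 4L)
  setNames(counts / length(speeds), PHASE_NAMES)
}

#' Derive the rest and slow cutoffs from a reference distribution
#'
#' The rest and slow cutoffs are set to quantiles (by default the 25th and
#' 75th percentiles) of a reference collection of max-speeds, mirroring how
#' the 10 and 30 um/hr conventions arise from the quartiles of a mutant
#' population. The moderate/fast cutoff is not quantile-derived and is
#' supplied as a fixed constant.
#'
#' @param reference_max_speeds Numeric vector of max-speeds (um/hr), at
#'   least 4 values.
#' @param probs Pair of quantile probabilities, default `c(0.25, 0.75)`.
#' @param moderate_max Fixed moderate/fast cutoff, default 60 um/hr.
#' @param digits Optional rounding of the derived cutoffs.
#' @param type Quantile estimation type passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A [speed_bands()]. Degenerate references (equal quantiles) fail
#'   the band invariant and raise an error.
#' @export
derive_band_cutoffs <- function(reference_max_speeds, probs = c(0.25, 0.75),
                                moderate_max = 60, digits = NULL, type = 7) {
  if (length(reference_max_speeds) < 4) {
    abort("At least 4 reference values are needed to derive cutoffs.")
  }
  if (length(probs) != 2 || any(probs <= 0) || any(probs >= 1) ||
      probs[1] >= probs[2]) {
    abort("`probs` must be two increasing probabilities in (0, 1).")
  }
  q <- quantile(reference_max_speeds, probs = probs, names = FALSE, type = type)
  if (!is.null(digits)) q <- round(q, digits)
  speed_bands(rest_max = q[1], slow_max = q[2], moderate_max = moderate_max)
}

#' Per-frame displacement implied by a speed cutoff
#'
#' Converts a speed cutoff (um/hr) into the maximum soma displacement
#' between two consecutive frames that still counts as below the cutoff:
#' e.g. 10 um/hr at 10-min sampling corresponds to 1.7 um per frame, the
#' displacement non-migratory cells never exceed.
#'
#' @param speed_cutoff Speed cutoff in um/hr (> 0).
#' @param frame_interval_min Frame interval in minutes (> 0).
#' @param digits Optional rounding (e.g. `1` to report 1.7).
#' @return Displacement in micrometres.
#' @export
frame_displacement_threshold <- function(speed_cutoff, frame_interval_min,
                                         digits = NULL) {
  if (!is.numeric(speed_cutoff) || speed_cutoff <= 0 ||
      !is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    abort("Both inputs must be positive.")
  }
  out <- speed_cutoff * frame_interval_min / 60
  if (!is.null(digits)) out <- round(out, digits)
  out
}
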