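deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap degrees into (-180, 180].
wrap_angle <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Midline-referenced trajectory angle of a track
#'
#' The trajectory angle is the signed 2D angle between the midline axis
#' (the image y-axis, 0 degrees) and the cell's net displacement vector
#' from its first to its last soma position; z is ignored. Positive angles
#' point laterally (away from the midline): for cells on the left side of
#' the midline the x-displacement is mirrored so that +x means lateral for
#' every cell and both sides can be pooled. 90 degrees is movement
#' precisely along the lateral axis; 0 degrees is movement parallel to the
#' midline.
#'
#' @param pos Position matrix as in [instantaneous_speeds()].
#' @param side `"right"` or `"left"`: which side of the midline the cell
#'   lies on (decides the mirroring).
#' @return Angle in degrees in (-180, 180], or `NA` (with a warning) when
#'   the net xy-displacement is zero and the angle is undefined.
#' @export
#' @examples
#' trajectory_angle(rbind(c(0, 0, 0), c(5, 0, 0)), side = "right") # 90
trajectory_angle <- function(pos, side = c("right", "left")) {
  side <- match.arg(side)
  pos <- as.matrix(pos)
  dx <- pos[nrow(pos), 1] - pos[1, 1]
  dy <- pos[nrow(pos), 2] - pos[1, 2]
  if (side == "left") dx <- -dx
  if (dx == 0 && dy == 0) {
    warn("Zero net xy-displacement: trajectory angle undefined.")
    return(NA_real_)
  }
  wrap_angle(rad2deg(atan2(dx, dy)))
}

#' Fraction of laterally migrating cells
#'
#' A cell counts as migrating laterally when its trajectory angle lies in
#' the closed band (default 45 to 135 degrees) around the lateral axis.
#'
#' @param angles Non-empty numeric vector of trajectory angles in degrees.
#' @param band Closed angular band, default `c(45, 135)`.
#' @return Fraction in `[0, 1]`. `NA` angles (undefined trajectories) are
#'   not allowed.
#' @export
lateral_fraction <- function(angles, band = c(45, 135)) {
  if (length(angles) == 0) abort("`angles` must be non-empty.")
  if (anyNA(angles)) abort("`angles` must not contain NA.")
  a <- wrap_angle(angles)
  mean(a >= band[1] & a <= band[2])
}

#' Circular mean, resultant length and angular deviation
#'
#' Summarises a set of angles with the first trigonometric moment: the
#' circular mean `atan2(mean sin, mean cos)`, the mean resultant length R
#' in `[0, 1]`, and the angular deviation `sqrt(2 * (1 - R))` (radians,
#' reported in degrees; bounded by about 81.03 degrees). The angular
#' deviation is the spread statistic conventionally reported alongside the
#' angular mean for trajectory-angle distributions; it is bounded, unlike
#' the circular standard deviation `sqrt(-2 log R)`. When R is numerically
#' zero the mean direction is undefined and reported as `NA`.
#'
#' @param angles Non-empty numeric vector of angles in degrees.
#' @param tol Resultant length below which the mean is flagged undefined.
#' @return A list of class `angular_summary` with `n`, `mean_deg`,
#'   `resultant_R` and `ang_dev_deg`.
#' @export
#' @examples
#' circular_summary(c(0, 90)) # mean 45, R = sqrt(0.5), ang_dev 43.85
circular_summary <- function(angles, tol = 1e-9) {
  if (length(angles) == 0) abort("`angles` must be non-empty.")
  if (anyNA(angles)) abort("`angles` must not contain NA.")
  th <- deg2rad(angles)
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- min(sqrt(C^2 + S^2), 1)
  structure(
    list(
      n = length(angles),
      mean_deg = if (R < tol) NA_real_ else wrap_angle(rad2deg(atan2(S, C))),
      resultant_R = R,
      ang_dev_deg = rad2deg(sqrt(2 * (1 - R)))
    ),
    class = "angular_summary"
  )
}

#' @export
print.angular_summary <- function(x, ...) {
  cat("<angular_summary> n = ", x$n,
      ", mean = ", if (is.na(x$mean_deg)) "undefined" else
        paste0(signif(x$mean_deg, 4), " deg"),
      ", R = ", signif(x$resultant_R, 4),
      ", ang. deviation = ", signif(x$ang_dev_deg, 4), " deg\n", sep = "")
  invisible(x)
}

#' Two-sample Kuiper test for circular distributions
#'
#' Kuiper's statistic `V = max(F1 - F2) + max(F2 - F1)` over the circle,
#' where F1 and F2 are the sample ECDFs evaluated from a common origin. V
#' is invariant under a common rotation of both samples (including past the
#' +/-180 wrap), which makes it the appropriate two-sample test for
#' trajectory-angle distributions where no origin is privileged. Ties are
#' handled through the ECDF step heights directly; no jitter is applied.
#'
#' The p-value uses the asymptotic Kuiper tail series with effective sample
#' size `N = n1 * n2 / (n1 + n2)` and the standard small-sample correction
#' `lambda = (sqrt(N) + 0.155 + 0.24 / sqrt(N)) * V`. The approximation is
#' inaccurate for `min(n1, n2) < 5`; p is clamped to `[0, 1]`.
#'
#' @param a,b Non-empty numeric vectors of angles in degrees.
#' @return A list of class `kuiper_result` with `V`, `p`, `n1`, `n2`.
#' @export
kuiper_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be non-empty.")
  if (anyNA(a) || anyNA(b)) abort("Samples must not contain NA.")
  ra <- a %% 360
  rb <- b %% 360
  xs <- sort(unique(c(ra, rb)))
  Fa <- findInterval(xs, sort(ra)) / length(ra)
  Fb <- findInterval(xs, sort(rb)) / length(rb)
  V <- max(Fa - Fb) + max(Fb - Fa)
  structure(
    list(V = V, p = kuiper_pvalue(V, length(a), length(b)),
         n1 = length(a), n2 = length(b)),
    class = "kuiper_result"
  )
}

# Asymptotic upper tail of Kuiper's statistic.
kuiper_pvalue <- function(V, n1, n2) {
  N <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(N) + 0.155 + 0.24 / sqrt(N)) * V
  if (lambda < 0.4) return(1)
  j <- seq_len(120)
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.kuiper_result <- function(x, ...) {
  cat("<kuiper_result> V = ", signif(x$V, 4), ", p = ", signif(x$p, 4),
      " (n1 = ", x$n1, ", n2 = ", x$n2, ")\n", sep = "")
  invisible(x)
}

#' Polar histogram bin fractions
#'
#' Bins angles into `n_bins` equal-width bins partitioning the circle.
#' Bins are half-open `[lo, hi)`: an angle exactly on a bin edge goes to
#' the upper bin (180 degrees wraps to the -180 edge).
#'
#' @param angles Non-empty numeric vector of angles in degrees.
#' @param n_bins Number of bins (>= 2).
#' @return Tibble with `bin_lo`, `bin_hi`, `bin_mid`, `count`, `fraction`;
#'   fractions sum to 1.
#' @export
polar_histogram <- function(angles, n_bins = 24) {
  if (length(angles) == 0) abort("`angles` must be non-empty.")
  if (anyNA(angles)) abort("`angles` must not contain NA.")
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  a <- wrap_angle(angles)
  a[a == 180] <- -180
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  idx <- findInterval(a, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin_lo = breaks[-(n_bins + 1)],
    bin_hi = breaks[-1],
    bin_mid = (breaks[-(n_bins + 1)] + breaks[-1]) / 2,
    count = counts,
    fraction = counts / length(a)
  )
}

#' Per-step movement angles grouped by speed band
#'
#' Resolves each cell's movement into per-frame steps, computes the
#' midline-referenced 2D direction of every step (same convention as
#' [trajectory_angle()], with left-side mirroring), and attaches the speed
#' band of the step. This supports phase-level directional analyses, e.g.
#' comparing the anisotropy of slow-phase versus fast-phase movements.
#' Steps with zero xy-displacement have an undefined angle and are dropped.
#'
#' @param pop A [population()].
#' @param bands A [speed_bands()].
#' @return Tibble with `cell_id`, `frame` (index of the step's end frame),
#'   `speed`, `phase` (factor `rest`/`slow`/`moderate`/`fast`), and
#'   `angle_deg`.
#' @export
step_angles <- function(pop, bands = speed_bands()) {
  stopifnot(inherits(pop, "population"))
  cuts <- c(bands$rest_max, bands$slow_max, bands$moderate_max)
  by_cell <- split(pop$tracks, pop$tracks$cell_id)
  rows <- lapply(by_cell, function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$frame), ]
    dx <- diff(d$x_um)
    dy <- diff(d$y_um)
    dz <- diff(d$z_um)
    if (d$side[1] == "left") dx <- -dx
    sp <- sqrt(dx^2 + dy^2 + dz^2) / pop$dt
    ok <- !(dx == 0 & dy == 0)
    tibble(
      cell_id = d$cell_id[1],
      frame = d$frame[-1][ok],
      speed = sp[ok],
      phase = factor(PHASE_NAMES[findInterval(sp[ok], cuts) + 1L],
                     levels = PHASE_NAMES),
      angle_deg = wrap_angle(rad2deg(atan2(dx[ok], dy[ok])))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(cell_id = character(), frame = integer(), speed = numeric(),
                  phase = factor(character(), levels = PHASE_NAMES),
                  angle_deg = numeric())
  }
  out
}
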