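#' Parameters of the saltatory-migration generative model
#'
#' The generator is a hidden-state random walk: each cell carries a
#' three-state Markov chain (`rest`, `slow`, `spurt`) over uniformly
#' sampled frames. The step taken from frame k to k+1 is governed by the
#' state at frame k: its length is `speed * dt` with the speed drawn from
#' the state's lognormal distribution, and its xy-direction is drawn from
#' the state's von Mises distribution (mean direction in degrees with 90 =
#' lateral, concentration kappa; kappa = 0 is isotropic). z receives weak
#' isotropic jitter only, since soma speeds are 3D but directional signal
#' is confined to the horizontal plane. A fraction of cells is locked in
#' `rest` for the whole recording (never-migrating cells). Morphology is
#' emitted per frame from state-specific probabilities over the three
#' morphology states, and a per-frame branch-event rate drives a +/-1
#' random walk on the total branch count.
#'
#' @param n_frames Number of frames (default 27, about 4.3 h at 10-min
#'   sampling).
#' @param dt Frame interval in hours (default 1/6).
#' @param transition 3x3 row-stochastic matrix over states
#'   `c("rest", "slow", "spurt")` (rows = from, columns = to).
#' @param speed_median Named numeric: lognormal median speed per state,
#'   um/hr. The rest median must lie below 10 um/hr. The rest and slow
#'   distributions are truncated at `rest_cutoff` (rest below it, slow
#'   above it) so that the hidden states keep the phase semantics of the
#'   speed bands they are named after; the spurt distribution is left
#'   untruncated to preserve its heavy right tail.
#' @param speed_sdlog Named numeric: lognormal sdlog per state.
#' @param dir_mean_deg Named numeric: von Mises mean direction per state.
#' @param dir_kappa Named numeric: von Mises concentration per state
#'   (>= 0).
#' @param fraction_never_migrating Probability a cell is locked at rest.
#' @param morph_emission 3x3 row-stochastic matrix: rows = chain states,
#'   columns = `c("bipolar_unbranched", "bipolar_branched", "multipolar")`.
#' @param branch_event_rate Per-frame probability of a branch appearance or
#'   disappearance event.
#' @param bipolar_speed_min Speed floor (um/hr) above which the emitted
#'   morphology is forced bipolar: fast spurts occur only in bipolar
#'   morphology, so any frame whose forward step exceeds this speed emits a
#'   bipolar state regardless of the per-state emission probabilities
#'   (default 60, the moderate/fast cutoff). Set to `Inf` to decouple
#'   morphology from realized speed.
#' @param z_sigma Std. dev. of per-step z jitter in micrometres.
#' @param rest_cutoff Speed (um/hr) separating the rest and slow emission
#'   supports (default 10, the rest band cutoff).
#' @param midline_x Midline x-coordinate of the simulated field (um).
#' @param condition Free-text condition label attached to the tracks.
#' @param seed Default RNG seed used by [simulate_population()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_frames = 27, dt = 1 / 6,
                       transition,
                       speed_median, speed_sdlog,
                       dir_mean_deg, dir_kappa,
                       fraction_never_migrating,
                       morph_emission,
                       branch_event_rate,
                       bipolar_speed_min = 60,
                       z_sigma = 0.5,
                       rest_cutoff = 10,
                       midline_x = 0,
                       condition = "simulated",
                       seed = 1L) {
  states <- c("rest", "slow", "spurt")
  transition <- as.matrix(transition)
  morph_emission <- as.matrix(morph_emission)
  stopifnot(all(dim(transition) == c(3, 3)),
            all(dim(morph_emission) == c(3, 3)))
  dimnames(transition) <- list(states, states)
  dimnames(morph_emission) <- list(states, MORPH_STATES)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort("Each transition-matrix row must be non-negative and sum to 1.")
  }
  if (any(morph_emission < 0) ||
      any(abs(rowSums(morph_emission) - 1) > 1e-8)) {
    abort("Each morphology-emission row must be non-negative and sum to 1.")
  }
  named3 <- function(x, what) {
    if (length(x) != 3) abort(paste0("`", what, "` must have 3 entries."))
    setNames(as.numeric(x), states)
  }
  speed_median <- named3(speed_median, "speed_median")
  speed_sdlog <- named3(speed_sdlog, "speed_sdlog")
  dir_mean_deg <- named3(dir_mean_deg, "dir_mean_deg")
  dir_kappa <- named3(dir_kappa, "dir_kappa")
  if (any(dir_kappa < 0)) abort("`dir_kappa` must be >= 0.")
  if (any(speed_median <= 0) || any(speed_sdlog <= 0)) {
    abort("Speed parameters must be positive.")
  }
  if (rest_cutoff <= 0) abort("`rest_cutoff` must be positive.")
  if (speed_median[["rest"]] >= rest_cutoff) {
    abort("The rest-state median speed must lie below the rest cutoff.")
  }
  if (fraction_never_migrating < 0 || fraction_never_migrating > 1) {
    abort("`fraction_never_migrating` must be a probability.")
  }
  if (branch_event_rate < 0 || branch_event_rate > 1) {
    abort("`branch_event_rate` must be a probability.")
  }
  if (!is.numeric(bipolar_speed_min) || bipolar_speed_min <= 0) {
    abort("`bipolar_speed_min` must be positive (or Inf).")
  }
  if (n_frames < 2) abort("`n_frames` must be at least 2.")
  if (dt <= 0) abort("`dt` must be positive.")
  structure(
    list(
      n_frames = as.integer(n_frames), dt = dt,
      transition = transition,
      speed_median = speed_median, speed_sdlog = speed_sdlog,
      dir_mean_deg = dir_mean_deg, dir_kappa = dir_kappa,
      fraction_never_migrating = fraction_never_migrating,
      morph_emission = morph_emission,
      branch_event_rate = branch_event_rate,
      bipolar_speed_min = bipolar_speed_min,
      z_sigma = z_sigma, rest_cutoff = rest_cutoff, midline_x = midline_x,
      condition = condition, seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> '", x$condition, "': ", x$n_frames, " frames, dt = ",
      signif(x$dt, 4), " hr, never-migrating fraction = ",
      x$fraction_never_migrating, "\n", sep = "")
  invisible(x)
}

#' Default generator parameterisations
#'
#' Two bundled parameter sets encode the contrast between an intact
#' population (`control_like`) and one lacking Reelin/DAB1 signalling
#' (`mutant_like`). The control-like defaults were calibrated once so that
#' simulated max-speed quartiles fall near the quartile quartet observed in
#' control slices (about 12/24/48 um/hr) with laterally biased slow
#' movement (kappa about 0.5 at 90 degrees) and strongly lateral spurts.
#' The mutant-like set differs in the encoded biology: lower spurt-entry
#' probability, a higher never-migrating fraction, an isotropic slow phase
#' (kappa = 0), unchanged spurt anisotropy, less slow-phase exposure and a
#' higher morphology instability (more multipolar emission and more branch
#' events).
#'
#' @param condition `"control_like"` or `"mutant_like"`.
#' @return A [sim_params()].
#' @export
default_sim_params <- function(condition = c("control_like", "mutant_like")) {
  condition <- match.arg(condition)
  if (condition == "control_like") {
    sim_params(
      transition = rbind(
        rest  = c(0.880, 0.110, 0.010),
        slow  = c(0.530, 0.455, 0.015),
        spurt = c(0.400, 0.400, 0.200)
      ),
      speed_median = c(rest = 2.5, slow = 8, spurt = 80),
      speed_sdlog = c(rest = 0.45, slow = 0.65, spurt = 0.40),
      dir_mean_deg = c(rest = 90, slow = 90, spurt = 90),
      dir_kappa = c(rest = 0, slow = 0.4, spurt = 2.5),
      fraction_never_migrating = 0.14,
      morph_emission = rbind(
        rest  = c(0.45, 0.15, 0.40),
        slow  = c(0.52, 0.15, 0.33),
        spurt = c(0.85, 0.15, 0.00)
      ),
      branch_event_rate = 0.10,
      condition = condition
    )
  } else {
    sim_params(
      transition = rbind(
        rest  = c(0.900, 0.096, 0.004),
        slow  = c(0.594, 0.400, 0.006),
        spurt = c(0.400, 0.400, 0.200)
      ),
      speed_median = c(rest = 2.5, slow = 8, spurt = 80),
      speed_sdlog = c(rest = 0.45, slow = 0.55, spurt = 0.40),
      dir_mean_deg = c(rest = 90, slow = 90, spurt = 90),
      dir_kappa = c(rest = 0, slow = 0, spurt = 2.5),
      fraction_never_migrating = 0.20,
      morph_emission = rbind(
        rest  = c(0.35, 0.15, 0.50),
        slow  = c(0.42, 0.15, 0.43),
        spurt = c(0.85, 0.15, 0.00)
      ),
      branch_event_rate = 0.25,
      condition = condition
    )
  }
}

#' Set the spurt-entry probability of a parameter set
#'
#' Rewrites the `rest -> spurt` and `slow -> spurt` transition
#' probabilities to `p`, rescaling the remaining mass of each row
#' proportionally, so that parameter sets differing only in how readily
#' cells launch a fast spurt can be compared.
#'
#' @param params A [sim_params()].
#' @param p New spurt-entry probability (applied to the rest and slow
#'   rows).
#' @return A modified [sim_params()].
#' @export
set_spurt_entry <- function(params, p) {
  stopifnot(inherits(params, "sim_params"))
  if (p < 0 || p >= 1) abort("`p` must be in [0, 1).")
  tr <- params$transition
  for (row in c("rest", "slow")) {
    keep <- tr[row, c("rest", "slow")]
    tr[row, c("rest", "slow")] <- keep / sum(keep) * (1 - p)
    tr[row, "spurt"] <- p
  }
  params$transition <- tr
  params
}

# Best-Fisher rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu_deg, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -180, 180))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling((n - length(out)) * 1.6))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)) + mu
    out <- c(out, th)
  }
  wrap_angle(rad2deg(out[seq_len(n)]))
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param transition Row-stochastic square matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  setNames(v / sum(v), rownames(transition))
}

#' Simulate a population of saltatory migrating cells
#'
#' Draws `n_cells` independent cells under the generative model described
#' in [sim_params()]. Output is bit-identical for identical
#' `(params, n_cells, seed)`. Cells start at uniform random positions in a
#' slice-sized field on the right of the midline, so `side` is `"right"`
#' throughout and no mirroring is triggered downstream.
#'
#' @param params A [sim_params()].
#' @param n_cells Number of cells (>= 1).
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A list of class `migration_sim` with `population` (a
#'   [population()]), `morphology` (per-frame annotation tibble as read by
#'   [read_morphology()]), `truth` (list with `states`: tibble of the
#'   hidden state at every frame, and `locked`: tibble flagging
#'   never-migrating cells), and `params`.
#' @export
simulate_population <- function(params, n_cells, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  nf <- params$n_frames
  states <- c("rest", "slow", "spurt")
  pi0 <- stationary_distribution(params$transition)
  locked <- runif(n_cells) < params$fraction_never_migrating

  # hidden state paths: one state per frame, vectorised over cells
  S <- matrix(1L, n_cells, nf)
  cum0 <- cumsum(pi0)
  S[, 1] <- findInterval(runif(n_cells), cum0) + 1L
  S[, 1] <- pmin(S[, 1], 3L)
  cumP <- t(apply(params$transition, 1, cumsum))
  for (k in 2:nf) {
    u <- runif(n_cells)
    nxt <- integer(n_cells)
    for (s in 1:3) {
      idx <- S[, k - 1] == s
      if (any(idx)) nxt[idx] <- pmin(findInterval(u[idx], cumP[s, ]) + 1L, 3L)
    }
    S[, k] <- nxt
  }
  S[locked, ] <- 1L

  # steps: the move from frame k to k+1 is governed by the state at frame k
  n_steps <- nf - 1L
  step_state <- S[, seq_len(n_steps), drop = FALSE]
  speeds <- matrix(0, n_cells, n_steps)
  angles <- matrix(0, n_cells, n_steps)
  for (s in 1:3) {
    idx <- step_state == s
    m <- sum(idx)
    if (m == 0) next
    ml <- log(params$speed_median[s])
    sd <- params$speed_sdlog[s]
    u <- runif(m)
    speeds[idx] <- if (s == 1L) {
      # rest: lognormal truncated below the rest cutoff
      stats::qlnorm(u * stats::plnorm(params$rest_cutoff, ml, sd), ml, sd)
    } else if (s == 2L) {
      # slow: lognormal truncated above the rest cutoff
      p0 <- stats::plnorm(params$rest_cutoff, ml, sd)
      stats::qlnorm(p0 + u * (1 - p0), ml, sd)
    } else {
      stats::qlnorm(u, ml, sd)
    }
    angles[idx] <- rvonmises(m, params$dir_mean_deg[s], params$dir_kappa[s])
  }
  th <- deg2rad(angles)
  dx <- speeds * params$dt * sin(th)
  dy <- speeds * params$dt * cos(th)
  dz <- matrix(rnorm(n_cells * n_steps, 0, params$z_sigma), n_cells, n_steps)
  # z jitter contributes to 3D speed just like in real tracks; rest-state
  # jitter is capped so a resting step never crosses the rest cutoff in 3D
  rest_idx <- step_state == 1L
  cap <- 0.999 * sqrt(pmax(
    (params$rest_cutoff * params$dt)^2 - (speeds[rest_idx] * params$dt)^2, 0))
  dz[rest_idx] <- sign(dz[rest_idx]) * pmin(abs(dz[rest_idx]), cap)

  x0 <- runif(n_cells, params$midline_x + 60, params$midline_x + 260)
  y0 <- runif(n_cells, 0, 400)
  z0 <- runif(n_cells, 0, 30)
  X <- cbind(x0, x0 + t(apply(dx, 1, cumsum)))
  Y <- cbind(y0, y0 + t(apply(dy, 1, cumsum)))
  Z <- cbind(z0, z0 + t(apply(dz, 1, cumsum)))

  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  tracks <- tibble(
    cell_id = rep(cell_ids, each = nf),
    frame = rep(seq_len(nf) - 1L, n_cells),
    t_hr = rep((seq_len(nf) - 1L) * params$dt, n_cells),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y)),
    z_um = as.vector(t(Z)),
    side = "right",
    condition = params$condition,
    slice_id = "sim"
  )

  # morphology: emitted per frame from the state at that frame
  emis_cum <- t(apply(params$morph_emission, 1, cumsum))
  u <- matrix(runif(n_cells * nf), n_cells, nf)
  M <- matrix(1L, n_cells, nf)
  for (s in 1:3) {
    idx <- S == s
    if (any(idx)) M[idx] <- pmin(findInterval(u[idx], emis_cum[s, ]) + 1L, 3L)
  }
  # speed-morphology coupling: frames whose forward step is a fast spurt
  # are bipolar (multipolar resamples to unbranched/branched by emission)
  if (is.finite(params$bipolar_speed_min)) {
    fast_frame <- cbind(speeds >= params$bipolar_speed_min, FALSE)
    force_idx <- fast_frame & M == 3L
    if (any(force_idx)) {
      s_at <- S[force_idx]
      p_b <- params$morph_emission[cbind(s_at, 2L)]
      p_u <- params$morph_emission[cbind(s_at, 1L)]
      pr <- ifelse(p_u + p_b > 0, p_b / (p_u + p_b), 0.5)
      M[force_idx] <- ifelse(runif(sum(force_idx)) < pr, 2L, 1L)
    }
  }
  # branch-count random walk driven by the per-frame event rate
  ev <- matrix(runif(n_cells * nf) < params$branch_event_rate, n_cells, nf)
  sgn <- matrix(sample(c(-1L, 1L), n_cells * nf, replace = TRUE), n_cells, nf)
  B <- matrix(0L, n_cells, nf)
  B[, 1] <- 1L
  for (k in 2:nf) {
    delta <- ifelse(ev[, k], ifelse(B[, k - 1] == 0L, 1L, sgn[, k]), 0L)
    B[, k] <- B[, k - 1] + delta
  }
  morph <- tibble(
    cell_id = rep(cell_ids, each = nf),
    frame = rep(seq_len(nf) - 1L, n_cells),
    n_soma_processes = ifelse(as.vector(t(M)) == 3L, 3L, 2L),
    lp_branched = as.vector(t(M)) == 2L,
    n_branches_total = as.vector(t(B))
  )

  truth_states <- tibble(
    cell_id = rep(cell_ids, each = nf),
    frame = rep(seq_len(nf) - 1L, n_cells),
    state = states[as.vector(t(S))]
  )

  structure(
    list(
      population = population(tracks, dt = params$dt,
                              midline_x = params$midline_x,
                              provenance = "simulate_population"),
      morphology = morph,
      truth = list(states = truth_states,
                   locked = tibble(cell_id = cell_ids, locked = locked)),
      params = params,
      seed = as.integer(seed)
    ),
    class = "migration_sim"
  )
}

#' @export
print.migration_sim <- function(x, ...) {
  cat("<migration_sim> '", x$params$condition, "', ",
      nrow(x$truth$locked), " cells, ", x$params$n_frames,
      " frames, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Compare pipeline estimates against simulation ground truth
#'
#' Runs the analysis pipeline on a simulated population and reports how
#' well it recovers the generative parameters: the pooled rest-band
#' occupancy of chain-governed (non-locked) cells versus the chain's
#' stationary rest probability, the trajectory-angle circular mean of
#' spurt-capable cells versus the configured spurt direction, per-state
#' resultant lengths of step directions (a monotone proxy for the von
#' Mises concentrations), and the max-speed class composition.
#'
#' @param sim A `migration_sim` from [simulate_population()].
#' @param bands A [speed_bands()].
#' @return A list of class `recovery_report`.
#' @export
recover_parameters <- function(sim, bands = speed_bands()) {
  stopifnot(inherits(sim, "migration_sim"))
  pop <- sim$population
  params <- sim$params
  ids <- sim$truth$locked$cell_id
  if (!setequal(unique(pop$tracks$cell_id), ids)) {
    abort("Ground truth does not match the population.")
  }
  chain_ids <- ids[!sim$truth$locked$locked]

  st <- step_angles(pop, bands)
  st_chain <- st[st$cell_id %in% chain_ids, ]
  # steps are governed by the states at frames 0..n-2 (stationary-distributed)
  stationary <- stationary_distribution(params$transition)
  rest_occ_est <- mean(st_chain$phase == "rest")

  feats <- analyze_population(pop, bands = bands)$features
  class_fracs <- prop.table(table(feats$speed_class))

  spurt_cells <- unique(sim$truth$states$cell_id[
    sim$truth$states$state == "spurt" &
      sim$truth$states$frame < params$n_frames - 1L])
  spurt_mean_est <- NA_real_
  spurt_mean_error <- NA_real_
  if (length(spurt_cells) > 0) {
    ang <- feats$trajectory_angle_deg[feats$cell_id %in% spurt_cells]
    ang <- ang[!is.na(ang)]
    if (length(ang) > 0) {
      cs <- circular_summary(ang)
      spurt_mean_est <- cs$mean_deg
      spurt_mean_error <- abs(wrap_angle(spurt_mean_est -
                                           params$dir_mean_deg[["spurt"]]))
    }
  }

  # per-state resultant length of step directions (kappa proxy)
  state_key <- paste(sim$truth$states$cell_id, sim$truth$states$frame)
  state_of <- setNames(sim$truth$states$state, state_key)
  governing <- state_of[paste(st$cell_id, st$frame - 1L)]
  kappa_proxy <- vapply(c("rest", "slow", "spurt"), function(s) {
    a <- st$angle_deg[governing == s]
    if (length(a) < 2) return(NA_real_)
    circular_summary(a)$resultant_R
  }, numeric(1))

  structure(
    list(
      stationary = stationary,
      rest_occupancy_true = stationary[["rest"]],
      rest_occupancy_est = rest_occ_est,
      rest_occupancy_error = abs(rest_occ_est - stationary[["rest"]]),
      class_fractions = class_fracs,
      fast_fraction = unname(class_fracs["fast"]),
      spurt_mean_true = params$dir_mean_deg[["spurt"]],
      spurt_mean_est = spurt_mean_est,
      spurt_mean_error = spurt_mean_error,
      step_resultant_by_state = kappa_proxy,
      n_cells = length(ids),
      n_chain_cells = length(chain_ids)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> rest occupancy ", signif(x$rest_occupancy_est, 3),
      " (truth ", signif(x$rest_occupancy_true, 3), "), spurt mean ",
      signif(x$spurt_mean_est, 4), " deg (truth ", x$spurt_mean_true,
      "), fast fraction ", signif(x$fast_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Write generator parameters as a flat key/value file
#'
#' @param params A [sim_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  num <- function(x) paste(format(x, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = ",")
  states <- rownames(params$transition)
  lines <- c(
    paste0("condition = ", params$condition),
    paste0("n_frames = ", params$n_frames),
    paste0("dt = ", num(params$dt)),
    paste0("seed = ", params$seed),
    vapply(states, function(s)
      paste0("transition.", s, " = ", num(params$transition[s, ])),
      character(1)),
    paste0("speed_median = ", num(params$speed_median)),
    paste0("speed_sdlog = ", num(params$speed_sdlog)),
    paste0("dir_mean_deg = ", num(params$dir_mean_deg)),
    paste0("dir_kappa = ", num(params$dir_kappa)),
    paste0("fraction_never_migrating = ", num(params$fraction_never_migrating)),
    vapply(states, function(s)
      paste0("morph_emission.", s, " = ", num(params$morph_emission[s, ])),
      character(1)),
    paste0("branch_event_rate = ", num(params$branch_event_rate)),
    paste0("bipolar_speed_min = ", num(params$bipolar_speed_min)),
    paste0("z_sigma = ", num(params$z_sigma)),
    paste0("rest_cutoff = ", num(params$rest_cutoff)),
    paste0("midline_x = ", num(params$midline_x))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read generator parameters from a flat key/value file
#'
#' @param path Path written by [write_sim_params()].
#' @return A [sim_params()].
#' @export
read_sim_params <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  get1 <- function(key) vals[match(key, keys)]
  nums <- function(key) as.numeric(strsplit(get1(key), ",")[[1]])
  tr <- rbind(rest = nums("transition.rest"), slow = nums("transition.slow"),
              spurt = nums("transition.spurt"))
  em <- rbind(rest = nums("morph_emission.rest"),
              slow = nums("morph_emission.slow"),
              spurt = nums("morph_emission.spurt"))
  sim_params(
    n_frames = as.integer(get1("n_frames")), dt = nums("dt"),
    transition = tr,
    speed_median = nums("speed_median"), speed_sdlog = nums("speed_sdlog"),
    dir_mean_deg = nums("dir_mean_deg"), dir_kappa = nums("dir_kappa"),
    fraction_never_migrating = nums("fraction_never_migrating"),
    morph_emission = em,
    branch_event_rate = nums("branch_event_rate"),
    bipolar_speed_min = nums("bipolar_speed_min"),
    z_sigma = nums("z_sigma"), rest_cutoff = nums("rest_cutoff"),
    midline_x = nums("midline_x"),
    condition = get1("condition"), seed = as.integer(get1("seed"))
  )
}
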