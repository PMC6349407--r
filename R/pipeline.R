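#' Run the full per-population analysis
#'
#' Validates the population (cells not detected at all frames are excluded
#' by default), computes per-cell kinematics, classifies cells by
#' max-speed, computes speed-band occupancies and — for migratory cells
#' only — midline-referenced trajectory angles, then assembles pooled and
#' per-class circular summaries. When per-frame morphology annotations are
#' supplied, per-cell morphology categories (over the analysis window),
#' bipolar/multipolar transition frequencies, branch-transition rates and
#' the pooled speed-band morphology composition are added. Non-migratory
#' cells are retained in class counts but excluded from displacement,
#' directionality and trajectory summaries.
#'
#' @param pop A [population()].
#' @param morph Optional per-frame morphology annotations (tibble as
#'   returned by [read_morphology()]); partial coverage of the population
#'   is reported, not fatal.
#' @param bands A [speed_bands()].
#' @param morph_window Number of initial frames used for morphology
#'   categorisation (default 18).
#' @param gaps Gap policy passed to [validate_population()].
#' @return A list of class `migration_analysis` with `features` (one row
#'   per cell), `summaries`, `morphology` (per-cell morphology metrics or
#'   `NULL`), `population` (the validated population), `bands`, and
#'   `validation` (the gap report).
#' @export
analyze_population <- function(pop, morph = NULL, bands = speed_bands(),
                               morph_window = 18, gaps = "exclude") {
  stopifnot(inherits(pop, "population"))
  val <- validate_population(pop, gaps = gaps)
  pop <- val$population
  dt <- pop$dt

  by_cell <- split(pop$tracks, pop$tracks$cell_id)
  features <- dplyr::bind_rows(lapply(by_cell, function(d) {
    d <- d[order(d$frame), ]
    pos <- as.matrix(d[, c("x_um", "y_um", "z_um")])
    kin <- summarize_kinematics(pos, dt)
    occ <- phase_occupancy(instantaneous_speeds(pos, dt), bands)
    cls <- classify_by_max_speed(kin$max_speed, bands)
    dx <- pos[nrow(pos), 1] - pos[1, 1]
    dy <- pos[nrow(pos), 2] - pos[1, 2]
    if (d$side[1] == "left") dx <- -dx
    angle <- if (cls == "non_migratory" || (dx == 0 && dy == 0)) NA_real_
             else as.numeric(wrap_angle(rad2deg(atan2(dx, dy))))
    tibble(
      cell_id = d$cell_id[1], side = d$side[1], condition = d$condition[1],
      slice_id = d$slice_id[1], n_frames = nrow(d),
      avg_speed = kin$avg_speed, max_speed = kin$max_speed,
      speed_class = cls,
      occ_rest = occ[["rest"]], occ_slow = occ[["slow"]],
      occ_moderate = occ[["moderate"]], occ_fast = occ[["fast"]],
      total_displacement = kin$total_displacement,
      path_length = kin$path_length,
      directionality = kin$directionality,
      trajectory_angle_deg = angle
    )
  }))

  migratory <- features[features$speed_class != "non_migratory", ]
  ang <- migratory$trajectory_angle_deg
  ang <- ang[!is.na(ang)]
  per_class_angles <- lapply(c("slow", "moderate", "fast"), function(cl) {
    a <- migratory$trajectory_angle_deg[migratory$speed_class == cl]
    a[!is.na(a)]
  })
  names(per_class_angles) <- c("slow", "moderate", "fast")

  summaries <- list(
    n_cells = nrow(features),
    n_migratory = nrow(migratory),
    class_counts = table(features$speed_class),
    class_proportions = prop.table(table(features$speed_class)),
    pooled_angles = if (length(ang) > 0) circular_summary(ang) else NULL,
    lateral_fraction = if (length(ang) > 0) lateral_fraction(ang) else NA_real_,
    class_angles = lapply(per_class_angles, function(a) {
      if (length(a) > 0) circular_summary(a) else NULL
    }),
    occupancy_by_class = do.call(rbind, lapply(SPEED_CLASSES, function(cl) {
      f <- features[features$speed_class == cl, ]
      if (nrow(f) == 0) return(NULL)
      c(rest = mean(f$occ_rest), slow = mean(f$occ_slow),
        moderate = mean(f$occ_moderate), fast = mean(f$occ_fast))
    }))
  )

  morph_out <- NULL
  if (!is.null(morph)) {
    morph <- morph[morph$cell_id %in% features$cell_id, ]
    covered <- unique(morph$cell_id)
    per_cell <- dplyr::bind_rows(lapply(split(morph, morph$cell_id),
                                        function(m) {
      m <- m[order(m$frame), ]
      m <- m[m$frame < morph_window, ]
      if (nrow(m) < 2) return(NULL)
      states <- morph_state(m$n_soma_processes, m$lp_branched)
      tibble(
        cell_id = m$cell_id[1],
        n_frames_analyzed = nrow(m),
        category = categorize_cell(states),
        morph_transitions_per_hr = morph_transition_frequency(states, dt),
        branch_transitions_per_hr =
          branch_transition_rate(m$n_branches_total, dt)
      )
    }))
    # pooled morphology composition of each speed band
    pair_tabs <- lapply(intersect(names(by_cell), covered), function(id) {
      m <- morph[morph$cell_id == id, ]
      m <- m[order(m$frame), ]
      d <- by_cell[[id]]
      n_use <- min(nrow(d), nrow(m))
      if (n_use < 2) return(NULL)
      pos <- as.matrix(d[order(d$frame), c("x_um", "y_um", "z_um")])[
        seq_len(n_use), , drop = FALSE]
      states <- morph_state(m$n_soma_processes, m$lp_branched)[seq_len(n_use)]
      tab <- pair_speed_morphology(pos, states, dt, bands)
      tab$n
    })
    pair_tabs <- pair_tabs[!vapply(pair_tabs, is.null, logical(1))]
    speed_morphology <- NULL
    if (length(pair_tabs) > 0) {
      template <- pair_speed_morphology(
        as.matrix(by_cell[[intersect(names(by_cell), covered)[1]]][
          , c("x_um", "y_um", "z_um")]),
        morph_state(
          morph$n_soma_processes[morph$cell_id ==
                                   intersect(names(by_cell), covered)[1]],
          morph$lp_branched[morph$cell_id ==
                              intersect(names(by_cell), covered)[1]]),
        dt, bands)
      counts <- Reduce(`+`, pair_tabs)
      speed_morphology <- template[, c("phase", "state")]
      speed_morphology$n <- counts
      totals <- tapply(counts, template$phase, sum)
      speed_morphology$fraction <- ifelse(
        totals[as.character(template$phase)] > 0,
        counts / totals[as.character(template$phase)], NA_real_)
    }
    morph_out <- list(
      per_cell = per_cell,
      category_counts = if (!is.null(per_cell) && nrow(per_cell) > 0)
        table(per_cell$category) else NULL,
      speed_morphology = speed_morphology,
      n_annotated = length(covered),
      n_without_annotation = nrow(features) - length(covered)
    )
  }

  structure(
    list(features = features, summaries = summaries, morphology = morph_out,
         population = pop, bands = bands, validation = val$report),
    class = "migration_analysis"
  )
}

#' @export
print.migration_analysis <- function(x, ...) {
  s <- x$summaries
  cat("<migration_analysis> ", s$n_cells, " cells (",
      s$n_migratory, " migratory)\n", sep = "")
  print(s$class_counts)
  if (!is.null(s$pooled_angles)) {
    cat("pooled trajectory angles: ")
    print(s$pooled_angles)
  }
  invisible(x)
}

#' Compare two analyzed conditions
#'
#' Emits the comparison scheme used for two-condition time-lapse studies:
#' rank-based (Mann-Whitney) tests on the average- and max-speed
#' distributions, Kuiper tests on pooled, per-class and per-phase
#' trajectory-angle distributions, the speed-class and morphology-category
#' composition with a two-proportion test on the transitionary fraction,
#' and a rank-based comparison of branch-transition rates. No
#' multiple-testing correction is applied across these test families; treat
#' the p-values accordingly.
#'
#' @param a,b `migration_analysis` objects produced with identical speed
#'   bands and frame interval.
#' @return A list of class `condition_comparison`.
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "migration_analysis"),
            inherits(b, "migration_analysis"))
  if (!identical(unclass(a$bands), unclass(b$bands)) ||
      abs(a$population$dt - b$population$dt) > 1e-9) {
    abort("Analyses were not produced with identical configuration.")
  }
  ang <- function(x, cl = NULL) {
    f <- x$features
    f <- f[f$speed_class != "non_migratory", ]
    if (!is.null(cl)) f <- f[f$speed_class == cl, ]
    v <- f$trajectory_angle_deg
    v[!is.na(v)]
  }
  kuiper_or_null <- function(x, y) {
    if (length(x) == 0 || length(y) == 0) return(NULL)
    kuiper_test(x, y)
  }
  sa <- step_angles(a$population, a$bands)
  sb <- step_angles(b$population, b$bands)
  phase_kuiper <- lapply(PHASE_NAMES, function(ph) {
    kuiper_or_null(sa$angle_deg[sa$phase == ph], sb$angle_deg[sb$phase == ph])
  })
  names(phase_kuiper) <- PHASE_NAMES

  morph_comp <- NULL
  if (!is.null(a$morphology) && !is.null(b$morphology) &&
      !is.null(a$morphology$category_counts) &&
      !is.null(b$morphology$category_counts)) {
    ca <- a$morphology$category_counts
    cb <- b$morphology$category_counts
    trans <- c(ca[["transitionary"]], cb[["transitionary"]])
    tot <- c(sum(ca), sum(cb))
    morph_comp <- list(
      category_counts = rbind(a = as.vector(ca), b = as.vector(cb)),
      transitionary_test = suppressWarnings(
        stats::prop.test(trans, tot)),
      branch_rate_test = suppressWarnings(stats::wilcox.test(
        a$morphology$per_cell$branch_transitions_per_hr,
        b$morphology$per_cell$branch_transitions_per_hr))
    )
  }

  structure(
    list(
      n = c(a = a$summaries$n_cells, b = b$summaries$n_cells),
      class_counts = rbind(a = as.vector(a$summaries$class_counts),
                           b = as.vector(b$summaries$class_counts)),
      class_proportions = rbind(
        a = as.vector(a$summaries$class_proportions),
        b = as.vector(b$summaries$class_proportions)),
      avg_speed_test = suppressWarnings(
        stats::wilcox.test(a$features$avg_speed, b$features$avg_speed)),
      max_speed_test = suppressWarnings(
        stats::wilcox.test(a$features$max_speed, b$features$max_speed)),
      kuiper_pooled = kuiper_or_null(ang(a), ang(b)),
      kuiper_by_class = setNames(
        lapply(c("slow", "moderate", "fast"),
               function(cl) kuiper_or_null(ang(a, cl), ang(b, cl))),
        c("slow", "moderate", "fast")),
      kuiper_by_phase = phase_kuiper,
      morphology = morph_comp
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> n =", x$n[1], "vs", x$n[2], "cells\n")
  cat("max-speed Mann-Whitney p =", signif(x$max_speed_test$p.value, 3), "\n")
  if (!is.null(x$kuiper_pooled)) {
    cat("pooled trajectory-angle Kuiper V =", signif(x$kuiper_pooled$V, 3),
        ", p =", signif(x$kuiper_pooled$p, 3), "\n")
  }
  invisible(x)
}

#' Write the per-cell feature table
#'
#' @param analysis A `migration_analysis`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(analysis, path) {
  stopifnot(inherits(analysis, "migration_analysis"))
  readr::write_csv(analysis$features, path, progress = FALSE)
  invisible(path)
}
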