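# Group comparisons (one-way ANOVA + Bonferroni post hoc) and the
# end-to-end pipeline orchestrator.

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare groups by one-way ANOVA with Bonferroni post hoc tests
#'
#' One-way ANOVA F test across groups followed by all pairwise two-sample
#' t tests using the pooled residual standard deviation, with Bonferroni
#' adjustment: each raw p value is multiplied by the number of pairwise
#' comparisons and capped at 1. Stars follow the conventional levels
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Groups with fewer than
#' two values are excluded with a warning.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) holding the response values
#'   and the grouping factor.
#' @return An object of class `group_comparison`: list with `anova`
#'   (one-row tibble: `f_statistic`, `df_between`, `df_within`, `p_value`)
#'   and `pairwise` (tibble: `group1`, `group2`, `mean_diff`, `p_raw`,
#'   `p_adj`, `stars`). [tidy()] returns the pairwise table, [glance()] the
#'   ANOVA row.
#' @export
compare_groups <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- tibble::tibble(
    value = rlang::eval_tidy(value, data),
    group = as.character(rlang::eval_tidy(group, data))
  )
  df <- df[is.finite(df$value), , drop = FALSE]
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(sprintf("excluding group(s) with < 2 values: %s",
                 paste(small, collapse = ", ")),
         class = "retinaivm_small_group_warning")
    df <- df[!df$group %in% small, , drop = FALSE]
  }
  groups <- sort(unique(df$group))
  if (length(groups) < 2) {
    abort("need at least two groups with >= 2 values each",
          class = "retinaivm_config_error")
  }
  df$group <- factor(df$group, levels = groups)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    f_statistic = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1]
  )
  # pooled residual SD for the post hoc t tests
  s_pooled <- sqrt(sum(an[["Sum Sq"]][2]) / an[["Df"]][2])
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)
  pairwise <- purrr::map(pairs, function(pr) {
    v1 <- df$value[df$group == pr[1]]
    v2 <- df$value[df$group == pr[2]]
    se <- s_pooled * sqrt(1 / length(v1) + 1 / length(v2))
    tstat <- (mean(v1) - mean(v2)) / se
    p_raw <- if (se == 0) {
      if (mean(v1) == mean(v2)) 1 else 0
    } else {
      2 * pt(-abs(tstat), df = an[["Df"]][2])
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   mean_diff = mean(v1) - mean(v2),
                   p_raw = p_raw,
                   p_adj = min(1, m * p_raw))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(stars = significance_stars(.data$p_adj))
  structure(list(anova = anova_tbl, pairwise = pairwise,
                 n_comparisons = m),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f_statistic,
              x$anova$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$anova

#' @method tidy calcium_calibration
#' @export
tidy.calcium_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("r_min", "r_max", "kd_M", "hill_n"),
    estimate = c(x$r_min, x$r_max, x$kd_M, x$hill_n)
  )
}

#' @method glance calcium_calibration
#' @export
glance.calcium_calibration <- function(x, ...) {
  tibble::tibble(kd_uM = x$kd_M * 1e6, hill_n = x$hill_n,
                 ratio_at_threshold = calcium_to_ratio(x$dysfunction_threshold_M, x),
                 dysfunction_threshold_uM = x$dysfunction_threshold_M * 1e6)
}

#' Configure a pipeline run
#'
#' Bundles everything [run_pipeline()] needs: the mode, phantom
#' configuration (simulate/full) or input directory (analyze), channel and
#' calcium calibrations, zone radii, detection and linking parameters, the
#' motile threshold, optional ROIs, the output directory and the seed.
#'
#' @param mode One of `"simulate"`, `"analyze"`, `"full"`.
#' @param out_dir Output directory (created if absent).
#' @param phantom A [phantom_config()] (required for simulate/full).
#' @param input_dir Directory of previously simulated sessions (analyze).
#' @param channel_cal A [channel_calibration()]; default: the phantom's.
#' @param calibration A [fit_calibration()] result.
#' @param zone_radii Concentric zone boundary radii (um).
#' @param detect_threshold,detect_size_range Passed to [detect_cells()].
#' @param max_link_distance_um,min_track_length Passed to [link_tracks()].
#' @param motile_threshold_um Passed to [classify_motile()].
#' @param rois Optional ROI tibble for [roi_time_course()].
#' @param seed Integer RNG seed for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       out_dir,
                       phantom = NULL,
                       input_dir = NULL,
                       channel_cal = NULL,
                       calibration = fit_calibration(),
                       zone_radii = c(226, 452, 678),
                       detect_threshold = "otsu",
                       detect_size_range = c(65, 4200),
                       max_link_distance_um = 25,
                       min_track_length = 5L,
                       motile_threshold_um = 10,
                       rois = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode %in% c("simulate", "full") && is.null(phantom)) {
    stop_config("mode requires a `phantom` configuration block")
  }
  if (mode == "analyze" && is.null(input_dir)) {
    stop_config("analyze mode requires an `input_dir` block")
  }
  if (is.null(channel_cal)) {
    channel_cal <- if (!is.null(phantom)) phantom$channel_cal
      else channel_calibration()
  }
  if (is.null(calibration)) {
    stop_config("missing `calibration` block (calcium calibration)")
  }
  structure(
    list(mode = mode, out_dir = out_dir, phantom = phantom,
         input_dir = input_dir, channel_cal = channel_cal,
         calibration = calibration, zone_radii = zone_radii,
         detect_threshold = detect_threshold,
         detect_size_range = detect_size_range,
         max_link_distance_um = max_link_distance_um,
         min_track_length = as.integer(min_track_length),
         motile_threshold_um = motile_threshold_um,
         rois = rois, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_echo <- function(config) {
  drop_classes <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_classes)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  echo <- unclass(config)
  # paths are run locations, not scientific configuration; the manifest is
  # byte-identical for identical configurations wherever it is written
  echo$out_dir <- NULL
  echo$input_dir <- NULL
  drop_classes(echo)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> register -> detect -> track -> zonal / motility /
#' FRET analyses per session day, writing per-day CSV tables, the session
#' stacks (simulate/full), and a JSON run manifest (config echo, seed,
#' package version, warnings, per-day summaries). Identical configuration
#' and seed reproduce identical outputs. Any stage error is re-raised with
#' the stage name attached.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, code) {
    tryCatch(withCallingHandlers(code, warning = log_warning),
             error = function(e) {
               abort(sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     class = "retinaivm_stage_error", parent = e)
             })
  }

  sessions_dir <- file.path(config$out_dir, "sessions")
  manifest <- list(
    package = "retinaivm",
    version = as.character(utils::packageVersion("retinaivm")),
    mode = config$mode, seed = config$seed,
    config = config_echo(config)
  )

  if (config$mode %in% c("simulate", "full")) {
    stage("simulate", {
      dir.create(sessions_dir, showWarnings = FALSE)
      ph <- config$phantom
      ph$rng_seed <- config$seed
      exp <- simulate_experiment(ph)
      for (d in names(exp$sessions)) {
        write_session(exp$sessions[[d]],
                      file.path(sessions_dir, sprintf("day%s.tif", d)))
      }
      readr::write_csv(exp$ground_truth$tracks,
                       file.path(sessions_dir, "ground_truth_tracks.csv"))
      jsonlite::write_json(
        list(days = ph$session_days,
             onh_center_um = ph$onh_center_um,
             global_radial = exp$ground_truth$global_radial,
             zone_counts = exp$ground_truth$zone_counts),
        file.path(sessions_dir, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
      manifest$simulated_days <- ph$session_days
    })
  }

  if (config$mode %in% c("analyze", "full")) {
    in_dir <- if (config$mode == "full") sessions_dir else config$input_dir
    paths <- sort(list.files(in_dir, pattern = "^day.*\\.tif$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      abort(sprintf("stage 'load' failed: no session files in '%s'", in_dir),
            class = "retinaivm_stage_error")
    }
    reference <- NULL
    onh <- NULL
    day_summaries <- list()
    all_zone <- list()
    all_tracks <- list()
    all_fret <- list()
    for (p in paths) {
      sess <- stage("load", read_session(p))
      day <- sess$day
      if (is.null(reference)) {
        reference <- sess
        offset <- c(0, 0)
      } else {
        reg <- stage("register", register_sessions(reference, sess))
        sess <- reg$aligned
        offset <- reg$offset_um
      }
      if (is.null(onh)) {
        onh <- stage("localize_onh", localize_onh(sess))
      }
      zones <- zone_config(onh_center_um = onh, radii = config$zone_radii)
      det <- stage("detect", detect_cells(
        sess, threshold = config$detect_threshold,
        size_range = config$detect_size_range))
      det <- assign_zone(det, zones)
      det$day <- day
      zc <- zone_counts(det, zones)
      tracks <- stage("track", link_tracks(
        det, max_link_distance = config$max_link_distance_um,
        min_length = config$min_track_length))
      summ <- if (nrow(tracks) > 0) {
        summarize_tracks(tracks, sess$frame_interval_min,
                         onh_center_um = onh) |>
          classify_motile(config$motile_threshold_um)
      } else {
        tibble::tibble()
      }
      gdv <- if (nrow(summ) > 0 && any(summ$motile)) {
        global_displacement_vector(summ)
      } else {
        0
      }
      fret <- stage("fret", session_fret(sess, config$channel_cal))
      zf <- zone_fret(fret, zones)
      zf$day <- day
      dys <- stage("fret", dysfunction_fraction(fret, config$calibration))
      if (!is.null(config$rois)) {
        tc <- roi_time_course(fret, config$rois)
        tc$day <- day
        all_fret[[length(all_fret) + 1L]] <- tc
      }
      if (nrow(summ) > 0) {
        summ$day <- day
        all_tracks[[length(all_tracks) + 1L]] <- summ
      }
      all_zone[[length(all_zone) + 1L]] <- zc |> dplyr::mutate(day = day)
      day_summaries[[as.character(day)]] <- list(
        day = day, registration_offset_um = offset,
        n_detections_frame1 = sum(det$frame == min(det$frame, Inf)),
        n_tracks = if (nrow(summ) > 0) nrow(summ) else 0L,
        n_motile = if (nrow(summ) > 0) sum(summ$motile) else 0L,
        global_displacement_um = gdv,
        mean_fret_ratio = mean(zf$mean_ratio[is.na(zf$zone)], na.rm = TRUE),
        dysfunction_fraction = dys)
      readr::write_csv(tracks,
                       file.path(config$out_dir,
                                 sprintf("track_points_day%s.csv", day)))
    }
    zone_tbl <- dplyr::bind_rows(all_zone)
    readr::write_csv(zone_tbl, file.path(config$out_dir, "zone_counts.csv"))
    track_tbl <- dplyr::bind_rows(all_tracks)
    readr::write_csv(track_tbl, file.path(config$out_dir, "track_summary.csv"))
    if (length(all_fret) > 0) {
      readr::write_csv(dplyr::bind_rows(all_fret),
                       file.path(config$out_dir, "fret_roi_time_courses.csv"))
    }
    # displacement-rate comparison across days (when enough tracks exist)
    stats_tbl <- NULL
    if (nrow(track_tbl) > 0) {
      enough <- track_tbl |>
        dplyr::count(.data$day) |>
        dplyr::filter(.data$n >= 2)
      if (nrow(enough) >= 2) {
        cg <- suppressWarnings(compare_groups(
          track_tbl[track_tbl$day %in% enough$day, ],
          .data$displacement_rate_um_min, .data$day))
        stats_tbl <- tidy(cg)
        readr::write_csv(stats_tbl,
                         file.path(config$out_dir, "stats_displacement.csv"))
        manifest$anova <- as.list(glance(cg))
      }
    }
    manifest$onh_center_um <- onh
    manifest$days <- day_summaries
  }

  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
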