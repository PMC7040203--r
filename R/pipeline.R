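#' Analyse a single trial
#'
#' Runs the full per-trial feature chain: gap filling, grip-centre speed,
#' velocity-threshold segmentation, geometric labelling, temporal features,
#' aperture/MGA features over the reach, and spatial grasp features at
#' contact. Trials whose fingertip trajectories retain unfilled gaps inside a
#' detected movement span are rejected (no imputation inside analysis
#' windows); for detection itself, untracked samples are treated as
#' stationary.
#'
#' @param x A [trial()].
#' @param cfg A [segmentation_config()].
#' @param cups Named list of [cup_spec()] objects for `empty` and `filled`.
#' @param max_gap Maximum gap length (samples) passed to [fill_gaps()].
#' @param manual Optional manual segment labels (see [label_segments()]).
#' @return List with one-row `features` tibble and a `segments` tibble.
#' @export
analyze_trial <- function(x, cfg = segmentation_config(),
                          cups = list(empty = cup_spec(),
                                      filled = cup_spec_filled()),
                          max_gap = 5L, manual = NULL) {
  stopifnot(inherits(x, "trial"))
  for (f in c("thumb", "index", "middle")) {
    x$trajectories[[f]] <- fill_gaps(x$trajectories[[f]], max_gap)
  }
  gc <- grip_center(x)
  speed <- velocity_norm(gc, cfg)
  speed[!is.finite(speed)] <- 0
  segments <- segment_movements(speed, cfg)
  if (nrow(segments)) {
    for (i in seq_len(nrow(segments))) {
      span_invalid <- !gc$valid[segments$onset[i]:(segments$offset[i] - 1L)]
      if (any(span_invalid)) {
        stop("unfilled tracking gap inside a movement span; trial excluded",
             call. = FALSE)
      }
    }
  }
  segments <- label_segments(segments, x, manual = manual, gc = gc)
  feats <- temporal_features(segments, speed, x$sample_rate)
  reach <- feats[feats$label == "reach", ]
  if (nrow(reach) != 1) {
    stop("labeling error: expected exactly one reach segment", call. = FALSE)
  }
  transport <- feats[feats$label == "transport", ]

  window <- reach$onset:(reach$offset - 1L)
  ap <- aperture_series(x$trajectories$thumb, x$trajectories$index, window)
  mga <- mga_features(ap, reach, x$sample_rate)
  cup <- cups[[x$condition$content]]
  grasp <- grip_features(x$trajectories$thumb, x$trajectories$index,
                         x$trajectories$middle, reach$offset, cup)

  features <- tibble::new_tibble(c(list(
    participant = x$participant_id, block = x$block,
    surface = x$condition$surface, content = x$condition$content,
    feedback = x$condition$feedback,
    reach_onset_ms = reach$onset_ms, reach_offset_ms = reach$offset_ms,
    reach_duration = reach$duration,
    reach_peak_velocity = reach$peak_velocity,
    adjustment_time = reach$adjustment_time,
    transport_peak_velocity = if (nrow(transport)) transport$peak_velocity[1]
                              else NA_real_,
    transport_duration = if (nrow(transport)) transport$duration[1]
                         else NA_real_),
    as.list(mga), as.list(grasp)), nrow = 1L)
  list(features = features, segments = feats)
}

#' Extract the feature table from a set of trials
#'
#' Maps [analyze_trial()] over trials, collecting one feature row per
#' analysable trial, the per-segment table, and a dispositions table
#' recording, for every input trial, whether it was analysed or excluded and
#' why — exclusion decisions are data, not log noise.
#'
#' @param trials Named list of [trial()] objects.
#' @inheritParams analyze_trial
#' @param manual_labels Optional named list: trial id -> manual label vector.
#' @return List of tibbles: `features`, `segments`, `dispositions`.
#' @export
extract_features <- function(trials, cfg = segmentation_config(),
                             cups = list(empty = cup_spec(),
                                         filled = cup_spec_filled()),
                             max_gap = 5L, manual_labels = NULL) {
  ids <- names(trials) %||% as.character(seq_along(trials))
  feats <- list(); segs <- list(); disp <- list()
  for (i in seq_along(trials)) {
    id <- ids[[i]]
    res <- tryCatch(
      analyze_trial(trials[[i]], cfg = cfg, cups = cups, max_gap = max_gap,
                    manual = manual_labels[[id]]),
      error = function(e) e)
    if (inherits(res, "error")) {
      disp[[id]] <- tibble::new_tibble(list(trial_id = id,
                                            status = "excluded",
                                            reason = conditionMessage(res)),
                                       nrow = 1L)
    } else {
      f <- res$features; f$trial_id <- id
      feats[[id]] <- f[, c("trial_id", setdiff(names(f), "trial_id"))]
      s <- res$segments; s$trial_id <- id
      segs[[id]] <- s[, c("trial_id", setdiff(names(s), "trial_id"))]
      disp[[id]] <- tibble::new_tibble(list(trial_id = id,
                                            status = "analyzed",
                                            reason = NA_character_),
                                       nrow = 1L)
    }
  }
  list(features = dplyr::bind_rows(feats), segments = dplyr::bind_rows(segs),
       dispositions = dplyr::bind_rows(disp))
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: where the trials come from
#' (a directory written by [write_dataset()], or an in-memory list), the
#' segmentation and cup parameters, which blocks get individual mixed-model
#' fits, optional ratings, and the output directory. The configuration
#' round-trips through JSON via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input_dir Directory with `manifest.csv` + trial TSVs (or `NULL`).
#' @param trials In-memory named list of trials (or `NULL`).
#' @param ratings Optional ratings tibble with design covariates.
#' @param output_dir Output directory (or `NULL` to skip writing).
#' @param segmentation A [segmentation_config()].
#' @param cups Named list of `empty`/`filled` [cup_spec()] objects.
#' @param max_gap Gap-filling limit in samples.
#' @param manual_labels Optional named list of manual segment labels.
#' @param blocks_to_fit Blocks receiving individual LMM fits (`NULL` = all).
#' @param fit_models Fit the statistical battery (default `TRUE`).
#' @param seed Integer seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, trials = NULL, ratings = NULL,
                            output_dir = NULL,
                            segmentation = segmentation_config(),
                            cups = list(empty = cup_spec(),
                                        filled = cup_spec_filled()),
                            max_gap = 5L, manual_labels = NULL,
                            blocks_to_fit = NULL, fit_models = TRUE,
                            seed = 1L) {
  if (is.null(input_dir) && is.null(trials)) {
    stop("provide either input_dir or trials", call. = FALSE)
  }
  structure(list(input_dir = input_dir, trials = trials, ratings = ratings,
                 output_dir = output_dir, segmentation = segmentation,
                 cups = cups, max_gap = as.integer(max_gap),
                 manual_labels = manual_labels,
                 blocks_to_fit = blocks_to_fit, fit_models = fit_models,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' From raw trials to feature table, model fits and a plain-text report.
#' Per-trial failures (unreadable files, segmentation or labelling errors,
#' gaps inside movement spans) are recorded in the dispositions table and the
#' pipeline continues; outputs are deterministic given fixed inputs and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a `prehensr_pipeline` list: `features`, `segments`,
#'   `dispositions`, `models` (named list of fits), `report` (character
#'   lines), `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  trials <- cfg$trials
  disp_read <- NULL
  if (is.null(trials)) {
    manifest <- readr::read_csv(file.path(cfg$input_dir, "manifest.csv"),
                                show_col_types = FALSE, progress = FALSE)
    trials <- list(); bad <- list()
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      tr <- tryCatch(
        read_trial_tsv(
          file.path(cfg$input_dir, row$file),
          metadata = list(
            participant_id = row$participant, block = row$block,
            condition = list(surface = row$surface, content = row$content,
                             feedback = row$feedback),
            landmarks = if (all(c("A_x", "B_x") %in% names(row))) {
              list(start = c(row$start_x, row$start_y, row$start_z),
                   A = c(row$A_x, row$A_y, row$A_z),
                   B = c(row$B_x, row$B_y, row$B_z))
            } else NULL)),
        error = function(e) e)
      id <- as.character(row$trial_id)
      if (inherits(tr, "error")) {
        bad[[id]] <- tibble::tibble(trial_id = id, status = "excluded",
                                    reason = paste("read error:",
                                                   conditionMessage(tr)))
      } else {
        trials[[id]] <- tr
      }
    }
    disp_read <- dplyr::bind_rows(bad)
  }
  ex <- extract_features(trials, cfg = cfg$segmentation, cups = cfg$cups,
                         max_gap = cfg$max_gap,
                         manual_labels = cfg$manual_labels)
  dispositions <- dplyr::bind_rows(disp_read, ex$dispositions)
  features <- ex$features

  models <- list()
  if (cfg$fit_models && nrow(features) > 0) {
    complete <- c("participant", "surface", "content", "feedback")
    for (dv in c("adjustment_time", "reach_peak_velocity",
                 "transport_peak_velocity", "mga", "mga_time_rel")) {
      ok <- stats::complete.cases(features[, c(complete, dv)])
      models[[paste0("anova_", dv)]] <-
        tryCatch(rm_anova(features[ok, ], dv), error = function(e) e)
    }
    for (dv in c("adjustment_time", "transport_peak_velocity")) {
      models[[paste0("kw_", dv, "_blocks")]] <-
        tryCatch(kruskal_wallis(features, dv, "block"), error = function(e) e)
    }
    blocks <- cfg$blocks_to_fit %||% sort(unique(features$block))
    for (b in blocks) {
      fb <- dplyr::filter(features, .data$block == b)
      for (dv in c("adjustment_time", "transport_peak_velocity",
                   "grip_deviation")) {
        models[[sprintf("lmm_%s_block%d", dv, b)]] <-
          tryCatch(lmm_fit(fb, dv), error = function(e) e)
      }
    }
    for (dv in c("adjustment_time", "transport_peak_velocity",
                 "grip_deviation")) {
      models[[paste0("lmm_", dv, "_all")]] <-
        tryCatch(lmm_fit(features, dv), error = function(e) e)
    }
    if (!is.null(cfg$ratings)) {
      for (dim in unique(cfg$ratings$dimension)) {
        for (ph in unique(cfg$ratings$phase)) {
          sub <- dplyr::filter(cfg$ratings, .data$dimension == dim,
                               .data$phase == ph)
          if (nrow(sub)) {
            models[[sprintf("clmm_%s_%s", dim, ph)]] <-
              tryCatch(clmm_fit(sub, "value"), error = function(e) e)
          }
        }
      }
    }
  }

  hash_cfg <- cfg
  hash_cfg$trials <- NULL  # hash settings, not bulk data
  config_hash <- rlang::hash(hash_cfg)
  report <- build_report(features, dispositions, models, config_hash)

  out <- structure(list(features = features, segments = ex$segments,
                        dispositions = dispositions, models = models,
                        report = report, config_hash = config_hash),
                   class = "prehensr_pipeline")
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(out, cfg$output_dir)
  invisible(out)
}

condition_mean_table <- function(features, dv) {
  features |>
    dplyr::filter(is.finite(.data[[dv]])) |>
    dplyr::group_by(.data$content) |>
    dplyr::summarise(mean = mean(.data[[dv]]), sd = stats::sd(.data[[dv]]),
                     n = dplyr::n(), .groups = "drop")
}

build_report <- function(features, dispositions, models, config_hash) {
  lines <- c("prehension kinematics pipeline report",
             paste("config hash:", config_hash),
             sprintf("trials analyzed: %d / %d (%d excluded)",
                     sum(dispositions$status == "analyzed"),
                     nrow(dispositions),
                     sum(dispositions$status == "excluded")))
  excl <- dispositions[dispositions$status == "excluded", ]
  if (nrow(excl)) {
    lines <- c(lines, "exclusions:",
               sprintf("  %s: %s", excl$trial_id, excl$reason))
  }
  if (nrow(features)) {
    for (dv in c("adjustment_time", "reach_peak_velocity",
                 "transport_peak_velocity", "mga", "mga_time_rel",
                 "grip_deviation")) {
      tab <- condition_mean_table(features, dv)
      lines <- c(lines, paste0(dv, " by content:"),
                 sprintf("  %s: M = %.2f, SD = %.2f (n = %d)",
                         tab$content, tab$mean, tab$sd, tab$n))
    }
  }
  for (nm in names(models)) {
    m <- models[[nm]]
    if (inherits(m, "error")) {
      lines <- c(lines, sprintf("%s: failed (%s)", nm, conditionMessage(m)))
    } else if (inherits(m, c("prehensr_lmm", "prehensr_clmm"))) {
      tab <- m$table
      lines <- c(lines, paste0(nm, ":"),
                 sprintf("  %s: b = %.2f, SE = %.2f, chi2(%d) = %.2f, p = %.4g",
                         tab$term, tab$estimate, tab$std.error, tab$df,
                         tab$chisq, tab$p.value))
    } else if (inherits(m, "prehensr_anova") && !m$degenerate) {
      tab <- m$table
      lines <- c(lines, paste0(nm, ":"),
                 sprintf("  %s: F(%d,%d) = %.2f, p = %.4g, ges = %.3f",
                         tab$term, tab$df, tab$df_error, tab$statistic,
                         tab$p.value, tab$ges))
    } else if (inherits(m, "prehensr_kw")) {
      lines <- c(lines,
                 sprintf("%s: chi2(%d) = %.2f, p = %.4g", nm, m$df,
                         m$statistic, m$p.value))
    }
  }
  lines
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out$features, file.path(dir, "features.csv"))
  readr::write_csv(out$segments, file.path(dir, "segments.csv"))
  readr::write_csv(out$dispositions, file.path(dir, "dispositions.csv"))
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (nm in names(out$models)) {
    m <- out$models[[nm]]
    if (!inherits(m, "error")) {
      readr::write_csv(tidy(m), file.path(mdir, paste0(nm, ".csv")))
    }
  }
  writeLines(out$report, file.path(dir, "report.txt"))
  writeLines(c(paste("config hash:", out$config_hash),
               paste("written:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.prehensr_pipeline <- function(x, ...) {
  cat(x$report[1:3], sep = "\n")
  cat(sprintf("(%d model fits, %d feature rows)\n", length(x$models),
              nrow(x$features)))
  invisible(x)
}

#' Serialize / restore a pipeline configuration
#'
#' The settings part of a [pipeline_config()] (everything except in-memory
#' trials and ratings) round-trips through a JSON file unchanged.
#'
#' @param cfg A `pipeline_config`.
#' @param path JSON path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ser <- list(
    input_dir = cfg$input_dir, output_dir = cfg$output_dir,
    segmentation = unclass(cfg$segmentation),
    cups = purrr::map(cfg$cups, unclass),
    max_gap = cfg$max_gap, blocks_to_fit = cfg$blocks_to_fit,
    fit_models = cfg$fit_models, seed = cfg$seed)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- do.call(segmentation_config, ser$segmentation %||% list())
  cups <- if (!is.null(ser$cups)) {
    purrr::map(ser$cups, function(cu) {
      cup_spec(h_cup = cu$h_cup, r1 = cu$r1, r2 = cu$r2, m_cup = cu$m_cup,
               liquid = cu$liquid, base_z = cu$base_z)
    })
  } else list(empty = cup_spec(), filled = cup_spec_filled())
  pipeline_config(
    input_dir = ser$input_dir, trials = NULL, output_dir = ser$output_dir,
    segmentation = seg, cups = cups, max_gap = ser$max_gap %||% 5L,
    blocks_to_fit = ser$blocks_to_fit, fit_models = ser$fit_models %||% TRUE,
    seed = ser$seed %||% 1L)
}
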