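#' @title Pipeline orchestration
#' @description
#' Runs the full analysis over a cohort of synthetic subjects: generation,
#' preprocessing, behavioral event detection, epoching + artifact rejection,
#' GLM encoding, sLORETA source imaging, sLDA decoding, and group-level
#' permutation statistics. One subject corresponds to one generated dataset
#' with its own seeds; determinism is guaranteed given (config, seed).
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' Stage parameters default to the study values; cohort and model sizes are
#' configurable for desk-scale runs.
#'
#' @param n_subjects cohort size (the study has 15; 5 is the CI-scale
#'   default).
#' @param synth generator configuration from [synth_config()].
#' @param epoch_window_trial,epoch_window_move epoch windows, s.
#' @param roi_window_trial,roi_window_move analysis windows for the ROI
#'   direction-encoding comparison, s.
#' @param n_perm permutations for group tests.
#' @param n_shuffles label shuffles per subject for decoding significance
#'   (set 0 to skip this stage).
#' @param shuffle_time_stride evaluate every k-th time-point in the shuffle
#'   stage.
#' @param gfp_reps repetitions for the GFP estimate (study setting 10,000).
#' @param do_decoding,do_source enable/disable stages.
#' @param windowed_len windowed-decoding history length (time-points).
#' @param decode_interval_trial,decode_interval_move evaluation intervals
#'   for the decoding curves, s.
#' @param fdr_q FDR level.
#' @return configuration list.
#' @export
pipeline_config <- function(n_subjects = 5L, synth = synth_config(),
                            epoch_window_trial = c(0.75, 4.75),
                            epoch_window_move = c(-2, 1.25),
                            roi_window_trial = c(2.9, 3.4),
                            roi_window_move = c(-0.3, 0.3),
                            n_perm = 10000L, n_shuffles = 0L,
                            shuffle_time_stride = 4L,
                            gfp_reps = 10000L,
                            do_decoding = TRUE, do_source = TRUE,
                            windowed_len = 6L,
                            decode_interval_trial = c(2.0, 4.0),
                            decode_interval_move = c(-1.2, 0.8),
                            fdr_q = 0.05) {
  as.list(environment())
}

# direction-only design (horz, vert, intercept) for a condition subset
.direction_design <- function(trials, seed) {
  dirs <- trials$direction
  n_cell <- table(factor(dirs, levels = .DIR_LEVELS))
  if (any(n_cell < 2)) stop("need >= 2 trials per direction")
  m <- min(n_cell)
  idx <- .with_seed(seed, {
    sort(unlist(lapply(.DIR_LEVELS, function(d) {
      w <- which(dirs == d)
      if (length(w) > m) sort(sample(w, m)) else w
    })))
  })
  tr <- dirs[idx]
  horz <- ifelse(tr == "right", 1, ifelse(tr == "left", -1, 0))
  vert <- ifelse(tr == "up", 1, ifelse(tr == "down", -1, 0))
  raw <- rbind(horz = horz, vert = vert)
  ctr <- rowMeans(raw); sc <- apply(raw, 1, stats::sd)
  S <- rbind((raw - ctr) / sc, intercept = rep(1, length(idx)))
  structure(list(S = S, index = idx,
                 zscore = list(center = ctr, scale = sc)),
            class = "design_matrix")
}

#' Run the full analysis for one synthetic subject
#'
#' @param config from [pipeline_config()].
#' @param seed subject seed (drives generation and all stochastic stages).
#' @return list with the subject's trial table, eye onsets, behavioral cell
#'   means, per-alignment GLM source maps and norms, ROI direction
#'   encoding, decoding curves and bookkeeping (GFP, kept trials).
#' @export
run_subject <- function(config = pipeline_config(), seed = 1L) {
  gen <- generate_experiment(config$synth, seed = seed)
  lf <- gen$leadfield
  pre <- preprocess_recording(gen$eeg, gen$calibration,
                              lf$channel_positions)
  trials <- detect_trial_events(gen$cursor, gen$trials)
  eye_onsets <- detect_eye_onset(pre$broadband, trials)

  onset_rel <- trials$detected_onset - trials$t_trial_start
  cells <- function(v) {
    out <- array(NA_real_, c(2, 4),
                 dimnames = list(c("exe", "obs"), .DIR_LEVELS))
    for (cd in c("exe", "obs")) for (d in .DIR_LEVELS) {
      sel <- trials$condition == cd & trials$direction == d & !trials$outlier
      out[cd, d] <- mean(v[sel])
    }
    out
  }
  behavior <- list(onset_cells = cells(onset_rel),
                   duration_cells = cells(trials$duration))

  keep0 <- which(!trials$outlier & !is.na(trials$detected_onset))
  mean_offset <- mean(trials$detected_offset[keep0] -
                        trials$t_trial_start[keep0])

  process_alignment <- function(anchors, window, tag) {
    bb <- extract_epochs(pre$broadband, anchors, window, alignment = tag,
                         band = "broadband")
    rej <- reject_artifact_epochs(bb)
    dl <- extract_epochs(pre$delta, anchors, window, alignment = tag,
                         band = "delta")
    dl <- apply_rejection(dl, rej$mask)
    kept <- drop_rejected(dl)
    list(epochs = kept$epochs, index = keep0[kept$index], rejection = rej)
  }
  al_trial <- process_alignment(trials$t_trial_start[keep0],
                                config$epoch_window_trial, "trial_start")
  al_move <- process_alignment(trials$detected_onset[keep0],
                               config$epoch_window_move, "movement_onset")

  out <- list(trials = trials, eye_onsets = eye_onsets, behavior = behavior,
              mean_offset = mean_offset, seed = seed,
              n_kept = c(trial_start = dim(al_trial$epochs$data)[1],
                         movement_onset = dim(al_move$epochs$data)[1]))

  if (config$do_source) {
    rest_len <- round(ncol(gen$calibration$data) / 2)
    noise_cov <- estimate_noise_covariance(
      pre$calibration_delta$data[
        pre$calibration_delta$channel_types == "eeg",
        seq_len(round(rest_len * pre$calibration_delta$fs / gen$eeg$fs)),
        drop = FALSE])
    inv <- compute_sloreta_operator(lf, noise_cov)
    gfp <- estimate_gfp(al_trial$epochs, inv, n_reps = config$gfp_reps,
                        seed = seed + 11L)

    glm_for <- function(al, roi_window) {
      tt <- trials[al$index, ]
      des <- build_design_matrix(tt, seed = seed + 13L)
      fit <- fit_glm_timecourse(al$epochs, des)
      nt <- length(fit$time)
      nv <- length(lf$roi_labels)
      A_src <- array(NA_real_, c(3 * nv, 4, nt))
      for (i in seq_len(nt)) {
        A_src[, , i] <- project_and_normalize(fit$A[, , i], inv,
                                              gfp)$values
      }
      cond_norm <- vapply(seq_len(nt),
                          function(i) voxel_norm(A_src[, 1, i]),
                          numeric(nv))
      dir_norm <- vapply(seq_len(nt), function(i) {
        voxel_direction_norm(A_src[, 2, i], A_src[, 3, i])
      }, numeric(nv))

      # condition-specific direction encoding, ROI means over the window
      roi <- matrix(NA_real_, 8, 2,
                    dimnames = list(names(roi_means(numeric(nv),
                                                    lf$roi_labels)),
                                    c("exe", "obs")))
      widx <- which(fit$time >= roi_window[1] & fit$time <= roi_window[2])
      for (cd in c("exe", "obs")) {
        sub <- which(tt$condition == cd)
        desd <- .direction_design(tt[sub, ], seed = seed + 17L)
        ep_sub <- new_epochs(al$epochs$data[sub, , , drop = FALSE],
                             al$epochs$time, al$epochs$fs,
                             al$epochs$alignment, al$epochs$band,
                             al$epochs$channel_names)
        fd <- fit_glm_timecourse(ep_sub, desd)
        dmap <- rowMeans(vapply(widx, function(i) {
          Asrc <- project_and_normalize(fd$A[, , i], inv, gfp)$values
          voxel_direction_norm(Asrc[, 1], Asrc[, 2])
        }, numeric(nv)))
        roi[, cd] <- roi_means(dmap, lf$roi_labels)
      }
      list(time = fit$time, A_src = A_src, cond_norm = cond_norm,
           dir_norm = dir_norm, roi_direction = roi)
    }
    out$glm <- list(trial_start = glm_for(al_trial,
                                          config$roi_window_trial),
                    movement_onset = glm_for(al_move,
                                             config$roi_window_move))
    out$gfp <- gfp
    out$roi_labels <- lf$roi_labels
  }

  if (config$do_decoding) {
    dec_for <- function(al, interval) {
      tt <- trials[al$index, ]
      res <- list(
        condition = crossval_accuracy_curve(al$epochs, tt$condition,
                                            interval = interval),
        direction = crossval_accuracy_curve(al$epochs, tt$direction,
                                            interval = interval))
      exe <- which(tt$condition == "exe")
      ep_exe <- new_epochs(al$epochs$data[exe, , , drop = FALSE],
                           al$epochs$time, al$epochs$fs,
                           al$epochs$alignment, al$epochs$band,
                           al$epochs$channel_names)
      res$direction_exe_windowed <- crossval_accuracy_curve(
        ep_exe, tt$direction[exe], mode = "windowed",
        window_len = config$windowed_len, interval = interval)
      if (config$n_shuffles >= 100) {
        nt <- dim(al$epochs$data)[3]
        tsub <- seq(1, nt, by = config$shuffle_time_stride)
        res$threshold_condition <- shuffle_significance_level(
          al$epochs, tt$condition, n_shuffles = config$n_shuffles,
          time_subset = tsub, seed = seed + 19L)$threshold
        res$threshold_direction <- shuffle_significance_level(
          al$epochs, tt$direction, n_shuffles = config$n_shuffles,
          time_subset = tsub, seed = seed + 23L)$threshold
      }
      res
    }
    out$decoding <- list(
      trial_start = dec_for(al_trial, config$decode_interval_trial),
      movement_onset = dec_for(al_move, config$decode_interval_move))
  }
  out
}

#' ROI-level condition-difference tests on direction encoding
#'
#' One two-sided paired permutation t-test per ROI and alignment
#' (8 x 2 = 16 tests) on the execution-minus-observation difference in
#' GFP-normalized direction-related voxel norms, with BH-FDR over the
#' family.
#'
#' @param subjects list of subject results from [run_subject()] (source
#'   stage enabled).
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @param q FDR level.
#' @return data.frame with one row per test (roi, alignment, mean_diff, t,
#'   p, significant).
#' @export
roi_difference_tests <- function(subjects, n_perm = 10000L, seed = 1L,
                                 q = 0.05) {
  if (length(subjects) < 2) stop("need >= 2 subjects for paired tests")
  aligns <- c("trial_start", "movement_onset")
  rois <- rownames(subjects[[1]]$glm$trial_start$roi_direction)
  rows <- list()
  k <- 0L
  for (al in aligns) {
    for (r in rois) {
      exe <- vapply(subjects,
                    function(s) s$glm[[al]]$roi_direction[r, "exe"], 0)
      obs <- vapply(subjects,
                    function(s) s$glm[[al]]$roi_direction[r, "obs"], 0)
      k <- k + 1L
      tst <- permutation_paired_ttest(exe, obs, sides = "two",
                                      n_perm = n_perm, seed = seed + k)
      rows[[k]] <- data.frame(roi = r, alignment = al,
                              mean_diff = mean(exe - obs),
                              t = tst$statistic, p = tst$p)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p, q = q)$mask
  out
}

#' Run the cohort pipeline and assemble the group report
#'
#' @param config from [pipeline_config()].
#' @param seed master seed; subject s uses `seed + 7919 * s`.
#' @return list of class `pipeline_report`: `subjects` (per-subject
#'   results), `behavior` (RM-ANOVAs on onset and duration), `eye_onsets`
#'   (group means per direction), `roi_tests`, `signflip`
#'   (group sign-flip tests on the source coefficient norms at the group
#'   peak time-points), `decoding` (group curves and alignment peak
#'   comparison), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L) {
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    run_subject(config, seed = seed + 7919L * s)
  })

  onset_arr <- array(NA_real_, c(config$n_subjects, 2, 4),
                     dimnames = list(NULL, c("exe", "obs"), .DIR_LEVELS))
  dur_arr <- onset_arr
  for (s in seq_along(subjects)) {
    onset_arr[s, , ] <- subjects[[s]]$behavior$onset_cells
    dur_arr[s, , ] <- subjects[[s]]$behavior$duration_cells
  }
  behavior <- list(onset = rm_anova_two_way(onset_arr),
                   duration = rm_anova_two_way(dur_arr))
  eye <- colMeans(do.call(rbind, lapply(subjects, `[[`, "eye_onsets")),
                  na.rm = TRUE)

  report <- list(subjects = subjects, behavior = behavior,
                 eye_onsets = eye)

  if (config$do_source) {
    report$roi_tests <- roi_difference_tests(subjects,
                                             n_perm = config$n_perm,
                                             seed = seed, q = config$fdr_q)
    # group-average the coefficient maps first (the cohort shares one
    # source space), then extract voxel norms and their peak locations
    group_norms <- function(al, what) {
      A <- Reduce(`+`, lapply(subjects, function(s) s$glm[[al]]$A_src)) /
        length(subjects)
      nt <- dim(A)[3]
      if (what == "cond_norm") {
        vapply(seq_len(nt), function(i) voxel_norm(A[, 1, i]),
               numeric(dim(A)[1] / 3))
      } else {
        vapply(seq_len(nt), function(i) {
          voxel_direction_norm(A[, 2, i], A[, 3, i])
        }, numeric(dim(A)[1] / 3))
      }
    }
    # ROI-mean norm curves are far less noisy than single-voxel argmaxes:
    # the reported peak is the ROI (and time) with the largest mean norm
    peak_roi <- function(al, what) {
      g <- group_norms(al, what)
      tv <- subjects[[1]]$glm[[al]]$time
      labels <- subjects[[1]]$roi_labels
      rois <- sort(unique(stats::na.omit(labels)))
      curves <- t(vapply(rois, function(r) {
        colMeans(g[which(labels == r), , drop = FALSE])
      }, numeric(ncol(g))))
      vx <- arrayInd(which.max(curves), dim(curves))
      list(roi = rois[vx[1]], time = tv[vx[2]],
           roi_curves = curves, map_at_peak = g[, vx[2]])
    }
    # sign-flip test on the subject coefficient maps at the group peak time
    signflip_at <- function(al, factor_cols, peak) {
      tv <- subjects[[1]]$glm[[al]]$time
      ti <- which.min(abs(tv - peak$time))
      eff <- do.call(rbind, lapply(subjects, function(s) {
        as.numeric(s$glm[[al]]$A_src[, factor_cols, ti])
      }))
      stat_fun <- if (length(factor_cols) == 1) {
        voxel_norm
      } else {
        function(v) {
          h <- v[seq_len(length(v) / 2)]
          voxel_direction_norm(h, v[-seq_len(length(v) / 2)])
        }
      }
      permutation_signflip_test(eff, n_perm = config$n_perm,
                                seed = seed + 31L, stat_fun = stat_fun)
    }
    sf <- list()
    for (al in c("trial_start", "movement_onset")) {
      pk_dir <- peak_roi(al, "dir_norm")
      pk_cond <- peak_roi(al, "cond_norm")
      sf[[al]] <- list(
        direction_peak = pk_dir, condition_peak = pk_cond,
        direction_test = signflip_at(al, c(2, 3), pk_dir),
        condition_test = signflip_at(al, 1, pk_cond))
    }
    report$signflip <- sf
  }

  if (config$do_decoding) {
    group_curve <- function(al, what) {
      accs <- do.call(rbind, lapply(subjects, function(s) {
        s$decoding[[al]][[what]]$accuracy
      }))
      list(time = subjects[[1]]$decoding[[al]][[what]]$time,
           mean = colMeans(accs), accuracies = accs)
    }
    dec <- list()
    for (al in c("trial_start", "movement_onset")) {
      dec[[al]] <- list(condition = group_curve(al, "condition"),
                        direction = group_curve(al, "direction"))
    }
    dec$alignment_peaks <- summarize_peaks(
      lapply(subjects, function(s) {
        s$decoding$trial_start$direction_exe_windowed
      }),
      lapply(subjects, function(s) {
        s$decoding$movement_onset$direction_exe_windowed
      }),
      interval_a = config$decode_interval_trial,
      interval_b = config$decode_interval_move,
      sides = "two", n_perm = config$n_perm, seed = seed + 37L)
    report$decoding <- dec
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "synth")],
                               auto_unbox = TRUE, digits = NA)
  report$provenance <- list(
    seed = seed,
    subject_seeds = seed + 7919L * seq_len(config$n_subjects),
    config_hash = unname(tools::md5sum(
      local({f <- tempfile(); writeLines(as.character(cfg_json), f); f}))),
    package_version = as.character(utils::packageVersion("deltamotor")),
    r_version = R.version.string)
  class(report) <- "pipeline_report"
  report
}
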