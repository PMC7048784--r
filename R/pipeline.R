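# End-to-end orchestration: simulate/load -> QC -> biomarkers -> features ->
# group statistics -> classifier, with reproducible artifacts.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with defaults matching the
#' published analysis: frame confidence threshold 0.75, participant
#' tracked-fraction threshold 0.90, 10-s mimicry windows, 1000-tree forests
#' with the {1,2,4,8,16,32,64}^2 depth-by-leaf grid, alpha 0.05 with Holm
#' correction within feature families.
#'
#' @param input_dir Directory of OpenFace CSVs / WAVs (or `NULL` to
#'   simulate).
#' @param out_dir Output directory for artifacts.
#' @param seed Root seed; all stage seeds derive from it.
#' @param simulate Cohort spec used when `input_dir` is `NULL`
#'   (default [cohort_spec()] with this config's seed).
#' @param conf_threshold,tracked_min Quality-control thresholds.
#' @param mimicry_window,mimicry_lags Mimicry parameters (seconds).
#' @param grid,n_trees,inner_folds Classifier parameters.
#' @param modality Which feature block the classifier uses
#'   (`"all"`, `"face"`, `"gaze"`, `"voice"`).
#' @param alpha Significance level for the statistics stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = tempfile("sit_run_"),
                       seed = 1, simulate = NULL,
                       conf_threshold = 0.75, tracked_min = 0.90,
                       mimicry_window = 10,
                       mimicry_lags = seq(0, 3, by = 0.25),
                       grid = default_grid(), n_trees = 1000,
                       inner_folds = 3,
                       modality = "all", alpha = 0.05) {
  structure(list(
    input_dir = input_dir, out_dir = out_dir, seed = seed,
    simulate = simulate %||% cohort_spec(seed = seed),
    conf_threshold = conf_threshold, tracked_min = tracked_min,
    mimicry_window = mimicry_window, mimicry_lags = mimicry_lags,
    grid = grid, n_trees = n_trees, inner_folds = inner_folds,
    modality = modality, alpha = alpha
  ), class = "run_config")
}

#' Load a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory containing per-participant OpenFace CSVs, optional
#'   WAVs, `metadata.csv`, `actress.csv` and `schedule.yaml`.
#' @return A `sit_cohort`-like list (`spec` is `NULL`).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  sched_path <- file.path(dir, "schedule.yaml")
  sched <- if (file.exists(sched_path)) load_schedule(sched_path) else
    default_schedule()
  actress <- read_frame_table(file.path(dir, "actress.csv"), "actress")
  frames <- list()
  waves <- list()
  for (pid in meta$subject_id) {
    frames[[pid]] <- read_frame_table(file.path(dir, paste0(pid, ".csv")), pid)
    wav <- file.path(dir, paste0(pid, ".wav"))
    waves[[pid]] <- if (file.exists(wav)) {
      w <- read_wav(wav)
      list(wave = w$wave, rate = w$rate)
    } else NULL
  }
  structure(list(spec = NULL, schedule = sched, actress = actress,
                 metadata = meta, frames = frames, waves = waves),
            class = "sit_cohort")
}

#' Quality-control stage for a cohort
#'
#' @param cohort A `sit_cohort`.
#' @param conf_threshold,tracked_min See [participant_qc()].
#' @return Data frame of per-participant QC reports.
#' @export
cohort_qc <- function(cohort, conf_threshold = 0.75, tracked_min = 0.90) {
  out <- do.call(rbind, lapply(cohort$frames, participant_qc,
                               conf_threshold = conf_threshold,
                               tracked_min = tracked_min))
  rownames(out) <- NULL
  out
}

#' Extract all biomarkers and feature blocks for a cohort
#'
#' Filters frames, computes the AU summaries, mimicry scores, gaze
#' kinematics and voice summaries for every QC-passing participant, and
#' assembles the face/gaze/voice feature blocks and the combined matrix.
#'
#' @param cohort A `sit_cohort`.
#' @param cfg A [run_config()].
#' @param include Subject ids to keep (default: all).
#' @return List: `biomarkers` (named list of tidy data frames: `au_summary`,
#'   `mimicry`, `gaze`, `voice`, `social_smiling`), `features` (named list
#'   of `feature_matrix` objects: `face`, `gaze`, `voice` (if audio
#'   present), `combined`).
#' @export
extract_cohort_features <- function(cohort, cfg = run_config(),
                                    include = NULL) {
  ids <- include %||% cohort$metadata$subject_id
  sched <- cohort$schedule
  actress_f <- filter_frames(cohort$actress, cfg$conf_threshold)
  au_rows <- list(); mim_rows <- list(); gaze_rows <- list()
  voice_rows <- list(); smile_rows <- list()
  face_vecs <- list(); gaze_vecs <- list(); voice_vecs <- list()
  have_audio <- TRUE
  for (pid in ids) {
    ft <- filter_frames(cohort$frames[[pid]], cfg$conf_threshold)
    gmeta <- cohort$metadata$gender[cohort$metadata$subject_id == pid]
    au_rows[[pid]] <- au_segment_summary(ft, sched)
    mim_rows[[pid]] <- mimicry_scores(ft, actress_f,
                                      window = cfg$mimicry_window,
                                      lag_grid = cfg$mimicry_lags)
    sm <- social_smiling(ft, sched)
    smile_rows[[pid]] <- data.frame(person_id = pid,
                                    AU12_occ = sm$AU12_occ,
                                    AU12_int = sm$AU12_int,
                                    AU6_occ = sm$AU6_occ,
                                    AU6_int = sm$AU6_int)
    gaze_rows[[pid]] <- gaze_kinematics(ft)
    face_vecs[[pid]] <- build_face_features(ft, sched, gmeta)
    gaze_vecs[[pid]] <- build_gaze_features(ft, sched, gmeta)
    w <- cohort$waves[[pid]]
    if (is.null(w)) {
      have_audio <- FALSE
    } else {
      vs <- voice_summary(w$wave, w$rate)
      voice_rows[[pid]] <- data.frame(person_id = pid, t(vs))
      voice_vecs[[pid]] <- build_voice_features(vs, gmeta)
    }
  }
  meta <- cohort$metadata[cohort$metadata$subject_id %in% ids, ]
  features <- list(
    face = feature_matrix(face_vecs, meta),
    gaze = feature_matrix(gaze_vecs, meta)
  )
  if (have_audio && length(voice_vecs) == length(ids)) {
    features$voice <- feature_matrix(voice_vecs, meta)
    features$combined <- combine_features(features$face, features$gaze,
                                          features$voice)
  } else {
    features$combined <- combine_features(features$face, features$gaze)
  }
  biomarkers <- list(
    au_summary = do.call(rbind, c(au_rows, make.row.names = FALSE)),
    mimicry = do.call(rbind, c(mim_rows, make.row.names = FALSE)),
    social_smiling = do.call(rbind, c(smile_rows, make.row.names = FALSE)),
    gaze = do.call(rbind, c(gaze_rows, make.row.names = FALSE)),
    voice = if (length(voice_rows))
      do.call(rbind, c(voice_rows, make.row.names = FALSE)) else NULL
  )
  list(biomarkers = biomarkers, features = features)
}

#' Univariate group statistics stage
#'
#' The published univariate comparisons on the extracted biomarkers:
#' Mann-Whitney group comparisons of whole-conversation AU12/AU6 occurrence
#' and intensity and of the AU6 mimicry score; Wilcoxon signed-rank
#' part-vs-neutral contrasts (AU12/AU6 in the positive part, AU4 in the
#' negative part, against the neutral part); group-by-gender ANOVAs of F0
#' mean and HNR median (when audio is present); Holm correction within each
#' family.
#'
#' @param biomarkers The `biomarkers` element of
#'   [extract_cohort_features()].
#' @param metadata Cohort metadata.
#' @return Tidy data frame: `family`, `feature`, `test`, `statistic`, `p`,
#'   `adjusted_p`, `effect_size`.
#' @export
group_statistics <- function(biomarkers, metadata) {
  lab <- stats::setNames(metadata$label, metadata$subject_id)
  gen <- stats::setNames(metadata$gender, metadata$subject_id)
  res <- list()
  add <- function(family, feature, r) {
    res[[length(res) + 1]] <<- cbind(
      data.frame(family = family, feature = feature), r
    )
  }
  sm <- biomarkers$social_smiling
  g <- lab[sm$person_id]
  for (f in c("AU12_occ", "AU12_int", "AU6_occ", "AU6_int")) {
    x <- sm[[f]][g == "ASD"]; y <- sm[[f]][g == "NT"]
    if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2) {
      add("face", paste0("social_smiling.", f),
          mann_whitney(x[!is.na(x)], y[!is.na(y)]))
    }
  }
  au <- biomarkers$au_summary
  paired_contrast <- function(auname, part, what) {
    a <- au[au$au == auname & au$segment == part, ]
    b <- au[au$au == auname & au$segment == "neutral_answer", ]
    ids <- intersect(a$person_id, b$person_id)
    x <- a[[what]][match(ids, a$person_id)]
    y <- b[[what]][match(ids, b$person_id)]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) >= 3) {
      add("face", paste0(auname, ".", part, "_vs_neutral.", what),
          wilcoxon_signed(x[keep], y[keep]))
    }
  }
  paired_contrast("AU12", "positive_answer", "intensity")
  paired_contrast("AU12", "positive_answer", "occurrence")
  paired_contrast("AU06", "positive_answer", "intensity")
  paired_contrast("AU06", "positive_answer", "occurrence")
  paired_contrast("AU04", "negative_answer", "intensity")
  mim <- biomarkers$mimicry
  for (auname in unique(mim$au)) {
    s <- mim[mim$au == auname, ]
    gg <- lab[s$person_id]
    x <- s$score[gg == "ASD"]; y <- s$score[gg == "NT"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) >= 2 && length(y) >= 2) {
      add("face", paste0("mimicry.", auname), mann_whitney(x, y))
    }
  }
  gz <- biomarkers$gaze
  gg <- lab[gz$person_id]
  for (ax in c("horizontal", "vertical")) {
    for (f in c("mean_angle", "abs_dev_median", "mean_speed", "mean_accel")) {
      x <- gz[[f]][gz$axis == ax & gg == "ASD"]
      y <- gz[[f]][gz$axis == ax & gg == "NT"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) >= 2 && length(y) >= 2) {
        add("gaze", paste0("gaze.", ax, ".", f), mann_whitney(x, y))
      }
    }
  }
  if (!is.null(biomarkers$voice)) {
    vo <- biomarkers$voice
    gg <- factor(lab[vo$person_id])
    sx <- factor(ifelse(gen[vo$person_id] == 1, "female", "male"))
    for (f in c("f0_mean", "hnr_median", "jitter_local", "shimmer_local",
                "rms_energy")) {
      v <- vo[[f]]
      keep <- !is.na(v)
      if (all(table(gg[keep], sx[keep]) >= 2)) {
        a <- anova_group_gender(v[keep], gg[keep], sx[keep])
        for (k in seq_len(nrow(a))) {
          add("voice", paste0("voice.", f, ".", a$test[k]), a[k, ])
        }
      }
    }
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$adjusted_p <- NA_real_
  for (fam in unique(out$family)) {
    i <- out$family == fam
    out$adjusted_p[i] <- holm_correct(out$p[i])
  }
  out
}

#' Run the full pipeline
#'
#' simulate (or load) -> participant QC -> biomarker extraction -> feature
#' matrices -> univariate group statistics -> leave-one-out nested-CV
#' classifier. Writes `qc_report.csv`, `au_summary.csv`, `mimicry.csv`,
#' `gaze.csv`, `voice.csv` (if audio), `features.csv`, `stats.csv`,
#' `cv_result.csv`, `metrics.json`, `roc.csv` and `run.log` into
#' `cfg$out_dir`. A rerun with the same config and seed is bit-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `qc`, `biomarkers`, `features`, `stats`,
#'   `cv`, `metrics`, `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  logmsg <- function(...) {
    msg <- sprintf("[%s] %s", "sitpipe", paste0(...))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (is.null(cfg$input_dir)) simulate_cohort(cfg$simulate)
    else read_cohort(cfg$input_dir)
  })
  qc <- stage("qc", cohort_qc(cohort, cfg$conf_threshold, cfg$tracked_min))
  utils::write.csv(qc, file.path(cfg$out_dir, "qc_report.csv"),
                   row.names = FALSE)
  keep <- qc$person_id[qc$included]
  logmsg(sprintf("qc: %d/%d participants included", length(keep), nrow(qc)))
  ex <- stage("extract", extract_cohort_features(cohort, cfg, include = keep))
  utils::write.csv(ex$biomarkers$au_summary,
                   file.path(cfg$out_dir, "au_summary.csv"), row.names = FALSE)
  utils::write.csv(ex$biomarkers$mimicry,
                   file.path(cfg$out_dir, "mimicry.csv"), row.names = FALSE)
  utils::write.csv(ex$biomarkers$gaze,
                   file.path(cfg$out_dir, "gaze.csv"), row.names = FALSE)
  if (!is.null(ex$biomarkers$voice)) {
    utils::write.csv(ex$biomarkers$voice,
                     file.path(cfg$out_dir, "voice.csv"), row.names = FALSE)
  }
  write_feature_matrix(ex$features$combined,
                       file.path(cfg$out_dir, "features.csv"))
  meta_kept <- cohort$metadata[cohort$metadata$subject_id %in% keep, ]
  stats_df <- stage("stats", group_statistics(ex$biomarkers, meta_kept))
  utils::write.csv(stats_df, file.path(cfg$out_dir, "stats.csv"),
                   row.names = FALSE)
  fm <- select_modality(ex$features$combined, cfg$modality)
  cv <- stage("classify", loo_nested_cv(fm, grid = cfg$grid,
                                        n_trees = cfg$n_trees,
                                        seed = child_seed(cfg$seed, "cv"),
                                        inner_folds = cfg$inner_folds))
  utils::write.csv(cv$subjects, file.path(cfg$out_dir, "cv_result.csv"),
                   row.names = FALSE)
  mcn <- mcnemar_vs_baseline(cv$subjects$pred,
                             majority_vote(cv$subjects$label),
                             cv$subjects$label)
  sev <- if ("severity" %in% names(meta_kept)) {
    severity_correlation(cv$subjects$prob,
                         meta_kept$severity[match(cv$subjects$subject_id,
                                                  meta_kept$subject_id)])
  } else NULL
  metrics <- list(
    seed = cfg$seed, modality = cfg$modality,
    n_subjects = nrow(cv$subjects),
    auc = cv$auc, accuracy = cv$accuracy,
    sensitivity = cv$sensitivity, specificity = cv$specificity,
    mcnemar_vs_majority = mcn,
    severity_spearman = sev
  )
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(roc_points(cv$subjects$prob, cv$subjects$label),
                   file.path(cfg$out_dir, "roc.csv"), row.names = FALSE)
  logmsg(sprintf("done: AUC %.3f accuracy %.2f", cv$auc, cv$accuracy))
  invisible(list(qc = qc, biomarkers = ex$biomarkers,
                 features = ex$features, stats = stats_df, cv = cv,
                 metrics = metrics, out_dir = cfg$out_dir))
}
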