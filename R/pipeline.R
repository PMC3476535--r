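## write a data frame as a deterministic TSV artifact
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.log_line <- function(log_path, ...) {
  cat(paste0(format(Sys.time(), "%H:%M:%S"), "  ", ..., "\n"),
      file = log_path, append = TRUE)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, per subject: simulation, preprocessing (high-pass, channel
#' rejection, average reference, mechanical trial-bound refinement),
#' mixture ICA with trial model-fit classification, dipole localization,
#' then across subjects: component clustering, time-frequency ERD
#' statistics with bootstrap masking, and 4-way naive Bayes decoding with
#' cross-validated grand-average confusion matrices.  All intermediate
#' tables are written under `out_dir`; results are a pure function of the
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed (default: the configuration's).
#' @return A results list (also summarised in the written artifacts):
#'   per-subject trial classification, the model-probability ANOVA,
#'   clusters, per-mode effort t-tests, and grand confusion matrices for
#'   the all-cluster and single-cluster decoders.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = config$seed) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  write_config(config, file.path(out_dir, "config.yaml"))
  stage <- function(name, fun) {
    .log_line(log_path, "stage ", name, " started")
    r <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .log_line(log_path, "stage ", name, " done")
    r
  }
  sphere <- sphere_model()
  freqs <- log_freq_grid(config$fmin, config$fmax, config$n_freqs)
  subjects <- sprintf("S%02d", seq_len(config$subjects))

  ## ---- per-subject simulation + preprocessing + ICA + localization ----
  per_subject <- list()
  all_records <- list()
  for (s in seq_along(subjects)) {
    sid <- subjects[s]
    sseed <- seed + 1000L * s
    sim <- stage(paste0("simulate:", sid), function()
      simulate_subject(subject_id = sid, seed = sseed,
                       reps = config$reps,
                       n_channels = config$n_channels, sphere = sphere,
                       shift_mm = config$shift_mm,
                       noise_rms = config$noise_rms,
                       line_amp = config$line_amp,
                       drift_rms = config$drift_rms))
    if (isTRUE(config$write_edf))
      write_recording(sim$recording, sim$events,
                      file.path(out_dir, sid))

    pp <- stage(paste0("preprocess:", sid), function() {
      rec <- highpass(sim$recording, config$hp_cutoff, config$hp_order)
      rj <- reject_channels(rec, std_limit = config$std_limit,
                            kurt_z = config$kurt_z,
                            r_limit = config$r_limit,
                            max_uncorrelated = config$max_uncorrelated,
                            window_s = config$corr_window_s,
                            n_neighbors = config$n_neighbors)
      rec <- rereference_average(rj$recording)
      ev <- detect_trial_bounds(rec, sim$events)
      list(recording = rec, events = ev, report = rj$report)
    })
    .write_tsv(data.frame(channel = names(pp$report$verdict),
                          verdict = pp$report$verdict),
               file.path(out_dir, paste0(sid, "_rejection.tsv")))
    .write_tsv(as.data.frame(pp$events),
               file.path(out_dir, paste0(sid, "_events_refined.tsv")))

    fit <- stage(paste0("ica:", sid), function()
      mixica(pp$recording, M = config$n_models,
             n_components = config$n_components,
             max_iter = config$ica_max_iter, tol = config$ica_tol,
             seed = sseed, max_samples = config$ica_max_samples,
             n_scale = config$ica_n_scale,
             n_restarts = config$ica_restarts))
    cls <- classify_trials_by_model(fit, pp$recording, pp$events)
    pk <- mean(cls$trial_probability[
      which(cls$mapping == "knee")[1], pp$events$joint == "knee"])
    pa <- mean(cls$trial_probability[
      which(cls$mapping == "knee")[1], pp$events$joint == "ankle"])

    recs <- stage(paste0("localize:", sid), function()
      component_records(fit, pp$recording, sphere))
    .write_tsv(do.call(rbind, lapply(recs, function(r)
      data.frame(component = sprintf("%s_m%d_c%02d", sid, r$model_id,
                                     r$component_index),
                 x = r$dipole$location[1], y = r$dipole$location[2],
                 z = r$dipole$location[3],
                 qx = r$dipole$moment[1], qy = r$dipole$moment[2],
                 qz = r$dipole$moment[3],
                 rv = r$dipole$rv, class = r$class))),
      file.path(out_dir, paste0(sid, "_dipoles.tsv")))

    all_records <- c(all_records, recs)
    ## keep only the low-dimensional whitened projection; component
    ## activations are W_h (proj - bias), so the full recording can be
    ## released before the next subject is simulated
    per_subject[[sid]] <- list(
      proj = fit$whitening %*% (pp$recording$eeg - fit$center),
      events = pp$events, fit = fit,
      classification = cls, p_model_knee = c(knee = pk, ankle = pa))
    rm(pp, sim); invisible(gc(FALSE))
  }

  anova <- anova_model_probabilities(
    vapply(per_subject, function(p) p$p_model_knee[["knee"]], numeric(1)),
    vapply(per_subject, function(p) p$p_model_knee[["ankle"]], numeric(1)))

  ## ---- clustering across subjects ----
  clusters <- stage("cluster", function()
    cluster_components(all_records,
                       k = min(config$k_clusters,
                               sum(vapply(all_records, function(r)
                                 r$class == "cortical", logical(1))) %/% 2),
                       seed = seed,
                       location_weight = config$location_weight,
                       n_pc = config$n_map_pc,
                       retain_fraction = config$retain_fraction,
                       n_subjects = config$subjects))
  retained <- Filter(function(cl) cl$retained, clusters)
  if (!length(retained)) retained <- clusters[
    order(-vapply(clusters, `[[`, numeric(1), "subject_count"))[1]]
  .write_tsv(do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, x = cl$centroid[1], y = cl$centroid[2],
               z = cl$centroid[3], members = length(cl$members),
               subjects = cl$subject_count, retained = cl$retained)
  })), file.path(out_dir, "clusters.tsv"))

  ## medial-superior cluster stands in for the supplementary motor area
  sma_idx <- which.max(vapply(retained, function(cl)
    cl$centroid[3] - abs(cl$centroid[1]), numeric(1)))

  ## ---- per-subject spectrograms on cluster activations ----
  spectro <- stage("spectro", function() {
    out <- list()
    for (sid in names(per_subject)) {
      ps <- per_subject[[sid]]
      ev <- ps$events
      tdur <- (ev$offset_sample - ev$onset_sample) / config$fs
      target <- stats::median(tdur)
      cl_specs <- list()
      for (ci in seq_along(retained)) {
        mem <- Filter(function(r) r$subject_id == sid,
                      retained[[ci]]$records)
        if (!length(mem)) next
        mdl <- ps$fit$models[[mem[[1]]$model_id]]
        a <- drop((mdl$W %*% (ps$proj - mdl$bias))[
          mem[[1]]$component_index, ])
        specs <- lapply(seq_len(nrow(ev)), function(j) {
          sp <- epoch_spectrogram(a, config$fs, ev$onset_sample[j],
                                  ev$offset_sample[j], freqs = freqs,
                                  window = config$tf_window,
                                  step = config$tf_step)
          sp <- baseline_normalize(sp, config$baseline)
          timewarp(sp, target_duration = target)
        })
        cl_specs[[paste0("cluster", ci)]] <- specs
      }
      out[[sid]] <- list(specs = cl_specs, labels = condition_label(ev),
                         modes = ev$mode, efforts = ev$effort,
                         target = target)
    }
    out
  })

  ## ---- ERD statistics: effort contrast per mode across subjects ----
  erd <- stage("erd", function() {
    bands <- list(alpha = c(8, 12), beta = c(12, 30))
    sma_name <- paste0("cluster", sma_idx)
    per_mode <- list()
    for (mode in c("isometric", "isotonic")) {
      vals <- list(high = numeric(0), low = numeric(0))
      for (sid in names(spectro)) {
        sp <- spectro[[sid]]
        if (is.null(sp$specs[[sma_name]])) next
        for (eff in c("high", "low")) {
          sel <- sp$modes == mode & sp$efforts == eff
          if (!any(sel)) next
          mk <- bootstrap_mask(sp$specs[[sma_name]][sel],
                               alpha = config$alpha,
                               n_boot = config$n_boot, seed = seed)
          es <- vapply(bands, function(b)
            erd_statistic(mk, b)$mean_db, numeric(1))
          vals[[eff]] <- c(vals[[eff]], mean(es, na.rm = TRUE))
        }
      }
      n <- min(length(vals$high), length(vals$low))
      per_mode[[mode]] <- c(
        list(erd_high = vals$high, erd_low = vals$low),
        if (n >= 2) compare_effort_ttest(vals$high[seq_len(n)],
                                         vals$low[seq_len(n)])
        else list(t = NA_real_, p = NA_real_))
    }
    per_mode
  })

  ## ---- decoding ----
  decode <- stage("decode", function() {
    reduce_all <- function(specs) lapply(specs, reduce_resolution,
                                         factor = config$reduce_factor)
    ## exclude the most posterior centroid as the putative visual cluster
    ## (gaze-control concern), but never at the cost of an empty decoder
    excl <- if (isTRUE(config$exclude_visual) && length(retained) > 1) {
      vi <- which.min(vapply(retained, function(cl) cl$centroid[2],
                             numeric(1)))
      paste0("cluster", vi)
    } else character(0)
    per_subj_all <- list(); per_subj_sma <- list()
    for (sid in names(spectro)) {
      sp <- spectro[[sid]]
      red <- lapply(sp$specs, reduce_all)
      run_cv <- function(cl_list) {
        if (isTRUE(config$paper_mode)) {
          bf <- build_features(cl_list, sp$labels, alpha = config$alpha,
                               n_boot = config$n_boot, seed = seed)
          crossvalidate(bf$features, sp$labels, k = config$cv_folds,
                        seed = seed)
        } else {
          crossvalidate(cl_list, sp$labels, k = config$cv_folds,
                        seed = seed, alpha = config$alpha,
                        n_boot = config$n_boot)
        }
      }
      keep_all <- setdiff(names(red), excl)
      per_subj_all[[sid]] <- run_cv(red[keep_all])
      sma_name <- paste0("cluster", sma_idx)
      if (!is.null(red[[sma_name]]))
        per_subj_sma[[sid]] <- run_cv(red[sma_name])
    }
    list(all = per_subj_all, sma = per_subj_sma,
         grand_all = aggregate_confusion(per_subj_all),
         grand_sma = aggregate_confusion(per_subj_sma))
  })
  for (nm in c("grand_all", "grand_sma")) {
    g <- decode[[nm]]
    .write_tsv(data.frame(actual = rownames(g$normalized),
                          round(as.data.frame.matrix(g$normalized), 4)),
               file.path(out_dir, paste0(nm, "_confusion.tsv")))
  }

  trial_acc <- vapply(per_subject, function(p)
    p$classification$accuracy, numeric(1))
  .write_tsv(data.frame(subject = names(per_subject),
                        knee_vs_ankle = round(trial_acc, 4)),
             file.path(out_dir, "trial_classification.tsv"))

  res <- list(config = config, seed = seed,
              subjects = lapply(per_subject, function(p)
                p[c("events", "classification", "p_model_knee")]),
              trial_accuracy = trial_acc,
              anova = anova,
              clusters = clusters,
              sma_cluster = sma_idx,
              erd = erd,
              decode = decode[c("grand_all", "grand_sma")],
              accuracy_all = decode$grand_all$accuracy,
              accuracy_sma = decode$grand_sma$accuracy)
  .log_line(log_path, "pipeline complete")
  res
}
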