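# Reproducible end-to-end runs: simulate a cohort to disk, then train,
# translate, evaluate mapping quality, run the intra-subject protocol,
# select the ensemble and run the inter-subject protocol, writing CSV
# reports with Mean rows. Every run writes its resolved configuration next
# to its outputs; one master seed propagates deterministically to all
# stages.

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config
}

stage_seed <- function(master, stage) {
  (as.numeric(master) * 131 + stage * 7919) %% 2147483629
}

#' Simulate a cohort and write it to disk
#'
#' @param config named list (or YAML file path) with optional entries
#'   `simulate` (fields of [simulation_config()]), `out_dir`, `format`
#'   (`"npz"` or `"rds"`) and `seed`
#' @return path of the written cohort file, invisibly; a resolved-config
#'   YAML and a provenance log are written beside it
#' @export
run_simulate <- function(config = list()) {
  config <- resolve_config(config)
  known <- c("simulate", "out_dir", "format", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  out_dir <- config$out_dir %||% "eegtranslate_run"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1
  sim_args <- config$simulate %||% list()
  sim_args$seed <- stage_seed(seed, 1)
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad)) stop("unknown simulate keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(simulation_config, sim_args)
  cohort <- simulate_cohort(cfg)
  format <- config$format %||% "npz"
  path <- file.path(out_dir, paste0("cohort.", format))
  write_cohort(cohort, path, format = format)
  fwd <- attr(cohort, "forward_model")
  resolved <- list(simulate = unclass(cfg), out_dir = out_dir,
                   format = format, seed = seed,
                   calibrated_spike_leakage = fwd$spike_leakage)
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  vis <- vapply(cohort$subjects, function(s)
    s$n_ied_visible / max(1, s$n_ied_total), numeric(1))
  writeLines(c(
    sprintf("seed: %s", seed),
    sprintf("geometry: L=%d M=%d M_bar=%d rate=%g", cfg$L, cfg$M, cfg$M_bar,
            cfg$sampling_rate),
    sprintf("subjects: %d x %d segments", cfg$n_subjects,
            cfg$segments_per_subject),
    sprintf("visibility: target=%s calibrated_leakage=%.4f measured=%s",
            format(cfg$target_visible_fraction), fwd$spike_leakage,
            paste(round(vis, 3), collapse = " "))),
    file.path(out_dir, "simulate.log"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full mapping + detection pipeline on a cohort file
#'
#' Executes train -> translate -> mapping evaluation -> intra-subject
#' classification -> subject selection -> inter-subject classification, and
#' writes `mapping.csv` (per-subject MSE/PCORR/COSSIM), `detection.csv`
#' (per-subject intra/inter accuracies) and per-subject training histories.
#' With `ablations = TRUE` it additionally trains the encoder-free and
#' SPADE-free variants and writes `ablation.csv`.
#'
#' @param config named list (or YAML path) with `cohort` (file path),
#'   `out_dir`, `seed`, optional `arch`, `train`, `classifier` argument
#'   lists, optional `ablations` flag and `inter_threshold`
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config = list()) {
  config <- resolve_config(config)
  cohort_path <- config$cohort %||% stop("config$cohort (cohort file) required")
  out_dir <- config$out_dir %||% "eegtranslate_run"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1
  cohort <- read_cohort(cohort_path)
  L <- nrow(cohort$subjects[[1]]$segments[[1]]$scalp$samples)
  M <- ncol(cohort$subjects[[1]]$segments[[1]]$scalp$samples)
  Mb <- ncol(cohort$subjects[[1]]$segments[[1]]$intracranial$samples)
  arch <- do.call(arch_config, c(list(L = L, M = M, M_bar = Mb),
                                 config$arch %||% list()))
  ctrl <- do.call(train_control,
                  c(config$train %||% list(),
                    list(seed = stage_seed(seed, 2))))
  cls_cfg <- do.call(eegnet_config,
                     c(config$classifier %||% list(),
                       list(seed = stage_seed(seed, 3))))
  run_variant <- function(arch_v) {
    models <- train_cohort(cohort, arch_v, ctrl)
    pairs <- list()
    intra <- list()
    for (s in cohort$subjects) {
      arr <- seg_input(s$segments)
      est <- translate(models[[s$subject_id]], arr$scalp, mode = "mean")
      pairs[[s$subject_id]] <- lapply(seq_len(dim(est)[1]), function(i) {
        list(matrix(arr$intracranial[i, , ], L, Mb), matrix(est[i, , ], L, Mb))
      })
      intra[[s$subject_id]] <- intra_subject_eval(
        s$segments, models[[s$subject_id]], cfg = cls_cfg,
        seed = stage_seed(seed, 4))
    }
    list(models = models, mapping = evaluate_mapping(pairs), intra = intra)
  }
  full <- run_variant(arch)
  write_metric_table(full$mapping$per_subject,
                     file.path(out_dir, "mapping.csv"), rounding = 3)
  intra_acc <- vapply(full$intra, function(r) r$metrics$ACC, numeric(1))
  selected <- select_training_subjects(intra_acc,
                                       config$inter_threshold %||% 0.70)
  inter_acc <- rep(NA_real_, length(cohort$subjects))
  names(inter_acc) <- vapply(cohort$subjects, function(s) s$subject_id,
                             character(1))
  for (s in cohort$subjects) {
    member_ids <- setdiff(selected, s$subject_id)
    if (!length(member_ids)) next
    members <- lapply(member_ids, function(id)
      list(model = full$models[[id]], classifier = full$intra[[id]]$classifier))
    names(members) <- member_ids
    inter_acc[s$subject_id] <-
      inter_subject_eval(s$segments, members, s$subject_id)$metrics$ACC
  }
  detection <- data.frame(subject = names(inter_acc),
                          ACC_intra = as.numeric(intra_acc[names(inter_acc)]),
                          ACC_inter = as.numeric(inter_acc))
  write_metric_table(detection, file.path(out_dir, "detection.csv"),
                     rounding = 3)
  histories <- lapply(full$models, function(m) m$history)
  for (id in names(histories)) {
    utils::write.csv(histories[[id]],
                     file.path(out_dir, paste0("history_", id, ".csv")),
                     row.names = FALSE)
  }
  if (isTRUE(config$ablations)) {
    rows <- lapply(c("no_encoder", "no_spade_resnet"), function(ab) {
      arch_ab <- arch
      arch_ab$ablation <- ab
      v <- run_variant(arch_ab)
      data.frame(variant = ab,
                 ACC_intra = mean(vapply(v$intra, function(r) r$metrics$ACC,
                                         numeric(1))),
                 MSE = v$mapping$cohort_mean["MSE"],
                 PCORR = v$mapping$cohort_mean["PCORR"],
                 COSSIM = v$mapping$cohort_mean["COSSIM"])
    })
    full_row <- data.frame(variant = "full",
                           ACC_intra = mean(intra_acc),
                           MSE = full$mapping$cohort_mean["MSE"],
                           PCORR = full$mapping$cohort_mean["PCORR"],
                           COSSIM = full$mapping$cohort_mean["COSSIM"])
    abl <- rbind(full_row, do.call(rbind, rows))
    rownames(abl) <- NULL
    utils::write.csv(abl, file.path(out_dir, "ablation.csv"),
                     row.names = FALSE)
  }
  resolved <- c(config, list(resolved_seed = seed,
                             selected_subjects = selected))
  yaml::write_yaml(resolved, file.path(out_dir, "pipeline_config.yaml"))
  invisible(out_dir)
}
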