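# Config-driven end-to-end orchestration: simulate -> preprocess -> fit the
# three calibration engines -> validate -> report, with deterministic
# seeding and stable on-disk output.

# 32-bit FNV-1a hash of a string; used for config fingerprints and for
# deriving per-stage child seeds, so adding a stage never perturbs the
# randomness of earlier stages.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^32
  }
  h
}

stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) + fnv1a32(stage)) %% 2147483647)
}

#' Default pipeline configuration
#'
#' A nested list understood by [run_pipeline()]: the simulation design
#' parameters, preprocessing widths, contour policy, split fraction, the
#' method list with per-method hyperparameters, and the global seed from
#' which every stage's randomness is derived.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for all artifacts.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("eemcal_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    design = list(n_samples = 21L, noise_sd = 0.01, n_spiked_pairs = 6L),
    preprocessing = list(w1 = 15, w2 = 15, wR = 10,
                         contour_policy = "max_energy",
                         cal_fraction = 3 / 4),
    methods = list(
      lar = list(grid_size = 30L),
      ipls = list(n_intervals = 8L, max_components = 10L),
      npls = list(max_lv = 8L, lv_rule = "global")
    ),
    write_eems = FALSE
  )
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file with the fields of [default_config()];
#'   missing fields take their defaults.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_lists <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]])) {
        merge_lists(base[[k]], new[[k]])
      } else new[[k]]
    }
    base
  }
  merge_lists(cfg, user)
}

#' Run the full EEM calibration pipeline
#'
#' Executes, in order: synthetic dataset generation (standards plus
#' spiked/unspiked real-sample surrogates), scatter excision and infilling,
#' calibration/prediction split of the standards, contour extraction (the
#' excitation column chosen on the calibration set only), fitting of each
#' configured method for each analyte with its own model selection (lasso
#' penalty by LOO RMSECV, iPLS interval/components by LOO RMSECV, N-PLS
#' latent variables by LOO PRESS), validation (Rc/RMSEC/Rp/RMSEP), spike
#' recoveries on the surrogate pairs, and the cross-method report. All
#' artifacts are written under `config$out_dir`; rerunning with an identical
#' config reproduces them byte-for-byte.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @return Invisibly, a run summary: the comparison tables, the per-method
#'   reports, selected hyperparameters, and output paths.
#' @export
run_pipeline <- function(config = default_config()) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- sprintf("%08x", as.integer(fnv1a32(yaml::as.yaml(config)) %% 2^31))
  stage <- "init"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  design <- run_stage("simulate", {
    do.call(simulation_design,
            c(config$design, list(seed = stage_seed(config$seed, "simulate"))))
  })
  dataset <- run_stage("simulate", generate_dataset(design))
  ana <- names(design$analytes)

  processed <- run_stage("preprocess", {
    mask <- build_scatter_mask(design$grid,
                               w1 = config$preprocessing$w1,
                               w2 = config$preprocessing$w2,
                               wR = config$preprocessing$wR)
    preprocess_dataset(dataset, mask)
  })

  std_idx <- which(processed$roles == "calibration")
  pair_idx <- which(processed$roles %in% c("real", "spiked"))
  standards <- dataset_subset(processed, std_idx)
  pairs <- if (length(pair_idx)) dataset_subset(processed, pair_idx) else NULL

  split <- run_stage("split",
                     split_calibration(standards,
                                       cal_fraction = config$preprocessing$cal_fraction))
  cal <- split$calibration
  pred <- split$prediction

  policy <- if (identical(config$preprocessing$contour_policy, "max_energy")) {
    contour_policy("max_energy")
  } else {
    contour_policy("fixed", excitation = config$preprocessing$contour_policy)
  }
  # choose the contour column once, on the calibration set only
  contour_ex <- run_stage("contours",
                          extract_contours(cal, policy)$excitation_used)
  fixed <- contour_policy("fixed", excitation = contour_ex)
  cal_contours <- extract_contours(cal, fixed)$X
  pred_contours <- extract_contours(pred, fixed)$X
  pair_contours <- if (!is.null(pairs)) extract_contours(pairs, fixed)$X else NULL

  methods <- names(config$methods)
  if (length(methods) == 0L) stop("config lists no methods", call. = FALSE)
  spikes <- spike_table(design)
  reports <- list(); recov_rows <- list(); selections <- list(); curves <- list()

  for (method in methods) {
    mp <- config$methods[[method]]
    for (a in ana) {
      key <- paste(method, a, sep = "_")
      y_cal <- cal$concentrations[[a]]
      y_pred <- pred$concentrations[[a]]
      run_stage(paste0("fit_", key), {
        if (method == "lar") {
          sel <- select_penalty(cal_contours, y_cal,
                                grid_size = mp$grid_size %||% 30L)
          model <- sel$model
          selections[[key]] <- list(penalty = sel$penalty,
                                    n_nonzero = length(model$coefficients))
          curves[[key]] <- sel$cv_curve
          fit_x <- cal_contours; pred_x <- pred_contours; pair_x <- pair_contours
        } else if (method == "ipls") {
          scheme <- make_intervals(ncol(cal_contours),
                                   mp$n_intervals %||% 8L)
          model <- ipls_select(cal_contours, y_cal, scheme,
                               max_components = mp$max_components %||% 10L,
                               wavelengths = cal$grid$emission)
          selections[[key]] <- list(interval = model$selected_interval,
                                    n_components = model$n_components,
                                    wavelength_range = model$wavelength_range)
          curves[[key]] <- model$rmsecv_table
          fit_x <- cal_contours; pred_x <- pred_contours; pair_x <- pair_contours
        } else if (method == "npls") {
          sel <- select_lv_by_press(cal, y_cal, max_lv = mp$max_lv %||% 8L,
                                    rule = mp$lv_rule %||% "global")
          model <- npls_fit(cal, y_cal, sel$n_lv)
          selections[[key]] <- list(n_lv = sel$n_lv)
          curves[[key]] <- sel$press_curve
          fit_x <- cal; pred_x <- pred; pair_x <- pairs
        } else {
          stop(sprintf("unknown method '%s'", method))
        }
        reports[[key]] <- evaluate_model(
          model, fit_x, y_cal, pred_x, y_pred,
          analyte = a, method = method,
          cal_ids = cal$concentrations$sample_id,
          pred_ids = pred$concentrations$sample_id)
        if (!is.null(pair_x) && nrow(spikes) > 0) {
          pair_preds <- as.numeric(stats::predict(model, pair_x))
          names(pair_preds) <- pairs$concentrations$sample_id
          sp <- spikes[spikes$analyte == a, , drop = FALSE]
          rec <- recovery(con1 = pair_preds[sp$spiked_id],
                          con0 = pair_preds[sp$unspiked_id],
                          cons = sp$spike,
                          sample_id = sp$unspiked_id, analyte = a)
          rec$method <- method
          recov_rows[[key]] <- rec
        }
      })
    }
  }

  comparison <- run_stage("report", {
    compare_methods(reports,
                    if (length(recov_rows)) do.call(rbind, recov_rows) else NULL)
  })

  run_stage("write", {
    write_manifest_csv(processed, file.path(out_dir, "manifest.csv"))
    write_numeric_csv(data.frame(sample_id = standards$concentrations$sample_id,
                                 set = ifelse(standards$concentrations$sample_id %in%
                                                cal$concentrations$sample_id,
                                              "calibration", "prediction")),
                      file.path(out_dir, "split.csv"))
    ct <- as.data.frame(cal_contours)
    ct <- cbind(sample_id = rownames(cal_contours), ct)
    write_numeric_csv(ct, file.path(out_dir, "contours_calibration.csv"))
    write_numeric_csv(comparison$statistics, file.path(out_dir, "statistics.csv"))
    if (!is.null(comparison$recoveries)) {
      write_numeric_csv(comparison$recoveries, file.path(out_dir, "recoveries.csv"))
    }
    for (key in names(curves)) {
      write_numeric_csv(curves[[key]],
                        file.path(out_dir, sprintf("curve_%s.csv", key)))
    }
    if (isTRUE(config$write_eems)) {
      for (i in seq_len(n_samples(processed))) {
        l <- dataset_landscape(processed, i)
        write_eem_csv(l, file.path(out_dir, sprintf("eem_%s.csv", l$sample_id)))
      }
    }
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           contour_excitation_nm = contour_ex,
           selections = selections),
      file.path(out_dir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(statistics = comparison$statistics,
                 recoveries = comparison$recoveries,
                 reports = reports, selections = selections,
                 contour_excitation_nm = contour_ex,
                 out_dir = out_dir, config_hash = cfg_hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
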