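#' Run an end-to-end analysis pipeline from a config
#'
#' Executes the stages named in the config, in order: `phantom` (simulate a
#' CT volume + ground truth), `cohort` (simulate a feature/outcome table),
#' `segment` (fat segmentation of a volume), `features` (adiposity feature
#' vector), `predict` (SFFS + logistic LOCO evaluation), `correlation`
#' (automated vs manual area agreement). Each stage writes flat-file outputs
#' (NIfTI/CSV/JSON) into `out_dir`, together with a YAML snapshot of the
#' config that produced them; rerunning the same config reproduces identical
#' numeric outputs.
#'
#' Config blocks (all optional, at least one required):
#' \describe{
#'   \item{phantom}{fields of [phantom_config()]}
#'   \item{cohort}{fields of [cohort_config()]}
#'   \item{segment}{`volume` (NIfTI path or DICOM dir; defaults to the
#'     phantom volume generated in the same run), `upper_slice`,
#'     `lower_slice`, plus [seg_params()] fields under `params`}
#'   \item{features}{`bmi`, optional `include_ratio`}
#'   \item{predict}{`endpoint` ("pfs"/"os"), `max_subset`, `seed`; uses the
#'     cohort generated in the same run or `features_csv`/`cases_csv` paths}
#'   \item{correlation}{`auto_csv`, `manual_csv`, `column` pairs}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir output directory (created if missing).
#' @param verbose print a provenance line per stage.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config_snapshot.yaml"))
  say <- function(...) if (verbose) message("[adipoct] ", ...)
  results <- list()

  if (!is.null(config$phantom)) {
    cfg <- do.call(phantom_config, config$phantom)
    ph <- generate_phantom(cfg)
    write_volume(ph$volume, file.path(out_dir, "phantom.nii.gz"))
    write_label_map(list(trunk = ph$truth$trunk, sfa = ph$truth$sfa,
                         vfa = ph$truth$vfa),
                    file.path(out_dir, "phantom_truth.nii.gz"))
    utils::write.csv(
      data.frame(slice = seq_along(ph$truth$true_sfa_area),
                 true_sfa_cm2 = ph$truth$true_sfa_area,
                 true_vfa_cm2 = ph$truth$true_vfa_area),
      file.path(out_dir, "phantom_true_areas.csv"), row.names = FALSE)
    say("phantom: ", cfg$n_slices, " slice(s), seed ", cfg$seed)
    results$phantom <- ph
  }

  if (!is.null(config$cohort)) {
    cfg <- do.call(cohort_config, config$cohort)
    co <- generate_cohort(cfg)
    utils::write.csv(co$features, file.path(out_dir, "cohort_features.csv"),
                     row.names = FALSE)
    utils::write.csv(co$outcomes, file.path(out_dir, "cohort_outcomes.csv"),
                     row.names = FALSE)
    say("cohort: ", cfg$n_cases, " cases, seed ", cfg$seed)
    results$cohort <- co
  }

  if (!is.null(config$segment)) {
    sc <- config$segment
    vol <- if (!is.null(sc$volume)) {
      if (!file.exists(sc$volume) && !dir.exists(sc$volume)) {
        stop("segment stage: volume not found: ", sc$volume)
      }
      read_volume(sc$volume)
    } else if (!is.null(results$phantom)) {
      results$phantom$volume
    } else {
      stop("segment stage: no `volume` path given and no phantom stage ran")
    }
    if (!is.null(sc$upper_slice)) {
      vol <- select_slice_range(vol, sc$upper_slice, sc$lower_slice)
    }
    params <- do.call(seg_params, sc$params %||% list())
    seg <- segment_case(vol, params)
    write_label_map(seg, file.path(out_dir, "segmentation_labels.nii.gz"))
    utils::write.csv(seg$counts, file.path(out_dir, "segmentation_counts.csv"),
                     row.names = FALSE)
    say("segment: ", nrow(seg$counts), " slice(s)")
    results$segment <- seg
  }

  if (!is.null(config$features)) {
    if (is.null(results$segment)) stop("features stage requires a segment stage")
    fc <- config$features
    fv <- compute_features(results$segment, bmi = fc$bmi %||% NA_real_,
                           include_ratio = isTRUE(fc$include_ratio))
    utils::write.csv(as.data.frame(t(fv)), file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    say("features: f2=", signif(fv[["f2"]], 4), " f3=", signif(fv[["f3"]], 4))
    results$features <- fv
  }

  if (!is.null(config$predict)) {
    pc <- config$predict
    if (!is.null(results$cohort)) {
      feats <- results$cohort$features
      cases <- results$cohort$outcomes
      months <- cases$months
    } else if (!is.null(pc$features_csv) && !is.null(pc$cases_csv)) {
      feats <- utils::read.csv(pc$features_csv, stringsAsFactors = FALSE)
      cases <- read_case_table(pc$cases_csv)
      endpoint_col <- paste0(tolower(pc$endpoint %||% "pfs"), "_months")
      months <- cases[[endpoint_col]]
    } else {
      stop("predict stage: no cohort stage ran and no features_csv/cases_csv given")
    }
    x <- as.matrix(feats[, setdiff(names(feats), "case_id"), drop = FALSE])
    lab <- dichotomize(months, endpoint = tolower(pc$endpoint %||% "pfs"))
    cv <- loco_evaluate(x, lab, max_subset = pc$max_subset %||% 4L,
                        seed = pc$seed %||% 7L)
    utils::write.csv(
      data.frame(case_id = feats$case_id, score = cv$scores,
                 label = cv$labels),
      file.path(out_dir, "prediction_scores.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(feature = names(cv$selection_frequency),
                 frequency = as.integer(cv$selection_frequency)),
      file.path(out_dir, "selection_frequency.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cv$confusion),
                     file.path(out_dir, "confusion_matrix.csv"))
    jsonlite::write_json(
      list(accuracy = cv$accuracy, ppv = cv$ppv, npv = cv$npv, auc = cv$auc,
           auc_ci = cv$auc_ci, p_null = cv$p_null),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    say(sprintf("predict: accuracy %.3f, AUC %.3f", cv$accuracy, cv$auc))
    results$predict <- cv
  }

  if (!is.null(config$correlation)) {
    cc <- config$correlation
    auto <- utils::read.csv(cc$auto_csv, stringsAsFactors = FALSE)
    manual <- utils::read.csv(cc$manual_csv, stringsAsFactors = FALSE)
    merged <- merge(auto, manual, by = "case_id")
    out <- list()
    for (pair in cc$pairs) {
      r <- pearson_correlation(merged[[pair$auto]], merged[[pair$manual]])
      out[[paste0(pair$auto, "_vs_", pair$manual)]] <- r
    }
    jsonlite::write_json(out, file.path(out_dir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    say("correlation: ", paste(names(out), signif(unlist(out), 3),
                               sep = "=", collapse = ", "))
    results$correlation <- out
  }

  if (length(results) == 0L) {
    stop("config names no runnable stage ",
         "(expected phantom/cohort/segment/features/predict/correlation)")
  }
  invisible(results)
}
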