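#' Read a grayscale TIFF or PNG image
#'
#' Returns the pixel grid on an 8-bit-like integer scale (values 0–255 for
#' 8-bit sources; 16-bit sources keep their native scale).
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return integer matrix of gray levels.
#' @export
read_grayscale_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
                png = png::readPNG(path) * 255,
                stop_bad("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' Configuration of an end-to-end pipeline run
#'
#' @param synthetic a [synthetic_params()] object describing the cohort.
#' @param threshold breast segmentation gray level, default 100.
#' @param base_radius,base_rows erosion radius policy
#'   ([scale_erosion_radius()]).
#' @param n_levels,symmetric,log_base feature configuration
#'   ([extract_features()]).
#' @param model a [model_config()]; its seed is re-derived per category
#'   from `seed`.
#' @param out_dir output directory for run artifacts.
#' @param seed global seed fanned out to the cohort and to each model.
#' @param stages named logical toggles: `simulate`, `features`, `label`,
#'   `train`, `scree`. Later stages require earlier ones.
#' @param write_images also write every synthetic image as TIFF (default
#'   `FALSE`; the manifest and panels are always written).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_params(),
                            threshold = 100,
                            base_radius = 100, base_rows = 2800,
                            n_levels = 8, symmetric = TRUE,
                            log_base = exp(1),
                            model = model_config(),
                            out_dir = tempfile("mammogist-run-"),
                            seed = 1L,
                            stages = c(simulate = TRUE, features = TRUE,
                                       label = TRUE, train = TRUE,
                                       scree = TRUE),
                            write_images = FALSE) {
  defaults <- c(simulate = TRUE, features = TRUE, label = TRUE,
                train = TRUE, scree = TRUE)
  defaults[names(stages)] <- stages
  structure(list(synthetic = synthetic, threshold = threshold,
                 base_radius = base_radius, base_rows = base_rows,
                 n_levels = n_levels, symmetric = symmetric,
                 log_base = log_base, model = model, out_dir = out_dir,
                 seed = as.integer(seed), stages = defaults,
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

config_echo <- function(config) {
  list(seed = config$seed, threshold = config$threshold,
       base_radius = config$base_radius, base_rows = config$base_rows,
       n_levels = config$n_levels, symmetric = config$symmetric,
       log_base = config$log_base,
       stages = as.list(config$stages),
       synthetic = unclass(config$synthetic),
       model = unclass(config$model))
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, extract features, label by gist quartiles, train and
#' evaluate the per-category classifiers, and apply the scree test —
#' writing every artifact (manifest, panels, features, labels, one report
#' JSON per category, scree selections, family summary, run summary and a
#' config echo) under `config$out_dir`. The run is fully determined by the
#' config: the global seed is fanned out to the cohort and to each model,
#' so re-running an echoed config reproduces all numeric outputs.
#'
#' Categories whose minority class is smaller than the fold count are
#' skipped and flagged in the summary rather than failing the run.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `manifest`, `features`, `labels`,
#'   `datasets`, `reports`, `selections`, `family_summary`, `summary`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  res <- list(out_dir = config$out_dir)
  jsonlite::write_json(config_echo(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!st[["simulate"]]) return(invisible(res))
  syn <- config$synthetic
  syn$seed <- derive_seed(config$seed, 0L)
  message("stage simulate: n = ", syn$n_images)
  cohort <- generate_cohort(syn)
  if (config$write_images) write_cohort(cohort, config$out_dir)
  write.csv(cohort$manifest[, c("image_id", "laterality", "category",
                                "latent_gist")],
            file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(panels_to_df(cohort$panels),
            file.path(config$out_dir, "panels.csv"), row.names = FALSE)
  res$manifest <- cohort$manifest

  if (!st[["features"]]) return(invisible(res))
  message("stage features: extracting 130 GRFs per image")
  feats <- extract_feature_table(cohort$images,
                                 threshold = config$threshold,
                                 base_radius = config$base_radius,
                                 base_rows = config$base_rows,
                                 n_levels = config$n_levels,
                                 symmetric = config$symmetric,
                                 log_base = config$log_base)
  write.csv(feats, file.path(config$out_dir, "features.csv"),
            row.names = FALSE)
  res$features <- feats

  if (!st[["label"]]) return(invisible(res))
  message("stage label: quartile split of averaged gist scores")
  mean_scores <- vapply(cohort$panels, average_panel, numeric(1))
  labels <- quartile_split(mean_scores, cohort$manifest$image_id)
  labels$category <- cohort$manifest$category
  write.csv(labels, file.path(config$out_dir, "labels.csv"),
            row.names = FALSE)
  res$labels <- labels
  res$datasets <- build_category_datasets(labels, feats)

  if (!st[["train"]]) return(invisible(res))
  rep_dir <- file.path(config$out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  reports <- list()
  for (i in seq_along(res$datasets)) {
    cat_name <- names(res$datasets)[i]
    d <- res$datasets[[i]]
    cfg <- config$model
    cfg$seed <- derive_seed(config$seed, i)
    counts <- table(factor(d$label, levels = c("low", "high")))
    if (nrow(d) == 0L || min(counts) < cfg$k_folds) {
      message("stage train: ", cat_name, " skipped: insufficient data")
      reports[[cat_name]] <- list(category = cat_name,
                                  skipped = "insufficient data",
                                  n_high = unname(counts[["high"]]),
                                  n_low = unname(counts[["low"]]))
      next
    }
    message("stage train: ", cat_name, " (", counts[["high"]], " high / ",
            counts[["low"]], " low)")
    reports[[cat_name]] <- cross_validate(d, cfg, category = cat_name)
  }
  for (cat_name in names(reports)) {
    r <- reports[[cat_name]]
    out <- if (inherits(r, "model_report")) {
      list(category = r$category, auc = r$auc,
           auc_ci = as.numeric(r$auc_ci), per_fold_auc = r$per_fold_auc,
           n_high = sum(r$labels == "high"), n_low = sum(r$labels == "low"),
           importance = as.list(r$importance),
           config = unclass(r$config))
    } else r
    jsonlite::write_json(out,
                         file.path(rep_dir, paste0(gsub("[^A-Za-z0-9-]", "_",
                                                        cat_name), ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$reports <- reports

  if (st[["scree"]]) {
    fitted <- Filter(function(r) inherits(r, "model_report"), reports)
    res$selections <- lapply(fitted, function(r) scree_select(r$importance))
    res$family_summary <- cross_model_summary(res$selections)
    scree_dir <- file.path(config$out_dir, "scree")
    dir.create(scree_dir, showWarnings = FALSE)
    jsonlite::write_json(
      lapply(res$selections, function(s)
        list(cut_index = s$cut_index, selected = s$selected,
             families = s$families)),
      file.path(scree_dir, "selections.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(res$family_summary,
              file.path(scree_dir, "family_summary.csv"), row.names = FALSE)
  }

  summary_df <- data.frame(
    category = names(reports),
    n_high = vapply(reports, function(r)
      if (inherits(r, "model_report")) sum(r$labels == "high")
      else r$n_high, numeric(1)),
    n_low = vapply(reports, function(r)
      if (inherits(r, "model_report")) sum(r$labels == "low")
      else r$n_low, numeric(1)),
    auc = vapply(reports, function(r)
      if (inherits(r, "model_report")) r$auc else NA_real_, numeric(1)),
    ci_lo = vapply(reports, function(r)
      if (inherits(r, "model_report")) r$auc_ci[1] else NA_real_,
      numeric(1)),
    ci_hi = vapply(reports, function(r)
      if (inherits(r, "model_report")) r$auc_ci[2] else NA_real_,
      numeric(1)),
    n_selected = vapply(names(reports), function(nm)
      if (!is.null(res$selections[[nm]])) res$selections[[nm]]$cut_index
      else NA_real_, numeric(1)),
    status = vapply(reports, function(r)
      if (inherits(r, "model_report")) "ok"
      else paste0("skipped: ", r$skipped), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  res$summary <- summary_df
  invisible(res)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and returns
#' the per-category summary (class counts, AUC with CI, scree selection
#' size) plus the family frequency table.
#'
#' @param run_dir a run directory produced by [run_pipeline()].
#' @return list with `summary` (data.frame) and `family_summary`
#'   (data.frame or `NULL`).
#' @export
pipeline_report <- function(run_dir) {
  need <- file.path(run_dir, "summary.csv")
  if (!file.exists(need)) {
    have <- list.files(run_dir, recursive = TRUE)
    stop_bad("incomplete run: missing summary.csv; artifacts present: ",
             paste(head(have, 20), collapse = ", "))
  }
  summary_df <- read.csv(need, stringsAsFactors = FALSE)
  fam_path <- file.path(run_dir, "scree", "family_summary.csv")
  fam <- if (file.exists(fam_path)) {
    read.csv(fam_path, stringsAsFactors = FALSE)
  } else NULL
  list(summary = summary_df, family_summary = fam)
}
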