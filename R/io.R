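# Readers and writers for the pipeline's formats (feature-table CSV in the
# per-object exporter dialect, multi-channel scene TIFF with a JSON ground-
# truth sidecar, plate and dose-response CSVs) plus the end-to-end pipeline
# driver with config and provenance.

#' Read a per-cell feature table from CSV
#'
#' Expects metadata columns `cell_id`, `treatment`, `replicate` and one or
#' more numeric parameter columns. Tolerates the two-row header some
#' per-object exporters write (group row over stat row): when the second
#' line is non-numeric in the parameter columns, the two header rows are
#' flattened with a dot (`Group.Stat`). `"NA"` and empty cells become
#' missing values and are counted.
#'
#' @param path CSV file path.
#' @return A feature table; attribute `n_missing` counts missing entries.
#' @export
read_feature_csv <- function(path) {
  header <- utils::read.csv(path, header = TRUE, nrows = 2L,
                            colClasses = "character", check.names = FALSE)
  two_row <- nrow(header) >= 1L && {
    first <- header[1L, setdiff(names(header), feature_metadata_cols()),
                    drop = TRUE]
    length(first) > 0L && all(is.na(suppressWarnings(as.numeric(
      unlist(first)))))
  }
  if (two_row) {
    sub <- unlist(header[1L, ], use.names = FALSE)
    top <- names(header)
    nm <- ifelse(top %in% feature_metadata_cols() | !nzchar(sub) |
                   is.na(sub), top, paste(top, sub, sep = "."))
    df <- utils::read.csv(path, header = FALSE, skip = 2L,
                          check.names = FALSE, na.strings = c("NA", ""))
    names(df) <- nm
  } else {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          na.strings = c("NA", ""))
  }
  missing_meta <- setdiff(feature_metadata_cols(), names(df))
  if (length(missing_meta))
    stop("feature CSV lacks column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  pars <- setdiff(names(df), feature_metadata_cols())
  if (length(pars) == 0L)
    stop("feature CSV has zero parameter columns", call. = FALSE)
  for (p in pars) df[[p]] <- as.numeric(df[[p]])
  df$cell_id <- as.character(df$cell_id)
  df$treatment <- as.character(df$treatment)
  df$replicate <- as.character(df$replicate)
  check_feature_table(df)
  attr(df, "n_missing") <- sum(is.na(df[pars]))
  df
}

#' Write a feature table to CSV
#'
#' @param table A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  check_feature_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write an image scene as multi-channel TIFF plus JSON sidecar
#'
#' Channels are stored as pages of one TIFF (16-bit; intensities are
#' scaled into `[0, 1]` by a factor recorded in the sidecar and restored
#' on read). The sidecar also keeps channel names, pixel size,
#' deconvolution flags and — for synthetic scenes — the ground-truth cell
#' list.
#'
#' @param scene An [image_scene()].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "image_scene"))
  mx <- max(1e-12, vapply(scene$channels, max, numeric(1L)))
  tiff::writeTIFF(lapply(scene$channels, function(m) m / mx), path,
                  bits.per.sample = 16L)
  truth <- NULL
  if (!is.null(scene$truth))
    truth <- lapply(scene$truth$cells, function(cell)
      list(center = cell$center, length_px = cell$length_px,
           width_px = cell$width_px, orientation = cell$orientation,
           channel_intensities = as.list(cell$channel_intensities),
           has_nucleoid = cell$has_nucleoid))
  meta <- list(channels = names(scene$channels), scale = mx,
               pixel_size = scene$pixel_size,
               deconvolved = as.list(scene$deconvolved), cells = truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image scene written by [write_scene()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return An [image_scene()]; ground truth (if present) is restored.
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == length(meta$channels))
  chans <- stats::setNames(lapply(pages, function(m) m * meta$scale),
                           meta$channels)
  scene <- image_scene(chans, pixel_size = meta$pixel_size,
                       deconvolved = unlist(meta$deconvolved))
  if (!is.null(meta$cells) && length(meta$cells)) {
    cells <- lapply(seq_len(nrow(meta$cells)), function(i) {
      row <- meta$cells[i, ]
      cell_truth(unlist(row$center), row$length_px, row$width_px,
                 row$orientation, unlist(row$channel_intensities),
                 row$has_nucleoid)
    })
    scene$truth <- list(cells = cells)
  }
  scene
}

#' Read a microdilution plate from CSV
#'
#' Columns: `concentration` (descending twofold) and `od`; optional
#' attributes `od_blank` / `growth_margin` may be supplied as arguments.
#'
#' @param path CSV path.
#' @param od_blank,growth_margin Passed to [plate_assay()].
#' @return A [plate_assay()].
#' @export
read_plate_csv <- function(path, od_blank = 0.05, growth_margin = 0.05) {
  df <- utils::read.csv(path)
  stopifnot(all(c("concentration", "od") %in% names(df)))
  ord <- order(df$concentration, decreasing = TRUE)
  plate_assay(df$concentration[ord], df$od[ord], od_blank = od_blank,
              growth_margin = growth_margin)
}

#' Read a dose-response table from CSV
#'
#' Columns: `concentration`, `viability`.
#'
#' @param path CSV path.
#' @return A [dose_response()].
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("concentration", "viability") %in% names(df)))
  dose_response(df$concentration, df$viability)
}

#' Build a pipeline run configuration
#'
#' @param query Path to the query feature CSV, or a feature table.
#' @param references Named character vector of reference CSV paths, a
#'   directory containing `*.csv` reference tables, or a named list of
#'   feature tables.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed for every random step.
#' @param outlier_sd SD multiple for the outlier filter.
#' @param subsample_n Per-treatment subsample size or `"auto"`.
#' @param level,method Confidence-ellipse level and method.
#' @return A `run_config` list.
#' @export
run_config <- function(query, references, out_dir, seed = 1,
                       outlier_sd = 5, subsample_n = "auto",
                       level = 0.95, method = "t") {
  stopifnot(level > 0, level < 1, outlier_sd > 0)
  structure(list(query = query, references = references, out_dir = out_dir,
                 seed = seed, outlier_sd = outlier_sd,
                 subsample_n = subsample_n, level = level, method = method),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

load_reference_tables <- function(references) {
  if (is.list(references) && all(vapply(references, is.data.frame,
                                        logical(1L))))
    return(references)
  if (is.character(references) && length(references) == 1L &&
      dir.exists(references)) {
    paths <- list.files(references, pattern = "\\.csv$", full.names = TRUE)
    references <- stats::setNames(paths,
                                  sub("\\.csv$", "", basename(paths)))
  }
  lapply(as.list(references), read_feature_csv)
}

#' Run the full profiling pipeline
#'
#' Loads the query and reference feature tables (CSV paths, a reference
#' directory, or in-memory tables), applies the QC sequence to each
#' (missing-data removal, within-treatment outlier removal; the balanced
#' subsample happens per pair inside the ranking), ranks the references by
#' concordance and writes `results.csv`, `qc_report.csv`, per-pair score
#' exports and a `provenance.json` record to the output directory. The run
#' is fully determined by the configuration.
#'
#' @param config A `run_config` (or YAML path).
#' @return The [rank_references()] result, invisibly; `qc_report` and
#'   `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage ", sQuote(name), ": ", conditionMessage(e),
           call. = FALSE))
  }
  query <- stage("read_query",
                 if (is.data.frame(config$query)) config$query
                 else read_feature_csv(config$query))
  refs <- stage("read_references", load_reference_tables(config$references))
  qc_one <- function(tab) {
    t1 <- drop_incomplete(tab)
    t2 <- drop_outliers(t1, k = config$outlier_sd)
    report <- data.frame(treatment = unique(tab$treatment)[1L],
                         n_input = nrow(tab),
                         n_incomplete = attr(t1, "n_removed"),
                         n_outlier = attr(t2, "n_removed"))
    list(table = t2, report = report)
  }
  qq <- stage("qc", qc_one(query))
  rr <- stage("qc", lapply(refs, qc_one))
  qc_report <- do.call(rbind, c(list(qq$report),
                                lapply(rr, `[[`, "report")))
  ranking <- stage("concordance",
                   rank_references(qq$table, lapply(rr, `[[`, "table"),
                                   level = config$level,
                                   method = config$method,
                                   seed = config$seed,
                                   subsample_n = config$subsample_n))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ranking$table, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(qc_report, file.path(config$out_dir, "qc_report.csv"),
                   row.names = FALSE)
  for (nm in names(ranking$results)) {
    r <- ranking$results[[nm]]
    sc <- rbind(data.frame(treatment = r$treatment_a, r$pca$scores_a),
                data.frame(treatment = r$treatment_b, r$pca$scores_b))
    utils::write.csv(sc, file.path(config$out_dir,
                                   paste0("scores_", nm, ".csv")),
                     row.names = FALSE)
  }
  prov <- list(
    seed = config$seed, outlier_sd = config$outlier_sd,
    subsample_n = config$subsample_n, level = config$level,
    method = config$method,
    query = if (is.character(config$query)) config$query else "<in-memory>",
    references = if (is.character(config$references)) config$references
                 else names(refs),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("bcprofiler")))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(ranking, "qc_report") <- qc_report
  attr(ranking, "out_dir") <- config$out_dir
  invisible(ranking)
}
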