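#' Write one sensor's recording to CSV with a YAML sidecar
#'
#' Signal dialect: header `t,ax,ay,az,gx,gy,gz`, one row per sample,
#' missing (gap) samples as empty fields; units g and deg/s. Metadata
#' (sample_rate, placement, exercise, eye condition, subject id) goes in a
#' sidecar YAML next to the CSV.
#'
#' @param series An [imu_series()].
#' @param path CSV path; the sidecar is written to `<path minus .csv>.yaml`.
#' @param placement,exercise,eye_condition,subject_id Metadata for the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(series, path, placement = NA_character_,
                             exercise = NA_character_,
                             eye_condition = NA_character_,
                             subject_id = NA_character_) {
  stopifnot(inherits(series, "imu_series"))
  df <- data.frame(t = series$t, ax = series$ax, ay = series$ay,
                   az = series$az, gx = series$gx, gy = series$gy,
                   gz = series$gz)
  df[series$gap_mask, -1] <- NA
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(sample_rate = series$sample_rate, placement = placement,
               exercise = exercise, eye_condition = eye_condition,
               subject_id = subject_id)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".yaml", path)

#' Read one sensor's recording from CSV (+ YAML sidecar)
#'
#' @param path CSV path written by [write_signal_csv()]. Empty fields
#'   become gaps.
#' @return An [imu_series()] with attribute `meta` holding the sidecar
#'   list.
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df)))
    stop(sprintf("read_signal_csv: %s: header must contain %s",
                 path, paste(need, collapse = ",")))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("read_signal_csv: missing sidecar '%s'", sc))
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$sample_rate))
    stop(sprintf("read_signal_csv: sidecar '%s' lacks sample_rate", sc))
  gap <- !is.finite(df$ax) | !is.finite(df$ay) | !is.finite(df$az)
  s <- imu_series(t = df$t, ax = df$ax, ay = df$ay, az = df$az,
                  gx = df$gx, gy = df$gy, gz = df$gz,
                  sample_rate = meta$sample_rate, gap_mask = gap)
  attr(s, "meta") <- meta
  s
}

#' Write an exercise recording as one CSV per sensor
#'
#' @param recording An [exercise_recording()].
#' @param dir Output directory (created if needed). Files are named
#'   `<subject>_<exercise>_<condition>_<placement>.csv`.
#' @return Character vector of the written CSV paths, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "exercise_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sid <- if (is.na(recording$subject_id)) "anon" else recording$subject_id
  paths <- character(0)
  for (pl in names(recording$sensors)) {
    p <- file.path(dir, sprintf("%s_%s_%s_%s.csv", sid, recording$exercise,
                                recording$eye_condition, pl))
    write_signal_csv(recording$sensors[[pl]], p, placement = pl,
                     exercise = recording$exercise,
                     eye_condition = recording$eye_condition,
                     subject_id = sid)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Convert a cohort to the canonical long-form feature table
#'
#' Long dialect: one row per (subject, exercise, feature) with columns
#' `subject_id,group,exercise,feature_name,value,provenance`.
#'
#' @param cohort A [cohort_dataset()].
#' @return A long-form data.frame.
#' @export
cohort_to_long <- function(cohort) {
  cohort <- cohort_dataset(cohort)
  fc <- feature_columns(cohort, include_edx = TRUE)
  out <- do.call(rbind, lapply(fc, function(nm) {
    parts <- regmatches(nm, regexpr("\\.", nm), invert = TRUE)[[1]]
    data.frame(subject_id = cohort$subject_id,
               group = cohort$label,
               exercise = parts[1],
               feature_name = parts[2],
               value = cohort[[nm]],
               provenance = cohort$provenance,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rebuild a wide cohort from the long-form feature table
#'
#' @param long Long-form data.frame as from [cohort_to_long()].
#' @return A [cohort_dataset()]; the round trip is lossless for finite
#'   values.
#' @export
long_to_cohort <- function(long) {
  need <- c("subject_id", "group", "exercise", "feature_name", "value")
  if (!all(need %in% names(long)))
    stop("long_to_cohort: columns must contain ",
         paste(need, collapse = ","))
  long$col <- paste(long$exercise, long$feature_name, sep = ".")
  wide <- stats::reshape(
    long[, c("subject_id", "group", "col", "value",
             intersect("provenance", names(long)))],
    idvar = c("subject_id", "group",
              intersect("provenance", names(long))),
    timevar = "col", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  names(wide)[names(wide) == "group"] <- "label"
  rownames(wide) <- NULL
  cohort_dataset(wide)
}

#' Write / read the feature-table CSV
#'
#' @param cohort A [cohort_dataset()] (written in the canonical long
#'   form).
#' @param path CSV path.
#' @return `write_feature_csv`: `path` invisibly. `read_feature_csv`: a
#'   [cohort_dataset()].
#' @export
write_feature_csv <- function(cohort, path) {
  utils::write.csv(cohort_to_long(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  long_to_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read the EDx nerve-conduction table CSV
#'
#' Dialect: `subject_id,nerve,side,fiber,site,measure,value,units`, one
#' row per measured parameter. Amplitude units differ by fiber type (mV
#' motor, uV sensory), so each row carries its units tag.
#'
#' @param cohort A [cohort_dataset()] with `edx.*` columns generated from
#'   [edx_templates()]-style templates.
#' @param templates The EDx templates describing each column.
#' @param path CSV path.
#' @return `path` invisibly; `read_edx_csv` returns the long data.frame.
#' @export
write_edx_csv <- function(cohort, path, templates = edx_templates()) {
  cohort <- cohort_dataset(cohort)
  rows <- list()
  for (e in templates) {
    col <- paste0("edx.", e$name)
    if (!col %in% names(cohort)) next
    rows[[e$name]] <- data.frame(
      subject_id = cohort$subject_id, nerve = e$nerve, side = e$side,
      fiber = e$fiber, site = e$site, measure = e$measure,
      value = cohort[[col]], units = e$units, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("write_edx_csv: no edx.* columns in cohort")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edx_csv
#' @export
read_edx_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a masked correlation matrix to CSV
#'
#' Masked cells (|r| below the threshold) are written as empty fields.
#'
#' @param cm A [correlation_matrix()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  disp <- ifelse(cm$masked, "", formatC(cm$r, digits = 3, format = "f"))
  df <- data.frame(parameter = rownames(cm$r), disp, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a metrics report to JSON
#'
#' @param report A [evaluate_predictions()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  x <- list(schema = "dnscreen-metrics-v1",
            confusion = as.data.frame(report$confusion),
            per_class = report$per_class,
            sensitivity = report$sensitivity,
            specificity = report$specificity,
            accuracy = report$accuracy,
            threshold = report$threshold,
            auc = report$auc)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of the pipeline with the standard defaults:
#' 100 Hz sampling, order-4 high-pass at 0.1 Hz, Welch window 256 with
#' overlap 0.5, band cut-offs 5/10/15 Hz, 200+200 augmentation, 70:30
#' split, SVM models, 0.5 decision threshold. Serialized to YAML, a
#' config plus a seed reproduces a run exactly.
#'
#' @param sample_rate,cutoff_hz,filter_order,window_length,overlap_fraction
#'   Signal/spectral settings.
#' @param band_cutoffs_hz Band cut-offs in Hz.
#' @param n_negative,n_positive Augmentation counts.
#' @param train_fraction Train share of the split.
#' @param model_kind Classifier family.
#' @param threshold Decision threshold.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sample_rate = 100, cutoff_hz = 0.1, filter_order = 4L,
                       window_length = 256L, overlap_fraction = 0.5,
                       band_cutoffs_hz = c(5, 10, 15),
                       n_negative = 200L, n_positive = 200L,
                       train_fraction = 0.7, model_kind = "svm",
                       threshold = 0.5, seed = 1L) {
  cfg <- list(sample_rate = sample_rate, cutoff_hz = cutoff_hz,
              filter_order = as.integer(filter_order),
              window_length = as.integer(window_length),
              overlap_fraction = overlap_fraction,
              band_cutoffs_hz = band_cutoffs_hz,
              n_negative = as.integer(n_negative),
              n_positive = as.integer(n_positive),
              train_fraction = train_fraction, model_kind = model_kind,
              threshold = threshold, seed = as.integer(seed))
  stopifnot(cfg$sample_rate > 0, cfg$cutoff_hz > 0,
            cfg$sample_rate > 2 * cfg$cutoff_hz,
            cfg$window_length >= 8,
            cfg$overlap_fraction >= 0, cfg$overlap_fraction < 1,
            all(cfg$band_cutoffs_hz >= 0),
            cfg$n_negative >= 0, cfg$n_positive >= 0,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$model_kind %in% c("svm", "logistic_regression",
                                  "decision_tree"),
            cfg$threshold >= 0, cfg$threshold <= 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML path.
#' @param config A `run_config` to write.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# run manifest written next to every CLI artifact
write_manifest <- function(path, subcommand, config = NULL, seed = NULL,
                           extra = list()) {
  m <- c(list(schema = "dnscreen-manifest-v1",
              package_version = as.character(utils::packageVersion("dnscreen")),
              subcommand = subcommand, seed = seed,
              config = if (!is.null(config)) unclass(config)),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
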