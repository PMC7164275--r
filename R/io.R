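STUDY_CSV_REQUIRED <- c("subject_id", "group", "day", "parameter", "phase",
                        "side", "replicate", "value")
STUDY_CSV_SUBJECT <- c("symptoms", "t5ss", "age", "sex", "weight", "height", "bmi")

#' Write a study dataset as a long-format CSV
#'
#' One row per measurement with the columns `subject_id, group, day,
#' parameter, phase, side, replicate, value`; subject-level covariates
#' (symptoms, t5ss, demographics) are repeated on each of the subject's
#' rows. UTF-8, header row, `.` decimal separator. The root seed is
#' recorded in a `# seed:` comment line so every artifact carries its
#' provenance.
#'
#' @param data a `study_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(data, path) {
  stopifnot(inherits(data, "study_dataset"))
  df <- merge(data$measurements, data$subjects,
              by = c("subject_id", "group"), sort = FALSE)
  df <- df[do.call(order, df[c("subject_id", "day", "parameter", "phase",
                               "side", "replicate")]), ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", data$config$seed %||% NA_integer_), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format study CSV
#'
#' Parses and validates the dialect written by [write_study_csv()].
#' Validation failures raise classed conditions carrying machine-readable
#' codes and row numbers: `schema` (missing required columns), `parse`
#' (non-numeric values), `duplicate_key` (repeated
#' `(subject_id, day, parameter, phase, side, replicate)`), `domain`
#' (unknown parameter or phase, negative day).
#'
#' @param path CSV file path.
#' @return a `study_dataset`.
#' @export
read_study_csv <- function(path) {
  if (!file.exists(path)) stop_rhino("io", "file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  missing_cols <- setdiff(STUDY_CSV_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop_rhino("schema", "missing required columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  for (col in c("day", "replicate", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0 || anyNA(df[[col]])) {
      bad <- if (length(bad) > 0) bad else which(is.na(df[[col]]))
      stop_rhino("parse", "column '%s' has non-numeric or missing values at rows: %s",
                 col, paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[col]] <- v
  }
  if (any(df$day < 0)) {
    stop_rhino("domain", "negative day at rows: %s",
               paste(utils::head(which(df$day < 0), 5), collapse = ", "))
  }
  bad_param <- which(!df$parameter %in% aar_parameters)
  if (length(bad_param) > 0) {
    stop_rhino("domain", "unknown parameter at rows: %s",
               paste(utils::head(bad_param, 5), collapse = ", "))
  }
  bad_phase <- which(!df$phase %in% aar_phases)
  if (length(bad_phase) > 0) {
    stop_rhino("domain", "unknown phase at rows: %s",
               paste(utils::head(bad_phase, 5), collapse = ", "))
  }
  key <- do.call(paste, c(df[c("subject_id", "day", "parameter", "phase",
                               "side", "replicate")], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_rhino("duplicate_key", "duplicated measurement keys at rows: %s",
               paste(utils::head(dup, 5), collapse = ", "))
  }
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  measurements <- df[STUDY_CSV_REQUIRED]
  subj_cols <- intersect(STUDY_CSV_SUBJECT, names(df))
  subjects <- unique(df[c("subject_id", "group", subj_cols)])
  if ("symptoms" %in% names(subjects)) {
    subjects$symptoms <- as.logical(subjects$symptoms)
  }
  rownames(measurements) <- rownames(subjects) <- NULL
  seed <- NA_integer_
  first <- readLines(path, n = 1)
  if (grepl("^# seed:", first)) seed <- as.integer(sub("^# seed:\\s*", "", first))
  structure(
    list(measurements = measurements, subjects = subjects,
         config = list(seed = seed, source = path)),
    class = "study_dataset"
  )
}
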