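#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with CpGs as rows and samples as
#' columns (EWAS convention: samples are few, CpGs many). All non-missing
#' entries must be methylation fractions in \[0, 1\]; row and column names
#' must be unique.
#'
#' @param Y numeric matrix, CpG-by-sample.
#' @param what label used in error messages.
#' @return `Y`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(Y, what = "beta matrix") {
  if (!is.matrix(Y) || !is.numeric(Y))
    stop_fmt("%s must be a numeric matrix", what)
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop_fmt("%s must have CpG row names and sample column names", what)
  if (anyDuplicated(rownames(Y)))
    stop_fmt("%s has duplicate CpG ids (e.g. '%s')", what,
             rownames(Y)[duplicated(rownames(Y))][1])
  if (anyDuplicated(colnames(Y)))
    stop_fmt("%s has duplicate sample ids (e.g. '%s')", what,
             colnames(Y)[duplicated(colnames(Y))][1])
  bad <- which(!is.na(Y) & (Y < 0 | Y > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_fmt("%s has value %s outside [0,1] at CpG '%s', sample '%s'",
             what, format(Y[bad[1, 1], bad[1, 2]]),
             rownames(Y)[bad[1, 1]], colnames(Y)[bad[1, 2]])
  }
  invisible(Y)
}

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids and a first column of CpG ids.
#' Missing values are encoded as `NA` (case-insensitive).
#'
#' @param path file path.
#' @return validated numeric CpG-by-sample matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", "na", "Na", "nA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop_fmt("'%s': expected CpG id column plus at least one sample", path)
  ids <- as.character(df[[1]])
  Y <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(Y))
    stop_fmt("'%s': non-numeric beta values", path)
  rownames(Y) <- ids
  validate_beta_matrix(Y, what = sprintf("'%s'", path))
  Y
}

#' Write a beta-value matrix as TSV
#'
#' Values are written with 6 decimals and a fixed column order so repeated
#' runs diff cleanly.
#'
#' @param Y beta matrix.
#' @param path output path.
#' @export
write_beta_matrix <- function(Y, path) {
  validate_beta_matrix(Y)
  out <- data.frame(cpg_id = rownames(Y),
                    apply(Y, 2, format_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Required columns: `sample_id`, `subject_id`, `timepoint`, `group`, `age`,
#' `sex`, `batch`. Timepoints are validated against the declared ordered
#' levels; unknown levels are an error, not silently coerced to NA.
#'
#' @param path file path.
#' @param timepoint_levels ordered timepoint labels the study design uses.
#' @return data.frame with `timepoint` as an ordered-level factor.
#' @export
read_sample_sheet <- function(path, timepoint_levels = c("BL", "M3", "M6")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, timepoint_levels = timepoint_levels,
                        what = sprintf("'%s'", path))
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame to validate in place of a file.
#' @param what label for error messages.
#' @export
validate_sample_sheet <- function(sheet,
                                  timepoint_levels = c("BL", "M3", "M6"),
                                  what = "sample sheet") {
  need <- c("sample_id", "subject_id", "timepoint", "group",
            "age", "sex", "batch")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop_fmt("%s missing required columns: %s", what,
             paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_fmt("%s has duplicate sample ids", what)
  bad_tp <- setdiff(unique(as.character(sheet$timepoint)), timepoint_levels)
  if (length(bad_tp))
    stop_fmt("%s has unknown timepoint level(s): %s (declared: %s)", what,
             paste(bad_tp, collapse = ", "),
             paste(timepoint_levels, collapse = ", "))
  sheet$timepoint <- factor(as.character(sheet$timepoint),
                            levels = timepoint_levels)
  if (!is.numeric(sheet$age))
    stop_fmt("%s: age must be numeric", what)
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that a sample sheet and a beta matrix describe the same samples
#'
#' @param Y beta matrix.
#' @param sheet sample sheet.
#' @return TRUE invisibly; mismatched sample sets raise an error listing the
#'   offending ids on each side.
#' @export
check_sheet_matches_matrix <- function(Y, sheet) {
  only_y <- setdiff(colnames(Y), sheet$sample_id)
  only_s <- setdiff(sheet$sample_id, colnames(Y))
  if (length(only_y) || length(only_s)) {
    stop_fmt(paste0("sample sets differ: %d only in matrix (%s), ",
                    "%d only in sheet (%s)"),
             length(only_y), paste(utils::head(only_y, 5), collapse = ","),
             length(only_s), paste(utils::head(only_s, 5), collapse = ","))
  }
  invisible(TRUE)
}
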