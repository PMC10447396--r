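#' Write admission records to CSV
#'
#' Flat CSV with header `record_id, patient_id, date, age, sex, x, y,
#' icd10` (dates ISO-8601); the grid extent travels in a one-line comment
#' so [read_admissions_csv()] restores it.
#'
#' @param records admission records.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_admissions_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ext <- attr(records, "extent")
  if (!is.null(ext))
    writeLines(sprintf("# extent: %g %g", ext[1], ext[2]), con)
  cols <- intersect(c("record_id", "patient_id", "date", "age", "sex",
                      "x", "y", "icd10", "defect"), names(records))
  utils::write.csv(as.data.frame(records)[cols], con, row.names = FALSE)
  invisible(path)
}

#' Read admission records from CSV
#' @param path file written by [write_admissions_csv()].
#' @return records data.frame with the `extent` attribute restored.
#' @export
read_admissions_csv <- function(path) {
  first <- readLines(path, n = 1L)
  ext <- NULL
  if (startsWith(first, "# extent:"))
    ext <- as.numeric(strsplit(trimws(sub("# extent:", "", first)), " ")[[1]])
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  if (!"defect" %in% names(out)) out$defect <- NA_character_
  if (!is.null(ext)) attr(out, "extent") <- setNames(ext, c("x", "y"))
  out
}

#' Write a gridded surface to long-format CSV
#'
#' One row per cell-day: `cell, date, <variables>`. Works for both
#' temperature (`tmin`, `tmax`) and covariate (`rainfall`, `humidity`,
#' `wind`) surfaces.
#'
#' @param surface a `temp_surface` or `covariate_surface`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  vars <- if (inherits(surface, "temp_surface")) c("tmin", "tmax")
  else c("rainfall", "humidity", "wind")
  nc <- nrow(surface$cells); nd <- length(surface$dates)
  out <- data.frame(cell = rep(surface$cells$cell, nd),
                    date = rep(surface$dates, each = nc))
  for (v in vars) out[[v]] <- as.vector(surface[[v]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as a JSON sidecar
#' @param records records carrying a `truth` attribute.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(records, path) {
  truth <- attr(records, "truth")
  if (is.null(truth)) stop("records carry no ground-truth attribute")
  truth$patient_effects <- NULL      # per-patient vector is bulky; summarised
  truth$n_records <- nrow(records)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
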