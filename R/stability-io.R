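.validate_stability <- function(x, source = "input") {
  cols <- c("brand", "temperature_C", "conc_g_per_48mL", "time_h", "ratio", "unit_id")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    stop(source, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[, cols]
  x$brand <- as.character(x$brand)
  x$unit_id <- as.character(x$unit_id)
  for (col in c("temperature_C", "conc_g_per_48mL", "time_h", "ratio")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  bad <- which(is.na(x$time_h) | x$time_h < 0)
  if (length(bad)) stop(source, ": negative or unparseable time at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  n_missing <- sum(is.na(x$ratio))
  if (n_missing > 0) {
    x <- x[!is.na(x$ratio), , drop = FALSE]
    warning(sprintf("%s: dropped %d row(s) with missing ratio (%d retained)",
                    source, n_missing, nrow(x)), call. = FALSE)
  }
  bad <- which(x$ratio <= 0)
  if (length(bad)) stop(source, ": non-positive ratio at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        " (log-ratio undefined)")
  rownames(x) <- NULL
  x
}

#' Read stability measurements from tidy CSV
#'
#' Expects the header `brand,temperature_C,conc_g_per_48mL,time_h,ratio,unit_id`.
#' Rows with a blank/missing ratio are dropped with a warning stating the
#' count; non-positive ratios and negative times are errors naming the row.
#'
#' @param path CSV file path.
#' @return validated stability data.frame.
#' @export
read_stability_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  .validate_stability(x, source = basename(path))
}

#' Read stability measurements from an XLSX workbook
#'
#' Reads a spreadsheet whose first sheet (or `sheet`) carries the same tidy
#' columns as the CSV layout (`brand`, `temperature_C`, `conc_g_per_48mL`,
#' `time_h`, `ratio`, `unit_id`) and validates it identically to
#' [read_stability_data()]. Requires the readxl package.
#'
#' @param path XLSX file path.
#' @param sheet sheet name or index (default 1).
#' @return validated stability data.frame.
#' @export
read_stability_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading XLSX requires the 'readxl' package")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  x <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  .validate_stability(x, source = basename(path))
}
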