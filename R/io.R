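# Delimited-text I/O: long-format observation tables in, reference bands out.

#' Read a long-format observation CSV
#'
#' Expects a header `subject,index,value` (optional `group`), "." as decimal
#' separator and "," as field separator, locale-independent. Row order is
#' preserved in the `orig_order` attribute for streaming use; the returned
#' table itself is validated and canonically ordered.
#'
#' @param path CSV file path.
#' @param log_transform Apply a natural-log transform to `value` on read
#'   (for log-normal biomarkers); values <= 0 are an error.
#' @return An `obs_table` (see [validate_table()]).
#' @export
read_long_csv <- function(path, log_transform = FALSE) {
  if (!file.exists(path)) stop_usage(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = TRUE)
  needed <- c("subject", "index", "value")
  if (!all(needed %in% names(raw))) {
    stop_data(sprintf("bad header: expected columns %s, found %s",
                      paste(needed, collapse = ","),
                      paste(names(raw), collapse = ",")))
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop_data(sprintf("unparseable or non-finite value at data line %d",
                      bad[1]))
  }
  raw$value <- val
  if (log_transform) {
    if (any(val <= 0)) stop_data("log transform requires positive values")
    raw$value <- log(val)
  }
  tab <- validate_table(raw)
  attr(tab, "orig_order") <- raw[, intersect(c("subject", "index", "value"),
                                             names(raw))]
  attr(tab, "log_transformed") <- log_transform
  tab
}

#' Write a reference band to CSV
#'
#' Columns `subject,index,value,lower,upper,atypical,method` with 6-decimal
#' fixed formatting of the numeric columns and `true`/`false` flags.
#'
#' @param band A [reference_band()].
#' @param path Output path.
#' @param exp_transform Exponentiate `value`, `lower`, `upper` before writing
#'   (inverse of a log transform applied on read).
#' @return `path`, invisibly.
#' @export
write_band <- function(band, path, exp_transform = FALSE) {
  if (!inherits(band, "reference_band")) stop_usage("not a reference band")
  out <- band
  if (exp_transform) {
    out$value <- exp(out$value)
    out$lower <- exp(out$lower)
    out$upper <- exp(out$upper)
  }
  df <- data.frame(subject = out$subject, index = out$index,
                   value = sprintf("%.6f", out$value),
                   lower = sprintf("%.6f", out$lower),
                   upper = sprintf("%.6f", out$upper),
                   atypical = ifelse(out$atypical, "true", "false"),
                   method = out$method, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_usage(sprintf("cannot write to %s", path))
  invisible(path)
}
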