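#' Oxygen time series
#'
#' A uniform-interest container for optode traces: strictly increasing
#' timestamps in fractional hours since experiment start, the oxygen signal
#' in instrument units, and channel metadata. Clock-time labels are
#' metadata of the experimental design, not of the trace.
#'
#' @param time_h Numeric, strictly increasing timestamps (hours).
#' @param values Numeric signal, same length as `time_h`.
#' @param channel_id Channel label.
#' @param is_blank Logical; `TRUE` for a medium-only (blank) channel.
#' @param regime Optional [light_regime()] the trace was recorded under.
#' @param segment_label Optional provenance label (e.g. "LL-1").
#' @return An `oxy_ts` object.
#' @export
oxy_ts <- function(time_h, values, channel_id = "ch1", is_blank = FALSE,
                   regime = NULL, segment_label = NA_character_) {
  time_h <- as.numeric(time_h)
  values <- as.numeric(values)
  if (length(time_h) != length(values)) {
    abort_validation("time_h and values must have the same length")
  }
  if (length(time_h) == 0) abort_validation("time series must not be empty")
  if (anyNA(time_h) || anyNA(values)) {
    abort_validation("time series must not contain missing values")
  }
  bad <- which(diff(time_h) <= 0)
  if (length(bad)) {
    abort_validation(paste0(
      "timestamps must be strictly increasing; violation at row ", bad[1] + 1
    ))
  }
  structure(
    list(time_h = time_h, values = values, channel_id = channel_id,
         is_blank = isTRUE(is_blank), regime = regime,
         segment_label = segment_label),
    class = "oxy_ts"
  )
}

#' @export
print.oxy_ts <- function(x, ...) {
  cat(sprintf(
    "<oxy_ts> channel %s%s: %d points, %.2f-%.2f h%s\n",
    x$channel_id, if (x$is_blank) " (blank)" else "", length(x$time_h),
    min(x$time_h), max(x$time_h),
    if (!is.na(x$segment_label)) paste0(", segment ", x$segment_label) else ""
  ))
  invisible(x)
}

#' @export
length.oxy_ts <- function(x) length(x$time_h)

#' @export
as.data.frame.oxy_ts <- function(x, ...) {
  data.frame(time_h = x$time_h, channel_id = x$channel_id, value = x$values)
}

#' Read / write an oxygen trace as delimited text
#'
#' The on-disk schema is a delimited text table with a header row and
#' columns `time_h`, `channel_id`, `value` (comma-separated by default).
#' Reading validates the trace: malformed values and non-monotone or
#' duplicated timestamps are rejected with the offending row number.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @param is_blank Whether the file holds a blank (medium-only) channel.
#' @param regime Optional regime to attach.
#' @return `read_timeseries()` returns an `oxy_ts`.
#' @export
read_timeseries <- function(path, delim = ",", is_blank = FALSE, regime = NULL) {
  if (!file.exists(path)) abort_validation(paste("trace file not found:", path))
  df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("time_h", "channel_id", "value")
  if (!all(required %in% names(df))) {
    abort_validation(paste("trace file must have columns:", paste(required, collapse = ", ")))
  }
  time_h <- suppressWarnings(as.numeric(df$time_h))
  values <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(time_h) | is.na(values))
  if (length(bad)) {
    abort_validation(paste0("malformed numeric value at data row ", bad[1], " of ", path))
  }
  step <- diff(time_h)
  if (any(step == 0)) {
    abort_validation(paste0("duplicate timestamp at data row ", which(step == 0)[1] + 1))
  }
  if (any(step < 0)) {
    abort_validation(paste0("decreasing timestamp at data row ", which(step < 0)[1] + 1))
  }
  oxy_ts(time_h, values, channel_id = as.character(df$channel_id[1]),
         is_blank = is_blank, regime = regime)
}

#' @rdname read_timeseries
#' @param ts An `oxy_ts`.
#' @export
write_timeseries <- function(ts, path, delim = ",") {
  stopifnot(inherits(ts, "oxy_ts"))
  df <- data.frame(
    time_h = format(ts$time_h, digits = 17, trim = TRUE, scientific = FALSE),
    channel_id = ts$channel_id,
    value = format(ts$values, digits = 17, trim = TRUE, scientific = FALSE)
  )
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a qPCR Ct table
#'
#' CSV schema: `sample_id, gene, clock_time, condition, spectrum,
#' replicate, ct`. `condition` is `LD` or `LL`; `clock_time` is an `HH:MM`
#' string; `ct` is the cycle-threshold value (> 0). The key
#' `(sample_id, gene, replicate)` must be unique.
#'
#' @param path File path.
#' @return `read_ct_table()` returns a validated tibble.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort_validation(paste("Ct file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(tibble::as_tibble(df))
}

#' @rdname read_ct_table
#' @param ct A Ct table (data frame).
#' @export
write_ct_table <- function(ct, path) {
  ct <- validate_ct_table(ct)
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_ct_table
#' @export
validate_ct_table <- function(ct) {
  ct <- tibble::as_tibble(ct)
  required <- c("sample_id", "gene", "clock_time", "condition", "spectrum",
                "replicate", "ct")
  missing <- setdiff(required, names(ct))
  if (length(missing)) {
    abort_validation(paste("Ct table is missing columns:", paste(missing, collapse = ", ")))
  }
  if (anyNA(ct$ct) || any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort_validation("every ct must be a finite cycle number > 0")
  }
  bad_cond <- setdiff(unique(ct$condition), c("LD", "LL"))
  if (length(bad_cond)) {
    abort_validation(paste("unknown condition:", paste(bad_cond, collapse = ", ")))
  }
  if (any(!grepl("^[0-2][0-9]:[0-5][0-9]$", ct$clock_time))) {
    abort_validation("clock_time must be an HH:MM string")
  }
  key <- paste(ct$sample_id, ct$gene, ct$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort_validation(paste0(
      "duplicate (sample_id, gene, replicate) key: ",
      gsub("\r", " / ", dup, fixed = TRUE)
    ))
  }
  ct
}
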