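#' Observed per-field cell-count table
#'
#' Validates a tidy table of daily cell counts per microscope field. Required
#' columns: `day` (days since stimulation, starting at 0), `state` (one of
#' `"P"`, `"D"`, `"N"`), `count` (non-negative), `field_id`. Optional
#' annotation columns `condition`, `stimulus`, `replicate` are carried
#' through.
#'
#' @param df A data.frame in the schema above.
#' @return The validated data.frame with class `count_table`.
#' @export
count_table <- function(df) {
  need <- c("day", "state", "count", "field_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$state %in% c("P", "D", "N")))
    stop("state must be one of P, D, N", call. = FALSE)
  if (any(!is.finite(df$count)) || any(df$count < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(df$day < 0))
    stop("days must be non-negative", call. = FALSE)
  class(df) <- unique(c("count_table", class(df)))
  df
}

#' Read / write a count table as CSV
#'
#' @param path CSV file with the [count_table()] schema.
#' @return A `count_table`.
#' @export
read_count_table <- function(path) {
  count_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_count_table
#' @param counts A `count_table`.
#' @export
write_count_table <- function(counts, path) {
  write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

# Per-day, per-state mean counts: matrix [n_days x 3] with rownames = days.
count_day_means <- function(counts) {
  days <- sort(unique(counts$day))
  m <- matrix(NA_real_, length(days), 3,
              dimnames = list(days, c("P", "D", "N")))
  for (s in c("P", "D", "N")) {
    sub <- counts[counts$state == s, ]
    agg <- tapply(sub$count, sub$day, mean)
    m[names(agg), s] <- agg
  }
  if (any(is.na(m)))
    stop("count table must cover all three states at every observed day",
         call. = FALSE)
  m
}
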