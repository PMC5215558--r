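#' Parse a proximity-logger contact stream
#'
#' Reads a CSV stream of directed proximity-logger contact records. Each row
#' is one encounter as recorded by one logger: the logger's own ID, the
#' partner ID it detected, the encounter start time and the encounter
#' duration in seconds. Identifiers are normalised (trimmed, upper-cased) on
#' read so that case or whitespace differences between a logger's own ID and
#' its appearances as a partner do not split an animal in two.
#'
#' Exact duplicate rows are retained — loggers can legitimately record
#' repeated encounters — but are counted and reported in the `"qc"`
#' attribute of the result so that suspicious files can be inspected.
#'
#' @param file Path to a CSV file (or a connection) with columns
#'   `self_id`, `partner_id`, `start` (ISO-8601 timestamp) and `duration_s`.
#' @param tz Time zone used to parse timestamps. Default `"UTC"`.
#'
#' @return A `data.frame` of contact records with columns `self_id`,
#'   `partner_id` (character), `start` (`POSIXct`) and `duration_s`
#'   (integer), rows in input order, with an attribute `"qc"` listing the
#'   number of exact duplicate rows.
#' @seealso [filter_min_duration()], [directed_totals()],
#'   [write_contact_records()]
#' @export
parse_contact_records <- function(file, tz = "UTC") {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("self_id", "partner_id", "start", "duration_s")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("contact stream is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_contact_records())
  }

  self_id <- normalise_id(raw$self_id)
  partner_id <- normalise_id(raw$partner_id)
  start <- parse_timestamp(raw$start, tz)
  bad_time <- which(is.na(start) & !is.na(raw$start))
  if (length(bad_time) > 0L) {
    stop("unparseable timestamp at row ", bad_time[1L], ": '",
         raw$start[bad_time[1L]], "'", call. = FALSE)
  }
  duration_s <- suppressWarnings(as.numeric(raw$duration_s))
  bad_dur <- which(is.na(duration_s) | duration_s < 1 |
                     duration_s != round(duration_s))
  if (length(bad_dur) > 0L) {
    stop("non-positive or non-integer duration at row ", bad_dur[1L], ": '",
         raw$duration_s[bad_dur[1L]], "'", call. = FALSE)
  }
  bad_self <- which(self_id == partner_id)
  if (length(bad_self) > 0L) {
    stop("self-contact (self_id == partner_id) at row ", bad_self[1L],
         call. = FALSE)
  }

  rec <- data.frame(self_id = self_id, partner_id = partner_id,
                    start = start, duration_s = as.integer(duration_s),
                    stringsAsFactors = FALSE)
  attr(rec, "qc") <- list(n_duplicate_rows = sum(duplicated(rec)))
  rec
}

empty_contact_records <- function() {
  rec <- data.frame(self_id = character(0), partner_id = character(0),
                    start = as.POSIXct(character(0), tz = "UTC"),
                    duration_s = integer(0), stringsAsFactors = FALSE)
  attr(rec, "qc") <- list(n_duplicate_rows = 0L)
  rec
}

normalise_id <- function(x) toupper(trimws(as.character(x)))

# vectorised, NA-tolerant ISO-8601 parsing (rows failing every format stay NA)
parse_timestamp <- function(x, tz = "UTC") {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in fmts) {
    idx <- which(is.na(out))
    if (length(idx) == 0L) break
    out[idx] <- as.POSIXct(strptime(as.character(x[idx]), fmt, tz = tz), tz = tz)
  }
  out
}

#' Write contact records back to the logger CSV dialect
#'
#' @param records A contact-record `data.frame` as returned by
#'   [parse_contact_records()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_contact_records <- function(records, file) {
  out <- data.frame(self_id = records$self_id,
                    partner_id = records$partner_id,
                    start = format(records$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    duration_s = records$duration_s)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Drop short (unreliable) contact records
#'
#' One-second proximity-logger records are widely regarded as unreliable
#' sensor chatter and are removed before any network construction; the
#' default threshold keeps records of 2 s and longer.
#'
#' @param records Contact-record `data.frame`.
#' @param min_s Minimum duration (seconds) to keep; default 2.
#' @return The records with `duration_s >= min_s`, input order preserved.
#' @export
filter_min_duration <- function(records, min_s = 2) {
  stopifnot(is.numeric(min_s), length(min_s) == 1L, min_s >= 1)
  records[records$duration_s >= min_s, , drop = FALSE]
}

#' Directed association totals for a time window
#'
#' Sums contact durations into an N x N directed total matrix for one
#' window: entry \code{d[a, b]} is the total time logger `a` recorded
#' partner `b`. Each record is assigned wholly to the window containing its
#' start time, and windows are half-open \code{[start, end)} so that
#' adjacent windows never double-count a record.
#'
#' @param records Contact-record `data.frame`.
#' @param window_start,window_end `POSIXct` window bounds
#'   (`window_start < window_end`).
#' @param ids Character vector of all logger IDs (must cover every ID
#'   appearing in `records`); fixes the matrix dimension and order.
#' @param window Optional window label stored with the result.
#' @return A `directed_totals` object: list with `ids`, the `d` matrix
#'   (dimnames = ids, zero diagonal) and `window`.
#' @export
directed_totals <- function(records, window_start, window_end, ids,
                            window = NULL) {
  stopifnot(length(ids) >= 2L, window_start < window_end)
  ids <- normalise_id(ids)
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)
  seen <- unique(c(records$self_id, records$partner_id))
  unknown <- setdiff(seen, ids)
  if (length(unknown) > 0L) {
    stop("record identifier(s) not in ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  keep <- records$start >= window_start & records$start < window_end
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) > 0L) {
    agg <- stats::aggregate(duration_s ~ self_id + partner_id, data = rec, FUN = sum)
    d[cbind(agg$self_id, agg$partner_id)] <- agg$duration_s
  }
  structure(list(ids = ids, d = d, window = window), class = "directed_totals")
}

#' @export
print.directed_totals <- function(x, ...) {
  cat("Directed association totals (", length(x$ids), " loggers",
      if (!is.null(x$window)) paste0(", window ", x$window), ")\n", sep = "")
  cat("total recorded time:", sum(x$d), "s\n")
  invisible(x)
}

#' Write an id-labelled dense matrix to CSV
#'
#' @param m A matrix with identical row/column dimnames, or a
#'   `directed_totals` / `association_matrix` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(m, file) {
  if (inherits(m, "directed_totals")) m <- m$d
  if (inherits(m, "association_matrix")) m <- m$O
  utils::write.csv(as.data.frame(m), file, row.names = TRUE)
  invisible(file)
}

#' Read an id-labelled dense matrix from CSV
#'
#' @param file Path written by [write_matrix_csv()].
#' @return A numeric matrix with row/column names.
#' @export
read_matrix_csv <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  m
}
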