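#' Signed percentage difference between the two directions of a dyad
#'
#' Loggers vary in sensitivity, so the two members of a dyad rarely report
#' identical totals. The disagreement is measured as the percentage
#' difference relative to the dyad mean,
#' \deqn{100 (d_{ab} - d_{ba}) / \mathrm{mean}(d_{ab}, d_{ba}),}
#' which is antisymmetric in its arguments and scale-invariant.
#'
#' @param d_ab Total seconds logger `a` recorded partner `b`.
#' @param d_ba Total seconds logger `b` recorded partner `a`.
#' @return Signed percentage (vectorised). `NA` where both totals are zero
#'   (no information about relative bias).
#' @export
pairwise_pct_difference <- function(d_ab, d_ba) {
  stopifnot(all(d_ab >= 0), all(d_ba >= 0))
  m <- (d_ab + d_ba) / 2
  out <- ifelse(m > 0, 100 * (d_ab - d_ba) / m, NA_real_)
  out
}

#' Estimate per-logger recording bias
#'
#' For each logger the over-recording index is the mean signed percentage
#' difference against all partners with usable (not both-zero) dyads. The
#' most under-recorded logger (minimum index, ties broken by lexicographic
#' ID) becomes the reference, and every logger's bias is its index relative
#' to that reference, so biases are nonnegative and the reference has bias
#' zero.
#'
#' @param totals A `directed_totals` object.
#' @return A `logger_bias` object: list with `bias_pct` (named nonnegative
#'   vector), `reference_id`, and `index` (the raw per-logger means).
#' @export
estimate_logger_bias <- function(totals) {
  stopifnot(inherits(totals, "directed_totals"))
  d <- totals$d
  ids <- totals$ids
  n <- length(ids)
  pct <- pairwise_pct_difference(d, t(d))  # pct[a, b] for each ordered dyad
  diag(pct) <- NA_real_
  m <- rowMeans(pct, na.rm = TRUE)
  isolated <- ids[!is.finite(m)]
  if (length(isolated) > 0L) {
    stop("logger(s) with no usable dyads: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  }
  ref <- ids[order(m, ids)][1L]
  bias <- m - m[ref]
  structure(list(bias_pct = bias, reference_id = ref, index = m),
            class = "logger_bias")
}

#' @export
print.logger_bias <- function(x, ...) {
  cat("Per-logger recording bias (reference:", x$reference_id, ")\n")
  print(round(x$bias_pct, 2))
  invisible(x)
}

#' Apply recording-bias correction to directed totals
#'
#' Standardises loggers against the most under-recorded logger: a logger
#' with bias b% has every duration it recorded (its row of the directed
#' matrix) reduced by b%, i.e. multiplied by (1 - b/100). The reference
#' logger's row is unchanged.
#'
#' @param totals A `directed_totals` object.
#' @param bias A `logger_bias` object covering every logger in `totals`.
#' @return A corrected `directed_totals` object.
#' @export
apply_bias_correction <- function(totals, bias) {
  stopifnot(inherits(totals, "directed_totals"), inherits(bias, "logger_bias"))
  missing_ids <- setdiff(totals$ids, names(bias$bias_pct))
  if (length(missing_ids) > 0L) {
    stop("bias estimate missing for logger(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  b <- bias$bias_pct[totals$ids]
  if (any(b >= 100)) {
    stop("bias of 100% or more would zero or negate durations for: ",
         paste(totals$ids[b >= 100], collapse = ", "), call. = FALSE)
  }
  d <- totals$d * (1 - b / 100)  # recycles by row (rows scaled per logger)
  structure(list(ids = totals$ids, d = d, window = totals$window),
            class = "directed_totals")
}

#' Symmetrise corrected directed totals into an association matrix
#'
#' The two directed totals of a dyad are two measurements of the same
#' encounter time, so they are combined by their arithmetic mean (summing
#' would double-count the shared seconds).
#'
#' @param totals A `directed_totals` object (typically bias-corrected).
#' @return An `association_matrix` object: list with `ids`, the symmetric
#'   nonnegative matrix `O` (zero diagonal) and `window`.
#' @export
symmetrise <- function(totals) {
  stopifnot(inherits(totals, "directed_totals"))
  O <- (totals$d + t(totals$d)) / 2
  association_matrix(O, window = totals$window)
}

#' Construct an association matrix
#'
#' @param O Symmetric nonnegative numeric matrix with identical row/column
#'   names and zero diagonal.
#' @param window Optional window label.
#' @return An `association_matrix` object.
#' @export
association_matrix <- function(O, window = NULL) {
  O <- as.matrix(O)
  stopifnot(nrow(O) == ncol(O), nrow(O) >= 2L)
  if (is.null(rownames(O))) {
    rownames(O) <- colnames(O) <- paste0("N", seq_len(nrow(O)))
  }
  if (!isTRUE(all.equal(O, t(O), check.attributes = FALSE))) {
    stop("association matrix must be symmetric", call. = FALSE)
  }
  if (any(O < 0)) stop("association strengths must be nonnegative", call. = FALSE)
  if (any(diag(O) != 0)) stop("diagonal must be zero", call. = FALSE)
  structure(list(ids = rownames(O), O = O, window = window),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix (", length(x$ids), " individuals",
      if (!is.null(x$window)) paste0(", window ", x$window), ")\n", sep = "")
  cat("total dyadic association:", sum(x$O) / 2, "s;",
      "mean dyadic strength:",
      round(sum(x$O) / (length(x$ids) * (length(x$ids) - 1)), 1), "s\n")
  invisible(x)
}

# Accept either an association_matrix or a plain symmetric matrix.
assoc_mat <- function(M) {
  if (inherits(M, "association_matrix")) return(M$O)
  if (is.matrix(M)) return(association_matrix(M)$O)
  stop("expected an association_matrix or a symmetric matrix", call. = FALSE)
}
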