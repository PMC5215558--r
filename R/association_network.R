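#' Weighted degree centrality
#'
#' The sum of the strength of an individual's associations: the row sum of
#' the association matrix over all partners.
#'
#' @param M An `association_matrix` (or plain symmetric matrix).
#' @param i Calf ID, or `NULL` for all calves.
#' @return Named numeric vector of seconds (or a single value when `i` is
#'   given).
#' @export
weighted_degree <- function(M, i = NULL) {
  O <- assoc_mat(M)
  deg <- rowSums(O)
  if (is.null(i)) return(deg)
  if (!i %in% rownames(O)) stop("unknown id: ", i, call. = FALSE)
  deg[[i]]
}

#' Eigenvector centrality of a weighted association network
#'
#' Leading-eigenvector scores of the symmetric nonnegative association
#' matrix, sign-fixed nonnegative and scaled to unit Euclidean norm. On the
#' dense ("completely saturated") networks produced by proximity loggers
#' this is nearly collinear with weighted degree and serves mainly as a
#' redundancy check. If the network is disconnected a warning is raised and
#' scores are computed per connected component (each component's block
#' scaled by its own leading eigenvector, the whole vector then renormed).
#'
#' @param M An `association_matrix` (or plain symmetric matrix).
#' @return Named nonnegative numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(M) {
  O <- assoc_mat(M)
  comp <- connected_components(O)
  scores <- numeric(nrow(O))
  names(scores) <- rownames(O)
  if (max(comp) > 1L) {
    warning("network is disconnected; eigenvector centrality computed per component")
  }
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(idx) == 1L) {
      scores[idx] <- 0
      next
    }
    e <- eigen(O[idx, idx, drop = FALSE], symmetric = TRUE)
    v <- e$vectors[, 1L]
    # Perron vector of a nonnegative matrix: fix the sign to nonnegative
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    scores[idx] <- v
  }
  n2 <- sqrt(sum(scores^2))
  if (n2 > 0) scores <- scores / n2
  scores
}

connected_components <- function(O) {
  n <- nrow(O)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier) > 0L) {
      nb <- which(colSums(O[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- k
      frontier <- nb
    }
  }
  comp
}

#' Coefficient of variation in association strength
#'
#' 100 x sample SD / mean of one calf's dyadic strengths, a per-individual
#' measure of how heterogeneous its associations are. Optionally excludes
#' one partner (e.g. the ex-penmate) so treatment comparisons can be re-run
#' independent of the pen-rearing bond.
#'
#' @param M An `association_matrix` (or plain symmetric matrix).
#' @param i Calf ID.
#' @param exclude Optional partner ID to omit from `i`'s strengths.
#' @return CV as a percentage. `NA` with a warning if the remaining
#'   strengths have zero mean.
#' @export
cv_strength <- function(M, i, exclude = NULL) {
  O <- assoc_mat(M)
  if (!i %in% rownames(O)) stop("unknown id: ", i, call. = FALSE)
  keep <- setdiff(rownames(O), c(i, exclude))
  if (length(keep) < 2L) stop("need at least 2 dyadic strengths", call. = FALSE)
  x <- O[i, keep]
  if (mean(x) <= 0) {
    warning("all-zero association row for ", i, "; CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(x) / mean(x)
}

#' Percentage of association time spent with the ex-penmate
#'
#' @param M An `association_matrix` (or plain symmetric matrix).
#' @param i Calf ID.
#' @param penmate ID of the calf `i` was pair-housed with.
#' @return `100 * O[i, penmate] / weighted_degree(i)`. `NA` with a warning
#'   when `i` has zero weighted degree.
#' @export
pair_time_pct <- function(M, i, penmate) {
  O <- assoc_mat(M)
  if (!i %in% rownames(O)) stop("unknown id: ", i, call. = FALSE)
  if (!penmate %in% rownames(O)) stop("unknown id: ", penmate, call. = FALSE)
  if (identical(i, penmate)) stop("penmate must differ from i", call. = FALSE)
  deg <- sum(O[i, ])
  if (deg <= 0) {
    warning("zero weighted degree for ", i, "; pair time undefined")
    return(NA_real_)
  }
  100 * O[i, penmate] / deg
}

#' Average pair-housed calves to one value per pen
#'
#' The experimental unit in a pair-housing design is the pen: the two
#' calves of a pair contribute the mean of their values, individually
#' housed calves their own value. Calves whose value is `NA` (e.g. removed
#' from study) are dropped; a pen with no remaining calves is dropped.
#'
#' @param values Named numeric vector, one value per calf ID.
#' @param schedule A `housing_schedule` (see [generate_schedule()]).
#' @return A data.frame with one row per pen: `pen_id`, `treatment`,
#'   `block`, `value`.
#' @export
pen_average <- function(values, schedule) {
  stopifnot(inherits(schedule, "housing_schedule"))
  sched <- schedule[match(names(values), schedule$calf_id), ]
  if (anyNA(sched$calf_id)) {
    stop("values contain ids not in schedule: ",
         paste(names(values)[is.na(sched$calf_id)], collapse = ", "),
         call. = FALSE)
  }
  keep <- !is.na(values)
  df <- data.frame(pen_id = sched$pen_id[keep],
                   treatment = sched$treatment[keep],
                   block = sched$block[keep],
                   value = unname(values[keep]),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(value ~ pen_id + treatment + block, data = df, FUN = mean)
  agg[order(agg$pen_id), c("pen_id", "treatment", "block", "value")]
}
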