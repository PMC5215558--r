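#' Add-one permutation p-value
#'
#' The standard Monte-Carlo convention that counts the observed arrangement
#' among the permutations: `p = (n_as_extreme + 1) / (n_perm + 1)`. With
#' 4999 permutations and an observed statistic more extreme than every
#' null draw this gives the attainable floor 0.0002.
#'
#' @param n_as_extreme Number of null statistics at least as extreme as the
#'   observed one.
#' @param n_perm Number of permutations drawn.
#' @return The p-value.
#' @export
permutation_p <- function(n_as_extreme, n_perm) {
  stopifnot(n_as_extreme >= 0, n_as_extreme <= n_perm, n_perm >= 1)
  (n_as_extreme + 1) / (n_perm + 1)
}

#' Mantel test with node-label (QAP) permutations
#'
#' Spearman rank correlation between the off-diagonal strengths of two
#' association matrices over the same individuals, with significance from
#' jointly permuting the rows and columns (node labels) of the second
#' matrix — the quadratic assignment procedure. The test is two-sided on
#' `|rho|`.
#'
#' @param M1,M2 `association_matrix` objects (or symmetric matrices) over
#'   the same ID set.
#' @param n_perm Number of node-label permutations (default 4999).
#' @param seed Optional RNG seed for reproducibility.
#' @param exhaustive If `TRUE`, enumerate all `N!` node permutations
#'   (feasible only for small N) and report the exact permutation p-value
#'   `#\{|rho_perm| >= |rho_obs|\} / N!` (the identity permutation counts).
#' @return A `mantel_qap` object: `rho`, `r_squared`, `p`, `n_perm`.
#' @export
mantel_qap <- function(M1, M2, n_perm = 4999, seed = NULL, exhaustive = FALSE) {
  O1 <- assoc_mat(M1)
  O2 <- assoc_mat(M2)
  if (!setequal(rownames(O1), rownames(O2))) {
    stop("matrices must be over the same id set", call. = FALSE)
  }
  O2 <- O2[rownames(O1), rownames(O1)]
  n <- nrow(O1)
  ut <- upper.tri(O1)
  rx <- rank(O1[ut])
  rho <- function(O2p) stats::cor(rx, rank(O2p[ut]))
  rho_obs <- rho(O2)

  if (exhaustive) {
    perms <- all_permutations(n)
    null_rho <- vapply(perms, function(p) rho(O2[p, p]), numeric(1))
    p <- mean(abs(null_rho) >= abs(rho_obs) - 1e-12)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_rho <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      rho(O2[p, p])
    }, numeric(1))
    p <- permutation_p(sum(abs(null_rho) >= abs(rho_obs) - 1e-12), n_perm)
  }
  structure(list(rho = rho_obs, r_squared = rho_obs^2, p = p, n_perm = n_perm),
            class = "mantel_qap")
}

#' @export
print.mantel_qap <- function(x, ...) {
  cat("Mantel/QAP node-label permutation test\n")
  cat(sprintf("  Spearman rho = %.3f (R^2 = %.3f), p = %.4g (%d permutations)\n",
              x$rho, x$r_squared, x$p, x$n_perm))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' Expected association matrix under uniform mixing
#'
#' Spreads the observed total association time evenly over all ordered
#' dyads: every off-diagonal entry becomes the mean off-diagonal strength,
#' so total mass is conserved.
#'
#' @param M An `association_matrix` (or symmetric matrix).
#' @return An `association_matrix` of expected strengths.
#' @export
expected_uniform <- function(M) {
  O <- assoc_mat(M)
  n <- nrow(O)
  e <- sum(O) / (n * (n - 1))
  E <- matrix(e, n, n, dimnames = dimnames(O))
  diag(E) <- 0
  w <- if (inherits(M, "association_matrix")) M$window else NULL
  association_matrix(E, window = w)
}

#' Social differentiation statistic
#'
#' Group-level heterogeneity of association: the squared deviation of each
#' dyad's observed strength from its uniform-mixing expectation, summed
#' over ordered dyads and divided by the number of ordered dyads,
#' \deqn{S = \sum_i \sum_{j \ne i} (O_{ij} - E_{ij})^2 / (N(N-1)).}
#' S is zero iff all dyads are equal and scales with the square of total
#' association time.
#'
#' @param M An `association_matrix` (or symmetric matrix).
#' @return The statistic S (seconds squared).
#' @export
differentiation <- function(M) {
  O <- assoc_mat(M)
  n <- nrow(O)
  E <- expected_uniform(M)$O
  sum((O - E)^2) / (n * (n - 1))
}

#' Permutation null test for social differentiation
#'
#' Compares the observed differentiation statistic with null networks in
#' which the group's total association time is redistributed uniformly at
#' random over the unordered dyads (a multinomial draw at one-second
#' resolution, mirrored to a symmetric matrix) — the direct
#' operationalisation of "all individuals associate uniformly". Note the
#' null generator is a modelling choice: any mechanism that scatters
#' integer seconds exchangeably over dyads would serve.
#'
#' @param M An `association_matrix` (or symmetric matrix) with positive
#'   total mass.
#' @param n_perm Number of null networks (default 4999).
#' @param seed Optional RNG seed.
#' @return A `differentiation_test` object: `S_obs`, `null_median`,
#'   `null_q95`, `p`, `n_perm`, `N`.
#' @export
differentiation_null_test <- function(M, n_perm = 4999, seed = NULL) {
  O <- assoc_mat(M)
  n <- nrow(O)
  K <- n * (n - 1) / 2
  total <- round(sum(O[upper.tri(O)]))
  if (total <= 0) stop("zero total association mass", call. = FALSE)
  S_obs <- differentiation(M)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(n_perm, total, rep(1 / K, K))
  # S of a mirrored multinomial matrix reduces to a sum over unordered dyads
  e <- total / K
  null_S <- 2 * colSums((draws - e)^2) / (n * (n - 1))
  p <- permutation_p(sum(null_S >= S_obs), n_perm)
  structure(list(S_obs = S_obs,
                 null_median = stats::median(null_S),
                 null_q95 = stats::quantile(null_S, 0.95, names = FALSE),
                 p = p, n_perm = n_perm, N = n),
            class = "differentiation_test")
}

#' @export
print.differentiation_test <- function(x, ...) {
  cat("Social differentiation permutation test (N =", x$N, ")\n")
  cat(sprintf("  S observed = %.4g; null median = %.4g; null 95%% quantile = %.4g\n",
              x$S_obs, x$null_median, x$null_q95))
  cat(sprintf("  p = %.4g (%d null networks)\n", x$p, x$n_perm))
  invisible(x)
}

#' One-way ANOVA with permutation p-value and bootstrap CIs
#'
#' The observed one-way F statistic is referred to a null distribution
#' built by permuting group labels; per-group confidence intervals for the
#' means come from a nonparametric percentile bootstrap within groups.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param n_resamples Number of label permutations and of bootstrap draws
#'   (default 5000).
#' @param seed Optional RNG seed.
#' @param conf Confidence level for the bootstrap CIs (default 0.95).
#' @param exhaustive If `TRUE` (two groups only), enumerate all distinct
#'   label assignments and report the exact permutation p-value.
#' @return A `bootstrap_anova` object: `F`, `df`, `p`, `group_means`,
#'   `ci` (matrix with `lower`/`upper` per group), `n_resamples`.
#' @export
bootstrap_anova <- function(groups, n_resamples = 5000, seed = NULL,
                            conf = 0.95, exhaustive = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- nlevels(g)
  n <- length(y)
  if (stats::var(y) == 0) {
    ci <- cbind(lower = vapply(groups, mean, 0), upper = vapply(groups, mean, 0))
    return(structure(list(F = 0, df = c(k - 1L, n - k), p = 1,
                          group_means = vapply(groups, mean, 0), ci = ci,
                          n_resamples = 0L),
                     class = "bootstrap_anova"))
  }
  F_obs <- fstat_oneway(y, g)

  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    if (k != 2L) stop("exhaustive enumeration implemented for 2 groups", call. = FALSE)
    n1 <- lengths(groups)[1L]
    idx <- utils::combn(n, n1)
    null_F <- apply(idx, 2, function(sel) {
      lab <- factor(ifelse(seq_len(n) %in% sel, levels(g)[1], levels(g)[2]),
                    levels = levels(g))
      fstat_oneway(y, lab)
    })
    p <- mean(null_F >= F_obs - 1e-12)
    n_used <- ncol(idx)
  } else {
    null_F <- vapply(seq_len(n_resamples), function(i) {
      fstat_oneway(y, g[sample.int(n)])
    }, numeric(1))
    p <- permutation_p(sum(null_F >= F_obs - 1e-12), n_resamples)
    n_used <- n_resamples
  }

  alpha <- (1 - conf) / 2
  B <- max(n_resamples, 1000L)
  ci <- t(vapply(groups, function(x) {
    bm <- rowMeans(matrix(sample(x, length(x) * B, replace = TRUE), B))
    stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")

  structure(list(F = F_obs, df = c(k - 1L, n - k), p = p,
                 group_means = vapply(groups, mean, 0), ci = ci,
                 n_resamples = n_used),
            class = "bootstrap_anova")
}

fstat_oneway <- function(y, g) {
  n <- length(y)
  k <- nlevels(g)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tabulate(g, k)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[as.integer(g)])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @export
print.bootstrap_anova <- function(x, ...) {
  cat(sprintf("Permutation one-way ANOVA: F(%d,%d) = %.3f, p = %.4g (%d resamples)\n",
              x$df[1], x$df[2], x$F, x$p, x$n_resamples))
  tab <- cbind(mean = x$group_means, x$ci)
  print(round(tab, 3))
  invisible(x)
}
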