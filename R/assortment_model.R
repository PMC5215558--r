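#' Days of prior full social contact between two calves
#'
#' Familiarity for a dyad is the number of days the two calves had been in
#' full social contact before the first day of barn grouping, which is
#' taken to be the day the last block enters the barn (observation of the
#' full group can only start then). Contact accrues from whichever event
#' first put the pair together: pen pairing (penmates), the within-block
#' pen merge, or shared residence in the barn as blocks accumulate.
#' Cross-block dyads involving the last block have zero familiarity.
#'
#' @param schedule A `housing_schedule`.
#' @param a,b Calf IDs (`a != b`).
#' @return Integer days (>= 0), symmetric in `a` and `b`.
#' @export
familiarity_days <- function(schedule, a, b) {
  stopifnot(inherits(schedule, "housing_schedule"))
  ids <- schedule$calf_id
  if (!a %in% ids) stop("unknown id: ", a, call. = FALSE)
  if (!b %in% ids) stop("unknown id: ", b, call. = FALSE)
  if (identical(a, b)) stop("a and b must differ", call. = FALSE)
  fam <- familiarity_matrix(schedule)
  fam[a, b]
}

#' Pairwise familiarity matrix for a housing schedule
#'
#' @param schedule A `housing_schedule`.
#' @return Symmetric integer matrix of familiarity days, zero diagonal.
#' @export
familiarity_matrix <- function(schedule) {
  stopifnot(inherits(schedule, "housing_schedule"))
  sp <- attr(schedule, "block_spacing_days")
  merge_day <- attr(schedule, "pen_merge_day")
  entry_day <- attr(schedule, "barn_entry_day")
  offset <- (schedule$block - 1L) * sp         # calendar offset of each block
  grouping_cal <- max(offset) + entry_day       # day the last block enters

  n <- nrow(schedule)
  ids <- schedule$calf_id
  same_block <- outer(schedule$block, schedule$block, "==")
  # earliest shared-contact calendar day for each dyad
  entry_cal <- offset + entry_day
  start <- outer(entry_cal, entry_cal, pmax)            # shared barn
  start[same_block] <- (offset + merge_day)[row(start)[same_block]]  # pen merge
  is_pen <- outer(seq_len(n), seq_len(n), function(i, j) {
    !is.na(schedule$penmate[i]) & schedule$penmate[i] == ids[j]
  })
  start[is_pen] <- (offset + schedule$pairing_age)[row(start)[is_pen]]

  fam <- pmax(grouping_cal - start, 0)
  diag(fam) <- 0
  dimnames(fam) <- list(ids, ids)
  storage.mode(fam) <- "integer"
  fam
}

#' Build the dyadic regression table
#'
#' One row per ordered dyad (each unordered dyad appears twice with roles
#' swapped, the standard layout for multi-membership dyadic models), with
#' log-transformed association strength, familiarity in days, and an
#' indicator that is 0 for same-treatment and 1 for different-treatment
#' dyads. Zero strengths — impossible in a fully saturated network but
#' possible in sparse synthetic data — are handled as `log(strength + 1)`
#' and counted in the `"n_zero_strength"` attribute.
#'
#' @param M An `association_matrix` (or symmetric matrix).
#' @param schedule A `housing_schedule` covering all IDs of `M`.
#' @return A data.frame with columns `calf_a`, `calf_b`, `strength`,
#'   `log_strength`, `familiarity_days`, `different_treatment`.
#' @export
build_dyad_table <- function(M, schedule) {
  O <- assoc_mat(M)
  ids <- rownames(O)
  missing_ids <- setdiff(ids, schedule$calf_id)
  if (length(missing_ids) > 0L) {
    stop("ids not in schedule: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  fam <- familiarity_matrix(schedule)[ids, ids]
  trt <- schedule$treatment[match(ids, schedule$calf_id)]
  diff_trt <- outer(trt, trt, "!=") * 1L

  pair <- which(row(O) != col(O), arr.ind = TRUE)  # all ordered dyads
  strength <- O[pair]
  n_zero <- sum(strength <= 0)
  log_strength <- ifelse(strength > 0, log(strength), log(strength + 1))
  tab <- data.frame(calf_a = ids[pair[, 1L]], calf_b = ids[pair[, 2L]],
                    strength = strength, log_strength = log_strength,
                    familiarity_days = fam[pair],
                    different_treatment = diff_trt[pair],
                    stringsAsFactors = FALSE)
  attr(tab, "n_zero_strength") <- n_zero
  if (n_zero > 0L) {
    warning(n_zero, " zero-strength dyad rows; log(strength + 1) used for these")
  }
  tab
}

#' Bayesian dyadic regression of association strength
#'
#' Fits the Gaussian model
#' \deqn{\log O_{ab} = \mu + \beta' x_{ab} + u_a + u_b + \varepsilon_{ab}}
#' where the fixed covariates are any subset of familiarity (days) and the
#' different-treatment indicator, and the calf effects `u` form a single
#' multi-membership random term: both members of each dyad draw from one
#' pool of individual effects, which accounts for the non-independence of
#' dyads sharing a calf. Estimation is by Gibbs sampling with conjugate
#' weakly-informative priors: Normal(0, `beta_sd`^2) on fixed effects and
#' inverse-gamma(`ig_shape`, `ig_rate`) on both variance components.
#'
#' Reported per fixed effect: posterior mean, 95\% credible interval, and
#' `pMCMC` = twice the smaller posterior tail mass around zero. Model fit
#' is summarised by the deviance information criterion
#' (DIC = mean deviance + effective number of parameters), lower is better.
#'
#' @param table Dyad table from [build_dyad_table()].
#' @param fixed Character subset of
#'   `c("familiarity", "different_treatment")`; empty for intercept-only.
#' @param n_iter,burn_in,thin MCMC controls (kept samples =
#'   `(n_iter - burn_in) / thin`).
#' @param seed Optional RNG seed; the full chain is reproducible from it.
#' @param priors List with `beta_sd` (default 10), `ig_shape`, `ig_rate`
#'   (default 0.001 each).
#' @param ess_warn Warn if any fixed effect's effective sample size falls
#'   below this (default 100).
#' @return A `dyadic_mcmc` object with `summary()`, `coef()`, `print()`
#'   and [DIC()] methods. Components include `samples` (kept draws),
#'   `summary` (fixed-effect table), `dic`, `vcv` (posterior mean variance
#'   components) and the MCMC controls.
#' @export
fit_dyadic_model <- function(table, fixed = c("familiarity", "different_treatment"),
                             n_iter = 6000, burn_in = 1000, thin = 5,
                             seed = NULL, priors = list(), ess_warn = 100) {
  stopifnot(nrow(table) > 0L, n_iter > burn_in, thin >= 1)
  if (length(fixed) > 0L) {
    fixed <- match.arg(fixed, c("familiarity", "different_treatment"),
                       several.ok = TRUE)
  } else {
    fixed <- character(0)
  }
  pr <- utils::modifyList(list(beta_sd = 10, ig_shape = 0.001, ig_rate = 0.001),
                          priors)
  if (!is.null(seed)) set.seed(seed)

  y <- table$log_strength
  N <- length(y)
  X <- cbind(`(Intercept)` = rep(1, N))
  if ("familiarity" %in% fixed) X <- cbind(X, familiarity = table$familiarity_days)
  if ("different_treatment" %in% fixed) {
    X <- cbind(X, different_treatment = table$different_treatment)
  }
  p <- ncol(X)
  calves <- sort(unique(c(table$calf_a, table$calf_b)))
  nc <- length(calves)
  ia <- match(table$calf_a, calves)
  ib <- match(table$calf_b, calves)
  Z <- matrix(0, N, nc)
  Z[cbind(seq_len(N), ia)] <- 1
  Z[cbind(seq_len(N), ib)] <- Z[cbind(seq_len(N), ib)] + 1  # guards a==b (never happens)
  XtX <- crossprod(X)
  ZtZ <- crossprod(Z)

  beta <- stats::coef(stats::lm.fit(X, y))
  u <- rep(0, nc)
  s2e <- max(stats::var(y), 1e-6)
  s2u <- s2e / 2

  n_keep <- (n_iter - burn_in) %/% thin
  beta_s <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  s2u_s <- s2e_s <- dev_s <- numeric(n_keep)
  u_mean <- rep(0, nc)
  prior_prec <- diag(1 / pr$beta_sd^2, p)
  keep <- 0L

  for (it in seq_len(n_iter)) {
    # fixed effects
    r_u <- y - Z %*% u
    Vb_inv <- XtX / s2e + prior_prec
    Rb <- chol(Vb_inv)
    mb <- backsolve(Rb, forwardsolve(t(Rb), crossprod(X, r_u) / s2e))
    beta <- drop(mb + backsolve(Rb, stats::rnorm(p)))

    # multi-membership calf effects
    r_b <- y - X %*% beta
    Vu_inv <- ZtZ / s2e
    diag(Vu_inv) <- diag(Vu_inv) + 1 / s2u
    Ru <- chol(Vu_inv)
    mu_u <- backsolve(Ru, forwardsolve(t(Ru), crossprod(Z, r_b) / s2e))
    u <- drop(mu_u + backsolve(Ru, stats::rnorm(nc)))

    # variance components (conjugate inverse-gamma updates)
    s2u <- 1 / stats::rgamma(1, pr$ig_shape + nc / 2, pr$ig_rate + sum(u^2) / 2)
    e <- drop(y - X %*% beta - Z %*% u)
    s2e <- 1 / stats::rgamma(1, pr$ig_shape + N / 2, pr$ig_rate + sum(e^2) / 2)

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      keep <- keep + 1L
      beta_s[keep, ] <- beta
      s2u_s[keep] <- s2u
      s2e_s[keep] <- s2e
      dev_s[keep] <- N * log(2 * pi * s2e) + sum(e^2) / s2e
      u_mean <- u_mean + (u - u_mean) / keep
    }
  }

  # DIC from the conditional deviance (focus on calf-level effects)
  beta_hat <- colMeans(beta_s)
  s2e_hat <- mean(s2e_s)
  e_hat <- drop(y - X %*% beta_hat - Z %*% u_mean)
  d_hat <- N * log(2 * pi * s2e_hat) + sum(e_hat^2) / s2e_hat
  d_bar <- mean(dev_s)
  dic <- 2 * d_bar - d_hat

  q <- apply(beta_s, 2, stats::quantile, probs = c(0.025, 0.975))
  pmcmc <- apply(beta_s, 2, function(b) {
    max(2 * min(mean(b > 0), mean(b < 0)), 2 / length(b))
  })
  summ <- data.frame(post_mean = beta_hat, lower_95 = q[1, ], upper_95 = q[2, ],
                     pMCMC = pmcmc, ess = apply(beta_s, 2, ess_acf))
  if (any(summ$ess < ess_warn)) {
    warning("low effective sample size for: ",
            paste(rownames(summ)[summ$ess < ess_warn], collapse = ", "),
            " (min ", round(min(summ$ess)), ")")
  }

  structure(list(fixed = fixed, summary = summ, dic = dic,
                 samples = list(beta = beta_s, s2_calf = s2u_s, s2_resid = s2e_s),
                 vcv = c(calf = mean(s2u_s), residual = s2e_hat),
                 u_mean = stats::setNames(u_mean, calves),
                 n_obs = N, n_calves = nc,
                 mcmc = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                             seed = seed)),
            class = "dyadic_mcmc")
}

# ESS from the initial-positive-sequence autocorrelation sum
ess_acf <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos) > 0) ac <- ac[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(ac))
}

#' @export
print.dyadic_mcmc <- function(x, ...) {
  cat("Dyadic multi-membership regression of log association strength\n")
  cat("  fixed effects:",
      if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "(intercept only)",
      "\n")
  cat(sprintf("  %d dyad rows, %d calves; DIC = %.2f\n", x$n_obs, x$n_calves, x$dic))
  print(round(x$summary[, c("post_mean", "lower_95", "upper_95", "pMCMC")], 4))
  invisible(x)
}

#' @export
summary.dyadic_mcmc <- function(object, ...) {
  out <- object$summary
  attr(out, "dic") <- object$dic
  attr(out, "vcv") <- object$vcv
  out
}

#' @export
coef.dyadic_mcmc <- function(object, ...) {
  stats::setNames(object$summary$post_mean, rownames(object$summary))
}

#' Deviance information criterion
#'
#' @param object A fitted model object.
#' @param ... Unused.
#' @return The DIC (lower indicates better fit).
#' @export
DIC <- function(object, ...) UseMethod("DIC")

#' @rdname DIC
#' @export
DIC.dyadic_mcmc <- function(object, ...) object$dic

#' Fit all fixed-effect combinations of the assortment model
#'
#' Convenience wrapper fitting the intercept-only, familiarity-only,
#' treatment-only and familiarity + treatment models on one dyad table.
#'
#' @param table Dyad table from [build_dyad_table()].
#' @param seed Optional base seed; model `k` uses `seed + k`.
#' @param ... Passed to [fit_dyadic_model()].
#' @return Named list of `dyadic_mcmc` fits.
#' @export
fit_assortment_models <- function(table, seed = NULL, ...) {
  combos <- list(intercept_only = character(0),
                 familiarity = "familiarity",
                 treatment = "different_treatment",
                 familiarity_treatment = c("familiarity", "different_treatment"))
  fits <- vector("list", length(combos))
  names(fits) <- names(combos)
  for (k in seq_along(combos)) {
    s <- if (is.null(seed)) NULL else seed + k
    fits[[k]] <- fit_dyadic_model(table, fixed = combos[[k]], seed = s, ...)
  }
  fits
}

#' Select the best model by DIC
#'
#' @param fits List of `dyadic_mcmc` fits of the same dyad table.
#' @return A `dic_comparison` object: `best` (the winning fit), `best_name`,
#'   and `table` (the full DIC ladder with deltas). Exact ties are broken
#'   by list order and reported.
#' @export
compare_dic <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  dics <- vapply(fits, DIC, numeric(1))
  ord <- order(dics)
  tab <- data.frame(model = names(fits)[ord], dic = dics[ord],
                    delta = dics[ord] - min(dics), row.names = NULL)
  tied <- sum(abs(dics - min(dics)) < 1e-9) > 1L
  structure(list(best = fits[[ord[1L]]], best_name = names(fits)[ord[1L]],
                 table = tab, tie = tied),
            class = "dic_comparison")
}

#' @export
print.dic_comparison <- function(x, ...) {
  cat("DIC model comparison (best:", x$best_name,
      if (x$tie) "- tie, first by order" else "", ")\n")
  print(transform(x$table, dic = round(dic, 2), delta = round(delta, 2)))
  invisible(x)
}
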