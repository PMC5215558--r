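#' Specific growth rate
#'
#' Percentage body-weight growth per day between two weighings,
#' \deqn{SGR = 100 (\ln W_2 - \ln W_1) / t,} negative when weight is lost.
#' Time-weighted averages of SGR over consecutive intervals chain exactly
#' because logarithms add.
#'
#' @param W1,W2 Weights (kg) at sample points one and two; must be > 0.
#' @param t Days between the sample points; must be > 0.
#' @return SGR in percent per day (vectorised).
#' @export
specific_growth_rate <- function(W1, W2, t) {
  if (any(W1 <= 0) || any(W2 <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  100 * (log(W2) - log(W1)) / t
}

#' Overall respiratory score
#'
#' Sum of the four daily respiratory health components (cough, nasal
#' discharge, eye, ear) of the calf health-scoring scheme.
#'
#' @param cough,nasal,eye,ear Nonnegative integer scores (vectorised).
#' @return Integer sum.
#' @export
respiratory_score <- function(cough, nasal, eye, ear) {
  if (any(c(cough, nasal, eye, ear) < 0)) {
    stop("scores must be nonnegative", call. = FALSE)
  }
  cough + nasal + eye + ear
}

#' Percentage of days with impaired health
#'
#' @param daily_scores Numeric vector of daily scores (one per observed
#'   day).
#' @param rule Either `"faecal"` (impaired when score > 1) or
#'   `"respiratory"` (impaired when score > 0).
#' @return Percentage of observed days flagged impaired.
#' @export
impaired_days_pct <- function(daily_scores, rule = c("faecal", "respiratory")) {
  rule <- match.arg(rule)
  if (length(daily_scores) == 0L) stop("empty score series", call. = FALSE)
  thr <- if (rule == "faecal") 1 else 0
  100 * mean(daily_scores > thr)
}

#' Pre-weaning, weaning and post-weaning period means
#'
#' Weaning-window summaries: arithmetic means over study days 45-47
#' (pre-weaning), 48-50 (weaning) and 51-53 (post-weaning).
#'
#' @param daily_values Numeric vector named by study day (must cover days
#'   45-53), or a data.frame with columns `day` and `value`.
#' @return Named vector `c(pre, weaning, post)`.
#' @export
weaning_period_means <- function(daily_values) {
  if (is.data.frame(daily_values)) {
    daily_values <- stats::setNames(daily_values$value, daily_values$day)
  }
  days <- as.integer(names(daily_values))
  need <- 45:53
  miss <- setdiff(need, days)
  if (length(miss) > 0L) stop("missing day ", miss[1L], call. = FALSE)
  v <- daily_values[match(need, days)]
  c(pre = mean(v[1:3]), weaning = mean(v[4:6]), post = mean(v[7:9]))
}

#' Arcsine square-root transformation
#'
#' Variance-stabilising transform applied to percentages and proportions
#' before parametric tests.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return `asin(sqrt(p))` in radians.
#' @export
arcsine_sqrt <- function(p) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Two-stage sharpened FDR q-values
#'
#' Adjusted p-values for the two-stage sharpened false-discovery-rate
#' procedure (Benjamini, Krieger & Yekutieli 2006): stage one runs a
#' linear step-up test at level `q/(1+q)` to estimate the number of true
#' nulls `m0`, stage two re-runs it at the sharpened level `q m / m0`.
#' The q-value of a hypothesis is the smallest nominal FDR level at which
#' the two-stage procedure rejects it (found by bisection; the procedure's
#' rejection sets are nested in `q`).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order, in `[0, 1]`.
#' @export
two_stage_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals)) {
    # undefined tests (e.g. all-tied data) pass through as NA
    out <- rep(NA_real_, length(pvals))
    ok <- !is.na(pvals)
    out[ok] <- two_stage_fdr(pvals[ok])
    return(out)
  }
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  sp <- pvals[o]
  # rejection count of the two-stage procedure at nominal level q
  n_reject <- function(q) {
    qp <- q / (1 + q)
    r1 <- bh_n_reject(sp, qp)
    if (r1 == 0L) return(0L)
    if (r1 == m) return(m)
    bh_n_reject(sp, qp * m / (m - r1))
  }
  # rejections are a down-set of sorted p-values and nested in q, so the
  # q-value of sp[i] is the smallest q with n_reject(q) >= i
  qv <- numeric(m)
  for (i in seq_len(m)) {
    if (i > 1L && sp[i] == sp[i - 1L]) {
      qv[i] <- qv[i - 1L]
      next
    }
    lo <- 0; hi <- 1
    if (n_reject(1) < i) {
      qv[i] <- 1
      next
    }
    for (iter in 1:50) {
      mid <- (lo + hi) / 2
      if (n_reject(mid) >= i) hi <- mid else lo <- mid
    }
    qv[i] <- hi
  }
  qv <- cummax(qv)  # enforce monotonicity against bisection round-off
  out <- numeric(m)
  out[o] <- pmin(qv, 1)
  out
}

# number of rejections of the BH linear step-up test at level alpha
bh_n_reject <- function(sorted_p, alpha) {
  m <- length(sorted_p)
  ok <- which(sorted_p <= seq_len(m) * alpha / m)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Pool treatment-level means into one overall mean, weighting by pens
#'
#' Treatment summaries in a pair-housing design are means over pens (the
#' experimental unit); the overall mean is their pen-count-weighted
#' combination.
#'
#' @param means Numeric vector of treatment-level means.
#' @param n_pens Integer vector of pen counts per treatment.
#' @return The pooled mean.
#' @export
pool_treatment_means <- function(means, n_pens) {
  stopifnot(length(means) == length(n_pens), all(n_pens > 0))
  sum(means * n_pens) / sum(n_pens)
}

#' Run the pen-rearing production and weaning-stress battery
#'
#' Pen-averages all calf-level quantities (the pen is the experimental
#' unit), drops any calf removed from the study (all its data omitted),
#' then runs the standard battery: Friedman's ANOVA of pen vocalisation
#' rates across the three weaning periods, Kruskal-Wallis tests across
#' treatments within each period, pairwise Mann-Whitney contrasts with
#' two-stage sharpened FDR q-values, paired Wilcoxon tests between
#' consecutive periods, and one-way ANOVAs for specific growth rate
#' (whole trial and over weaning) and concentrate intake (whole trial and
#' per period). Health impairment percentages are summarised after the
#' arcsine square-root transform, with an optional MANOVA (Pillai's trace)
#' across treatments.
#'
#' Classical test statistics are delegated to the standard routines
#' (`friedman.test`, `kruskal.test`, `wilcox.test`, `aov`, `manova`) with
#' their default tie handling.
#'
#' @param records A `calf_rearing_records` object (see
#'   [generate_rearing_data()]); must carry its `schedule`.
#' @param manova Run the optional health-score MANOVA (default `FALSE`).
#' @return A `weaning_report` list with components `units`, `vocal`,
#'   `growth`, `intake`, `health`.
#' @export
run_weaning_analysis <- function(records, manova = FALSE) {
  stopifnot(inherits(records, "calf_rearing_records"))
  schedule <- records$schedule
  calves <- records$calves
  removed <- calves$calf_id[!is.na(calves$removed_day)]
  calves <- calves[!calves$calf_id %in% removed, , drop = FALSE]
  live_pens <- unique(calves$pen_id)
  pen_trt <- calves$treatment[match(live_pens, calves$pen_id)]

  ## --- vocalisations: per-pen period means ------------------------------
  voc <- records$vocal[records$vocal$pen_id %in% live_pens, , drop = FALSE]
  if (nrow(voc) == 0L) stop("no vocalisation data for live pens", call. = FALSE)
  pm <- t(vapply(live_pens, function(p) {
    d <- voc[voc$pen_id == p, ]
    weaning_period_means(stats::setNames(d$calls_per_h, d$day))
  }, numeric(3)))
  rownames(pm) <- live_pens

  long <- data.frame(pen = factor(rep(rownames(pm), 3)),
                     period = factor(rep(colnames(pm), each = nrow(pm)),
                                     levels = c("pre", "weaning", "post")),
                     treatment = factor(rep(pen_trt, 3)),
                     value = as.vector(pm))
  fried <- stats::friedman.test(value ~ period | pen, data = long)
  kw <- lapply(stats::setNames(levels(long$period), levels(long$period)),
               function(per) {
                 d <- long[long$period == per, ]
                 stats::kruskal.test(value ~ treatment, data = d)
               })
  trts <- sort(unique(pen_trt))
  pairs <- utils::combn(trts, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(levels(long$period), function(per) {
    d <- long[long$period == per, ]
    do.call(rbind, lapply(pairs, function(tp) {
      x <- d$value[d$treatment == tp[1]]
      y <- d$value[d$treatment == tp[2]]
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      data.frame(period = per, group1 = tp[1], group2 = tp[2],
                 U = unname(wt$statistic), p = wt$p.value)
    }))
  }))
  pw$q <- two_stage_fdr(pw$p)
  contrast <- function(a, b) {
    suppressWarnings(stats::wilcox.test(pm[, a], pm[, b], paired = TRUE,
                                        exact = FALSE))$p.value
  }
  period_contrasts <- c(pre_vs_weaning = contrast("pre", "weaning"),
                        weaning_vs_post = contrast("weaning", "post"))
  period_means <- colMeans(pm)
  treatment_period_means <- stats::aggregate(value ~ treatment + period,
                                             data = long, FUN = mean)

  ## --- growth -----------------------------------------------------------
  entry_day <- records$entry_day
  sgr_whole <- specific_growth_rate(calves$weight_entry, calves$weight_d55,
                                    55 - entry_day)
  sgr_wean <- specific_growth_rate(calves$weight_d47, calves$weight_d55, 8)
  pa_whole <- pen_average(stats::setNames(sgr_whole, calves$calf_id), schedule)
  pa_wean <- pen_average(stats::setNames(sgr_wean, calves$calf_id), schedule)
  growth <- list(
    mean_sgr_whole = mean(pa_whole$value),
    anova_whole = summary(stats::aov(value ~ treatment, data = pa_whole))[[1]],
    anova_weaning = summary(stats::aov(value ~ treatment, data = pa_wean))[[1]],
    pen_means = pa_whole)

  ## --- concentrate intake ----------------------------------------------
  intk <- records$intake[records$intake$pen_id %in% live_pens, , drop = FALSE]
  whole <- stats::aggregate(intake_g ~ pen_id, data = intk, FUN = mean)
  whole$treatment <- factor(pen_trt[match(whole$pen_id, live_pens)])
  ilong <- do.call(rbind, lapply(live_pens, function(p) {
    d <- intk[intk$pen_id == p & intk$day %in% 45:53, ]
    m <- weaning_period_means(stats::setNames(d$intake_g, d$day))
    data.frame(pen = p, treatment = pen_trt[match(p, live_pens)],
               period = names(m), value = unname(m))
  }))
  ilong$period <- factor(ilong$period, levels = c("pre", "weaning", "post"))
  ilong$treatment <- factor(ilong$treatment)
  intake <- list(
    mean_whole = mean(whole$intake_g),
    anova_whole = summary(stats::aov(intake_g ~ treatment, data = whole))[[1]],
    anova_period = summary(stats::aov(value ~ treatment * period, data = ilong))[[1]])

  ## --- health -----------------------------------------------------------
  hl <- records$health[!records$health$calf_id %in% removed, , drop = FALSE]
  resp <- respiratory_score(hl$cough, hl$nasal, hl$eye, hl$ear)
  fae_pct <- tapply(hl$faecal, hl$calf_id, impaired_days_pct, rule = "faecal")
  resp_pct <- tapply(resp, hl$calf_id, impaired_days_pct, rule = "respiratory")
  pa_fae <- pen_average(fae_pct[calves$calf_id], schedule)
  pa_resp <- pen_average(resp_pct[calves$calf_id], schedule)
  health <- list(mean_faecal_pct = mean(pa_fae$value),
                 mean_resp_pct = mean(pa_resp$value),
                 pen_faecal = pa_fae, pen_resp = pa_resp)
  if (manova) {
    Y <- cbind(arcsine_sqrt(pa_fae$value / 100), arcsine_sqrt(pa_resp$value / 100))
    health$manova <- summary(stats::manova(Y ~ factor(pa_fae$treatment)),
                             test = "Pillai")
  }

  structure(list(
    units = data.frame(pen_id = live_pens, treatment = pen_trt),
    n_removed = length(removed),
    vocal = list(pen_period_means = pm, period_means = period_means,
                 treatment_period_means = treatment_period_means,
                 friedman = fried, kruskal_by_period = kw,
                 pairwise = pw, period_contrasts = period_contrasts),
    growth = growth, intake = intake, health = health),
    class = "weaning_report")
}

#' @export
print.weaning_report <- function(x, ...) {
  cat("Pen-rearing / weaning-stress report —", nrow(x$units),
      "pen units (", x$n_removed, "calf removed )\n")
  cat("\nVocalisations (calls/h), period means across pens:\n")
  print(round(x$vocal$period_means, 2))
  cat(sprintf("Friedman across periods: chi^2(%d) = %.2f, p = %.3g\n",
              x$vocal$friedman$parameter, x$vocal$friedman$statistic,
              x$vocal$friedman$p.value))
  for (per in names(x$vocal$kruskal_by_period)) {
    k <- x$vocal$kruskal_by_period[[per]]
    cat(sprintf("Kruskal-Wallis (%s): H(%d) = %.2f, p = %.3g\n",
                per, k$parameter, k$statistic, k$p.value))
  }
  cat("\nPairwise treatment contrasts (Mann-Whitney, two-stage FDR q):\n")
  print(transform(x$vocal$pairwise, p = signif(p, 3), q = signif(q, 3)))
  cat(sprintf("\nMean SGR (whole trial): %.3f %%/day; mean intake: %.1f g/day\n",
              x$growth$mean_sgr_whole, x$intake$mean_whole))
  cat(sprintf("Impaired days: faecal %.2f %%, respiratory %.2f %%\n",
              x$health$mean_faecal_pct, x$health$mean_resp_pct))
  invisible(x)
}
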