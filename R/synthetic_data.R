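#' Simulation configuration for the staggered pair-housing experiment
#'
#' Returns the default configuration of the synthetic cohort: 40 calves in
#' 8 blocks of 5 (one individually housed, two pair-housed from day 5, two
#' pair-housed from day 28), blocks entering the trial 3 days apart,
#' within-block pen merge on day 55 and barn entry on day 60, so that the
#' last block reaches the barn on calendar day 81 and dyadic familiarity
#' spans 0-76 days. Contact streams follow a dyadic rate model in which a
#' dyad's encounter rate grows log-linearly with familiarity; rearing
#' records are drawn around the treatment-level means of the emulated
#' study.
#'
#' @param ... Named overrides of any default listed below.
#' @return A `sim_config` list.
#' @section Main fields:
#' \describe{
#'   \item{n_blocks, calves_per_block, block_spacing_days}{cohort layout
#'     (8, 5, 3).}
#'   \item{pairing_age_p5, pairing_age_p28, pen_merge_day, barn_entry_day}{
#'     housing timeline in study days (5, 28, 55, 60).}
#'   \item{weeks}{number of 7-day association windows after grouping (4).}
#'   \item{baseline_contact_rate}{encounters per hour per dyad at zero
#'     familiarity (0.2).}
#'   \item{mean_encounter_s, encounter_sdlog}{lognormal encounter-duration
#'     model (mean 120 s, log-SD 1).}
#'   \item{familiarity_effect}{increase in log encounter rate per day of
#'     familiarity (0.02).}
#'   \item{treatment_effect}{increase in log encounter rate for
#'     same-treatment dyads (0; the emulated study found no treatment
#'     assortment).}
#'   \item{logger_bias_sdlog}{log-SD of the per-logger multiplicative
#'     recording bias (0.05).}
#'   \item{spurious_1s_rate}{expected spurious 1-s records per true
#'     directed record (0.02).}
#'   \item{separation_s}{logger separation time; encounters of a dyad
#'     closer than this are merged (120 s).}
#'   \item{entry_weight_mean, entry_weight_sd, sgr_mean, sgr_sd}{growth
#'     model (37.39 kg, 5.55 kg, 1.06 and 0.14 percent per day).}
#'   \item{impaired_faecal_rate, impaired_resp_rate}{daily probability of
#'     an impaired-health day (0.0525, 0.05).}
#'   \item{vocal_mean, vocal_sd}{3 x 3 period-by-treatment matrices of
#'     pen vocalisation rates (calls/h).}
#'   \item{intake_mean_g}{whole-trial mean concentrate intake (448.41
#'     g/day), reached by a linear ramp.}
#'   \item{i_calf_dropout}{remove one individually housed calf on day 12
#'     (`TRUE`, matching the emulated cohort).}
#'   \item{noise}{global noise scale; 0 collapses all pens of a treatment
#'     onto the configured means.}
#' }
#' @export
sim_config <- function(...) {
  trt <- c("I", "P5", "P28")
  per <- c("pre", "weaning", "post")
  vocal_mean <- matrix(c(0.86, 0.10, 0.10,
                         2.76, 0.73, 0.46,
                         109.38, 26.08, 45.42),
                       nrow = 3, byrow = TRUE, dimnames = list(per, trt))
  vocal_sd <- matrix(c(1.72, 0.90, 0.13,
                       1.14, 0.21, 0.16,
                       51.40, 20.16, 26.77),
                     nrow = 3, byrow = TRUE, dimnames = list(per, trt))
  cfg <- list(
    n_blocks = 8L, calves_per_block = 5L, block_spacing_days = 3L,
    pairing_age_p5 = 5L, pairing_age_p28 = 28L,
    pen_merge_day = 55L, barn_entry_day = 60L, entry_day = 5L,
    weeks = 4L,
    baseline_contact_rate = 0.2, mean_encounter_s = 120, encounter_sdlog = 1,
    familiarity_effect = 0.02, treatment_effect = 0,
    logger_bias_sdlog = 0.05, logger_bias_multipliers = NULL,
    spurious_1s_rate = 0.02, separation_s = 120,
    entry_weight_mean = 37.39, entry_weight_sd = 5.55,
    sgr_mean = 1.06, sgr_sd = 0.14,
    impaired_faecal_rate = 0.0525, impaired_resp_rate = 0.05,
    vocal_mean = vocal_mean, vocal_sd = vocal_sd,
    intake_mean_g = 448.41, intake_cv = 0.35,
    i_calf_dropout = TRUE, noise = 1,
    origin = "2013-04-01")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Generate the housing schedule
#'
#' Lays out the cohort on a common calendar: block `b` starts `(b-1) x
#' block_spacing_days` later than block 1, each block holds one
#' individually housed calf and two pairs (paired at day 5 and day 28),
#' blocks merge their pens on study day 55 and enter the barn on study day
#' 60. The schedule is deterministic given the configuration.
#'
#' @param config A `sim_config`.
#' @return A `housing_schedule` data.frame with columns `calf_id`, `block`,
#'   `treatment`, `pen_id`, `penmate`, `pairing_age`, and timeline
#'   attributes `pen_merge_day`, `barn_entry_day`, `block_spacing_days`,
#'   `grouping_day` (calendar day the last block enters the barn).
#' @export
generate_schedule <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$n_blocks
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    idx <- (b - 1L) * 5L + 1:5
    ids <- sprintf("C%02d", idx)
    rows[[b]] <- data.frame(
      calf_id = ids, block = b,
      treatment = c("I", "P5", "P5", "P28", "P28"),
      pen_id = sprintf("B%dP%d", b, c(1L, 2L, 2L, 3L, 3L)),
      penmate = c(NA, ids[3], ids[2], ids[5], ids[4]),
      pairing_age = c(NA, config$pairing_age_p5, config$pairing_age_p5,
                      config$pairing_age_p28, config$pairing_age_p28),
      stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, rows)
  attr(sched, "pen_merge_day") <- config$pen_merge_day
  attr(sched, "barn_entry_day") <- config$barn_entry_day
  attr(sched, "block_spacing_days") <- config$block_spacing_days
  attr(sched, "grouping_day") <- (nb - 1L) * config$block_spacing_days +
    config$barn_entry_day
  class(sched) <- c("housing_schedule", "data.frame")
  sched
}

#' Write / read a housing schedule as CSV
#'
#' The timeline attributes are stored as constant columns so the schedule
#' survives a CSV round trip.
#'
#' @param schedule A `housing_schedule`.
#' @param file Path.
#' @return `file` (write) or the schedule (read).
#' @export
write_schedule <- function(schedule, file) {
  df <- as.data.frame(schedule)
  df$pen_merge_day <- attr(schedule, "pen_merge_day")
  df$barn_entry_day <- attr(schedule, "barn_entry_day")
  df$block_spacing_days <- attr(schedule, "block_spacing_days")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  sched <- df[, c("calf_id", "block", "treatment", "pen_id", "penmate",
                  "pairing_age")]
  attr(sched, "pen_merge_day") <- df$pen_merge_day[1L]
  attr(sched, "barn_entry_day") <- df$barn_entry_day[1L]
  attr(sched, "block_spacing_days") <- df$block_spacing_days[1L]
  attr(sched, "grouping_day") <- (max(df$block) - 1L) * df$block_spacing_days[1L] +
    df$barn_entry_day[1L]
  class(sched) <- c("housing_schedule", "data.frame")
  sched
}

#' Generate a synthetic proximity-logger contact stream
#'
#' Simulates the barn-grouping weeks: each dyad's encounters arrive at rate
#' `baseline_contact_rate * exp(familiarity_effect * familiarity_days +
#' treatment_effect * same_treatment)` per hour, with lognormal durations
#' (heavy-tailed contact bouts, as typical of proximity data). Encounters
#' of a dyad separated by less than the logger separation time are merged.
#' Every encounter is emitted as two directed records whose durations are
#' scaled by each logger's multiplicative recording bias (lognormal across
#' loggers), and spurious 1-second records are injected at the configured
#' rate.
#'
#' @param schedule A `housing_schedule`.
#' @param config A `sim_config`.
#' @param seed RNG seed (required: streams must be reproducible).
#' @return A contact-record data.frame (as from [parse_contact_records()]),
#'   ordered by start time, with attributes `"logger_multipliers"` (the
#'   true per-logger bias multipliers, for validation studies) and
#'   `"windows"` (the weekly window boundaries as POSIXct).
#' @export
generate_contact_stream <- function(schedule, config = sim_config(), seed) {
  stopifnot(inherits(schedule, "housing_schedule"), !missing(seed))
  set.seed(seed)
  ids <- schedule$calf_id
  n <- length(ids)
  fam <- familiarity_matrix(schedule)
  trt <- schedule$treatment
  same_trt <- outer(trt, trt, "==") * 1

  pair <- which(upper.tri(fam), arr.ind = TRUE)
  rate <- config$baseline_contact_rate *
    exp(config$familiarity_effect * fam[pair] +
          config$treatment_effect * same_trt[pair])
  hours <- config$weeks * 7 * 24
  n_enc <- stats::rpois(nrow(pair), rate * hours)

  t0 <- as.POSIXct(paste0(config$origin, " 00:00:00"), tz = "UTC") +
    attr(schedule, "grouping_day") * 86400
  total_s <- hours * 3600

  di <- rep(pair[, 1L], n_enc)
  dj <- rep(pair[, 2L], n_enc)
  start_s <- floor(stats::runif(length(di), 0, total_s))
  meanlog <- log(config$mean_encounter_s) - config$encounter_sdlog^2 / 2
  dur <- pmax(2, round(stats::rlnorm(length(di), meanlog, config$encounter_sdlog)))

  # merge encounters of the same dyad closer than the separation time
  dyad <- (di - 1L) * n + dj
  o <- order(dyad, start_s)
  di <- di[o]; dj <- dj[o]; start_s <- start_s[o]; dur <- dur[o]; dyad <- dyad[o]
  end_s <- start_s + dur
  new_bout <- c(TRUE, dyad[-1] != dyad[-length(dyad)] |
                  start_s[-1] > end_s[-length(end_s)] + config$separation_s)
  grp <- cumsum(new_bout)  # group ids are 1..G in appearance order
  m_start <- start_s[new_bout]  # sorted within dyad, so first start is the min
  m_end <- tapply(end_s, factor(grp, levels = unique(grp)), max)
  m_i <- di[new_bout]
  m_j <- dj[new_bout]
  m_dur <- as.numeric(m_end) - m_start

  # per-logger multiplicative recording bias (drawn, or planted exactly)
  if (!is.null(config$logger_bias_multipliers)) {
    bias <- rep_len(config$logger_bias_multipliers, n)
  } else {
    bias <- exp(stats::rnorm(n, 0, config$logger_bias_sdlog * config$noise))
  }
  names(bias) <- ids
  d_i <- pmax(1, round(m_dur * bias[m_i]))
  d_j <- pmax(1, round(m_dur * bias[m_j]))

  rec <- data.frame(
    self_id = c(ids[m_i], ids[m_j]),
    partner_id = c(ids[m_j], ids[m_i]),
    start = t0 + rep(as.numeric(m_start), 2),
    duration_s = as.integer(c(d_i, d_j)),
    stringsAsFactors = FALSE)

  n_spur <- stats::rpois(1, config$spurious_1s_rate * nrow(rec))
  if (n_spur > 0) {
    si <- sample.int(n, n_spur, replace = TRUE)
    sj <- vapply(si, function(i) sample(seq_len(n)[-i], 1L), integer(1))
    spur <- data.frame(self_id = ids[si], partner_id = ids[sj],
                       start = t0 + floor(stats::runif(n_spur, 0, total_s)),
                       duration_s = 1L, stringsAsFactors = FALSE)
    rec <- rbind(rec, spur)
  }
  rec <- rec[order(rec$start, rec$self_id, rec$partner_id), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "logger_multipliers") <- bias
  attr(rec, "windows") <- t0 + seq(0, config$weeks) * 7 * 86400
  attr(rec, "qc") <- list(n_duplicate_rows = sum(duplicated(rec)))
  rec
}

#' Generate synthetic pen-rearing records
#'
#' Weights follow per-calf specific growth rates drawn from
#' `N(sgr_mean, sgr_sd^2)`; daily health scores flag impaired days at the
#' configured incidences; per-pen concentrate intake ramps linearly so the
#' whole-trial mean matches `intake_mean_g`; per-pen vocalisation rates for
#' days 45-53 are drawn around the period-by-treatment means (gamma
#' distributed, with the configured between-pen SDs). With `noise = 0` all
#' randomness collapses and pens of a treatment are identical.
#'
#' @param schedule A `housing_schedule`.
#' @param config A `sim_config`.
#' @param seed RNG seed (required).
#' @return A `calf_rearing_records` object: list with `calves`, `health`,
#'   `intake`, `vocal`, the `schedule` and `entry_day`.
#' @export
generate_rearing_data <- function(schedule, config = sim_config(), seed) {
  stopifnot(inherits(schedule, "housing_schedule"), !missing(seed))
  set.seed(seed)
  ns <- config$noise
  ids <- schedule$calf_id
  n <- length(ids)
  entry_day <- config$entry_day
  days <- entry_day:54

  w0 <- config$entry_weight_mean +
    stats::rnorm(n, 0, config$entry_weight_sd * ns)
  sgr <- config$sgr_mean + stats::rnorm(n, 0, config$sgr_sd * ns)
  w47 <- w0 * exp(sgr / 100 * (47 - entry_day))
  w55 <- w0 * exp(sgr / 100 * (55 - entry_day))
  removed <- rep(NA_integer_, n)
  if (isTRUE(config$i_calf_dropout)) {
    removed[sample(which(schedule$treatment == "I"), 1L)] <- 12L
  }
  calves <- data.frame(calf_id = ids, pen_id = schedule$pen_id,
                       treatment = schedule$treatment, block = schedule$block,
                       weight_entry = w0, weight_d47 = w47, weight_d55 = w55,
                       removed_day = removed, stringsAsFactors = FALSE)

  p_fae <- config$impaired_faecal_rate * (ns > 0)
  p_resp <- config$impaired_resp_rate * (ns > 0)
  nd <- length(days)
  health <- data.frame(
    calf_id = rep(ids, each = nd), day = rep(days, n),
    faecal = ifelse(stats::runif(n * nd) < p_fae,
                    sample(2:3, n * nd, replace = TRUE),
                    stats::rbinom(n * nd, 1, 0.3 * (ns > 0))),
    stringsAsFactors = FALSE)
  resp_imp <- stats::runif(n * nd) < p_resp
  health$cough <- ifelse(resp_imp, stats::rbinom(n * nd, 2, 0.5) + 1L, 0L)
  health$nasal <- ifelse(resp_imp, stats::rbinom(n * nd, 2, 0.3), 0L)
  health$eye <- 0L
  health$ear <- 0L

  pens <- unique(schedule$pen_id)
  ramp <- 2 * config$intake_mean_g * (days - entry_day) / (54 - entry_day)
  intake <- do.call(rbind, lapply(pens, function(p) {
    pen_mult <- exp(stats::rnorm(1, 0, config$intake_cv * ns))
    daily <- ramp * pen_mult * exp(stats::rnorm(nd, 0, 0.1 * ns))
    data.frame(pen_id = p, day = days, intake_g = round(daily, 1),
               stringsAsFactors = FALSE)
  }))

  per_days <- list(pre = 45:47, weaning = 48:50, post = 51:53)
  pen_trt <- schedule$treatment[match(pens, schedule$pen_id)]
  vocal <- do.call(rbind, lapply(seq_along(pens), function(k) {
    do.call(rbind, lapply(names(per_days), function(per) {
      m <- config$vocal_mean[per, pen_trt[k]]
      s <- config$vocal_sd[per, pen_trt[k]] * ns
      lev <- if (s > 0) stats::rgamma(1, shape = (m / s)^2, rate = m / s^2) else m
      daily <- if (ns > 0) {
        stats::rgamma(3, shape = 25, rate = 25 / max(lev, 1e-9))
      } else rep(lev, 3)
      data.frame(pen_id = pens[k], day = per_days[[per]],
                 calls_per_h = round(daily, 2), stringsAsFactors = FALSE)
    }))
  }))

  structure(list(calves = calves, health = health, intake = intake,
                 vocal = vocal, schedule = schedule, entry_day = entry_day),
            class = "calf_rearing_records")
}

#' Write / read rearing records as plain CSV files
#'
#' @param records A `calf_rearing_records` object.
#' @param dir Directory for `calves.csv`, `health.csv`, `intake.csv`,
#'   `vocal.csv`, `schedule.csv`.
#' @return `dir` (write) or the records (read).
#' @export
write_rearing <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records$calves, file.path(dir, "calves.csv"), row.names = FALSE)
  utils::write.csv(records$health, file.path(dir, "health.csv"), row.names = FALSE)
  utils::write.csv(records$intake, file.path(dir, "intake.csv"), row.names = FALSE)
  utils::write.csv(records$vocal, file.path(dir, "vocal.csv"), row.names = FALSE)
  write_schedule(records$schedule, file.path(dir, "schedule.csv"))
  writeLines(as.character(records$entry_day), file.path(dir, "entry_day.txt"))
  invisible(dir)
}

#' @rdname write_rearing
#' @export
read_rearing <- function(dir) {
  structure(list(
    calves = utils::read.csv(file.path(dir, "calves.csv"), stringsAsFactors = FALSE),
    health = utils::read.csv(file.path(dir, "health.csv"), stringsAsFactors = FALSE),
    intake = utils::read.csv(file.path(dir, "intake.csv"), stringsAsFactors = FALSE),
    vocal = utils::read.csv(file.path(dir, "vocal.csv"), stringsAsFactors = FALSE),
    schedule = read_schedule(file.path(dir, "schedule.csv")),
    entry_day = as.integer(readLines(file.path(dir, "entry_day.txt")))),
    class = "calf_rearing_records")
}
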