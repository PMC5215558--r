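#' Simulate a full synthetic study and write it to disk
#'
#' Generates the housing schedule, the proximity-logger contact stream and
#' the rearing records for one synthetic cohort, writes them as plain CSV
#' files, and records a run manifest (configuration snapshot, seed, file
#' digests, package version) so the run can be reproduced byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `sim_config`.
#' @param seed Top-level seed; stage substreams are derived from it.
#' @return Invisibly, the manifest list.
#' @export
pipeline_simulate <- function(out_dir, config = sim_config(), seed) {
  stopifnot(!missing(seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  schedule <- generate_schedule(config)
  contacts <- generate_contact_stream(schedule, config, seed = seed + 1L)
  rearing <- generate_rearing_data(schedule, config, seed = seed + 2L)

  write_schedule(schedule, file.path(out_dir, "schedule.csv"))
  write_contact_records(contacts, file.path(out_dir, "contacts.csv"))
  write_rearing(rearing, file.path(out_dir, "rearing"))

  files <- c(file.path(out_dir, c("schedule.csv", "contacts.csv")),
             list.files(file.path(out_dir, "rearing"), full.names = TRUE))
  manifest <- list(
    stage = "simulate", seed = seed,
    config = config_snapshot(config),
    package_version = as.character(utils::packageVersion("calfnet")),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = stats::setNames(as.list(unname(tools::md5sum(files))), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  cfg <- unclass(config)
  cfg$vocal_mean <- as.data.frame(cfg$vocal_mean)
  cfg$vocal_sd <- as.data.frame(cfg$vocal_sd)
  cfg
}

#' Build corrected weekly association matrices from a contact stream
#'
#' Reads and validates the contact stream, drops 1-second records, splits
#' the stream into week-long windows, and for each week estimates
#' per-logger recording bias, corrects the directed totals and symmetrises
#' them into an association matrix. Matrices and a QC report of the
#' per-logger biases are written as CSV.
#'
#' @param contacts_csv Contact-stream CSV path.
#' @param schedule_csv Housing-schedule CSV path.
#' @param out_dir Output directory.
#' @param min_duration_s Minimum record duration to keep (default 2).
#' @param weeks Number of 7-day windows (default 4).
#' @param origin Calendar origin date of the schedule (default
#'   "2013-04-01").
#' @return Invisibly, a list with the `association_matrix` objects
#'   (`matrices`), the per-week `logger_bias` estimates (`biases`) and the
#'   written file paths.
#' @export
pipeline_networks <- function(contacts_csv, schedule_csv, out_dir,
                              min_duration_s = 2, weeks = 4,
                              origin = "2013-04-01") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- read_schedule(schedule_csv)
  records <- parse_contact_records(contacts_csv)
  records <- filter_min_duration(records, min_duration_s)
  t0 <- as.POSIXct(paste0(origin, " 00:00:00"), tz = "UTC") +
    attr(schedule, "grouping_day") * 86400
  bounds <- t0 + seq(0, weeks) * 7 * 86400

  matrices <- vector("list", weeks)
  biases <- vector("list", weeks)
  paths <- character(weeks)
  for (w in seq_len(weeks)) {
    dt <- directed_totals(records, bounds[w], bounds[w + 1L],
                          ids = schedule$calf_id, window = paste0("week", w))
    b <- estimate_logger_bias(dt)
    matrices[[w]] <- symmetrise(apply_bias_correction(dt, b))
    biases[[w]] <- b
    paths[w] <- file.path(out_dir, sprintf("association_week%d.csv", w))
    write_matrix_csv(matrices[[w]], paths[w])
  }
  qc <- data.frame(logger = schedule$calf_id,
                   sapply(seq_len(weeks), function(w) {
                     biases[[w]]$bias_pct[schedule$calf_id]
                   }))
  names(qc) <- c("logger", paste0("bias_pct_week", seq_len(weeks)))
  utils::write.csv(qc, file.path(out_dir, "logger_bias_qc.csv"), row.names = FALSE)
  invisible(list(matrices = matrices, biases = biases,
                 files = c(paths, file.path(out_dir, "logger_bias_qc.csv"))))
}

#' Run the full network and rearing analysis
#'
#' Given the weekly association matrices, the housing schedule and the
#' rearing records, computes: the Mantel/QAP stability table over all week
#' pairs, the social-differentiation permutation test per week, the DIC
#' ladder of dyadic assortment models for the first and last weeks,
#' bootstrap-permutation ANOVAs of pen-averaged CV in association
#' strength (with and without ex-penmates), ex-penmate pair-time and
#' weighted degree across treatments, and the pen-rearing weaning battery.
#' Results are written as machine-readable JSON and a human-readable text
#' report, both stamped with the seed.
#'
#' @param matrix_csvs Character vector of weekly association-matrix CSVs
#'   (in week order).
#' @param schedule_csv Housing-schedule CSV path.
#' @param rearing_dir Directory written by [write_rearing()].
#' @param out_dir Output directory.
#' @param seed Seed for all permutation and MCMC stages.
#' @param n_perm Permutations for Mantel and differentiation tests
#'   (default 4999).
#' @param n_boot Resamples for the bootstrap ANOVAs (default 5000).
#' @param mcmc List of MCMC controls passed to [fit_dyadic_model()].
#' @return Invisibly, the report list.
#' @export
pipeline_analyse <- function(matrix_csvs, schedule_csv, rearing_dir, out_dir,
                             seed, n_perm = 4999, n_boot = 5000,
                             mcmc = list()) {
  stopifnot(!missing(seed), length(matrix_csvs) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- read_schedule(schedule_csv)
  mats <- lapply(seq_along(matrix_csvs), function(w) {
    association_matrix(read_matrix_csv(matrix_csvs[w]), window = paste0("week", w))
  })
  weeks <- length(mats)

  ## network stability: all week pairs (needs at least two weeks)
  if (weeks >= 2L) {
    pairs <- utils::combn(weeks, 2)
    stability <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      w1 <- pairs[1, k]; w2 <- pairs[2, k]
      mt <- mantel_qap(mats[[w1]], mats[[w2]], n_perm = n_perm,
                       seed = seed + 100L + k)
      data.frame(weeks = paste(w1, w2, sep = ","), rho = mt$rho,
                 r_squared = mt$r_squared, p = mt$p)
    }))
  } else {
    stability <- data.frame(weeks = character(0), rho = numeric(0),
                            r_squared = numeric(0), p = numeric(0))
  }

  ## social differentiation per week
  differentiation <- do.call(rbind, lapply(seq_len(weeks), function(w) {
    dt <- differentiation_null_test(mats[[w]], n_perm = n_perm,
                                    seed = seed + 200L + w)
    data.frame(week = w, S_obs = dt$S_obs, null_median = dt$null_median,
               null_q95 = dt$null_q95, p = dt$p)
  }))

  ## assortment: first and last week
  ws <- unique(c(1L, weeks))
  assort <- lapply(stats::setNames(ws, paste0("week", ws)),
                   function(w) {
    tab <- build_dyad_table(mats[[w]], schedule)
    fits <- do.call(fit_assortment_models,
                    c(list(table = tab, seed = seed + 300L + 10L * w), mcmc))
    cmp <- compare_dic(fits)
    list(dic_table = cmp$table, best = cmp$best_name,
         full_model = summary(fits$familiarity_treatment))
  })

  ## treatment contrasts of individual network measures, pen-averaged
  trt_tests <- lapply(stats::setNames(ws, paste0("week", ws)),
                      function(w) {
    M <- mats[[w]]
    ids <- M$ids
    penmate <- schedule$penmate[match(ids, schedule$calf_id)]
    cv <- vapply(ids, function(i) cv_strength(M, i), numeric(1))
    cv_ex <- vapply(seq_along(ids), function(k) {
      cv_strength(M, ids[k], exclude = if (is.na(penmate[k])) NULL else penmate[k])
    }, numeric(1))
    names(cv_ex) <- ids
    deg <- weighted_degree(M)
    paired <- !is.na(penmate)
    pt <- vapply(which(paired), function(k) {
      pair_time_pct(M, ids[k], penmate[k])
    }, numeric(1))
    names(pt) <- ids[paired]

    by_trt <- function(pa) split(pa$value, pa$treatment)
    list(
      cv = bootstrap_anova(by_trt(pen_average(cv, schedule)),
                           n_resamples = n_boot, seed = seed + 400L + w),
      cv_excl_penmate = bootstrap_anova(by_trt(pen_average(cv_ex, schedule)),
                                        n_resamples = n_boot,
                                        seed = seed + 420L + w),
      degree = bootstrap_anova(by_trt(pen_average(deg, schedule)),
                               n_resamples = n_boot, seed = seed + 440L + w),
      pair_time = bootstrap_anova(by_trt(pen_average(pt, schedule)),
                                  n_resamples = n_boot, seed = seed + 460L + w),
      mean_pair_time = mean(pt))
  })

  ## rearing / weaning battery
  rearing <- read_rearing(rearing_dir)
  weaning <- run_weaning_analysis(rearing)

  report <- list(seed = seed, n_perm = n_perm, n_boot = n_boot,
                 stability = stability, differentiation = differentiation,
                 assortment = assort, treatment_tests = trt_tests,
                 weaning = weaning)
  jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report_text(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

# flatten the report into JSON-serialisable pieces
report_json <- function(r) {
  ba_json <- function(b) list(F = b$F, df = b$df, p = b$p,
                              group_means = as.list(b$group_means),
                              ci = as.data.frame(b$ci))
  list(
    seed = r$seed, n_perm = r$n_perm, n_boot = r$n_boot,
    stability = r$stability,
    differentiation = r$differentiation,
    assortment = lapply(r$assortment, function(a) {
      s <- a$full_model
      list(dic_table = a$dic_table, best = a$best,
           full_model = cbind(term = rownames(s), as.data.frame(s)))
    }),
    treatment_tests = lapply(r$treatment_tests, function(tt) {
      c(lapply(tt[c("cv", "cv_excl_penmate", "degree", "pair_time")], ba_json),
        list(mean_pair_time = tt$mean_pair_time))
    }),
    weaning = list(
      n_units = nrow(r$weaning$units),
      vocal_period_means = as.list(r$weaning$vocal$period_means),
      friedman_p = r$weaning$vocal$friedman$p.value,
      kruskal_p = lapply(r$weaning$vocal$kruskal_by_period, `[[`, "p.value"),
      pairwise = r$weaning$vocal$pairwise,
      mean_sgr = r$weaning$growth$mean_sgr_whole,
      mean_intake_g = r$weaning$intake$mean_whole,
      faecal_impaired_pct = r$weaning$health$mean_faecal_pct,
      resp_impaired_pct = r$weaning$health$mean_resp_pct))
}

report_text <- function(r) {
  out <- c(
    sprintf("calfnet analysis report (seed %d, %d permutations, %d resamples)",
            r$seed, r$n_perm, r$n_boot),
    "", "Network stability (Mantel/QAP):",
    utils::capture.output(print(transform(r$stability,
                                          rho = round(rho, 3),
                                          r_squared = round(r_squared, 3)),
                                row.names = FALSE)),
    "", "Social differentiation:",
    utils::capture.output(print(transform(r$differentiation,
                                          S_obs = signif(S_obs, 5),
                                          null_median = signif(null_median, 5),
                                          null_q95 = signif(null_q95, 5)),
                                row.names = FALSE)),
    "")
  for (w in names(r$assortment)) {
    a <- r$assortment[[w]]
    out <- c(out, sprintf("Assortment (%s): best model by DIC = %s", w, a$best),
             utils::capture.output(print(a$dic_table, row.names = FALSE)), "")
  }
  for (w in names(r$treatment_tests)) {
    tt <- r$treatment_tests[[w]]
    out <- c(out, sprintf("Treatment contrasts (%s):", w),
             sprintf("  CV in strength:        F = %.3f, p = %.4g", tt$cv$F, tt$cv$p),
             sprintf("  CV (excl. penmate):    F = %.3f, p = %.4g",
                     tt$cv_excl_penmate$F, tt$cv_excl_penmate$p),
             sprintf("  weighted degree:       F = %.3f, p = %.4g",
                     tt$degree$F, tt$degree$p),
             sprintf("  pair time (P5 vs P28): F = %.3f, p = %.4g; mean %.2f%%",
                     tt$pair_time$F, tt$pair_time$p, tt$mean_pair_time),
             "")
  }
  c(out, "Weaning battery:",
    utils::capture.output(print(r$weaning)))
}
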