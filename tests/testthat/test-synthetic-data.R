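test_that("the default schedule lays out the full cohort", {
  sched <- small_schedule()
  expect_equal(nrow(sched), 40)
  expect_equal(length(unique(sched$block)), 8)
  expect_equal(unname(table(sched$treatment)[c("I", "P5", "P28")]),
               c(8L, 16L, 16L), ignore_attr = TRUE)
  # penmate links are mutual and pairing ages correct
  paired <- sched[!is.na(sched$penmate), ]
  expect_true(all(sched$penmate[match(paired$penmate, sched$calf_id)] ==
                    paired$calf_id))
  expect_equal(unique(paired$pairing_age[paired$treatment == "P5"]), 5)
  expect_equal(unique(paired$pairing_age[paired$treatment == "P28"]), 28)
  expect_equal(attr(sched, "grouping_day"), 81)
  # familiarity spans the full 0-76 range
  fam <- familiarity_matrix(sched)
  expect_equal(range(fam[upper.tri(fam)]), c(0L, 76L))

  # schedule CSV round trip preserves the timeline attributes
  f <- tempfile(fileext = ".csv")
  write_schedule(sched, f)
  back <- read_schedule(f)
  expect_equal(as.data.frame(back), as.data.frame(sched))
  expect_equal(attr(back, "grouping_day"), 81)
})

test_that("contact streams are reproducible, valid, and carry the rate model", {
  cfg <- sim_config(weeks = 1L, baseline_contact_rate = 0.05)
  sched <- generate_schedule(cfg)
  a <- generate_contact_stream(sched, cfg, seed = 5)
  b <- generate_contact_stream(sched, cfg, seed = 5)
  expect_identical(a$duration_s, b$duration_s)
  expect_identical(a$start, b$start)

  # streams pass the reader's validation after a CSV round trip
  f <- tempfile(fileext = ".csv")
  write_contact_records(a, f)
  parsed <- parse_contact_records(f)
  expect_equal(nrow(parsed), nrow(a))
  expect_true(all(parsed$duration_s >= 1))
  expect_true(all(parsed$self_id != parsed$partner_id))

  # spurious 1-s records exist at the configured rate and filter away
  expect_gt(sum(a$duration_s == 1), 0)
  kept <- filter_min_duration(a)
  expect_equal(sum(kept$duration_s == 1), 0)

  # familiar dyads associate more: penmates vs cross-block strangers
  win <- attr(a, "windows")
  dt <- directed_totals(kept, win[1], win[2], sched$calf_id)
  M <- symmetrise(dt)$O
  p5 <- sched[sched$treatment == "P5", ]
  mate_strength <- mean(M[cbind(p5$calf_id, p5$penmate)])
  b1 <- sched$calf_id[sched$block == 1]
  b8 <- sched$calf_id[sched$block == 8]
  stranger_strength <- mean(M[b1, b8])
  expect_gt(mate_strength, 2 * stranger_strength)
})

test_that("planted 10% logger bias is recoverable from long streams", {
  mult <- rep(1, 40)
  mult[c(3, 11, 24, 30, 38)] <- 1.10  # five loggers over-record by 10%
  cfg <- sim_config(weeks = 2L, baseline_contact_rate = 0.15,
                    logger_bias_multipliers = mult, spurious_1s_rate = 0)
  sched <- generate_schedule(cfg)
  rec <- generate_contact_stream(sched, cfg, seed = 21)
  truth <- attr(rec, "logger_multipliers")
  win <- attr(rec, "windows")
  dt <- directed_totals(filter_min_duration(rec), win[1], win[3], sched$calf_id)
  est <- estimate_logger_bias(dt)
  # true relative bias versus the estimator's reference logger, in percent
  truth_pct <- 100 * (truth / truth[est$reference_id] - 1)
  expect_lt(max(abs(est$bias_pct - truth_pct[names(est$bias_pct)])), 2)
})

test_that("rearing records track the configured growth and stress structure", {
  cfg <- sim_config()
  sched <- generate_schedule(cfg)
  rec <- generate_rearing_data(sched, cfg, seed = 31)
  expect_s3_class(rec, "calf_rearing_records")
  expect_equal(nrow(rec$calves), 40)
  expect_equal(sum(!is.na(rec$calves$removed_day)), 1)
  expect_equal(rec$calves$treatment[!is.na(rec$calves$removed_day)], "I")

  # realised mean SGR within 0.05 of the configured 1.06 %/day at n = 40
  sgr <- specific_growth_rate(rec$calves$weight_entry, rec$calves$weight_d55,
                              55 - rec$entry_day)
  expect_lt(abs(mean(sgr) - 1.06), 0.05)

  # post-weaning vocalisation: I pens exceed P5 pens in nearly all runs
  hits <- vapply(1:20, function(s) {
    r <- generate_rearing_data(sched, cfg, seed = 4000 + s)
    v <- r$vocal[r$vocal$day %in% 51:53, ]
    pen_trt <- sched$treatment[match(v$pen_id, sched$pen_id)]
    mean(v$calls_per_h[pen_trt == "I"]) > mean(v$calls_per_h[pen_trt == "P5"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # reproducibility and the zero-noise collapse
  r1 <- generate_rearing_data(sched, cfg, seed = 8)
  r2 <- generate_rearing_data(sched, cfg, seed = 8)
  expect_identical(r1$calves, r2$calves)
  expect_identical(r1$vocal, r2$vocal)

  cfg0 <- sim_config(noise = 0, i_calf_dropout = FALSE)
  r0 <- generate_rearing_data(generate_schedule(cfg0), cfg0, seed = 1)
  expect_equal(length(unique(r0$calves$weight_entry)), 1)
  v0 <- r0$vocal
  v0$trt <- sched$treatment[match(v0$pen_id, sched$pen_id)]
  per_pen <- tapply(v0$calls_per_h, list(v0$pen_id), mean)
  trt_of_pen <- sched$treatment[match(names(per_pen), sched$pen_id)]
  expect_true(all(tapply(per_pen, trt_of_pen, function(x) length(unique(x))) == 1))

  # rearing CSV round trip
  d <- tempfile()
  write_rearing(rec, d)
  back <- read_rearing(d)
  expect_equal(back$calves$weight_d55, rec$calves$weight_d55)
  expect_equal(back$vocal$calls_per_h, rec$vocal$calls_per_h)
})
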