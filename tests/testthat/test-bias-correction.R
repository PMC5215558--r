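make_totals <- function(d, ids = LETTERS[seq_len(nrow(d))]) {
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, window = NULL), class = "directed_totals")
}

test_that("pairwise percentage difference is antisymmetric and mean-based", {
  expect_equal(pairwise_pct_difference(100, 100), 0)
  expect_equal(pairwise_pct_difference(105, 95), 10)
  for (xy in list(c(3, 7), c(120, 80), c(0, 5))) {
    expect_equal(pairwise_pct_difference(xy[1], xy[2]),
                 -pairwise_pct_difference(xy[2], xy[1]))
  }
  expect_true(is.na(pairwise_pct_difference(0, 0)))
  # scale invariance
  expect_equal(pairwise_pct_difference(210, 190), pairwise_pct_difference(21, 19))
})

test_that("logger bias is estimated relative to the most under-recorded logger", {
  # perfectly reciprocal totals: all biases zero
  d <- matrix(c(0, 100, 50, 100, 0, 80, 50, 80, 0), 3, 3)
  b <- estimate_logger_bias(make_totals(d))
  expect_equal(unname(b$bias_pct), c(0, 0, 0))

  # logger A records 10% more than B and C, which agree with each other.
  # hand calculation: pct(110,100) = 100*10/105 = 9.5238...; m_A = 9.5238,
  # m_B = m_C = (-9.5238 + 0)/2 = -4.7619; bias_A = m_A - m_B = 14.2857
  d2 <- matrix(0, 3, 3)
  d2[1, 2] <- 110; d2[2, 1] <- 100
  d2[1, 3] <- 110; d2[3, 1] <- 100
  d2[2, 3] <- 60; d2[3, 2] <- 60
  b2 <- estimate_logger_bias(make_totals(d2))
  m_a <- 100 * 10 / 105
  expect_equal(unname(b2$bias_pct["A"]), m_a - (-m_a / 2))
  expect_equal(unname(b2$bias_pct["B"]), 0)
  expect_equal(b2$reference_id, "B")  # tie with C broken lexicographically
  expect_true(all(b2$bias_pct >= 0))

  # scaling every duration by a constant leaves biases unchanged
  b3 <- estimate_logger_bias(make_totals(d2 * 7))
  expect_equal(b3$bias_pct, b2$bias_pct)

  # isolated logger is an error naming it
  d4 <- matrix(0, 3, 3)
  d4[1, 2] <- 10; d4[2, 1] <- 12
  expect_error(estimate_logger_bias(make_totals(d4)), "C")
})

test_that("bias correction reduces each logger's row by its bias percent", {
  d <- matrix(c(0, 1000, 2000, 0), 2, 2, byrow = TRUE)
  tot <- make_totals(d)
  bias <- structure(list(bias_pct = c(A = 5, B = 0), reference_id = "B"),
                    class = "logger_bias")
  corr <- apply_bias_correction(tot, bias)
  expect_equal(corr$d["A", "B"], 950)   # the 5% worked example
  expect_equal(corr$d["B", "A"], 2000)  # reference row unchanged

  # zero bias is the identity
  b0 <- structure(list(bias_pct = c(A = 0, B = 0), reference_id = "A"),
                  class = "logger_bias")
  expect_equal(apply_bias_correction(tot, b0)$d, tot$d)

  # 3-logger toy equals hand-scaled rows, and correction is homogeneous
  d3 <- matrix(c(0, 40, 60, 30, 0, 10, 20, 50, 0), 3, 3, byrow = TRUE)
  t3 <- make_totals(d3)
  b3 <- structure(list(bias_pct = c(A = 10, B = 0, C = 25), reference_id = "B"),
                  class = "logger_bias")
  expect_equal(apply_bias_correction(t3, b3)$d,
               d3 * c(0.9, 1, 0.75)[row(d3)], ignore_attr = TRUE)
  expect_equal(apply_bias_correction(make_totals(d3 * 3), b3)$d,
               3 * apply_bias_correction(t3, b3)$d)

  bad <- structure(list(bias_pct = c(A = 120, B = 0), reference_id = "B"),
                   class = "logger_bias")
  expect_error(apply_bias_correction(tot, bad), "100%")
})

test_that("symmetrisation averages the two directed totals", {
  d <- matrix(c(0, 100, 50, 0), 2, 2, byrow = TRUE)
  M <- symmetrise(make_totals(d))
  expect_equal(M$O["A", "B"], 75)
  expect_equal(M$O, t(M$O))

  # already-symmetric input is a fixed point
  ds <- matrix(c(0, 80, 80, 0), 2, 2)
  expect_equal(symmetrise(make_totals(ds))$O, make_totals(ds)$d)

  # mass conservation on random toys: total = mean of the two directed masses
  set.seed(7)
  for (k in 1:5) {
    d <- matrix(sample.int(100, 25), 5, 5)
    diag(d) <- 0
    M <- symmetrise(make_totals(d))
    expect_equal(sum(M$O), sum(d))
    expect_true(all(M$O >= 0) && all(diag(M$O) == 0))
  }
})

test_that("estimate+apply shrinks planted recording bias on synthetic streams", {
  cfg <- sim_config(weeks = 1L, baseline_contact_rate = 0.1,
                    logger_bias_sdlog = 0.08, spurious_1s_rate = 0)
  sched <- generate_schedule(cfg)
  rec <- generate_contact_stream(sched, cfg, seed = 11)
  win <- attr(rec, "windows")
  dt <- directed_totals(filter_min_duration(rec), win[1], win[2], sched$calf_id)
  bias <- estimate_logger_bias(dt)
  corr <- apply_bias_correction(dt, bias)
  recip_err <- function(d) {
    pct <- abs(pairwise_pct_difference(d, t(d)))
    mean(pct[upper.tri(pct)], na.rm = TRUE)
  }
  expect_lt(recip_err(corr$d), recip_err(dt$d))

  # unbiased stream: correction changes totals by well under 1%
  cfg0 <- sim_config(weeks = 1L, baseline_contact_rate = 0.1,
                     logger_bias_sdlog = 0, spurious_1s_rate = 0)
  rec0 <- generate_contact_stream(generate_schedule(cfg0), cfg0, seed = 12)
  dt0 <- directed_totals(filter_min_duration(rec0), win[1], win[2], sched$calf_id)
  corr0 <- apply_bias_correction(dt0, estimate_logger_bias(dt0))
  expect_lt(abs(sum(corr0$d) - sum(dt0$d)) / sum(dt0$d), 0.01)

  # symmetrised corrected output satisfies all association-matrix invariants
  M <- symmetrise(corr)
  expect_s3_class(M, "association_matrix")
  expect_equal(M$O, t(M$O))
  expect_true(all(M$O >= 0) && all(diag(M$O) == 0))
})
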