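test_that("familiarity arithmetic reproduces the schedule timeline", {
  sched <- small_schedule()
  # block-1 P5 pair: paired at age 5, grouping on calendar day 81 -> 76 days
  p5 <- sched$calf_id[sched$block == 1 & sched$treatment == "P5"]
  expect_equal(familiarity_days(sched, p5[1], p5[2]), 76L)
  # block-1 P28 pair: paired at day 28 -> 53 days
  p28 <- sched$calf_id[sched$block == 1 & sched$treatment == "P28"]
  expect_equal(familiarity_days(sched, p28[1], p28[2]), 53L)
  # block 8 enters the barn on the grouping day: zero familiarity to block 1
  b8 <- sched$calf_id[sched$block == 8][1]
  b1 <- sched$calf_id[sched$block == 1][1]
  expect_equal(familiarity_days(sched, b8, b1), 0L)
  # symmetric in its arguments
  expect_equal(familiarity_days(sched, b1, b8), familiarity_days(sched, b8, b1))
  # same-block non-penmates share contact from the pen merge: 81 - 55 = 26
  i1 <- sched$calf_id[sched$block == 1 & sched$treatment == "I"]
  expect_equal(familiarity_days(sched, i1, p5[1]), 26L)
  # earlier blocks overlap in the barn: block 1 vs block 2 -> 81 - 63 = 18
  b2 <- sched$calf_id[sched$block == 2][1]
  expect_equal(familiarity_days(sched, b1, b2), 18L)

  fam <- familiarity_matrix(sched)
  expect_equal(fam, t(fam))
  expect_equal(max(fam), 76L)
  expect_equal(min(fam[upper.tri(fam)]), 0L)
  # bounded by grouping day minus earliest pairing age
  expect_lte(max(fam), 81 - 5)
  expect_error(familiarity_days(sched, "NOPE", b1), "unknown id")

  # single block: every dyad has positive familiarity
  s1 <- generate_schedule(sim_config(n_blocks = 1L))
  f1 <- familiarity_matrix(s1)
  expect_true(all(f1[upper.tri(f1)] > 0))
})

test_that("the dyad table duplicates dyads with swapped roles", {
  sched4 <- small_schedule()
  ids <- sched4$calf_id[1:5]  # block 1
  O <- rand_assoc(5)
  dimnames(O) <- list(ids, ids)
  tab <- build_dyad_table(O, sched4)
  expect_equal(nrow(tab), 5 * 4)
  # every unordered dyad appears exactly twice with roles swapped
  key <- paste(pmin(tab$calf_a, tab$calf_b), pmax(tab$calf_a, tab$calf_b))
  expect_true(all(table(key) == 2))
  swapped <- tab[match(paste(tab$calf_b, tab$calf_a),
                       paste(tab$calf_a, tab$calf_b)), ]
  expect_equal(tab$strength, swapped$strength)
  expect_equal(tab$familiarity_days, swapped$familiarity_days)

  # fields match hand-built rows for one dyad
  a <- ids[2]; b <- ids[3]  # the block-1 P5 pair
  row <- tab[tab$calf_a == a & tab$calf_b == b, ]
  expect_equal(row$strength, O[a, b])
  expect_equal(row$log_strength, log(O[a, b]))
  expect_equal(row$familiarity_days, 76L)
  expect_equal(row$different_treatment, 0L)
  # penmates carry the maximum familiarity within their block
  expect_equal(max(tab$familiarity_days[tab$calf_a == a]), row$familiarity_days)
  # treatment indicator is 0 iff treatments are equal
  trt <- sched4$treatment[match(tab$calf_a, sched4$calf_id)]
  trt_b <- sched4$treatment[match(tab$calf_b, sched4$calf_id)]
  expect_equal(tab$different_treatment, as.integer(trt != trt_b))

  # zero strengths are flagged and logged as log(strength + 1)
  O0 <- O
  O0[ids[1], ids[2]] <- O0[ids[2], ids[1]] <- 0
  expect_warning(tab0 <- build_dyad_table(O0, sched4), "zero-strength")
  expect_equal(attr(tab0, "n_zero_strength"), 2L)
  expect_equal(tab0$log_strength[tab0$calf_a == ids[1] & tab0$calf_b == ids[2]], 0)
})

test_that("the Gibbs sampler recovers least-squares answers and is reproducible", {
  # fixture: synthetic dyad table with a known familiarity slope
  sched <- small_schedule()
  fam <- familiarity_matrix(sched)
  set.seed(99)
  n <- 20
  ids <- sched$calf_id[1:n]
  eta <- 5 + 0.03 * fam[ids, ids]
  noise <- matrix(rnorm(n * n, 0, 0.3), n, n)
  noise <- (noise + t(noise)) / 2
  O <- exp(eta + noise)
  diag(O) <- 0
  O <- (O + t(O)) / 2
  tab <- build_dyad_table(O, sched)

  fit <- fit_dyadic_model(tab, fixed = "familiarity",
                          n_iter = 3000, burn_in = 500, thin = 2, seed = 42)
  expect_s3_class(fit, "dyadic_mcmc")

  # posterior means agree with GLS at the posterior-mean variance components
  y <- tab$log_strength
  X <- cbind(1, tab$familiarity_days)
  Z <- matrix(0, nrow(tab), n)
  Z[cbind(seq_len(nrow(tab)), match(tab$calf_a, sort(ids)))] <- 1
  Z[cbind(seq_len(nrow(tab)), match(tab$calf_b, sort(ids)))] <- 1
  V <- fit$vcv["calf"] * tcrossprod(Z) + fit$vcv["residual"] * diag(nrow(tab))
  W <- solve(V)
  beta_gls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(coef(fit)), drop(beta_gls), tolerance = 0.05)
  # and the credible interval covers the planted slope
  s <- summary(fit)
  expect_gt(s["familiarity", "lower_95"], 0)
  expect_lt(abs(s["familiarity", "post_mean"] - 0.03), 0.01)

  # constant response: slope posteriors centred at zero
  tab_const <- tab
  tab_const$log_strength <- 5
  # (the degenerate chain legitimately trips the low-ESS diagnostic)
  fit0 <- suppressWarnings(
    fit_dyadic_model(tab_const, fixed = c("familiarity", "different_treatment"),
                     n_iter = 2000, burn_in = 500, thin = 2, seed = 7))
  s0 <- summary(fit0)
  expect_lt(abs(s0["familiarity", "post_mean"]), 1e-3)
  expect_lt(abs(s0["different_treatment", "post_mean"]), 0.05)

  # full chain reproducible from seed
  fitA <- fit_dyadic_model(tab, fixed = "familiarity",
                           n_iter = 800, burn_in = 200, thin = 2, seed = 13)
  fitB <- fit_dyadic_model(tab, fixed = "familiarity",
                           n_iter = 800, burn_in = 200, thin = 2, seed = 13)
  expect_identical(fitA$samples, fitB$samples)
  expect_identical(fitA$dic, fitB$dic)

  # role-swap invariance: relabelling a/b leaves the fit unchanged
  tab_sw <- tab
  tab_sw$calf_a <- tab$calf_b
  tab_sw$calf_b <- tab$calf_a
  fit_sw <- fit_dyadic_model(tab_sw, fixed = "familiarity",
                             n_iter = 800, burn_in = 200, thin = 2, seed = 13)
  expect_identical(fit_sw$samples, fitA$samples)
})

test_that("DIC comparison prefers the generating model", {
  sched <- small_schedule()
  fam <- familiarity_matrix(sched)
  set.seed(123)
  n <- 20
  ids <- sched$calf_id[1:n]
  eta <- 4 + 0.03 * fam[ids, ids] + matrix(rnorm(n * n, 0, 0.4), n, n)
  eta <- (eta + t(eta)) / 2
  O <- exp(eta)
  diag(O) <- 0
  tab <- build_dyad_table(association_matrix((O + t(O)) / 2), sched)
  fits <- fit_assortment_models(tab, seed = 1, n_iter = 1500, burn_in = 300,
                                thin = 2)
  cmp <- compare_dic(fits)
  expect_true(grepl("familiarity", cmp$best_name))
  expect_equal(nrow(cmp$table), 4)
  expect_equal(cmp$table$delta[1], 0)

  # duplicate fits tie and either is returned
  cmp2 <- compare_dic(list(a = fits[[2]], b = fits[[2]]))
  expect_true(cmp2$tie)
  expect_equal(DIC(cmp2$best), DIC(fits[[2]]))
})
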