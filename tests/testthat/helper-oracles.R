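# Independent oracles and fixture builders shared across the suite.
# These deliberately use the most naive formulation available so they stay
# independent of the package's vectorised implementations.

# social differentiation by explicit double loop over ordered dyads
oracle_differentiation <- function(O) {
  n <- nrow(O)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) tot <- tot + O[i, j]
  e <- tot / (n * (n - 1))
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) s <- s + (O[i, j] - e)^2
  }
  s / (n * (n - 1))
}

# iterative (Heap-free) enumeration of all permutations of 1..n
oracle_all_perms <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out) {
      for (pos in seq_len(k)) {
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos - 1L)
      }
    }
    out <- nxt
  }
  out
}

# exhaustive QAP p-value: spearman of upper triangles over every node relabel
oracle_qap_exhaustive <- function(O1, O2) {
  ut <- upper.tri(O1)
  obs <- cor(O1[ut], O2[ut], method = "spearman")
  perms <- oracle_all_perms(nrow(O1))
  vals <- vapply(perms, function(p) {
    cor(O1[ut], O2[p, p][ut], method = "spearman")
  }, numeric(1))
  list(rho = obs, p = mean(abs(vals) >= abs(obs) - 1e-12))
}

# exhaustive two-group permutation ANOVA p-value
oracle_anova_exhaustive <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  fstat <- function(a, b) {
    gm <- mean(c(a, b))
    ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    (ssb / 1) / (ssw / (n - 2))
  }
  obs <- fstat(x, y)
  sel <- combn(n, length(x))
  null <- apply(sel, 2, function(s) fstat(vals[s], vals[-s]))
  list(F = obs, p = mean(null >= obs - 1e-12))
}

# grid-search oracle for the two-stage sharpened FDR q-values:
# for each hypothesis, the smallest grid level at which the two-stage
# procedure rejects it
oracle_two_stage_grid <- function(p, grid = seq(0, 1, by = 1e-4)) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  bh_r <- function(alpha) {
    ok <- which(sp <= seq_len(m) * alpha / m)
    if (length(ok) == 0L) 0L else max(ok)
  }
  nrej <- vapply(grid, function(q) {
    qp <- q / (1 + q)
    r1 <- bh_r(qp)
    if (r1 == 0L) return(0L)
    if (r1 == m) return(m)
    bh_r(qp * m / (m - r1))
  }, integer(1))
  qv <- vapply(seq_len(m), function(i) {
    hit <- which(nrej >= i)
    if (length(hit) == 0L) 1 else grid[hit[1L]]
  }, numeric(1))
  out <- numeric(m)
  out[o] <- qv
  out
}

# random symmetric integer association matrix with zero diagonal
rand_assoc <- function(n, max_val = 200) {
  O <- matrix(0L, n, n)
  vals <- sample.int(max_val, n * (n - 1) / 2, replace = TRUE)
  O[upper.tri(O)] <- vals
  O <- O + t(O)
  dimnames(O) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  O
}

# write a small contact CSV and return its path
write_contact_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("self_id,partner_id,start,duration_s", rows), path)
  path
}

small_schedule <- function(...) generate_schedule(sim_config(...))
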