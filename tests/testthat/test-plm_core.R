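test_that("local gap-run energy matches the run-enumeration oracle", {
  g <- gap_run_table(starts = c(2L, 2L, 6L, 5L), lengths = c(4L, 1L, 2L, 1L),
                     values = c(1.5, -0.7, 0.3, 2.0), n_col = 8L,
                     max_length_L = 4L)
  # row: A - [r=3] - - A A A  with lam=1 (col 2), rho=2 (cols 4,5)
  row <- c(1L, 0L, 9L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(local_gap_energy(row, 3L, 0L, g), 1.5)        # g_2^4
  expect_equal(local_gap_energy(row, 3L, 7L, g), -0.7 + 0)   # g_2^1 + g_4^2(absent)
  # no flanking gaps: candidate gap activates g_r^1
  row2 <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 1L)
  expect_equal(local_gap_energy(row2, 2L, 0L, g), -0.7)      # g_2^1
  expect_equal(local_gap_energy(row2, 2L, 4L, g), 0)
  expect_error(local_gap_energy(row, 0L, 0L, g), "index error")

  # oracle: for any row and site, the difference between the gap and non-gap
  # candidate energies equals the difference of total run energies of the
  # two completed sequences (runs enumerated independently by find_gap_runs)
  total_energy <- function(x) {
    runs <- find_gap_runs(x)
    if (!nrow(runs)) return(0)
    sum(mapply(function(s, l) gapdca:::gap_lookup(g, s, l),
               runs$start, runs$length))
  }
  set.seed(3)
  for (k in 1:25) {
    x <- sample(0:2, 8, replace = TRUE)
    r <- sample(8, 1)
    xg <- x; xg[r] <- 0L
    xa <- x; xa[r] <- 1L
    expect_equal(local_gap_energy(x, r, 0L, g) -
                   local_gap_energy(x, r, 1L, g),
                 total_energy(xg) - total_energy(xa))
  }
})

test_that("site 5 candidate-gap energy merges flanking runs", {
  g <- gap_run_table(starts = 5L, lengths = 3L, values = 4.0, n_col = 8L)
  row2 <- c(1L, 2L, 3L, 4L, 9L, 0L, 0L, 1L)  # rho = 2 right of site 5
  expect_equal(local_gap_energy(row2, 5L, 0L, g), 4.0)  # g_5^3 (merged run)
})

test_that("conditional log-probabilities match uniform, softmax and exact enumeration", {
  q <- 21L; N <- 3L
  p0 <- potts_parameters(matrix(0, q, N), array(0, c(q, q, N, N)))
  lp <- conditional_logprobs(c(0L, 1L, 2L), 2L, p0)
  expect_equal(lp, rep(log(1 / 21), 21))

  set.seed(8)
  h <- matrix(rnorm(q * N), q, N)
  pf <- potts_parameters(h, array(0, c(q, q, N, N)))
  lp2 <- conditional_logprobs(c(0L, 5L, 3L), 1L, pf)
  expect_equal(lp2, h[, 1] - gapdca:::log_sum_exp(h[, 1]))
  expect_equal(sum(exp(lp2)), 1, tolerance = 1e-12)

  # N = 2 with one nonzero block: compare against the enumerated conditional
  h2 <- matrix(rnorm(q * 2, sd = 0.5), q, 2)
  blk <- matrix(rnorm(q * q, sd = 0.5), q, q)
  J2 <- array(0, c(q, q, 2, 2))
  J2[, , 1, 2] <- blk; J2[, , 2, 1] <- t(blk)
  pp <- potts_parameters(h2, J2)
  joint <- enum_joint_n2(h2, blk)
  for (b in c(1L, 7L, 21L)) {
    cond <- joint[, b] / sum(joint[, b])
    got <- exp(conditional_logprobs(c(0L, b - 1L), 1L, pp))
    expect_equal(got, cond, tolerance = 1e-12)
  }
})

test_that("site objective is log q at zero and its gradient is exact", {
  msa <- compute_weights(rand_msa(8, 5, gap_frac = 0.25, seed = 21))
  q <- 21L; N <- 5L
  zero <- list(h = numeric(q), J = array(0, c(q, q, N)), g = numeric(0))
  res0 <- site_objective_and_gradient(msa, 2L, zero, reg_config(0, 0, 0))
  expect_equal(res0$objective, log(21))

  # analytic vs central finite differences at a random point, gaps on
  set.seed(22)
  sp <- list(h = rnorm(q, sd = 0.2), J = array(rnorm(q * q * N, sd = 0.2),
                                               c(q, q, N)))
  reg <- reg_config(0.01, 0.02, 0.03)
  ana <- site_objective_and_gradient(msa, 3L, sp, reg, use_gaps = TRUE)
  eps <- 1e-5
  fd_at <- function(field, k) {
    spp <- sp; spm <- sp
    spp[[field]][k] <- spp[[field]][k] + eps
    spm[[field]][k] <- spm[[field]][k] - eps
    (site_objective_and_gradient(msa, 3L, spp, reg, TRUE)$objective -
       site_objective_and_gradient(msa, 3L, spm, reg, TRUE)$objective) /
      (2 * eps)
  }
  ih <- sample(q, 6); iJ <- sample(q * q * N, 12)
  fd <- c(sapply(ih, function(k) fd_at("h", k)),
          sapply(iJ, function(k) fd_at("J", k)))
  an <- c(ana$gradient$h[ih], ana$gradient$J[iJ])
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-6)
})

test_that("penalty-only gradient is 2 lambda theta elementwise", {
  # a state never observed contributes only through the normalizer; with a
  # single-row alignment the penalty part of the gradient is checked exactly
  q <- 21L; N <- 3L
  msa <- new_encoded_msa(matrix(c(1L, 2L, 3L), 1, 3), q = q)
  sp <- list(h = rep(0.5, q), J = array(0.25, c(q, q, N)), g = numeric(0))
  reg <- reg_config(0.4, 0.3, 0.2)
  with_pen <- site_objective_and_gradient(msa, 1L, sp, reg)
  no_pen <- site_objective_and_gradient(msa, 1L, sp, reg_config(0, 0, 0))
  expect_equal(with_pen$gradient$h - no_pen$gradient$h, 2 * 0.4 * sp$h)
  d <- with_pen$gradient$J - no_pen$gradient$J
  expect_equal(d[, , 2], matrix(2 * 0.3 * 0.25, q, q))
  expect_equal(d[, , 1], matrix(0, q, q))  # own site carries no couplings
})

test_that("independent-site data recover fields and leave couplings near zero", {
  q <- 4L; N <- 3L
  set.seed(34)
  probs <- matrix(runif(q * N, 0.5, 1.5), q, N)
  probs <- sweep(probs, 2, colSums(probs), "/")
  # only the row-centred couplings and fields-plus-row-means are identified:
  # per-state shifts move freely between h and J at vanishing penalty
  reduce <- function(f, r) {
    h_eff <- f$h; Jc <- f$J
    for (i in seq_len(N)) {
      if (i == r) next
      rm <- rowMeans(f$J[, , i])
      h_eff <- h_eff + rm
      Jc[, , i] <- f$J[, , i] - rm
    }
    list(h = h_eff - mean(h_eff), J = Jc)
  }

  # exact check: weights equal to the independent-site population law
  states <- as.matrix(expand.grid(0:(q - 1), 0:(q - 1), 0:(q - 1)))
  w <- probs[states[, 1] + 1, 1] * probs[states[, 2] + 1, 2] *
    probs[states[, 3] + 1, 3]
  pmsa <- new_encoded_msa(states, q = q)
  pmsa$weights <- w; pmsa$b_eff <- sum(w)
  pfit <- reduce(fit_site(pmsa, 2L, reg_config(1e-8, 1e-8, 1e-8),
                          settings = optim_settings(maxit = 3000,
                                                    grad_tol = 1e-9,
                                                    factr = 10)), 2L)
  expect_lt(max(abs(pfit$h - (log(probs[, 2]) - mean(log(probs[, 2]))))),
            1e-4)
  expect_lt(max(abs(pfit$J)), 1e-4)

  # finite-sample check on drawn data with default shrinkage
  B <- 20000L
  set.seed(35)
  data <- sapply(seq_len(N), function(j)
    sample.int(q, B, replace = TRUE, prob = probs[, j]) - 1L)
  fitr <- reduce(fit_site(new_encoded_msa(data, q = q), 2L), 2L)
  emp <- tabulate(data[, 2] + 1L, q) / B
  expect_lt(max(abs(fitr$h - (log(emp) - mean(log(emp))))), 0.1)
  expect_lt(max(abs(fitr$J)), 0.05)
})

test_that("per-site fits are deterministic, stationary, and shrink under heavy penalty", {
  msa <- compute_weights(rand_msa(30, 6, gap_frac = 0.15, seed = 5))
  f1 <- fit_site(msa, 4L, use_gaps = TRUE)
  f2 <- fit_site(msa, 4L, use_gaps = TRUE)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_lte(f1$grad_max, 1e-5 * (1 + 1e-8))
  expect_lt(f1$objective, log(21))  # descent from the zero start

  heavy <- fit_site(msa, 4L, reg_config(100, 100, 100), use_gaps = TRUE)
  expect_lt(max(abs(heavy$h)), 0.01)
  expect_lt(max(abs(heavy$J)), 0.01)
})

test_that("collapsing duplicate rows with summed weights leaves fits unchanged", {
  base <- rand_msa(10, 5, gap_frac = 0.2, seed = 14)
  dup <- new_encoded_msa(base$data[c(1:10, 1L, 3L), ], q = 21L)
  dup$weights <- c(rep(1, 10), 1, 1)
  dup$b_eff <- 12
  collapsed <- gapdca:::collapse_duplicates(dup)
  expect_equal(nrow(collapsed$data), 10L)
  expect_equal(sum(collapsed$weights), 12)
  fa <- fit_site(dup, 2L)
  fb <- fit_site(collapsed, 2L)
  expect_equal(fa$objective, fb$objective, tolerance = 1e-10)
  expect_equal(fa$J, fb$J, tolerance = 1e-6)
})

test_that("symmetrization averages the two directed estimates", {
  q <- 21L; N <- 3L
  set.seed(6)
  A <- array(rnorm(q * q * N), c(q, q, N))
  Bm <- array(rnorm(q * q * N), c(q, q, N))
  Cm <- array(rnorm(q * q * N), c(q, q, N))
  J <- symmetrize_couplings(list(A, Bm, Cm))
  expect_equal(J[, , 1, 2], (A[, , 2] + t(Bm[, , 1])) / 2)
  expect_equal(J[, , 2, 1], t(J[, , 1, 2]))
  # both directed estimates equal (and consistent) -> output equals either
  Bc <- Bm; Bc[, , 1] <- t(A[, , 2])
  J2 <- symmetrize_couplings(list(A, Bc, Cm))
  expect_equal(J2[, , 1, 2], A[, , 2])
  # one estimate zero -> half the other
  Bz <- Bm; Bz[, , 1] <- 0
  J3 <- symmetrize_couplings(list(A, Bz, Cm))
  expect_equal(J3[, , 1, 2], A[, , 2] / 2)
})

test_that("zero-sum gauge zeroes margins, is idempotent and linear", {
  expect_equal(zero_sum_gauge(matrix(3.7, 21, 21)), matrix(0, 21, 21))
  set.seed(7)
  M <- matrix(rnorm(441), 21, 21)
  G <- zero_sum_gauge(M)
  expect_lt(max(abs(rowSums(G))), 1e-8)
  expect_lt(max(abs(colSums(G))), 1e-8)
  expect_equal(zero_sum_gauge(G), G)
  M2 <- matrix(rnorm(441), 21, 21)
  expect_equal(zero_sum_gauge(2 * M - 3 * M2),
               2 * zero_sum_gauge(M) - 3 * zero_sum_gauge(M2))

  # single entry c at (1,1): hand expansion of the four means
  q <- 21; cval <- q^2 * 2
  E <- matrix(0, q, q); E[1, 1] <- cval
  G2 <- zero_sum_gauge(E)
  expect_equal(G2[1, 1], cval * (1 - 1 / q - 1 / q + 1 / q^2))
  expect_equal(G2[1, 2], cval * (-1 / q + 1 / q^2))
  expect_equal(G2[2, 2], cval / q^2)
})

test_that("per-site gauge shifts compensated in fields leave scores unchanged", {
  q <- 5L; N <- 4L
  J <- symmetric_J(q, N, seed = 10)
  set.seed(11)
  Jshift <- J
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    c1 <- rnorm(q); c2 <- rnorm(q)
    blk <- J[, , i, j] + outer(c1, rep(1, q)) + outer(rep(1, q), c2)
    Jshift[, , i, j] <- blk
    Jshift[, , j, i] <- t(blk)
  }
  gauge_all <- function(Jarr) {
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      b <- zero_sum_gauge(Jarr[, , i, j])
      Jarr[, , i, j] <- b; Jarr[, , j, i] <- t(b)
    }
    Jarr
  }
  expect_equal(gauge_all(Jshift), gauge_all(J), tolerance = 1e-8)
  s1 <- frobenius_scores(fake_fit(gauge_all(J)), "fn21")
  s2 <- frobenius_scores(fake_fit(gauge_all(Jshift)), "fn21")
  expect_equal(s1$values, s2$values, tolerance = 1e-8)
})

test_that("full fits symmetrize, gauge-fix and serialize losslessly", {
  msa <- compute_weights(rand_msa(40, 6, gap_frac = 0.15, seed = 18))
  fit <- fit_model(msa, use_gaps = TRUE)
  expect_s3_class(fit, "FitResult")
  q <- msa$q
  for (k in 1:5) {
    i <- sample(5, 1); j <- i + 1L
    blk <- fit$params$J[, , i, j]
    expect_lt(max(abs(rowSums(blk))), 1e-8)
    expect_lt(max(abs(colSums(blk))), 1e-8)
    expect_equal(fit$params$J[, , j, i], t(blk))
  }
  expect_length(fit$per_site_objectives, 6L)
  expect_true(all(is.finite(fit$per_site_objectives)))

  p <- tempfile(fileext = ".rds")
  write_fit(fit, p)
  expect_identical(read_fit(p), fit)
})
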