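# Structured coalescent engine: closed-form neutral checks, the exact
# small-population forward-backward oracle, and focal-site bookkeeping.

test_that("sample_allele_counts is binomial with the right edge cases", {
  expect_equal(unname(sample_allele_counts(120, 1)), c(120L, 0L))
  expect_equal(unname(sample_allele_counts(120, 0)), c(0L, 120L))
  set.seed(1)
  nd <- replicate(1e4, sample_allele_counts(120, 0.5)[["n_derived"]])
  se <- sd(nd) / sqrt(length(nd))
  expect_lt(abs(mean(nd) - 60), 3 * se)
  expect_error(sample_allele_counts(10, 1.5), "\\[0, 1\\]")
})

test_that("neutral engine with r = 0 reproduces the coalescent tree-length moment", {
  set.seed(2)
  N <- 500; n <- 10
  m <- make_constant(N)
  reg <- region_config(1000, mu = 0, r = 0, n = n, focal_pos = 0)
  tl <- replicate(2000, {
    g <- simulate_structured_genealogy(NULL, m, NULL, reg)
    total_tree_length(g, 500)
  })
  expected <- 4 * N * sum(1 / seq_len(n - 1))
  se <- sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - expected), 3 * se)
})

test_that("pairwise coalescence time is geometric-like with mean 2N", {
  set.seed(3)
  N <- 300
  m <- make_constant(N)
  reg <- region_config(100, mu = 0, r = 0, n = 2, focal_pos = 0)
  tm <- replicate(2000, tmrca_at(simulate_structured_genealogy(NULL, m, NULL, reg), 50))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
  # memoryless within MC error: sd ~ mean for a geometric with small rate
  expect_lt(abs(sd(tm) - 2 * N), 6 * se)
})

test_that("mutation dropping matches Watterson's E[S] and the neutral SFS shape", {
  set.seed(4)
  N <- 500; n <- 12; L <- 2000; mu <- 2e-6
  m <- make_constant(N)
  reg <- region_config(L, mu = mu, r = 0, n = n, focal_pos = 0)
  xi <- matrix(0, 2000, n - 1)
  S <- numeric(2000)
  for (i in 1:2000) {
    smp <- simulate_neutral_sample(m, reg)
    xi[i, ] <- unfolded_sfs(smp)$xi
    S[i] <- smp$S
  }
  a1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - 4 * N * mu * L * a1), 3 * sd(S) / sqrt(length(S)))
  # E[xi_i] = theta / i, checked class by class with empirical standard
  # errors (classes are correlated within a replicate, so a chi-square on
  # pooled counts would be anti-conservative)
  theta <- 4 * N * mu * L
  for (i in seq_len(n - 1)) {
    se_i <- sd(xi[, i]) / sqrt(nrow(xi))
    expect_lt(abs(mean(xi[, i]) - theta / i), 4 * se_i)
  }

  # mu = 0 gives an empty sample
  reg0 <- region_config(L, mu = 0, r = 0, n = n, focal_pos = 0)
  expect_equal(simulate_neutral_sample(m, reg0)$S, 0L)
})

test_that("structured engine with r = 0 matches the exact forward-population oracle", {
  # Diploid forward simulation at N = 50 with full parent tracking gives the
  # exact genealogy distribution of samples drawn at fixation; the engine,
  # fed the same realized frequency paths, must agree.
  set.seed(5)
  N <- 50; n <- 6; s <- 0.05
  m <- make_constant(N)
  reg <- region_config(100, mu = 0, r = 0, n = n, focal_pos = 0)
  oracle_tm <- c(); engine_tm <- c()
  oracle_len <- c(); engine_len <- c()
  runs <- 0
  while (runs < 120) {
    run <- oracle_forward_population(N, 1 + s, 1 + 2 * s)
    if (is.null(run)) next
    runs <- runs + 1
    og <- oracle_sample_genealogy(run, sample.int(2 * N, n))
    oracle_tm <- c(oracle_tm, og$tmrca)
    oracle_len <- c(oracle_len, og$total_len)
    path <- oracle_freq_path(run, N)           # origin .. fixation
    traj <- structure(list(freqs = rev(path), origin_gen = length(path) - 1L,
                           final_freq = 1, scenario = NULL, model_label = "",
                           attempts = 1), class = "trajectory")
    g <- simulate_structured_genealogy(traj, m, c(n_derived = n, n_ancestral = 0L), reg)
    engine_tm <- c(engine_tm, tmrca_at(g, 50))
    engine_len <- c(engine_len, total_tree_length(g, 50))
  }
  expect_gt(suppressWarnings(ks.test(engine_tm, oracle_tm)$p.value), 0.001)
  se <- sqrt(sd(engine_len)^2 / length(engine_len) +
             sd(oracle_len)^2 / length(oracle_len))
  expect_lt(abs(mean(engine_len) - mean(oracle_len)), 3 * se)
})

test_that("focal bookkeeping: derived leaves carry the focal allele at the right frequency", {
  set.seed(6)
  N <- 400
  m <- make_constant(N)
  reg <- region_config(5e4, mu = 1e-6, r = 1e-7, n = 20, focal_pos = 0)
  tr <- simulate_current_freq(m, c(0.4, 0.6), s = 0, method = "backward")
  cnt <- sample_allele_counts(reg$n, tr$final_freq)
  g <- simulate_structured_genealogy(tr, m, cnt, reg)
  smp <- drop_mutations(g)
  expect_equal(smp$focal$freq, tr$final_freq)
  expect_equal(smp$focal$n_der, cnt[["n_derived"]])
  if (!is.na(smp$focal$col)) {
    col <- smp$mat[, smp$focal$col]
    expect_equal(which(col == 1L), seq_len(cnt[["n_derived"]]))
    expect_equal(smp$positions[smp$focal$col], 0)
  }

  # conditioned neutral samples have a matched focal frequency, and with
  # mu = 0 only the focal column can appear
  reg0 <- region_config(5e4, mu = 0, r = 1e-7, n = 20, focal_pos = 0)
  smp0 <- simulate_neutral_sample(m, reg0, condition_focal = c(0.45, 0.5))
  expect_true(smp0$focal$freq >= 0.45 && smp0$focal$freq <= 0.5)
  expect_lte(smp0$S, 1L)

  # sampling after fixation: every chromosome is derived class, no focal column
  trf <- simulate_current_freq(m, c(0.999, 1), s = 0.2, method = "forward",
                               t_max = 3000)
  trf$freqs[1] <- 1  # force exact fixation at present for the edge case
  trf$final_freq <- 1
  smpf <- simulate_sweep_sample(m, trf, reg)
  expect_equal(smpf$focal$n_der, 20L)
  expect_true(is.na(smpf$focal$col))
})

test_that("every output column is polymorphic and positions are sorted", {
  set.seed(7)
  m <- make_constant(300)
  reg <- region_config(2e4, mu = 2e-6, r = 1e-6, n = 15, focal_pos = 1e4)
  for (i in 1:20) {
    smp <- simulate_neutral_sample(m, reg)
    if (smp$S > 0) {
      cnt <- colSums(smp$mat)
      expect_true(all(cnt > 0 & cnt < smp$n))
      expect_true(!is.unsorted(smp$rel_pos))
    }
  }
})
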