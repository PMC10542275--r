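# Wright-Fisher trajectory generation: single steps, the three conditioning
# schemes, and their independent brute-force oracles.

test_that("wf_step_forward keeps absorbing states and rejects bad input", {
  expect_identical(wf_step_forward(0, 1000, 0.1), 0)
  expect_identical(wf_step_forward(1, 1000, 0.1), 1)
  expect_error(wf_step_forward(-0.1, 1000, 0.1), "\\[0, 1\\]")
  expect_error(wf_step_forward(1.2, 1000, 0.1), "\\[0, 1\\]")
})

test_that("neutral drift is unbiased and the selected mean matches the closed form", {
  set.seed(1)
  N <- 5000
  draws <- replicate(2e4, wf_step_forward(0.3, N, 0))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.3), 3 * se)

  # deterministic part: genotype fitnesses 1 : 1+2hs : 1+2s evaluated
  # independently of the package
  s <- 0.005; h <- 0.5; p <- 0.5
  pstar <- oracle_pstar(p, 1, 1 + 2 * h * s, 1 + 2 * s)
  draws <- replicate(1e5, wf_step_forward(p, N, s, h))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - pstar), 3 * se)
  expect_equal(selection_pstar(p, s, h), pstar, tolerance = 1e-12)

  # frequencies live on the lattice k/(2N)
  expect_true(all(abs(draws * 2 * N - round(draws * 2 * N)) < 1e-9))
})

test_that("per-step frequency change is a martingale under neutrality", {
  # aggregated over unconditioned steps from a spread of frequencies
  # (survival-conditioned paths are deliberately excluded: conditioning
  # induces positive drift at low frequency)
  set.seed(2)
  N <- 300
  deltas <- unlist(lapply(c(0.05, 0.2, 0.5, 0.8, 0.95), function(p) {
    p0 <- round(p * 2 * N) / (2 * N)
    replicate(4000, wf_step_forward(p0, N, 0)) - p0
  }))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("SDN trajectories have the documented structure", {
  set.seed(3)
  m <- make_constant(500)
  tr <- simulate_sdn(m, s = 0.1, t_age = 1)
  expect_length(tr$freqs, 2)
  expect_equal(tr$freqs[2], 1 / 1000)           # origin at 1/(2N)
  expect_true(tr$freqs[1] > 0)                  # non-lost at present
  expect_equal(tr$origin_gen, 1L)

  tr <- simulate_sdn(m, s = 0.02, t_age = 300)
  expect_equal(tr$freqs[tr$origin_gen + 1], 1 / 1000)
  expect_true(all(tr$freqs >= 0 & tr$freqs <= 1))

  trs <- simulate_sdn(m, s = 0.02, t_age = 300, condition = "segregating")
  expect_true(trs$final_freq > 0 && trs$final_freq < 1)

  expect_error(simulate_sdn(m, s = 0, t_age = 5000, max_attempts = 3),
               "attempts")
})

test_that("neutral SDN final frequencies match a brute-force conditioned WF simulator", {
  set.seed(4)
  N <- 100; t_age <- 50
  m <- make_constant(N)
  pkg <- replicate(800, simulate_sdn(m, s = 0, t_age = t_age)$final_freq)
  ora <- replicate(4000, oracle_wf_path(N, t_age, 1, 1))
  ora <- ora[ora > 0]
  expect_gt(suppressWarnings(ks.test(pkg, ora)$p.value), 0.001)
})

test_that("de novo survival probability matches the diffusion approximation", {
  set.seed(5)
  N <- 500; s <- 0.02
  m <- make_constant(N)
  acc <- sdn_acceptance_probability(m, s = s, t_age = 20 * N, n_attempts = 4000)
  u <- oracle_kimura_u(N, s)
  expect_lt(abs(acc - u), 3 * sqrt(u * (1 - u) / 4000))
})

test_that("current-frequency conditioning hits the requested bin, fixation included", {
  set.seed(6)
  m <- make_constant(400)
  tr <- simulate_current_freq(m, c(0.999, 1), s = 0.1, method = "forward",
                              t_max = 4000)
  expect_true(tr$final_freq >= 0.999)

  tr2 <- simulate_current_freq(m, c(0.4, 0.6), s = 0, method = "backward")
  expect_true(tr2$final_freq >= 0.4 && tr2$final_freq <= 0.6)
  expect_true(all(tr2$freqs > 0))
})

test_that("backward accelerator agrees with forward rejection (origin-time distribution)", {
  # contract for the accelerated sampler: its origin-generation distribution
  # must be indistinguishable from the exactly-specified forward-rejection
  # baseline
  set.seed(7)
  N <- 5000; s <- 0.005
  m <- make_constant(N)
  n_each <- 2000
  fw <- replicate(n_each,
    simulate_current_freq(m, c(0.4, 0.6), s = s, method = "forward",
                          t_max = 10000)$origin_gen)
  bw <- replicate(n_each,
    simulate_current_freq(m, c(0.4, 0.6), s = s, method = "backward")$origin_gen)
  expect_gt(suppressWarnings(ks.test(fw, bw)$p.value), 0.01)
})

test_that("SSV trajectories splice a neutral past onto a selected present", {
  set.seed(8)
  N <- 500
  m <- make_constant(N)
  tr <- simulate_ssv(m, s = 0.05, p1 = 0.2, t_sel = 100)
  # frequency at the onset generation is the nearest lattice value to p1
  expect_equal(tr$freqs[101], round(0.2 * 2 * N) / (2 * N))
  expect_gte(tr$origin_gen, 100L)
  expect_true(all(tr$freqs > 0))

  # p1 = 1/(2N) degenerates to (nearly) a de novo history at t_sel
  tr2 <- simulate_ssv(m, s = 0.05, p1 = 1 / (2 * N), t_sel = 60)
  expect_equal(tr2$freqs[61], 1 / (2 * N))

  # s = 0 after onset: the forward segment is plain neutral WF from p1,
  # conditioned on survival; compare with a direct R simulator
  set.seed(9)
  p1l <- round(0.2 * 2 * N) / (2 * N)
  pkg <- replicate(600, simulate_ssv(m, s = 0, p1 = 0.2, t_sel = 80)$final_freq)
  ora <- replicate(3000, {
    p <- p1l
    for (g in 1:80) {
      if (p <= 0 || p >= 1) break
      p <- rbinom(1, 2 * N, p) / (2 * N)
    }
    p
  })
  ora <- ora[ora > 0]
  expect_gt(suppressWarnings(ks.test(pkg, ora)$p.value), 0.001)
})

test_that("trajectory files round-trip losslessly", {
  set.seed(10)
  m <- make_constant(300)
  tr <- simulate_sdn(m, s = 0.03, t_age = 150)
  f <- tempfile(fileext = ".txt")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_identical(tr2$freqs, tr$freqs)
  expect_identical(tr2$origin_gen, tr$origin_gen)
  expect_equal(tr2$scenario$s, 0.03)
  expect_equal(tr2$scenario$mode, "SDN")
})
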