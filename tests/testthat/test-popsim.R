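test_that("inbreeding-adjusted genotype frequencies follow Wright's parameterization", {
  expect_equal(genotype_frequencies(0.5, 0), c(AA = 0.25, Aa = 0.5, aa = 0.25))
  expect_equal(genotype_frequencies(0.5, 1), c(AA = 0.5, Aa = 0, aa = 0.5))
  expect_equal(genotype_frequencies(1, 0.7), c(AA = 1, Aa = 0, aa = 0))
  set.seed(501)
  for (rep in 1:20) {
    g <- genotype_frequencies(runif(1), runif(1))
    expect_equal(sum(g), 1)
    expect_true(all(g >= 0))
  }
  expect_error(genotype_frequencies(1.2, 0), "\\[0, 1\\]")
  expect_error(genotype_frequencies(0.5, -0.1), "\\[0, 1\\]")
})

test_that("the deterministic selection recursion matches hand calculation", {
  expect_equal(step_deterministic(0.5, c(1, 1, 0.8)), 0.5 / 0.95)
  # neutrality is an identity for any p and F
  set.seed(502)
  for (rep in 1:10) {
    p <- runif(1)
    expect_equal(step_deterministic(p, c(1, 1, 1), f = runif(1)), p)
  }
  # boundaries absorb
  expect_equal(step_deterministic(0, c(2, 1, 0.5)), 0)
  expect_equal(step_deterministic(1, c(0.5, 1, 2)), 1)
  expect_error(step_deterministic(0.5, c(0, 0, 0)), "positive")
  expect_error(step_deterministic(1, c(0, 1, 1)), "degenerate")
})

test_that("one stochastic generation has the right support, mean and variance", {
  expect_equal(step_stochastic(0, c(1, 1, 1), n = 50)$p, 0)
  set.seed(503)
  for (rep in 1:20) {
    expect_true(step_stochastic(0.5, c(1, 1, 1), n = 1)$p %in% c(0, 0.5, 1))
  }
  # neutral, N = 50, p = 0.5: E[p'] = 0.5, Var[p'] = pq/(2N) = 0.0025
  set.seed(504)
  draws <- vapply(1:20000, function(i) step_stochastic(0.5, c(1, 1, 1), n = 50)$p,
                  numeric(1))
  expect_equal(mean(draws), 0.5, tolerance = 0.01)
  expect_equal(var(draws), 0.0025, tolerance = 0.05)
  # with inbreeding the one-generation variance is pq(1+F)/(2N)
  set.seed(505)
  draws_f <- vapply(1:20000, function(i) step_stochastic(0.5, c(1, 1, 1), f = 0.5, n = 50)$p,
                    numeric(1))
  expect_equal(var(draws_f), 0.25 * 1.5 / 100, tolerance = 0.05)
  # genotype counts sum to N
  one <- step_stochastic(0.3, c(1, 0.9, 0.8), n = 25)
  expect_equal(sum(one$counts), 25)
})

test_that("deterministic trajectories: neutrality is flat, heterozygote advantage equilibrates", {
  flat <- simulate_drift(0.37, c(1, 1, 1), generations = 100)
  expect_true(all(flat$freq == 0.37))
  # w = (0.9, 1, 0.8): s = 0.1, t = 0.2, equilibrium p = t/(s+t) = 2/3
  eq <- simulate_drift(0.5, c(0.9, 1, 0.8), generations = 400)
  expect_equal(eq$freq[eq$generation == 400], 2 / 3, tolerance = 1e-6)
  expect_equal(nrow(eq), 401)
  expect_equal(eq$freq[eq$generation == 0], 0.5)
})

test_that("trajectory sets respect their dimensions, bounds and seeding contract", {
  ts <- simulate_drift(0.5, c(1, 1, 0.98), n = 50, replicates = 4,
                       generations = 250, seed = 11)
  expect_equal(nrow(ts), 4 * 251)
  expect_true(all(ts$freq >= 0 & ts$freq <= 1))
  expect_true(all(ts$freq[ts$generation == 0] == 0.5))
  ts2 <- simulate_drift(0.5, c(1, 1, 0.98), n = 50, replicates = 4,
                        generations = 250, seed = 11)
  expect_identical(as.data.frame(ts), as.data.frame(ts2))
  # absorbed trajectories are held at the boundary
  ab <- attr(ts, "absorption")
  for (i in which(!is.na(ab$absorbed_at))) {
    tail_f <- ts$freq[ts$replicate == i & ts$generation >= ab$absorbed_at[i]]
    expect_true(all(tail_f == tail_f[1]) && tail_f[1] %in% c(0, 1))
  }
})

test_that("the finite-N mean trajectory tracks the deterministic one early on", {
  det <- simulate_drift(0.5, c(1, 1, 0.8), generations = 20)
  sto <- simulate_drift(0.5, c(1, 1, 0.8), n = 100, replicates = 2000,
                        generations = 20, seed = 42)
  mean_traj <- tapply(sto$freq, sto$generation, mean)
  # Monte-Carlo error of the mean is at most ~ sqrt(pq/(2N))/sqrt(reps) per step
  expect_lt(max(abs(mean_traj - det$freq)), 0.01)
})

test_that("neutral heterozygosity decays as (1 - 1/(2N))^t", {
  n <- 20
  reps <- 2000
  ts <- simulate_drift(0.5, c(1, 1, 1), n = n, replicates = reps,
                       generations = 50, seed = 7)
  het <- tapply(2 * ts$freq * (1 - ts$freq), ts$generation, mean)
  expected <- 2 * 0.5 * 0.5 * (1 - 1 / (2 * n))^(0:50)
  expect_lt(max(abs(het - expected)), 0.025)
})

test_that("fixation under neutrality is predicted by the starting frequency", {
  ts <- simulate_drift(0.3, c(1, 1, 1), n = 20, replicates = 1000,
                       generations = 2000, seed = 99)
  fs <- fixation_summary(ts)
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(fs$prop_fixed - 0.3), 3 * se)
  expect_equal(fs$prop_fixed + fs$prop_lost + fs$prop_segregating, 1)

  # trivial boundaries
  all_fixed <- simulate_drift(1, c(1, 1, 1), n = 10, replicates = 5,
                              generations = 5, seed = 1)
  fs2 <- fixation_summary(all_fixed)
  expect_equal(fs2$prop_fixed, 1)
  expect_equal(fs2$mean_absorption_time, 0)
  expect_error(fixation_summary(simulate_drift(0.5, generations = 10)), "finite")
})

test_that("an advantageous dominant allele initially spreads faster than a recessive one", {
  dom <- simulate_drift(0.01, c(1.05, 1.05, 1), generations = 50)
  rec <- simulate_drift(0.01, c(1.05, 1, 1), generations = 50)
  expect_gt(dom$freq[dom$generation == 50], rec$freq[rec$generation == 50])
})

test_that("inbreeding accelerates the deterministic purge of a recessive deleterious allele", {
  gens_to_rare <- function(f) {
    ts <- simulate_drift(0.5, c(1, 1, 0.8), f = f, generations = 2000)
    # tracked allele is the wild type here; q = 1 - p is the deleterious recessive
    hit <- which(1 - ts$freq < 0.01)
    if (length(hit) == 0) Inf else ts$generation[min(hit)]
  }
  t0 <- gens_to_rare(0)
  t5 <- gens_to_rare(0.5)
  t9 <- gens_to_rare(0.9)
  expect_true(t9 < t5 && t5 < t0)
})

test_that("trajectory sets tidy, glance and plot", {
  ts <- simulate_drift(0.5, c(1, 1, 0.98), n = 50, replicates = 4,
                       generations = 50, seed = 3)
  td <- tidy(ts)
  expect_true(all(c("replicate", "generation", "freq", "state", "absorbed_at") %in% names(td)))
  gl <- glance(ts)
  expect_equal(gl$replicates, 4)
  expect_equal(gl$n, 50)
  expect_s3_class(autoplot(ts), "ggplot")
})
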