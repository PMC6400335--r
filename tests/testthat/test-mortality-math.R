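test_that("composite mortality combines independent conditions", {
  expect_equal(composite_mortality(c(0.5, 0.5)), 0.75)
  expect_equal(composite_mortality(numeric(0)), 0)
  expect_equal(composite_mortality(0.2), 0.2)
  expect_error(composite_mortality(c(0.2, 1)), "\\[0, 1\\)")
  expect_error(composite_mortality(-0.1), "\\[0, 1\\)")

  # permutation invariance and dominance over the worst condition
  set.seed(42)
  for (i in 1:25) {
    p <- stats::runif(sample(1:5, 1), 0, 0.99)
    expect_equal(composite_mortality(p), composite_mortality(sample(p)))
    expect_gte(composite_mortality(p) + 1e-12, max(p))
    expect_lt(composite_mortality(p), 1)
  }
})

test_that("scaled per-cycle mortality inverts the n-cycle survival product", {
  expect_equal(scaled_cycle_mortality(0.75, 2), 0.5)
  expect_equal(scaled_cycle_mortality(0.37, 1), 0.37)
  expect_equal(scaled_cycle_mortality(0, 10), 0)
  expect_error(scaled_cycle_mortality(0.5, 0), "positive integer")

  set.seed(1)
  for (i in 1:25) {
    p_c <- stats::runif(1, 0, 0.999)
    n <- sample(1:500, 1)
    p <- scaled_cycle_mortality(p_c, n)
    expect_equal((1 - p)^n, 1 - p_c, tolerance = 1e-12)
  }
  # monotone in p_c, antitone in n
  expect_gt(scaled_cycle_mortality(0.6, 5), scaled_cycle_mortality(0.4, 5))
  expect_lt(scaled_cycle_mortality(0.6, 10), scaled_cycle_mortality(0.6, 5))
})

test_that("treatment decay matches its geometric closed form", {
  expect_equal(apply_treatment_cycle(0.4, 0.5), 0.2)
  expect_equal(apply_treatment_cycle(0.4, 1), 0)
  expect_equal(apply_treatment_cycle(0.4, 0), 0.4)
  expect_equal(treatment_closed_form(0.4, 0.5, 3), 0.05)
  expect_equal(treatment_closed_form(0.4, 0.9, 0), 0.4)
  expect_equal(treatment_closed_form(0.8, 0.2, 1), 0.64)

  set.seed(2)
  for (i in 1:25) {
    p0 <- stats::runif(1, 0, 0.999)
    eta <- stats::runif(1)
    cyc <- sample(0:200, 1)
    p <- p0
    for (k in seq_len(cyc)) p <- apply_treatment_cycle(p, eta)
    expect_equal(p, treatment_closed_form(p0, eta, cyc), tolerance = 1e-10)
  }
})

test_that("deterioration matches its gamma-function closed form", {
  expect_equal(apply_deterioration_cycle(0.5, 1, 1), 0.5^(1 / 2))
  expect_equal(apply_deterioration_cycle(0.5, 1, 2), 0.5^(1 / 3))
  expect_equal(apply_deterioration_cycle(0.5, 1e8, 1), 0.5, tolerance = 1e-7)
  expect_equal(apply_deterioration_cycle(0, 1, 1), 0)
  # exponent = 1^2 Gamma(2)/Gamma(4) = 1/6 after two cycles
  expect_equal(deterioration_closed_form(0.5, 1, 2), 0.5^(1 / 6))
  expect_equal(deterioration_closed_form(0.7, 3, 0), 0.7)
  expect_equal(deterioration_closed_form(0.9, 2, 1), 0.9^(2 / 3))

  set.seed(3)
  for (i in 1:25) {
    p0 <- stats::runif(1, 0.001, 0.999)
    lam <- 10^stats::runif(1, -2, 3)
    cyc <- sample(0:200, 1)
    p <- p0
    for (k in seq_len(cyc)) p <- apply_deterioration_cycle(p, lam, k)
    expect_equal(p, deterioration_closed_form(p0, lam, cyc),
                 tolerance = 1e-10)
  }
})

test_that("deterioration is strictly increasing and bounded below 1", {
  for (lam in c(0.1, 1, 50, 1000)) {
    p <- 0.05
    for (k in 1:300) {
      p_next <- apply_deterioration_cycle(p, lam, k)
      expect_gte(p_next, p)
      expect_lt(p_next, 1)
      if (p_next < 1 - 1e-9) expect_gt(p_next, p) # strict until saturation
      p <- p_next
    }
  }
  # closed form is monotone non-decreasing in c and approaches 1
  p_seq <- deterioration_closed_form(0.2, 5, 0:400)
  expect_true(all(diff(p_seq) >= 0))
  expect_gt(p_seq[401], 0.999)
})

test_that("per-cycle draws over n cycles reproduce the stay-long mortality", {
  # empirical cumulative death frequency within 3 binomial standard
  # errors at 1e5 replicates
  set.seed(11)
  for (case in list(c(0.3, 7), c(0.75, 2), c(0.05, 40))) {
    p_c <- case[1]
    n <- case[2]
    p <- scaled_cycle_mortality(p_c, n)
    n_rep <- 1e5
    alive <- rep(TRUE, n_rep)
    for (k in seq_len(n)) {
      u <- stats::runif(n_rep)
      alive <- alive & (u > p)
    }
    dead_frac <- 1 - mean(alive)
    se <- sqrt(p_c * (1 - p_c) / n_rep)
    expect_lt(abs(dead_frac - p_c), 3 * se)
  }
})

test_that("severity sampling matches truncated-normal oracle moments", {
  mean <- 0.1
  sd <- 0.1
  set.seed(123)
  x <- sample_severity(1e5, mean, sd)
  expect_true(all(x > 0 & x < 1))

  mom <- truncnorm_moments(mean, sd)
  expect_lt(abs(mean(x) - mom$mean), 3 * mom$sd / sqrt(1e5))
  expect_equal(stats::sd(x), mom$sd, tolerance = 0.02)

  # upper tail two SDs above the untruncated mean carries ~2.28% of mass
  tail_true <- truncnorm_tail_mass(mean, sd, mean + 2 * sd)
  tail_emp <- mean(x > mean + 2 * sd)
  se <- sqrt(tail_true * (1 - tail_true) / 1e5)
  expect_lt(abs(tail_emp - tail_true), 3 * se)
  # conditional tail mass = untruncated 2.28% upper tail / truncated mass
  expect_equal(tail_true,
               stats::pnorm(2, lower.tail = FALSE) / truncnorm_moments(mean, sd)$mass,
               tolerance = 1e-8)

  # degenerate sd -> all draws at the mean; seeded determinism
  set.seed(5)
  a <- sample_severity(10, 0.3, 1e-12)
  expect_equal(a, rep(0.3, 10), tolerance = 1e-6)
  set.seed(99)
  b1 <- sample_severity(50, 0.2, 0.1)
  set.seed(99)
  b2 <- sample_severity(50, 0.2, 0.1)
  expect_identical(b1, b2)
  expect_error(sample_severity(5, 0.2, 0), "positive")
})

test_that("severity sd derives from the SMO anchor two SDs above the mean", {
  expect_equal(derive_severity_sd(0.10, 0.30), 0.10)
  expect_equal(derive_severity_sd(0.02, 0.32), 0.15)
  expect_error(derive_severity_sd(0.05, 0.05), "exceed")
  expect_error(derive_severity_sd(0.05, 0.01), "exceed")
})

test_that("efficacy calibration hits the 1e-10 floor over the plan duration", {
  # (1e-9)^(1/9) = 0.1 analytically, so eta = 0.9
  expect_equal(calibrate_efficacy(0.1, 9), 0.9, tolerance = 1e-12)
  expect_equal(calibrate_efficacy(0.5, 1), 1 - 2e-10, tolerance = 1e-12)
  expect_error(calibrate_efficacy(0.5, 1, floor = 0.6), "floor")

  set.seed(4)
  for (i in 1:20) {
    mu <- stats::runif(1, 1e-4, 0.9)
    dur <- sample(1:300, 1)
    eta <- calibrate_efficacy(mu, dur)
    expect_equal(treatment_closed_form(mu, eta, dur), 1e-10,
                 tolerance = 1e-13)
  }
})
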