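test_that("repair_fraction matches closed forms and the Weibull CDF", {
  expect_equal(repair_fraction(kjma_params(1.7, 45, 0.6), 0), 0)
  expect_equal(repair_fraction(kjma_params(1, 60, 1), 60), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(repair_fraction(kjma_params(2, 60, 0.8), 120),
               0.8 * (1 - exp(-4)), tolerance = 1e-12)
  # f(t)/theta is identically the Weibull(shape m, scale tau) CDF
  for (m in c(0.6, 1, 1.8, 3.2)) for (tau in c(25, 60, 140)) {
    p <- kjma_params(m, tau, 0.77)
    t <- seq(0.5, 300, length.out = 60)
    expect_lt(max(abs(repair_fraction(p, t) / 0.77 - pweibull(t, m, tau))),
              1e-12)
  }
  expect_error(repair_fraction(kjma_params(1, 60, 1), -1), "negative")
})

test_that("repair_fraction is monotone and bounded by theta", {
  set.seed(1)
  for (i in 1:20) {
    p <- kjma_params(runif(1, 0.5, 4), runif(1, 20, 200), runif(1, 0.2, 1))
    f <- repair_fraction(p, seq(0, 600, by = 1))
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= p$theta))
  }
})

test_that("repair_rate matches its limits, a numerical derivative, and integrates to theta", {
  expect_equal(repair_rate(kjma_params(1, 60, 0.8), 0), 0.8 / 60,
               tolerance = 1e-12)
  expect_equal(repair_rate(kjma_params(2, 60, 0.8), 0), 0)
  expect_error(repair_rate(kjma_params(0.7, 60, 0.8), 0), "diverges")
  for (m in c(0.7, 1.3, 2, 3)) for (tau in c(30, 60, 150)) {
    p <- kjma_params(m, tau, 0.8)
    for (t in c(10, 30, 60, 120)) {
      # skip saturated points and negligible rates, where the finite
      # difference of nearly equal fractions is roundoff, not signal
      if ((t / tau)^m > 30 || repair_rate(p, t) < 1e-4) next
      h <- 1e-6 * t
      num <- (repair_fraction(p, t + h) - repair_fraction(p, t - h)) / (2 * h)
      expect_lt(abs(repair_rate(p, t) - num) / num, 1e-6)
    }
    total <- integrate(function(x) repair_rate(p, x), 0, Inf,
                       rel.tol = 1e-10)$value
    expect_lt(abs(total - 0.8), 1e-6)
    expect_true(all(repair_rate(p, seq(0.1, 400, by = 0.5)) >= 0))
  }
})

test_that("linearization is exactly collinear on noiseless data and drops zero points", {
  v <- kjma_forward(2, 60, 0.8, c(20, 60, 120))
  lin <- kjma_linearize(c(20, 60, 120), v, 0.8)
  expect_equal(nrow(lin), 3L)
  slopes <- diff(lin$y) / diff(lin$log_t)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-10)
  expect_equal(slopes[1], 2, tolerance = 1e-10)
  # at t = tau with exact theta: y = 0 at x = ln tau
  at_tau <- kjma_linearize(c(30, 60), kjma_forward(2, 60, 0.8, c(30, 60)), 0.8)
  expect_equal(at_tau$y[2], 0, tolerance = 1e-12)
  expect_equal(at_tau$log_t[2], log(60))
  # zero-repair exclusion
  lin0 <- kjma_linearize(c(20, 60, 120), c(0, 0.3, 0.5), 0.8)
  expect_equal(nrow(lin0), 2L)
  expect_equal(attr(lin0, "n_dropped"), 1L)
  expect_error(kjma_linearize(c(20, 60), c(0.3, 0.5), 0.45),
               class = "repairkinetics_infeasible_theta")
  # theta exactly at an observed value: the point saturates and is dropped
  expect_error(kjma_linearize(c(20, 60), c(0.3, 0.5), 0.5),
               class = "repairkinetics_unfittable")
  sat <- kjma_linearize(c(20, 60, 120), c(0.2, 0.4, 0.5), 0.5)
  expect_equal(nrow(sat), 2L)
  expect_equal(attr(sat, "n_dropped"), 1L)
  expect_error(kjma_linearize(c(20, 60, 120), c(0, 0, 0.5), 0.8),
               class = "repairkinetics_unfittable")
})

test_that("fit for a fixed theta recovers noiseless parameters and flags failures", {
  v <- kjma_forward(2, 60, 0.8, c(20, 60, 120))
  fit <- kjma_fit_theta(c(20, 60, 120), v, 0.8)
  expect_true(fit$ok)
  expect_equal(fit$m, 2, tolerance = 1e-6)
  expect_equal(fit$tau, 60, tolerance = 1e-3 / 60)
  expect_equal(fit$adj_r2, 1)
  # two-point course: exact interpolation, degenerate flag
  fit2 <- kjma_fit_theta(c(20, 120), c(0.2, 0.6), 0.8)
  expect_true(fit2$ok && fit2$degenerate)
  expect_equal(fit2$adj_r2, 1)
  # decreasing pairs give a non-positive slope: invalid marker, no error
  fit3 <- kjma_fit_theta(c(20, 60, 120), c(0.6, 0.4, 0.2), 0.9)
  expect_false(fit3$ok)
  expect_match(fit3$reason, "slope")
})

test_that("theta grid search selects near the true theta and respects feasibility", {
  v <- kjma_forward(2, 60, 0.8, c(20, 60, 120))
  fit <- kjma_fit(c(20, 60, 120), v, theta_min = 0.4)
  expect_true(fit$theta %in% c(0.79, 0.80, 0.81))
  expect_lt(abs(fit$m - 2) / 2, 0.05)
  expect_equal(fit$adj_r2, 1)
  expect_equal(fit$beta * fit$tau, 1)
  # max value 0.95 restricts the grid to theta > 0.95
  v95 <- kjma_forward(1.5, 30, 0.97, c(20, 60, 120))
  expect_gt(max(v95), 0.95)
  fit95 <- kjma_fit(c(20, 60, 120), v95, theta_min = 0.4)
  expect_gt(fit95$theta, 0.95)
  # all-zero course is unfittable
  expect_error(kjma_fit(c(20, 60, 120), c(0, 0, 0)),
               class = "repairkinetics_unfittable")
})

test_that("fit is invariant to duplicating every (t, value) pair", {
  set.seed(7)
  for (i in 1:10) {
    m <- runif(1, 0.8, 3); tau <- runif(1, 30, 150)
    theta <- sample(seq(0.5, 0.95, by = 0.01), 1)
    v <- kjma_forward(m, tau, theta, c(20, 60, 120)) *
      (1 + rnorm(3, 0, 0.02))
    v <- rectify(pmin(v, theta - 1e-6))
    f1 <- tryCatch(kjma_fit(c(20, 60, 120), v), error = function(e) NULL)
    f2 <- tryCatch(kjma_fit(rep(c(20, 60, 120), 2), rep(v, 2)),
                   error = function(e) NULL)
    if (is.null(f1)) { expect_null(f2); next }
    expect_equal(f1$m, f2$m, tolerance = 1e-10)
    expect_equal(f1$tau, f2$tau, tolerance = 1e-10)
    expect_equal(f1$theta, f2$theta)
  }
})

test_that("noiseless round-trip recovers any grid theta exactly", {
  set.seed(42)
  n_done <- 0
  while (n_done < 25) {
    m <- runif(1, 0.6, 4); tau <- runif(1, 25, 180)
    if ((120 / tau)^m > 25) next  # saturated by 120 min: shape not invertible
    n_done <- n_done + 1
    theta <- sample(seq(0.41, 1, by = 0.01), 1)
    v <- kjma_forward(m, tau, theta, c(20, 60, 120))
    fit <- kjma_fit(c(20, 60, 120), v, theta_min = 0.4)
    expect_equal(fit$theta, theta, tolerance = 1e-9)
    expect_lt(abs(fit$m - m) / m, 1e-3)
    expect_lt(abs(fit$tau - tau) / tau, 1e-3)
    expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  }
})

test_that("parameter filter applies the m and tau ranges", {
  expect_true(filter_params(kjma_params(2, 60, 0.8)))
  expect_false(filter_params(kjma_params(0.4, 60, 0.8)))
  expect_false(filter_params(kjma_params(2, 250, 0.8)))
  expect_false(filter_params(kjma_params(6, 60, 0.8)))
  expect_true(filter_params(kjma_params(6, 250, 0.8),
                            m_range = c(0.5, 10), tau_range = c(20, 300)))
})

test_that("batch fitting tabulates regions and tolerates unfittable ones", {
  v1 <- kjma_forward(2, 60, 0.8, c(20, 60, 120))
  courses <- rbind(
    data.frame(region_id = "good", time = c(20, 60, 120), value = v1),
    data.frame(region_id = "dead", time = c(20, 60, 120), value = c(0, 0, 0)))
  fits <- fit_regions(courses, tcr = c(good = TRUE, dead = FALSE))
  expect_equal(nrow(fits), 2L)
  good <- fits[fits$region_id == "good", ]
  expect_equal(good$class, "TCR")
  expect_equal(good$m, 2, tolerance = 1e-3)
  expect_true(good$passes_filter)
  dead <- fits[fits$region_id == "dead", ]
  expect_true(is.na(dead$m))
  expect_false(dead$passes_filter)
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fits(fits, path)
  back <- read_fits(path)
  expect_equal(back$m, fits$m, tolerance = 1e-12)
  expect_equal(back$region_id, fits$region_id)
})
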