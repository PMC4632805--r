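test_that("trapezoidal AUC matches closed forms", {
  # constant signal, normalized: area equals window length
  expect_equal(curve_auc(0:10, rep(3, 11)), 10)
  # linear decay 1 -> 0 over [0, T]: area T/2
  expect_equal(curve_auc(seq(0, 8, by = 0.5), seq(1, 0, length.out = 17)), 4)
  # exponential decay sampled at 60-s steps vs the analytic trapezoid sum
  k <- 0.3
  times <- seq(0, 60, by = 1)
  auc <- curve_auc(times, exp(-k * times))
  expect_equal(auc, oracle_trapz_exp(k, 1, 60), tolerance = 1e-12)
  # and within the trapezoid error bound of the true integral
  analytic <- (1 - exp(-k * 60)) / k
  expect_lt(abs(auc - analytic), 60 * 1^2 * k^2 / 12)
})

test_that("AUC is additive over partitions and invariant to collinear points", {
  t1 <- seq(0, 30, by = 1)
  t2 <- seq(30, 60, by = 1)
  tt <- seq(0, 60, by = 1)
  sig <- function(t) 2 * exp(-0.1 * t)
  expect_equal(
    curve_auc(tt, sig(tt), normalize = FALSE),
    curve_auc(t1, sig(t1), normalize = FALSE) + curve_auc(t2, sig(t2), normalize = FALSE)
  )
  # inserting the midpoint of a straight segment changes nothing
  t_lin <- c(0, 10, 20)
  s_lin <- c(4, 3, 2)
  expect_equal(
    curve_auc(t_lin, s_lin, normalize = FALSE),
    curve_auc(c(0, 5, 10, 20), c(4, 3.5, 3, 2), normalize = FALSE)
  )
})

test_that("curve validation rejects malformed kinetics", {
  expect_error(curve_auc(0, 1), "at least 2")
  expect_error(curve_auc(c(0, 1, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(curve_auc(c(0, 1), c(1, -1)), "non-negative")
  expect_error(curve_auc(c(0, 1), c(0, 1), normalize = TRUE), "normalize")
})

test_that("net AUC subtracts the blank", {
  tt <- 0:60
  same <- tibble::tibble(time = tt, signal = exp(-0.2 * tt))
  expect_equal(net_auc(same, same), 0)
  # fully protected sample vs immediately decayed blank approaches T
  sample <- tibble::tibble(time = tt, signal = rep(5, 61))
  blank <- tibble::tibble(time = tt, signal = exp(-2 * tt))
  expect_gt(net_auc(sample, blank), 59)
  expect_lt(net_auc(sample, blank), 60)
})

test_that("TEAC response is the interpolated OD decline at the read time", {
  tt <- 0:41
  control <- tibble::tibble(time = tt, signal = rep(0.70, 42))
  sample <- tibble::tibble(time = tt, signal = rep(0.45, 42))
  expect_equal(teac_response(sample, control, 40.5), 0.25)
  expect_equal(teac_response(sample, sample, 40.5), 0)
  # interpolation at 40.5 between the 40- and 41-min points is the midpoint
  ramp <- tibble::tibble(time = tt, signal = 0.5 + 0.01 * tt)
  expect_equal(
    teac_response(control, ramp, 40.5),
    (0.5 + 0.01 * 40.5) - 0.70
  )
  expect_error(teac_response(sample, control, 45), "outside")
})

test_that("calibration fit recovers exact lines and matches normal equations", {
  cal <- fit_calibration(1:10, 0.02 * (1:10) + 0.01)
  expect_equal(cal$slope, 0.02)
  expect_equal(cal$intercept, 0.01)
  expect_equal(cal$r_squared, 1)

  # noisy data vs closed-form OLS
  withr::with_seed(5, {
    x <- rep(1:10, each = 4)
    y <- 0.05 * x + 0.002 + rnorm(40, 0, 0.003)
  })
  cal2 <- fit_calibration(x, y)
  beta <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(cal2$slope, beta, tolerance = 1e-10)
  expect_equal(cal2$intercept, alpha, tolerance = 1e-10)

  expect_error(fit_calibration(rep(5, 4), 1:4), "distinct")
  expect_error(fit_calibration(1:3, 1:2), "length mismatch")
})

test_that("trolox-equivalent conversion is self-consistent", {
  cal <- fit_calibration(1:10, 0.03 * (1:10))
  # a sample responding like c uM trolox at c uM has AOC 1
  expect_equal(aoc_trolox_equivalents(0.03 * 4, cal, 4), 1)
  # same response at half the concentration doubles the AOC
  expect_equal(aoc_trolox_equivalents(0.03 * 4, cal, 2), 2)
  flat <- fit_calibration(1:10, rep(1, 10))
  flat$slope <- 0 # degenerate calibration: responses carry no information
  expect_error(aoc_trolox_equivalents(1, flat, 1), "slope")
  expect_error(aoc_trolox_equivalents(1, cal, -1), "positive")
  expect_error(aoc_trolox_equivalents(1, "x", 1), "aox_calibration")
})

test_that("final in-well concentration follows the dilution layout", {
  expect_equal(final_concentration(100, 20, 200), 10)
  expect_equal(final_concentration(c(50, 100)), c(5, 10))
  expect_error(final_concentration(100, 20, 0), "invalid")
})

test_that("noise-free plates round-trip the configured TE values exactly", {
  te <- c(Tyr = 1.02, Trp = 2.79)
  res <- tidy(orac_aoc(sim_orac_plate(te, seed = 1)))
  expect_equal(res$aoc[match(names(te), res$sample_id)], unname(te), tolerance = 1e-12)

  te2 <- c(Tyr = 3.38, Trp = 3.33, Cys = 2.04)
  res2 <- tidy(teac_aoc(sim_teac_plate(te2, seed = 1)))
  expect_equal(res2$aoc[match(names(te2), res2$sample_id)], unname(te2), tolerance = 1e-12)

  # calibration is an exact line in the noise-free case
  expect_equal(glance(orac_aoc(sim_orac_plate(te, seed = 1)))$r_squared, 1)
})

test_that("AOC is invariant to a common response rescaling", {
  plate <- sim_orac_plate(c(S = 2.0), seed = 7)
  scaled <- dplyr::mutate(plate, signal = signal * 3.7)
  expect_equal(tidy(orac_aoc(scaled))$aoc, tidy(orac_aoc(plate))$aoc, tolerance = 1e-12)
})

test_that("plate validation catches schema and monotonicity problems", {
  plate <- sim_orac_plate(c(S = 1), seed = 1)
  expect_error(orac_aoc(plate[, -1]), "missing column")
  dup <- dplyr::bind_rows(plate, plate[1, ])
  expect_error(orac_aoc(dup), "duplicate time")
  bad_role <- dplyr::mutate(plate, role = ifelse(role == "blank", "mystery", role))
  expect_error(orac_aoc(bad_role), "unknown role")
  # seconds input converts to minutes
  secs <- dplyr::mutate(plate, time = time * 60)
  expect_equal(
    tidy(orac_aoc(secs, time_unit = "s"))$aoc,
    tidy(orac_aoc(plate))$aoc,
    tolerance = 1e-12
  )
})
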