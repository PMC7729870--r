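# Calibration-curve parsing, interpolation, mixing, posteriors and HPD.

test_that("curve files parse, sort and reject malformed input", {
  f <- tempfile(fileext = ".14c")
  writeLines(c("# header comment", "100,500,10,0,0", "0,400,8,0,0",
               "200, 620, 12, 0, 0"), f)
  cv <- read_curve(f, name = "tiny")
  expect_s3_class(cv, "calibration_curve")
  expect_equal(cv$cal_bp, c(0, 100, 200))        # sorted regardless of file order
  expect_equal(cv$c14_age, c(400, 500, 620))
  writeLines(c("0,400,8", "100,oops,10"), f)
  expect_error(read_curve(f), "line 2")
  writeLines(c("# only", "0,400,8"), f)
  expect_error(read_curve(f), "fewer than 2")
  expect_error(read_curve(tempfile()), "not found")
})

test_that("curve interpolation is exact at knots and matches a brute-force oracle", {
  cv <- calibration_curve("t", c(0, 50, 120, 300), c(400, 500, 430, 700),
                          c(8, 12, 9, 20))
  at <- curve_at(cv, c(0, 50, 120, 300))
  expect_equal(at$mu, c(400, 500, 430, 700))
  expect_equal(at$sigma, c(8, 12, 9, 20))
  expect_equal(curve_at(cv, 25)$mu, 450)          # midpoint of 400 and 500
  grid <- seq(0, 300, by = 0.7)
  got <- curve_at(cv, grid)
  expect_equal(got$mu, interp_oracle(cv$cal_bp, cv$c14_age, grid), tolerance = 1e-9)
  expect_equal(got$sigma, interp_oracle(cv$cal_bp, cv$c14_sigma, grid), tolerance = 1e-9)
  expect_error(curve_at(cv, -1), "domain")
  expect_error(curve_at(cv, 301), "domain")
})

test_that("curve mixing weights components and propagates reservoir uncertainty", {
  atm <- synth_curve("constant", c(0, 100), c = 400, sigma = 5, name = "atm")
  mar <- synth_curve("constant", c(0, 100), c = 800, sigma = 7, name = "mar")
  # f = 0: bit-identical to the atmospheric curve, reservoir ignored
  s0 <- mixed_curve_spec(atm, mar, 0, reservoir_correction(500, 500))
  expect_identical(mix_curves(s0, c(10, 50)), curve_at(atm, c(10, 50)))
  # f = 1 with delta R = 53: marine + offset, sigma in quadrature
  s1 <- mixed_curve_spec(atm, mar, 1, reservoir_correction(53, 63))
  got <- mix_curves(s1, 50)
  expect_equal(got$mu, 853)
  expect_equal(got$sigma, sqrt(7^2 + 63^2))
  # worked arithmetic: 0.749 * 400 + 0.251 * (800 + 53) = 513.703
  atm0 <- synth_curve("constant", c(0, 100), c = 400, sigma = 0)
  mar0 <- synth_curve("constant", c(0, 100), c = 800, sigma = 0)
  sm <- mixed_curve_spec(atm0, mar0, 0.251, reservoir_correction(53, 0))
  expect_equal(mix_curves(sm, 50)$mu, 513.703)
  # mu is monotone in f when marine + delta R exceeds atmospheric
  mus <- vapply(seq(0, 1, 0.1), function(f) {
    mix_curves(mixed_curve_spec(atm, mar, f, reservoir_correction(53, 0)), 50)$mu
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
  expect_error(mix_curves(s1, 101), "overlap")
  disjoint <- synth_curve("constant", c(500, 600), c = 1)
  expect_error(mixed_curve_spec(atm, disjoint, 0.5), "overlap")
})

test_that("a constant curve yields a uniform posterior; posteriors are normalised", {
  cv <- synth_curve("constant", c(0, 200), c = 410, sigma = 0)
  post <- calibrate(radiocarbon_date(410, 30), cv)
  expect_equal(sum(post$density), 1, tolerance = 1e-9)
  expect_true(all(post$density >= 0))
  expect_equal(max(post$density) - min(post$density), 0, tolerance = 1e-12)
})

test_that("the linear-curve posterior recovers the Gaussian closed form", {
  cv <- synth_curve("linear", c(0, 1200), a = 0, b = 1, sigma = 0)
  post <- calibrate(radiocarbon_date(400, 30), cv)
  s <- posterior_summary(post)
  expect_lt(abs(s["mean"] - 400), 0.5)
  expect_lt(abs(s["sd"] - 30) / 30, 0.01)
  # property over random dates
  set.seed(31)
  for (i in 1:10) {
    age <- round(runif(1, 200, 1000))
    sig <- round(runif(1, 15, 60))
    p <- calibrate(radiocarbon_date(age, sig), cv)
    expect_equal(sum(p$density), 1, tolerance = 1e-9)
    ss <- posterior_summary(p)
    expect_lt(abs(ss["mean"] - age), 0.5)
    expect_lt(abs(ss["sd"] - sig) / sig, 0.01)
  }
})

test_that("HPD ranges match Gaussian quantiles and handle multimodality", {
  cv <- synth_curve("linear", c(0, 1200), a = 0, b = 1, sigma = 0)
  post <- calibrate(radiocarbon_date(400, 30), cv)
  h <- hpd_ranges(post, 0.954)
  expect_equal(nrow(h$ranges), 1)
  expect_lt(abs(h$ranges$cal_bp_end - 340), 1 + post$grid_step)   # ~mean - 2 sd
  expect_lt(abs(h$ranges$cal_bp_start - 460), 1 + post$grid_step) # ~mean + 2 sd
  expect_gte(sum(h$ranges$mass), 0.954)
  # equal mixture of two well-separated Gaussians: two ~0.477 ranges
  grid <- seq(0, 1000, 1)
  dens <- dnorm(grid, 250, 20) + dnorm(grid, 750, 20)
  bi <- structure(list(grid = grid, density = dens / sum(dens), grid_step = 1),
                  class = "calendar_posterior")
  h2 <- hpd_ranges(bi, 0.954)
  expect_equal(nrow(h2$ranges), 2)
  expect_equal(h2$ranges$mass, c(0.477, 0.477), tolerance = 0.01)
  # near-total level covers at least that much mass
  h3 <- hpd_ranges(post, 0.999)
  expect_gte(sum(h3$ranges$mass), 0.999)
})

test_that("HPD regions are minimal and nested", {
  set.seed(12)
  for (rep in 1:5) {
    grid <- seq(0, 39, 1)
    dens <- runif(40)^2
    post <- structure(list(grid = grid, density = dens / sum(dens), grid_step = 1),
                      class = "calendar_posterior")
    for (level in c(0.5, 0.8, 0.954)) {
      h <- hpd_ranges(post, level)
      width <- sum(h$ranges$cal_bp_start - h$ranges$cal_bp_end + 1)
      # brute force: smallest contiguous window holding >= level mass
      best <- Inf
      for (i in 1:40) for (j in i:40) {
        if (sum(post$density[i:j]) >= level) { best <- min(best, j - i + 1); break }
      }
      expect_lte(width, best)
    }
    # nesting: selected grid points at a lower level are a subset
    sel_points <- function(level) {
      h <- hpd_ranges(post, level)
      unlist(lapply(seq_len(nrow(h$ranges)), function(i) {
        seq(h$ranges$cal_bp_end[i], h$ranges$cal_bp_start[i])
      }))
    }
    expect_true(all(sel_points(0.5) %in% sel_points(0.8)))
    expect_true(all(sel_points(0.8) %in% sel_points(0.954)))
  }
})

test_that("a wiggle curve crossing the measured age three times gives three HPD modes", {
  cv <- synth_curve("wiggle", domain = c(150, 700), a = 0, b = 1,
                    amplitude = 80, period = 150, sigma = 0)
  expect_equal(sum(diff(sign(cv$c14_age - 410)) != 0), 3)  # crossing count
  post <- calibrate(radiocarbon_date(410, 8), cv)
  h <- hpd_ranges(post, 0.7)
  expect_equal(nrow(h$ranges), 3)
})

test_that("refining the grid step moves range endpoints by at most the coarse step", {
  cv <- synth_curve("wiggle", domain = c(150, 700), a = 0, b = 1,
                    amplitude = 80, period = 150, sigma = 10)
  d <- radiocarbon_date(410, 30)
  h5 <- hpd_ranges(calibrate(d, cv, grid_step = 5), 0.954)$ranges
  h1 <- hpd_ranges(calibrate(d, cv, grid_step = 1), 0.954)$ranges
  expect_equal(nrow(h5), nrow(h1))
  expect_true(all(abs(h5$cal_ad_start - h1$cal_ad_start) <= 5))
  expect_true(all(abs(h5$cal_ad_end - h1$cal_ad_end) <= 5))
})

test_that("marine-fraction uncertainty widens the posterior via quadrature", {
  atm <- synth_curve("linear", c(0, 1200), a = 0, b = 1, sigma = 0, name = "atm")
  mar <- synth_curve("linear", c(0, 1200), a = 400, b = 1, sigma = 0, name = "mar")
  d <- radiocarbon_date(600, 20)
  point <- mixed_curve_spec(atm, mar, 0.25)
  p0 <- calibrate(d, point)
  # sigma = 0 takes the point-fraction path exactly
  zero <- mixed_curve_spec(atm, mar, 0.25, marine_fraction_sigma = 0)
  expect_identical(calibrate(d, zero)$density, p0$density)
  s0 <- posterior_summary(p0)
  expect_lt(abs(s0["mean"] - 500), 0.5)
  expect_lt(abs(s0["sd"] - 20) / 20, 0.01)
  # f ~ N(0.25, 0.05) shifts 400 14C yr per unit f: extra sd = 400 * 0.05
  unc <- mixed_curve_spec(atm, mar, 0.25, marine_fraction_sigma = 0.05)
  su <- posterior_summary(calibrate(d, unc))
  expect_lt(abs(su["mean"] - 500), 1)
  expect_lt(abs(su["sd"] - sqrt(20^2 + 20^2)) / 28.28, 0.05)
  expect_equal(sum(calibrate(d, unc)$density), 1, tolerance = 1e-9)
  # a date with no likelihood anywhere on the grid is rejected
  expect_error(calibrate(radiocarbon_date(1e6, 1), atm), "no support")
})

test_that("calendar BP / AD conversion follows the 1950 convention", {
  expect_equal(cal_bp_to_ad(0), 1950)
  expect_equal(cal_bp_to_ad(484), 1466)
  expect_equal(cal_bp_to_ad(2), 1948)
})
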