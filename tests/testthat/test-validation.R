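# independent brute-force evaluation of the skill index, written before the
# implementation and kept deliberately literal
skill_brute <- function(M, D) {
  dbar <- sum(D) / length(D)
  num <- 0; den <- 0
  for (i in seq_along(D)) {
    num <- num + abs(M[i] - D[i])^2
    den <- den + (abs(M[i] - dbar) + abs(D[i] - dbar))^2
  }
  1 - num / den
}

test_that("willmott skill matches the brute-force evaluator on random pairs", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    D <- rnorm(n, sd = runif(1, 0.1, 10))
    M <- D + rnorm(n, sd = runif(1, 0, 5))
    s <- willmott_skill(M, D)
    expect_rel_equal(s$skill, skill_brute(M, D), 1e-12)
  }
})

test_that("skill is 1 iff the series agree, and shift-invariant", {
  D <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(willmott_skill(D, D)$skill, 1)
  expect_equal(willmott_skill(D, D)$rating, "excellent")
  M <- c(1, 2, 3, 4)
  s <- willmott_skill(M, D)
  expect_lt(s$skill, 1)
  expect_rel_equal(s$skill, skill_brute(M, D), 1e-12)
  # common shift of both series leaves the skill unchanged
  expect_equal(willmott_skill(M + 100, D + 100)$skill, s$skill,
               tolerance = 1e-12)
  # degenerate cases: constant observations still score when the model
  # deviates symmetrically, and a constant perfect match scores 1
  expect_equal(willmott_skill(c(2, 2), c(2, 2))$skill, 1)
  expect_equal(willmott_skill(c(1, 3), c(2, 2))$skill, 0)
  expect_error(willmott_skill(1, 1), "at least 2")
})

test_that("skill rating bands follow the standard rating cut points", {
  rate <- function(s) bayfate:::.skill_rating(s)
  expect_equal(rate(0.75), "excellent")
  expect_equal(rate(0.15), "poor")
  expect_equal(rate(0.35), "medium")
  expect_equal(rate(0.6), "good")
  # boundary values belong to the band below
  expect_equal(rate(0.2), "poor")
  expect_equal(rate(0.5), "medium")
  expect_equal(rate(0.7), "good")
})

test_that("direction series are compared on the circle", {
  # identical directions modulo wrap give perfect skill
  D <- c(350, 355, 5, 10, 15)
  M <- D + 360
  expect_equal(willmott_skill(M, D, circular = TRUE)$skill, 1)
  # small angular scatter across the wrap scores far better than the naive
  # linear comparison would
  M2 <- c(352, 353, 3, 12, 13)
  s_circ <- willmott_skill(M2, D, circular = TRUE)$skill
  expect_gt(s_circ, 0.5)
})

test_that("equilibration time finds the earliest stable window", {
  # reference evaluation of the windowed rule, coded independently
  equil_brute <- function(tt, vv, w, tol, k) {
    W <- floor(max(tt) / w)
    means <- sapply(seq_len(W), function(q) mean(vv[tt > (q - 1) * w & tt <= q * w]))
    for (w0 in seq_len(W - k)) {
      ok <- TRUE
      for (l in seq_len(k)) {
        rel <- abs(means[w0 + l] - means[w0 + l - 1]) /
          max(abs(means[w0 + l - 1]), .Machine$double.eps)
        if (rel >= tol) { ok <- FALSE; break }
      }
      if (ok) return(w0 * w)
    }
    NA_real_
  }
  tt <- seq(600, 40 * 86400, by = 600)
  # constant series stabilizes at the first window boundary
  s_const <- obs_series(tt, rep(3.5, length(tt)))
  expect_equal(equilibration_time(s_const, 86400, 0.01, 3), 86400)
  # linear growth never stabilizes
  s_lin <- obs_series(tt, tt / 86400)
  expect_true(is.na(equilibration_time(s_lin, 86400, 0.01, 3)))
  # saturating curve a(1 - exp(-t/tau)), tau = 5 d, 1% tolerance over 3
  # windows: the windowed rule fires at day 16 (frozen from the closed-form
  # window means: the first day-to-day relative change below 1% is the
  # 16 -> 17 transition)
  tau <- 5 * 86400
  s_sat <- obs_series(tt, 10 * (1 - exp(-tt / tau)))
  t_star <- equilibration_time(s_sat, 86400, 0.01, 3)
  expect_equal(t_star, equil_brute(tt, s_sat$value, 86400, 0.01, 3))
  expect_equal(t_star, 16 * 86400)
  # agreement with the reference on noisy random series
  set.seed(5)
  for (rep in 1:20) {
    vv <- 10 * (1 - exp(-tt / (runif(1, 2, 8) * 86400))) + rnorm(length(tt), sd = 0.02)
    s <- obs_series(tt, vv)
    expect_identical(equilibration_time(s, 86400, 0.02, 3),
                     equil_brute(tt, vv, 86400, 0.02, 3))
  }
  expect_error(equilibration_time(obs_series(1:3 * 600, 1:3), 86400, 0.01, 3),
               "windows")
})

test_that("coordinate descent stays in bounds and honours its trace", {
  # cheap quadratic surrogate forward model over two parameters
  obs <- rep(0, 20)
  fwd <- function(th) (th[["a"]] - 0.3)^2 + (th[["b"]] - 7)^2 + 0.01 * seq_len(20)
  spec <- calibration_spec(
    data.frame(name = c("a", "b"), lower = c(0, 5), upper = c(1, 9),
               n_trials = c(11, 9)),
    objective = "min_rmse"
  )
  res <- calibrate(spec, obs, fwd)
  expect_equal(res$best[["a"]], 0.3, tolerance = 1e-12)
  expect_equal(res$best[["b"]], 7, tolerance = 1e-12)
  expect_equal(res$n_evaluations, 20)
  expect_equal(nrow(res$trace), 20)
  # the returned objective is the optimum of its own trace
  expect_equal(res$objective, min(res$trace$objective, na.rm = TRUE))
  expect_true(all(res$trace$a >= 0 & res$trace$a <= 1))
  expect_true(all(res$trace$b >= 5 & res$trace$b <= 9))
})

test_that("ties break toward the lower parameter value", {
  obs <- c(0, 0)
  fwd <- function(th) c(0, 0)  # every trial is a perfect, tied fit
  spec <- calibration_spec(
    data.frame(name = "a", lower = 1, upper = 1 + 1e-9, n_trials = 2),
    objective = "max_skill"
  )
  res <- calibrate(spec, obs, fwd)
  expect_equal(res$best[["a"]], 1)
  expect_equal(res$n_evaluations, 2)
})

test_that("forward failures are skipped with a warning; total failure errors", {
  obs <- rnorm(10)
  fwd_flaky <- function(th) {
    if (th[["a"]] < 0.5) stop("blown up")
    rep(th[["a"]], 10)
  }
  spec <- calibration_spec(
    data.frame(name = "a", lower = 0, upper = 1, n_trials = 5),
    objective = "min_rmse"
  )
  w <- testthat::capture_warnings(res <- calibrate(spec, obs, fwd_flaky))
  expect_true(all(grepl("failed", w)))
  expect_length(w, 2)
  expect_equal(sum(res$trace$ok), 3)
  expect_gte(res$best[["a"]], 0.5)
  fwd_dead <- function(th) stop("no")
  expect_error(suppressWarnings(calibrate(spec, obs, fwd_dead)),
               "calibration failed")
})
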