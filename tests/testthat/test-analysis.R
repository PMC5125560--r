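test_that("ton_toff integrates the switch log exactly", {
  none <- data.frame(time = numeric(0), state = integer(0))
  st <- ton_toff(none, t_end = 1000, initial_active = FALSE)
  expect_equal(st$t_on_total, 0)
  expect_equal(st$t_off_total, 1000)

  one <- data.frame(time = 400, state = 1L)
  st1 <- ton_toff(one, t_end = 1000)
  expect_equal(st1$t_on_total, 600)
  expect_equal(st1$t_off_total, 400)

  three <- data.frame(time = c(100, 300, 900), state = c(1L, 0L, 1L))
  st3 <- ton_toff(three, t_end = 1000)
  expect_equal(st3$t_on_total, 300)   # 200 + 100
  expect_equal(st3$t_off_total, 700)
  expect_equal(st3$n_on_events, 2)
  expect_equal(st3$n_off_events, 1)

  bad <- data.frame(time = c(300, 100), state = c(1L, 0L))
  expect_error(ton_toff(bad, t_end = 1000), "ordered")
})

test_that("t_on + t_off partitions [0, t_end] for random logs", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(0:40, 1)
    init <- sample(c(TRUE, FALSE), 1)
    log <- data.frame(time = sort(runif(n, 0, 977.3)),
                      state = rep_len(if (init) c(0L, 1L) else c(1L, 0L), n))
    st <- ton_toff(log, t_end = 977.3, initial_active = init)
    expect_identical(st$t_on_total + st$t_off_total, 977.3)
  }
})

test_that("n_transitions counts events and coalesces at finite resolution", {
  tr <- structure(list(
    switch_log = data.frame(time = c(10, 10.2, 10.4, 500),
                            state = c(1L, 0L, 1L, 0L)),
    t_end = 1000, initial_active = FALSE), class = "crowdsim_trajectory")
  expect_equal(n_transitions(tr), 4L)
  # at 1-min resolution the 10 -> 10.4 flicker collapses to one transition
  expect_equal(n_transitions(tr, resolution = 1), 2L)
})

test_that("estimate_rates implements both estimator variants", {
  mk <- function(on, off, non = 1, noff = 1)
    structure(list(t_on_total = on, t_off_total = off, n_on_events = non,
                   n_off_events = noff, t_end = on + off),
              class = "switch_stats")
  ag <- estimate_rates(list(mk(30, 10), mk(10, 30)), "aggregate")
  expect_equal(ag$k_plus, 1 / 20)
  expect_equal(ag$k_minus, 1 / 20)
  expect_equal(ag$K_eq, 1)

  pe <- estimate_rates(list(mk(100, 50, non = 10, noff = 9)), "per_event")
  expect_equal(pe$k_plus, 10 / 50)
  expect_equal(pe$k_minus, 9 / 100)

  expect_error(estimate_rates(list(mk(0, 10)), "aggregate"), "undefined")
})

test_that("per-event estimator recovers telegraph rates at n = 500", {
  kp <- 0.1; km <- 0.1
  stats <- lapply(1:500, function(i)
    ton_toff(wellmixed_ssa(list(k_plus = kp, k_minus = km, s_A = 0, s_R = 0,
                                delta_M = 0.1), t_end = 100, sample_dt = 100,
                           seed = 9000 + i)))
  est <- estimate_rates(stats, "per_event")
  n_on <- sum(vapply(stats, `[[`, numeric(1), "n_on_events"))
  n_off <- sum(vapply(stats, `[[`, numeric(1), "n_off_events"))
  expect_lt(abs(est$k_plus - kp), 3 * kp / sqrt(n_on))
  expect_lt(abs(est$k_minus - km), 3 * km / sqrt(n_off))
  expect_lt(abs(est$K_eq - 1), 0.1)
})

test_that("kurtosis follows the biased-moment convention", {
  expect_equal(kurtosis(c(0, 0, 1, 1)), 1)         # symmetric two-point mass
  set.seed(5)
  expect_lt(abs(kurtosis(rnorm(50000)) - 3), 0.1)  # Gaussian reference
  # Bernoulli(p) closed form (1 - 3pq) / (pq)
  p <- 0.2
  oracle <- (1 - 3 * p * (1 - p)) / (p * (1 - p))
  set.seed(6)
  expect_lt(abs(kurtosis(rbinom(2e5, 1, p)) - oracle), 0.15)
  expect_equal(kurtosis(c(0, 0, 1, 1), excess = TRUE), -2)
  expect_error(kurtosis(c(1, 2, 3)), "n >= 4")
  expect_error(kurtosis(rep(2, 10)), "zero-variance")
})

test_that("kurtosis >= 1 for nondegenerate samples", {
  set.seed(8)
  for (i in 1:20) {
    x <- switch(1 + i %% 4,
                rnorm(200), rexp(200), rbinom(200, 1, runif(1, 0.1, 0.9)),
                c(rep(0, 100), rep(1, 100)))
    expect_gte(kurtosis(x), 1)
  }
})

test_that("kde_curve normalises and finds the two expression modes", {
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  set.seed(9)
  x <- rnorm(500, 100, 10)
  k <- kde_curve(x)
  expect_true(all(k$density >= 0))
  expect_lt(abs(trapz(k$grid, k$density) - 1), 1e-3)
  kh <- kde_curve(x, bandwidth = k$bandwidth / 2)
  expect_lt(abs(trapz(kh$grid, kh$density) - 1), 1e-3)

  # mixture with tight masses at the two stable modes
  xx <- c(rnorm(800, 50, 5), rnorm(800, 500, 20))
  k2 <- kde_curve(xx)
  peaks <- k2$grid[which(diff(sign(diff(k2$density))) == -2) + 1]
  expect_true(any(abs(peaks - 50) < 15))
  expect_true(any(abs(peaks - 500) < 30))
  expect_error(kde_curve(rep(1, 5)), "distinct")
})

test_that("kurtosis-theta regression recovers the exact and null cases", {
  th <- c(0, 0.25, 0.5, 0.75, 1)
  fit <- fit_kurtosis_theta(th, 15 * th)
  expect_equal(fit$slope, 15)
  expect_lt(fit$p_value, 0.01)

  null <- fit_kurtosis_theta(th, rep(2, 5) + c(0.01, -0.01, 0, 0.01, -0.01))
  expect_gt(null$p_value, 0.05)
  expect_error(fit_kurtosis_theta(c(0.5, 0.5, 0.5), 1:3), "distinct")
})

test_that("noisy slope fits concentrate around the generating slope", {
  th <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  set.seed(10)
  slopes <- vapply(1:100, function(i)
    fit_kurtosis_theta(th, 15 * th + rnorm(6))$slope, numeric(1))
  expect_gt(mean(slopes >= 12 & slopes <= 18), 0.95)
})

test_that("the two effective-diffusion maps agree where they must", {
  expect_equal(dstar_from_theta(0, "big"), 1)
  expect_equal(dstar_from_theta(1, "big"), 0.1)
  expect_equal(dstar_from_theta(0.5, "big"), 0.55)
  expect_equal(dstar_from_theta(1, "small"), 0.6)
  expect_equal(dstar_from_kurtosis(0), 1)
  expect_equal(dstar_from_kurtosis(15), 0.1)
  expect_equal(dstar_from_kurtosis(5), 0.7)
  # agreement at the calibration points by construction
  expect_equal(dstar_from_kurtosis(15), dstar_from_theta(1, "big"))
  expect_warning(d <- dstar_from_kurtosis(17), "clipped")
  expect_equal(d, 0)
  expect_error(dstar_from_theta(1.2), "\\[0, 1\\]")
})

test_that("dstar mapping returns one monotone-composed pair per D", {
  w <- make_empty_world()
  r <- rate_constants(s_P = 0)
  expect_warning(
    map <- dstar_mapping_experiment(c(10, 2), w$lattice, w$chromatin, r,
                                    gene_voxel = 50, n_cells = 60,
                                    base_seed = 2, t_end = 200),
    "unstable")
  expect_equal(nrow(map), 2)
  expect_equal(map$D_star, dstar_from_kurtosis(map$kurtosis))
})

test_that("power_spectrum handles degenerate and sinusoidal input", {
  const <- list(rep(5, 256))
  sp <- power_spectrum(const, 1)
  expect_true(all(sp$power < 1e-20))

  tt <- 0:255
  sine <- list(sin(2 * pi * tt / 100))
  sps <- power_spectrum(sine, 1)
  expect_equal(sps$frequencies[which.max(sps$power)], 0.01, tolerance = 0.3)
  expect_error(power_spectrum(list(1:10, 1:9), 1), "grid")
})

test_that("well-mixed mRNA spectrum matches the telegraph closed form", {
  ks <- list(k_plus = 0.1, k_minus = 0.1, s_A = 50, s_R = 5, delta_M = 0.1)
  sims <- lapply(1:30, function(i)
    wellmixed_ssa(ks, t_end = 256, sample_dt = 1, seed = 1200 + i))
  sp <- power_spectrum(sims, 1)
  keep <- sp$frequencies <= 0.1  # below ~Nyquist/5: negligible aliasing
  th <- telegraph_spectrum(sp$frequencies[keep], 0.1, 0.1, 50, 5, 0.1)
  bins <- cut(log10(sp$frequencies[keep]), 4)
  ratio <- tapply(sp$power[keep], bins, mean) / tapply(th, bins, mean)
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("ks_bonferroni adjusts two-sample KS p-values", {
  set.seed(11)
  ref <- rnorm(300)
  same <- rnorm(300)
  far <- rnorm(100, 50)
  out <- ks_bonferroni(list(same = same, far = far, same2 = rnorm(300)), ref)
  expect_equal(out$p_adj, pmin(1, out$p_raw * 3))
  expect_false(out$reject[out$comparison == "same"])
  expect_true(out$reject[out$comparison == "far"])
  expect_equal(out$D[out$comparison == "far"], 1)  # disjoint supports
  expect_error(ks_bonferroni(list(), ref), "at least one")
  expect_error(ks_bonferroni(list(a = numeric(0)), ref), "empty")
})
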