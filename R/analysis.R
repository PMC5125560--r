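#' Total active and repressed promoter time of one trajectory
#'
#' Integrates the piecewise-constant promoter state exactly from the
#' event log, including the boundary intervals, so that
#' `t_on_total + t_off_total == t_end` to machine precision.
#'
#' @param switch_log data frame with `time` (strictly increasing, within
#'   `[0, t_end]`) and `state` (state after the switch: 1 = active,
#'   0 = repressed), or a `crowdsim_trajectory`.
#' @param t_end trajectory duration, min (taken from the trajectory if one
#'   is given).
#' @param initial_active promoter state at `t = 0` (ignored for a
#'   trajectory input).
#' @return Object of class `switch_stats`: list with `t_on_total`,
#'   `t_off_total` (min), event counts `n_on_events` (activations),
#'   `n_off_events` (deactivations) and `t_end`.
#' @export
ton_toff <- function(switch_log, t_end = NULL, initial_active = FALSE) {
  if (inherits(switch_log, "crowdsim_trajectory")) {
    t_end <- switch_log$t_end
    initial_active <- isTRUE(switch_log$initial_active) ||
      identical(switch_log$initial_active, 1L)
    switch_log <- switch_log$switch_log
  }
  if (is.null(t_end)) stop("`t_end` is required", call. = FALSE)
  tt <- switch_log$time
  ss <- switch_log$state
  if (length(tt) && (is.unsorted(tt, strictly = FALSE) ||
                     tt[1] < 0 || tt[length(tt)] > t_end))
    stop("switch log must be ordered within [0, t_end]", call. = FALSE)
  bounds <- c(0, tt, t_end)
  states <- c(as.integer(initial_active), ss)  # state on each interval
  dur <- diff(bounds)
  t_on <- sum(dur[states == 1L])
  structure(list(
    t_on_total = t_on,
    t_off_total = t_end - t_on,
    n_on_events = sum(ss == 1L),
    n_off_events = sum(ss == 0L),
    t_end = t_end
  ), class = "switch_stats")
}

#' Number of promoter transitions of a trajectory
#'
#' Event-exact by default (every binding and unbinding event counts).
#' With a `resolution`, the promoter state is read off a uniform grid of
#' that spacing instead, so switches briefer than the resolution — rapid
#' unbind/rebind events — coalesce and only transitions visible at that
#' sampling resolution are counted.  Crowding slows the TF's escape from
#' the gene's neighbourhood and thereby clusters switching into
#' sub-resolution rebinding flickers; the event-exact count is invariant
#' under a uniform slowdown of diffusion, while the resolution-limited
#' count decreases, which is what a sampled expression time course shows.
#'
#' @param trajectory a `crowdsim_trajectory`.
#' @param resolution optional sampling interval, min.
#' @return Integer transition count.
#' @export
n_transitions <- function(trajectory, resolution = NULL) {
  log <- trajectory$switch_log
  if (is.null(resolution)) return(nrow(log))
  if (resolution <= 0) stop("`resolution` must be positive", call. = FALSE)
  grid <- seq(0, trajectory$t_end, by = resolution)
  # state at each grid time from the event-exact log
  idx <- findInterval(grid, log$time)
  states <- c(as.integer(isTRUE(trajectory$initial_active) ||
                           identical(trajectory$initial_active, 1L)),
              log$state)[idx + 1L]
  sum(diff(states) != 0L)
}

#' Effective promoter rate constants from an ensemble of switch statistics
#'
#' Two estimators are provided.  `"aggregate"` (default) follows the
#' operative definition `k_plus = 1 / mean(t_off_total)` and
#' `k_minus = 1 / mean(t_on_total)` over per-trajectory total durations of
#' fixed-length runs; it is the right quantity for *relative* comparisons
#' between crowding conditions, but its absolute scale depends on `t_end`.
#' `"per_event"` is the maximum-likelihood rate of a two-state Markov
#' switch: `k_plus` = total activation events / total repressed time,
#' `k_minus` = total deactivation events / total active time, and recovers
#' the generating rates of telegraph data.
#'
#' @param stats list of `switch_stats` (or a list of trajectories).
#' @param variant `"aggregate"` or `"per_event"`.
#' @return Object of class `rate_estimates`: `k_plus`, `k_minus` (min^-1),
#'   `K_eq = k_plus / k_minus`, `estimator_variant`, `n_trajectories`.
#' @export
estimate_rates <- function(stats, variant = c("aggregate", "per_event")) {
  variant <- match.arg(variant)
  if (length(stats) == 0L) stop("need at least one trajectory", call. = FALSE)
  if (inherits(stats[[1L]], "crowdsim_trajectory"))
    stats <- lapply(stats, ton_toff)
  t_on <- vapply(stats, `[[`, numeric(1), "t_on_total")
  t_off <- vapply(stats, `[[`, numeric(1), "t_off_total")
  n_on <- vapply(stats, `[[`, numeric(1), "n_on_events")
  n_off <- vapply(stats, `[[`, numeric(1), "n_off_events")
  if (variant == "aggregate") {
    if (mean(t_off) <= 0 || mean(t_on) <= 0)
      stop("undefined rate: zero mean duration", call. = FALSE)
    k_plus <- 1 / mean(t_off)
    k_minus <- 1 / mean(t_on)
  } else {
    if (sum(t_off) <= 0 || sum(t_on) <= 0)
      stop("undefined rate: zero total duration", call. = FALSE)
    k_plus <- sum(n_on) / sum(t_off)
    k_minus <- sum(n_off) / sum(t_on)
  }
  structure(list(k_plus = k_plus, k_minus = k_minus,
                 K_eq = if (k_minus > 0) k_plus / k_minus else NA_real_,
                 estimator_variant = variant,
                 n_trajectories = length(stats)),
            class = "rate_estimates")
}

#' Moment kurtosis of a sample
#'
#' Pearson moment kurtosis `m4 / m2^2` with biased sample moments
#' (Gaussian reference value 3, sharp lower bound 1 attained by a
#' symmetric two-point mass).  This plain-moment convention, not excess
#' kurtosis, is the population noise readout used throughout the package;
#' set `excess = TRUE` to subtract 3.
#'
#' @param x numeric sample, `n >= 4`, non-degenerate.
#' @param excess subtract 3 (Gaussian-centred) if `TRUE`.
#' @return Dimensionless kurtosis.
#' @export
kurtosis <- function(x, excess = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("kurtosis needs n >= 4", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("kurtosis undefined for a zero-variance sample",
                    call. = FALSE)
  k <- mean((x - m)^4) / m2^2
  if (excess) k - 3 else k
}

#' Gaussian kernel density curve
#'
#' Density estimate on an automatic grid, with bandwidth by Scott's rule
#' (`sd(x) * n^(-1/5)`) unless overridden.
#'
#' @param x numeric sample, `n >= 2`, non-degenerate.
#' @param bandwidth optional numeric bandwidth override.
#' @param n_grid grid size.
#' @return List with `grid`, `density` (non-negative, integrating to ~1)
#'   and `bandwidth`.
#' @export
kde_curve <- function(x, bandwidth = NULL, n_grid = 512L) {
  x <- as.numeric(x)
  if (length(x) < 2L || stats::sd(x) == 0)
    stop("KDE needs at least 2 distinct values", call. = FALSE)
  bw <- if (is.null(bandwidth)) stats::sd(x) * length(x)^(-1 / 5) else bandwidth
  if (bw <= 0) stop("bandwidth must be positive", call. = FALSE)
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = n_grid)
  list(grid = d$x, density = d$y, bandwidth = bw)
}

#' Zero-intercept kurtosis-vs-crowdedness regression
#'
#' Fits `kurtosis = slope * theta` by least squares through the origin and
#' assesses significance with the Pearson product-moment correlation of
#' the (theta, kurtosis) pairs.
#'
#' @param theta crowdedness values (>= 3 distinct).
#' @param kurt matching kurtosis values.
#' @return List with `slope` (per unit theta), `p_value` (Pearson),
#'   `r` (correlation), `n`.
#' @export
fit_kurtosis_theta <- function(theta, kurt) {
  if (length(theta) != length(kurt))
    stop("`theta` and `kurt` lengths differ", call. = FALSE)
  if (length(unique(theta)) < 3L)
    stop("need at least 3 distinct theta values", call. = FALSE)
  if (stats::sd(theta) == 0)
    stop("`theta` must vary", call. = FALSE)
  slope <- sum(theta * kurt) / sum(theta^2)
  ct <- stats::cor.test(theta, kurt, method = "pearson")
  list(slope = slope, p_value = ct$p.value,
       r = unname(ct$estimate), n = length(theta))
}

#' Effective diffusion factor from the crowdedness parameter
#'
#' Expected voxel-average attenuation of a Bernoulli(theta) crowder
#' placement: `1 - 0.9 theta` (big crowders) or `1 - 0.4 theta` (small).
#'
#' @param theta crowdedness in `[0, 1]`.
#' @param size_class `"big"` or `"small"`.
#' @return `D*/D`, dimensionless.
#' @export
dstar_from_theta <- function(theta, size_class = c("big", "small")) {
  size_class <- match.arg(size_class)
  if (any(theta < 0 | theta > 1))
    stop("`theta` must lie in [0, 1]", call. = FALSE)
  delta <- crowder_delta[[size_class]]
  1 - (1 - delta) * theta
}

#' Effective diffusion factor from population kurtosis
#'
#' Composes the kurtosis-theta regression (slope 15 per unit theta, big
#' crowders) with the big-crowder attenuation line `1 - 0.9 theta`,
#' giving `D* = 1 - 0.06 * kurtosis`.  Values below 0 (kurtosis > 50/3,
#' outside the physical theta range) are clipped to 0 with a warning.
#'
#' @param kurt kurtosis value(s), >= 0.
#' @param slope kurtosis-theta slope; default the reference value 15.
#' @return `D*/D`, dimensionless.
#' @export
dstar_from_kurtosis <- function(kurt, slope = 15) {
  if (any(kurt < 0)) stop("kurtosis must be >= 0", call. = FALSE)
  d <- 1 - (0.9 / slope) * kurt
  if (any(d < 0)) {
    warning("kurtosis outside the physical theta range; D* clipped at 0")
    d <- pmax(d, 0)
  }
  d
}

#' Map free diffusion coefficients to effective ones via population kurtosis
#'
#' The crowding-free calibration behind the D -> D* curve: for each `D`,
#' simulate an uncrowded population (theta = 0), compute the end-point
#' mRNA kurtosis, and convert it with [dstar_from_kurtosis()].  A kurtosis
#' matching the crowded system at some theta identifies the effective
#' coefficient `D* = 1 - 0.9 theta` that crowding would produce.
#'
#' @param D_values free diffusion coefficients to sweep, um^2 min^-1.
#' @param lattice,chromatin,rates,gene_voxel,n_cells,base_seed,t_end
#'   population configuration (crowding is disabled; `rates$D_TF` is
#'   replaced by each `D`).
#' @param slope kurtosis-theta slope used in the mapping.
#' @return Data frame with one row per `D`: `D`, `kurtosis`, `D_star`.
#' @export
dstar_mapping_experiment <- function(D_values, lattice, chromatin, rates,
                                     gene_voxel, n_cells = 500L,
                                     base_seed = 1L, t_end = 1000,
                                     slope = 15) {
  if (n_cells < 100L)
    warning("n_cells < 100: kurtosis estimates will be unstable")
  rows <- lapply(seq_along(D_values), function(j) {
    r <- rates
    r$D_TF <- D_values[j]
    ens <- run_ensemble(lattice, chromatin, r, gene_voxel,
                        theta = 0, n_cells = n_cells,
                        base_seed = derive_seed(base_seed, j),
                        t_end = t_end, sample_dt = t_end)
    k <- kurtosis(endpoint_M(ens))
    data.frame(D = D_values[j], kurtosis = k,
               D_star = dstar_from_kurtosis(k, slope = slope))
  })
  do.call(rbind, rows)
}

#' Ensemble-averaged mRNA power spectrum
#'
#' Mean-subtracted periodogram of each uniformly sampled series,
#' `P(f) = (dt / n) |FFT(x - mean(x))|^2`, averaged across the ensemble
#' and returned on the one-sided frequency grid `f_j = j / (n dt)`,
#' `j = 1 .. floor(n/2)`.  With this normalisation the periodogram is an
#' (asymptotically unbiased) estimate of the two-sided spectral density,
#' directly comparable to [telegraph_spectrum()].
#'
#' @param series list of equal-length numeric mRNA series (or a list of
#'   trajectories, whose `M` series are used).
#' @param sample_dt sampling interval, min.
#' @return Object of class `spectrum_estimate`: `frequencies` (min^-1),
#'   `power`, `n_trajectories`.
#' @export
power_spectrum <- function(series, sample_dt) {
  if (length(series) == 0L) stop("need at least one series", call. = FALSE)
  if (inherits(series[[1L]], "crowdsim_trajectory"))
    series <- lapply(series, `[[`, "M")
  n <- length(series[[1L]])
  if (any(vapply(series, length, integer(1)) != n))
    stop("all series must share one uniform sampling grid", call. = FALSE)
  if (sample_dt <= 0) stop("`sample_dt` must be positive", call. = FALSE)
  nf <- n %/% 2L
  acc <- numeric(nf)
  for (x in series) {
    x <- as.numeric(x) - mean(x)
    p <- (sample_dt / n) * Mod(stats::fft(x))^2
    acc <- acc + p[2L:(nf + 1L)]
  }
  structure(list(frequencies = (1:nf) / (n * sample_dt),
                 power = acc / length(series),
                 n_trajectories = length(series)),
            class = "spectrum_estimate")
}

#' Closed-form mRNA spectrum of the telegraph-driven birth-death model
#'
#' Two-sided spectral density of the mRNA count when transcription
#' switches between `s_R` and `s_A` as a two-state Markov (telegraph)
#' process with rates `k_plus`, `k_minus`, and mRNA decays at `delta_M`:
#' the intrinsic birth-death Lorentzian plus the telegraph input filtered
#' through the first-order decay kernel,
#' `S(f) = (2<s> + S_s(2 pi f)) / (delta_M^2 + (2 pi f)^2)` with
#' `S_s(w) = 2 (s_A - s_R)^2 p (1-p) k / (k^2 + w^2)`, `k = k_plus +
#' k_minus`, `p = k_plus / k`.  Serves as an independent oracle for
#' [power_spectrum()] estimates.
#'
#' @param f frequencies, min^-1.
#' @param k_plus,k_minus telegraph switching rates, min^-1.
#' @param s_A,s_R active/repressed transcription rates, min^-1.
#' @param delta_M mRNA decay rate, min^-1.
#' @return Spectral density values at `f`.
#' @export
telegraph_spectrum <- function(f, k_plus, k_minus, s_A, s_R, delta_M) {
  w <- 2 * pi * f
  k <- k_plus + k_minus
  p <- k_plus / k
  s_mean <- p * s_A + (1 - p) * s_R
  S_s <- 2 * (s_A - s_R)^2 * p * (1 - p) * k / (k^2 + w^2)
  (2 * s_mean + S_s) / (delta_M^2 + w^2)
}

#' Bonferroni-corrected two-sample Kolmogorov-Smirnov comparisons
#'
#' Compares each sample set against a common reference distribution with
#' the two-sample KS test and multiplies the p-values by the number of
#' comparisons (capped at 1).
#'
#' @param sample_sets named list of numeric samples.
#' @param reference_set numeric reference sample.
#' @param alpha family-wise significance level for the decisions.
#' @return Data frame with `comparison`, `D` (KS statistic), `p_raw`,
#'   `p_adj`, `reject`.
#' @export
ks_bonferroni <- function(sample_sets, reference_set, alpha = 0.01) {
  if (length(sample_sets) == 0L)
    stop("need at least one comparison", call. = FALSE)
  if (length(reference_set) == 0L)
    stop("empty reference sample", call. = FALSE)
  if (any(vapply(sample_sets, length, integer(1)) == 0L))
    stop("empty sample in `sample_sets`", call. = FALSE)
  m <- length(sample_sets)
  nm <- names(sample_sets)
  if (is.null(nm)) nm <- paste0("set", seq_len(m))
  rows <- lapply(seq_len(m), function(i) {
    # counts carry ties; the asymptotic KS p-value is the standard choice
    kt <- suppressWarnings(stats::ks.test(sample_sets[[i]], reference_set,
                                          exact = FALSE))
    data.frame(comparison = nm[i], D = unname(kt$statistic),
               p_raw = kt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * m)
  out$reject <- out$p_adj < alpha
  out
}
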