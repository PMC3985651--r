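site_bit <- function(ens, site) {
  i <- match(site, ens$arch$sites$site_id)
  if (is.na(i)) stop("reference error: unknown site_id ", site, call. = FALSE)
  2^(i - 1)
}

#' First arrival times at a site
#'
#' Time of the first `bind` event at `site` in each replicate. Replicates in
#' which the site is never bound within the horizon are censored, not
#' dropped.
#'
#' @param ens An `fd_ensemble`.
#' @param site A site_id of the ensemble's architecture.
#' @return data.frame with columns `replicate`, `first_arrival` (seconds; NA
#'   when censored) and `censored`.
#' @export
first_arrivals <- function(ens, site) {
  site_bit(ens, site)  # validates the site
  t <- vapply(ens$trajectories, function(tr) {
    ev <- tr$events
    hit <- ev$kind == "bind" & ev$site == site
    if (any(hit)) ev$time[which(hit)[1]] else NA_real_
  }, numeric(1))
  data.frame(replicate = seq_along(t), first_arrival = t,
             censored = is.na(t))
}

#' Log ratio of first-arrival times of two sites
#'
#' Per-replicate `ln(t1 / t2)` of the first arrivals at the two sites; the
#' quantity whose bimodality distinguishes switch-like competition (one TF
#' arrives first and blocks the other for a full residence time) from
#' independent binding. Replicates in which either arrival is censored are
#' excluded and counted.
#'
#' @param ens An `fd_ensemble`.
#' @param site1,site2 site_ids.
#' @return Numeric vector of log ratios, with attribute `n_censored`.
#' @export
log_ratio_arrivals <- function(ens, site1, site2) {
  a1 <- first_arrivals(ens, site1)
  a2 <- first_arrivals(ens, site2)
  keep <- !(a1$censored | a2$censored)
  if (!any(keep))
    stop("empty-sample error: no replicate has both arrivals", call. = FALSE)
  out <- log(a1$first_arrival[keep] / a2$first_arrival[keep])
  attr(out, "n_censored") <- sum(!keep)
  out
}

#' First-passage time to a configuration predicate
#'
#' The first time each replicate's configuration satisfies `predicate`
#' (censored if never within the horizon). The initial configuration counts:
#' if it already satisfies the predicate the first passage is 0.
#'
#' @param ens An `fd_ensemble`.
#' @param predicate Function taking a named logical occupancy vector and
#'   returning TRUE/FALSE. Default: the AND configuration (every site
#'   bound).
#' @return data.frame `replicate`, `first_passage`, `censored`.
#' @export
first_passage_to <- function(ens, predicate = all_bound) {
  arch <- ens$arch
  n <- nrow(arch$sites)
  masks <- 0:(2^n - 1)
  ok <- vapply(masks, function(m) isTRUE(predicate(mask_to_config(arch, m))),
               logical(1))
  t <- vapply(ens$trajectories, function(tr) {
    if (ok[tr$initial_state + 1]) return(0)
    hit <- ok[tr$events$state + 1]
    if (any(hit)) tr$events$time[which(hit)[1]] else NA_real_
  }, numeric(1))
  data.frame(replicate = seq_along(t), first_passage = t, censored = is.na(t))
}

#' AND-configuration predicate
#'
#' TRUE when every site is bound simultaneously.
#'
#' @param occupancy Named logical occupancy vector.
#' @export
all_bound <- function(occupancy) all(occupancy)

#' Censoring-aware summary of first-passage or arrival times
#'
#' @param times Numeric vector with NA for censored replicates.
#' @return List with `mean` (over uncensored), `n`, `n_censored`,
#'   `frac_censored`.
#' @export
summarize_times <- function(times) {
  list(mean = mean(times, na.rm = TRUE), n = length(times),
       n_censored = sum(is.na(times)),
       frac_censored = mean(is.na(times)))
}

#' Impulse profile of a focal site
#'
#' For each time bin, the number of replicates whose configuration at the
#' bin midpoint is exactly "focal site bound, every other site unbound".
#' Starting from naked DNA this count can transiently exceed its equilibrium
#' level — the impulse.
#'
#' @param ens An `fd_ensemble`.
#' @param focal site_id of the focal (central) site.
#' @param bin_width Bin width in seconds (default 10).
#' @return data.frame of class `fd_impulse`: `t_mid`, `count`, with
#'   attributes `n_reps` and `bin_width`.
#' @export
impulse_profile <- function(ens, focal, bin_width = 10) {
  if (bin_width <= 0) stop("bin width must be > 0", call. = FALSE)
  target <- site_bit(ens, focal)
  edges <- seq(0, ens$t_max, by = bin_width)
  if (edges[length(edges)] < ens$t_max) edges <- c(edges, ens$t_max)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- integer(length(mids))
  for (tr in ens$trajectories) {
    counts <- counts + as.integer(state_at(tr, mids) == target)
  }
  out <- data.frame(t_mid = mids, count = counts)
  attr(out, "n_reps") <- ens$n_reps
  attr(out, "bin_width") <- bin_width
  class(out) <- c("fd_impulse", "data.frame")
  out
}

#' Fraction of time a site is bound
#'
#' Lebesgue measure of the intervals during which the site is bound, divided
#' by the horizon.
#'
#' @param traj An `fd_trajectory`.
#' @param site site_id.
#' @param horizon Seconds (defaults to the trajectory's `t_max`; must not
#'   exceed it).
#' @return Fraction in `[0, 1]`.
#' @export
occupancy_fraction <- function(traj, site, horizon = traj$t_max) {
  if (horizon > traj$t_max)
    stop("horizon exceeds the simulated t_max", call. = FALSE)
  i <- match(site, traj$site_ids)
  if (is.na(i)) stop("reference error: unknown site_id ", site, call. = FALSE)
  bit <- 2^(i - 1)
  times <- c(0, traj$events$time, horizon)
  states <- c(traj$initial_state, traj$events$state)
  keep <- times[-length(times)] < horizon
  starts <- pmin(times[-length(times)], horizon)[keep]
  ends <- pmin(times[-1], horizon)[keep]
  bound <- bitwAnd(states[keep], bit) > 0
  sum((ends - starts)[bound]) / horizon
}

#' Fano factor of a sample
#'
#' Unbiased sample variance divided by the sample mean; 1 for Poisson
#' counts.
#'
#' @param sample Numeric vector.
#' @return Variance/mean ratio.
#' @export
fano_factor <- function(sample) {
  m <- mean(sample)
  if (!is.finite(m) || m <= 0)
    stop("value error: Fano factor needs a positive mean", call. = FALSE)
  stats::var(sample) / m
}

#' Fano factor of an impulse profile
#'
#' Variance/mean of the per-bin replicate counts of an impulse profile over
#' a quasi-stationary window (by default the second half of the horizon, so
#' the systematic rise of the impulse itself does not inflate the variance).
#' This operationalizes the stochasticity comparison between promoter
#' architectures: counts fluctuating like independent Poisson draws give 1;
#' slowly switching configurations give more.
#'
#' @param profile An `fd_impulse` from [impulse_profile()].
#' @param window Numeric `c(lo, hi)` in seconds; bins with midpoints inside
#'   are used. Default: second half of the profile.
#' @return Fano factor of the windowed counts.
#' @export
impulse_fano <- function(profile, window = NULL) {
  if (is.null(window)) window <- c(max(profile$t_mid) / 2, Inf)
  use <- profile$t_mid >= window[1] & profile$t_mid <= window[2]
  fano_factor(profile$count[use])
}

#' Per-replicate visit counts of the focal-only configuration
#'
#' For each replicate, the number of separate visits to the configuration
#' "focal site bound, all others unbound" within the horizon (a visit starts
#' when the configuration is entered, including at t = 0). The Fano factor
#' of these counts is the package's noise statistic for comparing impulse
#' architectures: visit counts are Poisson-like (Fano near 1) when the
#' configuration is entered by many quasi-independent short excursions, and
#' over-dispersed when a single strong site gates the configuration.
#'
#' @param ens An `fd_ensemble`.
#' @param focal site_id of the focal site.
#' @return Integer vector of per-replicate visit counts.
#' @export
focal_visit_counts <- function(ens, focal) {
  target <- site_bit(ens, focal)
  vapply(ens$trajectories, function(tr) {
    states <- c(tr$initial_state, tr$events$state)
    inb <- states == target
    sum(diff(inb) == 1L) + as.integer(inb[1])
  }, integer(1))
}

#' Fano factor of focal-configuration visit counts
#'
#' `fano_factor(focal_visit_counts(ens, focal))`; the headline stochasticity
#' comparison between impulse-generating promoter architectures.
#'
#' @inheritParams focal_visit_counts
#' @return Variance/mean of the per-replicate visit counts.
#' @export
visit_fano <- function(ens, focal) {
  fano_factor(focal_visit_counts(ens, focal))
}

#' Two-sided F test for equality of variances
#'
#' Thin wrapper around [stats::var.test()] returning the F statistic and the
#' two-sided p-value.
#'
#' @param sample_a,sample_b Numeric vectors (n >= 2 each).
#' @return List with `statistic` and `p.value`.
#' @export
variance_ratio_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples need n >= 2", call. = FALSE)
  if (stats::var(sample_b) == 0)
    stop("value error: zero variance in denominator sample", call. = FALSE)
  ht <- stats::var.test(sample_a, sample_b)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Parameter sweep of an ensemble statistic
#'
#' Runs one ensemble per cell of an abundance x affinity-scale grid and
#' records the natural log of the statistic (by default the censoring-aware
#' mean first-passage time to the AND configuration). Cells where more than
#' half the replicates are censored are flagged.
#'
#' @param arch_fun Function `(abundance, affinity_scale) -> fd_architecture`
#'   building the architecture family member for one grid cell.
#' @param abundance_grid,affinity_grid Numeric grids (non-empty).
#' @param statistic Function `(fd_ensemble) -> numeric(1)`; default mean AND
#'   first-passage time over uncensored replicates.
#' @param n_reps,t_max,base_seed,mode Passed to [run_ensemble()].
#' @return List with `ln_value` (matrix, rows = abundances, cols = affinity
#'   scales) and `censored_heavy` (logical matrix).
#' @export
sweep_and_heatmap <- function(arch_fun, abundance_grid, affinity_grid,
                              statistic = NULL, n_reps = 100, t_max = 3000,
                              base_seed = 1, mode = "facilitated") {
  if (!length(abundance_grid) || !length(affinity_grid))
    stop("grids must be non-empty", call. = FALSE)
  censored_frac <- 0
  if (is.null(statistic)) {
    statistic <- function(ens) {
      fp <- first_passage_to(ens)
      censored_frac <<- mean(fp$censored)
      mean(fp$first_passage, na.rm = TRUE)
    }
  }
  ln_value <- matrix(NA_real_, length(abundance_grid), length(affinity_grid),
                     dimnames = list(abundance_grid, affinity_grid))
  heavy <- matrix(FALSE, length(abundance_grid), length(affinity_grid),
                  dimnames = dimnames(ln_value))
  cell_seed <- base_seed
  for (i in seq_along(abundance_grid)) {
    for (j in seq_along(affinity_grid)) {
      censored_frac <- 0
      arch <- arch_fun(abundance_grid[i], affinity_grid[j])
      cell_seed <- cell_seed + n_reps + 1
      ens <- run_ensemble(arch, t_max = t_max, n_reps = n_reps,
                          base_seed = cell_seed, mode = mode)
      ln_value[i, j] <- log(statistic(ens))
      heavy[i, j] <- censored_frac > 0.5
    }
  }
  list(ln_value = ln_value, censored_heavy = heavy)
}
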