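mask_of <- function(arch, occupancy) {
  occ <- normalize_config(arch, occupancy)
  sum(2^(which(occ) - 1))
}

mask_to_config <- function(arch, mask) {
  n <- nrow(arch$sites)
  stats::setNames(as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0),
                  arch$sites$site_id)
}

# Memoized transition tables keyed by configuration bitmask: the state space
# is tiny (<= 2^n), so every table is computed at most once per ensemble.
transition_memo <- function(arch, mode, cluster_threshold) {
  env <- new.env(parent = emptyenv())
  get_table <- function(mask) {
    key <- as.character(mask)
    tab <- env[[key]]
    if (!is.null(tab)) return(tab)
    occ <- mask_to_config(arch, mask)
    tr <- build_transitions(arch, occ, mode = mode,
                            cluster_threshold = cluster_threshold)
    keep <- tr$propensity > 0
    tr <- tr[keep, , drop = FALSE]
    idx_site <- match(tr$site, arch$sites$site_id)
    idx_dest <- match(tr$dest, arch$sites$site_id)
    new_mask <- vapply(seq_len(nrow(tr)), function(k) {
      m <- mask
      if (tr$kind[k] == "bind") m <- bitwOr(m, 2^(idx_site[k] - 1))
      if (tr$kind[k] == "unbind") m <- bitwAnd(m, bitwNot(2^(idx_site[k] - 1)))
      if (tr$kind[k] == "relocate") {
        m <- bitwAnd(m, bitwNot(2^(idx_site[k] - 1)))
        m <- bitwOr(m, 2^(idx_dest[k] - 1))
      }
      m
    }, numeric(1))
    tab <- list(kind = tr$kind, site = tr$site, dest = tr$dest,
                prop = tr$propensity, cum = cumsum(tr$propensity),
                total = sum(tr$propensity), new_mask = new_mask)
    env[[key]] <- tab
    tab
  }
  get_table
}

#' Run one exact stochastic simulation of the promoter Markov chain
#'
#' Gillespie direct method over promoter configurations: in each step the
#' waiting time is exponential with rate equal to the total propensity of the
#' current configuration's transition table, the reaction is drawn with
#' probability proportional to its propensity, and the table is rebuilt (or
#' fetched from a per-architecture cache) after every event. The trajectory
#' is fully determined by the seed.
#'
#' @param arch An `fd_architecture`.
#' @param t_max Simulated horizon in seconds (default 3000 s, roughly one
#'   E. coli cell cycle).
#' @param initial Initial occupancy (default: naked DNA, nothing bound).
#' @param seed Integer RNG seed.
#' @param mode `"facilitated"` or `"3d_only"`.
#' @param cluster_threshold Passed to [build_transitions()].
#' @param memo Internal: a shared transition cache from an ensemble run.
#' @return Object of class `fd_trajectory`: list with `events` (data.frame
#'   `time`, `kind`, `site`, `dest`, `state`; `state` is the configuration
#'   bitmask *after* the event, bit i = i-th site of `arch$sites` bound),
#'   `initial_state`, `t_max`, `seed`, `mode`, `site_ids`.
#' @export
run_ssa <- function(arch, t_max = 3000, initial = NULL, seed = 1,
                    mode = c("facilitated", "3d_only"),
                    cluster_threshold = NULL, memo = NULL) {
  mode <- match.arg(mode)
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  occ0 <- normalize_config(arch, initial)
  if (!valid_configuration(arch, occ0))
    stop("invalid initial configuration", call. = FALSE)
  if (is.null(memo)) memo <- transition_memo(arch, mode, cluster_threshold)

  set.seed(as.integer(seed))
  state <- mask_of(arch, occ0)
  t <- 0
  cap <- 256L
  ev_t <- numeric(cap); ev_k <- integer(cap)
  ev_s <- integer(cap); ev_d <- integer(cap); ev_m <- numeric(cap)
  n_ev <- 0L
  kinds <- c("bind", "unbind", "relocate")

  repeat {
    tab <- memo(state)
    if (tab$total <= 0) break
    dt <- stats::rexp(1, tab$total)
    if (t + dt > t_max) break
    t <- t + dt
    u <- stats::runif(1) * tab$total
    k <- which(u <= tab$cum)[1]
    stopifnot(tab$prop[k] > 0)  # propensity-conservation audit
    n_ev <- n_ev + 1L
    if (n_ev > cap) {
      cap <- cap * 2L
      length(ev_t) <- cap; length(ev_k) <- cap
      length(ev_s) <- cap; length(ev_d) <- cap; length(ev_m) <- cap
    }
    ev_t[n_ev] <- t
    ev_k[n_ev] <- match(tab$kind[k], kinds)
    ev_s[n_ev] <- match(tab$site[k], arch$sites$site_id)
    ev_d[n_ev] <- if (is.na(tab$dest[k])) NA_integer_ else
      match(tab$dest[k], arch$sites$site_id)
    ev_m[n_ev] <- tab$new_mask[k]
    state <- tab$new_mask[k]
  }

  idx <- seq_len(n_ev)
  events <- data.frame(
    time = ev_t[idx],
    kind = kinds[ev_k[idx]],
    site = arch$sites$site_id[ev_s[idx]],
    dest = ifelse(is.na(ev_d[idx]), NA_character_,
                  arch$sites$site_id[ev_d[idx]]),
    state = ev_m[idx],
    stringsAsFactors = FALSE)
  structure(list(events = events, initial_state = mask_of(arch, occ0),
                 t_max = t_max, seed = as.integer(seed), mode = mode,
                 site_ids = arch$sites$site_id, arch = arch),
            class = "fd_trajectory")
}

#' @export
print.fd_trajectory <- function(x, ...) {
  cat(sprintf("<fd_trajectory> %d events over %g s (seed %d, %s)\n",
              nrow(x$events), x$t_max, x$seed, x$mode))
  invisible(x)
}

#' Configuration of a trajectory at given times
#'
#' @param traj An `fd_trajectory`.
#' @param t Numeric vector of times in `[0, t_max]`.
#' @return Numeric vector of configuration bitmasks at those times.
#' @export
state_at <- function(traj, t) {
  states <- c(traj$initial_state, traj$events$state)
  states[findInterval(t, traj$events$time) + 1L]
}

#' Run an ensemble of independent replicates
#'
#' Independent Gillespie trajectories with per-replicate seeds derived from
#' `base_seed` by a counter (`base_seed + replicate index`), recorded in the
#' result so that any replicate can be replayed exactly. All replicates share
#' one transition-table cache.
#'
#' @inheritParams run_ssa
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Base seed for the counter-derived per-replicate seeds.
#' @return Object of class `fd_ensemble`: list with `trajectories`, `seeds`,
#'   `n_reps`, `base_seed`, `t_max`, `mode`, `arch`.
#' @export
run_ensemble <- function(arch, t_max = 3000, n_reps = 400, base_seed = 1,
                         initial = NULL, mode = c("facilitated", "3d_only"),
                         cluster_threshold = NULL) {
  mode <- match.arg(mode)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  memo <- transition_memo(arch, mode, cluster_threshold)
  seeds <- as.integer(base_seed) + seq_len(n_reps)
  trajectories <- lapply(seeds, function(s)
    run_ssa(arch, t_max = t_max, initial = initial, seed = s, mode = mode,
            cluster_threshold = cluster_threshold, memo = memo))
  structure(list(trajectories = trajectories, seeds = seeds,
                 n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed),
                 t_max = t_max, mode = mode, arch = arch),
            class = "fd_ensemble")
}

#' @export
print.fd_ensemble <- function(x, ...) {
  cat(sprintf("<fd_ensemble> %d replicates of %g s (base seed %d, %s)\n",
              x$n_reps, x$t_max, x$base_seed, x$mode))
  invisible(x)
}

#' Export an ensemble's event logs as long-format TSV
#'
#' Columns: replicate, time, kind, site, dest, config (occupancy bitstring,
#' leftmost character = leftmost site).
#'
#' @param ens An `fd_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ens, path) {
  n_sites <- length(ens$arch$sites$site_id)
  bitstring <- function(mask) {
    paste(as.integer(bitwAnd(mask, 2^(seq_len(n_sites) - 1)) > 0),
          collapse = "")
  }
  rows <- lapply(seq_along(ens$trajectories), function(r) {
    ev <- ens$trajectories[[r]]$events
    if (!nrow(ev)) return(NULL)
    data.frame(replicate = r, time = ev$time, kind = ev$kind, site = ev$site,
               dest = ev$dest,
               config = vapply(ev$state, bitstring, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(replicate = integer(), time = numeric(),
                      kind = character(), site = character(),
                      dest = character(), config = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
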