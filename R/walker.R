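# Explicit-position facilitated-diffusion Monte Carlo: a deliberately small
# validation device for the semi-analytical propensities. Each molecule
# alternates 3D excursions (fixed duration t_3d, uniform landing on
# unoccluded DNA) with 1D random walks (unbiased 1-bp steps). Landing on or
# walking onto an empty site of the molecule's own species binds it; bound
# molecules occlude their footprint and reflect other walkers; residence
# times are drawn from the same energy model as the Markov-chain kinetics.
# Scale caps keep this an oracle, not a production simulator.

walker_steps <- function(sp, site_len) {
  # step count calibrated so the expected landing catchment of a site of
  # length L equals the sliding length: mean walk range + L - 1 = s_l,
  # with E[range_N] ~ sqrt(8 N / pi) for an unbiased 1-bp walk.
  span <- max(sp$sliding_length - site_len + 1, 2)
  sliding_steps(sp, span)
}

#' Mean 1D coverage of one walk (calibration diagnostic)
#'
#' Simulates free 1D walks of a species and returns the landing catchment
#' each walk would offer a site of length `site_len` (covered span plus
#' `site_len - 1`). The calibration target is the species' sliding length.
#'
#' @param species An [tf_species()].
#' @param n_walks Number of walks.
#' @param site_len Site length in bp used in the calibration.
#' @return Numeric vector of per-walk catchments in bp.
#' @export
walk_coverage_sample <- function(species, n_walks = 1000, site_len = 20) {
  N <- walker_steps(species, site_len)
  vapply(seq_len(n_walks), function(i) {
    path <- cumsum(sample(c(-1L, 1L), N, replace = TRUE))
    (max(path, 0L) - min(path, 0L) + 1L) + site_len - 1L
  }, numeric(1))
}

#' Explicit-walker simulation of TF target search
#'
#' Simulates individual molecules performing facilitated diffusion on the
#' modelled segment and reports per-site first arrivals and occupancy. This
#' is the package's independent validation oracle for the semi-analytical
#' Markov-chain propensities and is limited to small systems (at most 2
#' sites, 20 molecules, M <= 5000 bp).
#'
#' During a walk the occupancy of the sites is frozen (walks are
#' milliseconds, residences much longer); bound molecules and `pinned` sites
#' reflect walkers at the edge of their occluded interval.
#'
#' @param arch An `fd_architecture` (sites for at most 2 positions).
#' @param t_max Simulated horizon in seconds.
#' @param seed RNG seed.
#' @param pinned Character vector of site_ids held permanently occupied by a
#'   phantom obstacle (used for barrier experiments).
#' @return List with `first_arrival` (named, NA = never bound),
#'   `occupancy` (named fraction of `t_max` bound) and `n_rounds`.
#' @export
simulate_walkers <- function(arch, t_max, seed = 1, pinned = character(0)) {
  st <- arch$sites
  n_sites <- nrow(st)
  if (n_sites > 2) stop("capacity error: walker oracle supports <= 2 sites",
                        call. = FALSE)
  if (arch$M > 5000) stop("capacity error: walker oracle needs M <= 5000",
                          call. = FALSE)
  copies <- vapply(arch$species, function(s) s$copy_number, integer(1))
  if (sum(copies) > 20)
    stop("capacity error: walker oracle supports <= 20 molecules",
         call. = FALSE)
  if (length(setdiff(pinned, st$site_id)))
    stop("unknown pinned site", call. = FALSE)
  set.seed(as.integer(seed))

  mol_sp <- rep(names(copies), copies)
  n_mol <- length(mol_sp)
  spl <- arch$species[mol_sp]
  # site occupancy: 0 free, -1 pinned, else molecule index
  occ <- integer(n_sites)
  occ[match(pinned, st$site_id)] <- -1L
  bound_site <- rep(NA_integer_, n_mol)
  # molecules start at a uniformly random phase of their search round
  t_next <- vapply(spl, function(s) stats::runif(1) * (s$t_walk + s$t_3d),
                   numeric(1))
  first_arrival <- rep(NA_real_, n_sites)
  bound_time <- numeric(n_sites)
  bound_since <- rep(NA_real_, n_sites)
  bound_since[occ == -1L] <- 0
  n_rounds <- 0L

  site_lo <- st$start
  site_hi <- st$start + st$length - 1
  occl <- t(vapply(seq_len(n_sites), function(i) occluded_interval(arch, i),
                   numeric(2)))

  current_config <- function() {
    stats::setNames(occ != 0L, st$site_id)
  }
  residence_rate <- function(i) {
    unbinding_propensity(arch, current_config(), st$site_id[i])
  }

  while (n_mol > 0) {
    m <- which.min(t_next)
    t <- t_next[m]
    if (t > t_max) break
    sp <- spl[[m]]
    if (!is.na(bound_site[m])) {
      # unbind
      i <- bound_site[m]
      bound_time[i] <- bound_time[i] + (t - bound_since[i])
      bound_since[i] <- NA_real_
      occ[i] <- 0L
      bound_site[m] <- NA_integer_
      t_next[m] <- t + sp$t_3d
      next
    }
    # 3D landing
    n_rounds <- n_rounds + 1L
    pos <- floor(stats::runif(1) * arch$M)
    occ_idx <- which(occ != 0L)
    in_occl <- any(pos >= occl[occ_idx, 1] & pos < occl[occ_idx, 2])
    if (in_occl) { t_next[m] <- t + sp$t_3d; next }

    own_empty <- which(st$tf == mol_sp[m] & occ == 0L)
    if (!length(own_empty)) { t_next[m] <- t + sp$t_walk + sp$t_3d; next }

    # landing directly on an empty own site
    on_site <- own_empty[pos >= site_lo[own_empty] & pos <= site_hi[own_empty]]
    hit_site <- NA_integer_
    hit_time <- NA_real_
    if (length(on_site)) {
      hit_site <- on_site[1]
      hit_time <- t
    } else {
      L_ref <- round(mean(st$length[own_empty]))
      N <- walker_steps(sp, L_ref)
      delta <- sp$t_walk / N
      # skip the walk when no reachable target (keeps the oracle fast);
      # 5*sqrt(N) truncates < 1e-5 of walks
      reach_cut <- 5 * sqrt(N) + 1
      near <- min(abs(pos - site_lo[own_empty]), abs(pos - site_hi[own_empty]))
      if (near <= reach_cut) {
        # reflecting walls from occupied occluded intervals and segment ends
        wl <- 0
        wr <- arch$M - 1
        for (i in occ_idx) {
          if (occl[i, 2] <= pos) wl <- max(wl, occl[i, 2])
          if (occl[i, 1] > pos) wr <- min(wr, occl[i, 1] - 1)
        }
        path <- pos + cumsum(sample(c(-1L, 1L), N, replace = TRUE))
        K <- wr - wl
        if (K > 0) {
          z <- (path - wl) %% (2 * K)
          path <- wl + ifelse(z <= K, z, 2 * K - z)
        } else path <- rep(wl, N)
        hits <- lapply(own_empty, function(i)
          which(path >= site_lo[i] & path <= site_hi[i])[1])
        idx <- vapply(hits, function(h) if (length(h)) h else NA_integer_,
                      integer(1))
        if (any(!is.na(idx))) {
          k <- own_empty[which.min(idx)]
          hit_site <- k
          hit_time <- t + min(idx, na.rm = TRUE) * delta
        }
      }
    }
    if (!is.na(hit_site)) {
      occ[hit_site] <- m
      bound_site[m] <- hit_site
      bound_since[hit_site] <- hit_time
      if (is.na(first_arrival[hit_site])) first_arrival[hit_site] <- hit_time
      t_next[m] <- hit_time + stats::rexp(1, residence_rate(hit_site))
    } else {
      t_next[m] <- t + sp$t_walk + sp$t_3d
    }
  }
  # close open residence intervals at the horizon
  open <- which(!is.na(bound_since))
  bound_time[open] <- bound_time[open] + (t_max - pmin(bound_since[open],
                                                       t_max))
  list(first_arrival = stats::setNames(first_arrival, st$site_id),
       occupancy = stats::setNames(pmin(bound_time / t_max, 1), st$site_id),
       n_rounds = n_rounds)
}
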