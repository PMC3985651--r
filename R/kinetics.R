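#' Effective sliding region of a site in a configuration
#'
#' The association propensity of a site is governed by `s_eff`, the length of
#' DNA from which one 1D random walk reaches the site. In isolation a site of
#' length `L` is reached from a catchment of one sliding length: `s_eff =
#' L + 2 r` with the one-sided reach `r = (s_l - L) / 2`, i.e. `s_eff = s_l`.
#' Occupied neighbouring intervals (barriers, or bound cluster partners)
#' truncate the catchment on their side at the unobstructed distance; an
#' *empty* binding site of the same species also shortens the catchment (it
#' captures any molecule that reaches it first — a trap), claiming half of
#' the gap between the two sites. The walk region used for unbinding is
#' truncated by occupied intervals only: empty cluster partners do not
#' restrict a random walk, they are sampled by it.
#'
#' @param arch An `fd_architecture`.
#' @param config Occupancy vector (see [valid_configuration()]).
#' @param site A site_id present in `arch`.
#' @param mode `"facilitated"` (default) or `"3d_only"`. In 3D-only mode the
#'   sliding contribution is removed: `s_eff` is the bare site length and the
#'   walk region is the site itself, independent of any neighbour.
#' @param cluster_threshold Max gap (bp) at which a same-TF pair counts as a
#'   cluster; default half the species' sliding length.
#' @return List with `site_id`, `s_eff` (bp) and `walk_region`
#'   (`c(lo, hi)`, half-open bp interval containing the site).
#' @export
effective_region <- function(arch, config, site, mode = "facilitated",
                             cluster_threshold = NULL) {
  st <- arch$sites
  i <- match(site, st$site_id)
  if (is.na(i)) stop("unknown site_id: ", site, call. = FALSE)
  occ <- normalize_config(arch, config)
  sp <- arch$species[[st$tf[i]]]
  L <- st$length[i]
  s_i <- st$start[i]
  e_i <- s_i + L

  if (mode == "3d_only") {
    return(list(site_id = site, s_eff = L, walk_region = c(s_i, e_i)))
  }
  reach <- max((sp$sliding_length - L) / 2, 0)
  c_thr <- if (is.null(cluster_threshold)) sp$sliding_length / 2 else
    cluster_threshold

  side <- function(dir) {
    # dir = +1 (right of the site) or -1 (left)
    d_bind <- d_walk <- if (dir > 0) arch$M - e_i else s_i
    for (j in seq_len(nrow(st))) {
      if (j == i) next
      oj <- occluded_interval(arch, j)
      if (occ[j]) {
        d <- if (dir > 0) oj[1] - e_i else s_i - oj[2]
        if (d >= 0) { d_bind <- min(d_bind, d); d_walk <- min(d_walk, d) }
      } else if (st$tf[j] == st$tf[i]) {
        gap <- if (dir > 0) st$start[j] - e_i else
          s_i - (st$start[j] + st$length[j])
        if (gap >= 0 && gap < c_thr) d_bind <- min(d_bind, gap / 2)
        if (gap < 0 && gap > -min(L, st$length[j])) d_bind <- min(d_bind, 0)
      }
    }
    c(bind = max(min(reach, d_bind), 0), walk = max(min(reach, d_walk), 0))
  }
  r <- side(+1)
  l <- side(-1)
  list(site_id = site,
       s_eff = max(L + l[["bind"]] + r[["bind"]], 1),
       walk_region = c(s_i - l[["walk"]], e_i + r[["walk"]]))
}

#' Search parameters for a binding reaction
#'
#' Collects the remaining quantities of the association kinetics: the number
#' of unbound molecules, the modelled segment length and the association
#' adjustment for a reduced system. Promoter models describe a short segment
#' but the molecules search the whole chromosome; by default `assoc_adjust =
#' M / max(M, genome_length)`, so the association propensity effectively
#' counts a landing catchment of `s_eff` bp out of the genomic background.
#'
#' @param n_free Unbound copies of the species in the current configuration.
#' @param M Modelled segment length (bp).
#' @param species The searching [tf_species()].
#' @param assoc_adjust Optional explicit adjustment factor.
#' @return List of class `fd_search_params`.
#' @export
search_params <- function(n_free, M, species, assoc_adjust = NULL) {
  if (n_free < 0) stop("n_free must be >= 0", call. = FALSE)
  if (is.null(assoc_adjust))
    assoc_adjust <- M / max(M, species$genome_length)
  structure(list(n_free = n_free, M = M, assoc_adjust = assoc_adjust),
            class = "fd_search_params")
}

#' Binding propensity (geometric facilitated-diffusion search)
#'
#' One search round is a 1D walk plus a 3D excursion and lasts
#' `t_walk + t_3d` seconds; a round hits the target with probability
#' `s_eff / M`, so the number of rounds to a hit is geometric with mean
#' `M / s_eff` and the association propensity is
#' \deqn{k_{on} = n_{free} \cdot a \cdot \frac{s_{eff}/M}{t_{walk}+t_{3d}}}
#' with `a` the association adjustment of [search_params()]. The propensity
#' is linear in the number of searching molecules and zero when none are
#' free.
#'
#' @param params An `fd_search_params`.
#' @param region An effective region (from [effective_region()]), or a list
#'   with an `s_eff` element.
#' @param species The searching [tf_species()].
#' @return Propensity in 1/seconds.
#' @export
binding_propensity <- function(params, region, species) {
  s_eff <- region$s_eff
  if (s_eff > params$M)
    stop("s_eff exceeds segment length M", call. = FALSE)
  if (params$n_free == 0) return(0)
  params$n_free * params$assoc_adjust * (s_eff / params$M) /
    (species$t_walk + species$t_3d)
}

# Boltzmann-weighted visit-time sum over a walk region.
# Positions inside same-species site intervals that the walk can sample
# (the bound site itself plus empty same-TF sites) carry weight
# exp(-lambda * E); everything else is non-specific DNA with weight 1.
walk_weight_sum <- function(arch, occ, i, region) {
  st <- arch$sites
  lo <- region$walk_region[1]
  hi <- region$walk_region[2]
  total <- hi - lo
  for (j in seq_len(nrow(st))) {
    if (st$tf[j] != st$tf[i]) next
    if (j != i && occ[j]) next
    cov <- site_overlap(lo, hi, st$start[j], st$start[j] + st$length[j])
    if (cov > 0) {
      lam <- arch$species[[st$tf[i]]]$affinity_scale
      total <- total + cov * (exp(-lam * st$energy[j]) - 1)
    }
  }
  total
}

#' Unbinding propensity
#'
#' A bound TF keeps performing a 1D random walk over a restricted region `W`
#' around its site; the time it spends at position `i` is Boltzmann-weighted,
#' `exp(-lambda E_i)` relative to non-specific DNA, and the expected duration
#' of the whole walk before dissociation is
#' \deqn{T = t_{walk} \cdot \frac{\sum_{i \in W} e^{-\lambda E_i}}{|W|}}
#' so the unbinding propensity is `|W| / (t_walk * sum)`. On purely
#' non-specific DNA this reduces to one walk duration. Occupied barriers
#' shrink `W` and thereby concentrate the walk on the target (slower
#' unbinding); an empty cluster partner adds a second energy well inside `W`
#' (the TF samples both sites and stays bound much longer) without shrinking
#' the walk region.
#'
#' @inheritParams effective_region
#' @return Propensity in 1/seconds.
#' @export
unbinding_propensity <- function(arch, config, site, mode = "facilitated",
                                 cluster_threshold = NULL) {
  occ <- normalize_config(arch, config)
  if (!occ[[site]])
    stop("state error: site ", site, " is not bound", call. = FALSE)
  i <- match(site, arch$sites$site_id)
  sp <- arch$species[[arch$sites$tf[i]]]
  region <- effective_region(arch, occ, site, mode = mode,
                             cluster_threshold = cluster_threshold)
  W <- region$walk_region[2] - region$walk_region[1]
  W / (sp$t_walk * walk_weight_sum(arch, occ, i, region))
}

#' Expected 1D-walk transit time between two sites
#'
#' Mean first-passage time of an unbiased 1-bp-step walk from a source site
#' to a destination `d` bp away, with a reflecting boundary at the far edge
#' of the source and absorption at the near edge of the destination. Each
#' position is left at rate `1/(2 delta_i)` per direction, where the waiting
#' time `delta_i` is the microscopic step time [step_time()] scaled by the
#' Boltzmann weight of the position (so a walk starting in the energy well of
#' the bound source site includes the escape from that well). On a flat
#' landscape with no source well the closed form is
#' `delta * d * (d + 1)` — the diffusive `d^2` scaling.
#'
#' @param d Distance in bp between the two site intervals (>= 1).
#' @param species The relocating [tf_species()].
#' @param source_length Length (bp) of the source site treated as an energy
#'   well at the start of the walk (0 = start from non-specific DNA).
#' @param source_energy Binding energy (kT) of the source site.
#' @return Expected transit time in seconds.
#' @export
relocation_time <- function(d, species, source_length = 0,
                            source_energy = 0) {
  if (d < 1) stop("distance d must be >= 1 bp", call. = FALSE)
  d <- as.integer(round(d))
  delta <- step_time(species)
  waits <- c(rep(delta * exp(-species$affinity_scale * source_energy),
                 source_length),
             rep(delta, d))
  start <- max(source_length, 1L)  # 1-based index of the walk's start position
  cs <- cumsum(waits)
  2 * sum(cs[start:length(cs)])
}

#' Relocation propensity between cluster sites
#'
#' The propensity of a bound TF jumping to an empty nearby site of its own
#' species is the reciprocal of the expected 1D-walk transit time between
#' the two sites, [relocation_time()]. Relocation only exists between
#' same-TF cluster pairs with the source bound and the destination empty.
#'
#' @inheritParams relocation_time
#' @return Propensity in 1/seconds.
#' @export
relocation_propensity <- function(d, species, source_length = 0,
                                  source_energy = 0) {
  1 / relocation_time(d, species, source_length, source_energy)
}

#' Transition table of a configuration
#'
#' Builds the complete reaction list leaving one configuration of the
#' promoter Markov chain: one `bind` per unbound, sterically unblocked site
#' with free molecules; one `unbind` per bound site; one `relocate` per
#' (bound source, empty destination) same-TF cluster pair with no bound site
#' in between. In `"3d_only"` mode the 1D contribution is removed: `s_eff`
#' is the bare site length, no neighbour adjustments apply and there are no
#' relocations.
#'
#' @inheritParams effective_region
#' @param species_counts Optional named integer vector overriding the copy
#'   numbers of `arch$species`.
#' @return data.frame with columns `kind`, `site`, `dest`, `propensity`.
#' @export
build_transitions <- function(arch, config, species_counts = NULL,
                              mode = "facilitated",
                              cluster_threshold = NULL) {
  st <- arch$sites
  occ <- normalize_config(arch, config)
  if (!valid_configuration(arch, occ))
    stop("state error: invalid configuration", call. = FALSE)
  n <- nrow(st)
  copies <- vapply(arch$species, function(s) s$copy_number, integer(1))
  if (!is.null(species_counts)) copies[names(species_counts)] <-
      as.integer(species_counts)
  bound_by <- vapply(names(copies), function(tf)
    sum(occ & st$tf == tf), integer(1))
  n_free <- copies - bound_by

  kind <- character(0); site <- character(0); dest <- character(0)
  prop <- numeric(0)
  blocked <- function(i, ignore = integer(0)) {
    oi <- occluded_interval(arch, i)
    for (j in which(occ)) {
      if (j == i || j %in% ignore) next
      oj <- occluded_interval(arch, j)
      if (site_overlap(oi[1], oi[2], oj[1], oj[2]) > 0) return(TRUE)
    }
    FALSE
  }

  for (i in seq_len(n)) {
    sp <- arch$species[[st$tf[i]]]
    if (!occ[i]) {
      if (n_free[[st$tf[i]]] <= 0 || blocked(i)) next
      region <- effective_region(arch, occ, st$site_id[i], mode = mode,
                                 cluster_threshold = cluster_threshold)
      p <- binding_propensity(
        search_params(n_free[[st$tf[i]]], arch$M, sp), region, sp)
      kind <- c(kind, "bind"); site <- c(site, st$site_id[i])
      dest <- c(dest, NA_character_); prop <- c(prop, p)
    } else {
      p <- unbinding_propensity(arch, occ, st$site_id[i], mode = mode,
                                cluster_threshold = cluster_threshold)
      kind <- c(kind, "unbind"); site <- c(site, st$site_id[i])
      dest <- c(dest, NA_character_); prop <- c(prop, p)
    }
  }

  if (mode != "3d_only") {
    for (i in which(occ)) {
      sp <- arch$species[[st$tf[i]]]
      c_thr <- if (is.null(cluster_threshold)) sp$sliding_length / 2 else
        cluster_threshold
      for (j in seq_len(n)) {
        if (j == i || occ[j] || st$tf[j] != st$tf[i]) next
        e_i <- st$start[i] + st$length[i]
        e_j <- st$start[j] + st$length[j]
        gap <- max(st$start[j] - e_i, st$start[i] - e_j)
        if (gap >= c_thr) next
        # no relocation across a bound intervening site, nor across an empty
        # same-TF site (the walk is captured by the first site it reaches)
        lo <- min(e_i, e_j); hi <- max(st$start[i], st$start[j])
        hop_blocked <- FALSE
        for (k in which(occ)) {
          if (k == i) next
          ok <- occluded_interval(arch, k)
          if (site_overlap(ok[1], ok[2], lo, hi) > 0) hop_blocked <- TRUE
        }
        for (k in seq_len(n)) {
          if (k == i || k == j || occ[k] || st$tf[k] != st$tf[i]) next
          if (site_overlap(st$start[k], st$start[k] + st$length[k],
                           lo, hi) > 0) hop_blocked <- TRUE
        }
        if (hop_blocked || blocked(j, ignore = i)) next
        p <- relocation_propensity(max(gap, 1), sp,
                                   source_length = st$length[i],
                                   source_energy = st$energy[i])
        kind <- c(kind, "relocate"); site <- c(site, st$site_id[i])
        dest <- c(dest, st$site_id[j]); prop <- c(prop, p)
      }
    }
  }
  data.frame(kind = kind, site = site, dest = dest, propensity = prop,
             stringsAsFactors = FALSE)
}
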