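#' Define a transcription-factor species
#'
#' A TF species bundles the physical parameters of the facilitated-diffusion
#' search performed by one kind of molecule: how many copies search the cell,
#' how far one 1D sliding walk reaches, how long the 1D and 3D phases of a
#' search round last, and how strongly binding energies are felt.
#'
#' @param name Species identifier (single string).
#' @param copy_number Number of molecules per cell (non-negative integer).
#' @param sliding_length Mean DNA span scanned during one 1D random walk, in
#'   bp. The canonical single-molecule estimate for lacI is 90 bp.
#' @param t_walk Duration of one 1D random walk, in seconds.
#' @param t_3d Duration of one 3D excursion between walks, in seconds.
#' @param affinity_scale Dimensionless multiplier applied to binding energies
#'   (often written lambda); energies enter the kinetics as
#'   `exp(-affinity_scale * energy)` with energies in units of kT.
#' @param footprint_left,footprint_right Extra bp occluded to the left/right
#'   of a bound site (steric hindrance beyond the site interval itself).
#' @param genome_length Length in bp of the genomic background over which the
#'   molecules search. Promoter models usually describe a short DNA segment;
#'   the molecules nevertheless spend most of their search on the rest of the
#'   chromosome, so association propensities are computed against
#'   `max(M, genome_length)`. Set to `1` (or any value `<= M`) to confine the
#'   search to the modelled segment, e.g. when cross-validating against the
#'   explicit-walker simulator.
#'
#' @return An object of class `fd_species`.
#' @examples
#' tf_species("lacI", copy_number = 10)
#' @export
tf_species <- function(name, copy_number, sliding_length = 90,
                       t_walk = 5e-3, t_3d = 5e-4, affinity_scale = 0.33,
                       footprint_left = 0, footprint_right = 0,
                       genome_length = 4.6e6) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(copy_number) != 1L || is.na(copy_number) || copy_number < 0 ||
      copy_number != round(copy_number))
    stop("copy_number must be a non-negative integer", call. = FALSE)
  if (sliding_length < 1) stop("sliding_length must be >= 1 bp", call. = FALSE)
  if (t_walk <= 0) stop("t_walk must be > 0", call. = FALSE)
  if (t_3d <= 0) stop("t_3d must be > 0", call. = FALSE)
  if (affinity_scale <= 0) stop("affinity_scale must be > 0", call. = FALSE)
  if (footprint_left < 0 || footprint_right < 0)
    stop("footprints must be >= 0", call. = FALSE)
  if (genome_length < 1) stop("genome_length must be >= 1", call. = FALSE)
  structure(
    list(name = name, copy_number = as.integer(copy_number),
         sliding_length = sliding_length, t_walk = t_walk, t_3d = t_3d,
         affinity_scale = affinity_scale,
         footprint_left = footprint_left, footprint_right = footprint_right,
         genome_length = genome_length),
    class = "fd_species"
  )
}

#' @export
print.fd_species <- function(x, ...) {
  cat(sprintf(
    "<fd_species %s> copies=%d s_l=%g bp t_walk=%g s t_3d=%g s lambda=%g\n",
    x$name, x$copy_number, x$sliding_length, x$t_walk, x$t_3d,
    x$affinity_scale))
  invisible(x)
}

#' Number of sliding events in one 1D random walk
#'
#' An unbiased 1-bp-step walk of `N` steps covers on average
#' `sqrt(8 N / pi)` distinct positions, so the step count that makes the mean
#' covered span match a target catchment `span` is `N = pi * span^2 / 8`.
#' This is the operational link between the sliding length (a measured mean
#' span) and the microscopic step time `t_walk / N` used for relocation
#' kinetics and by the explicit-walker validator.
#'
#' @param species An `fd_species`.
#' @param span Target mean 1D coverage in bp; defaults to the sliding length.
#' @return Integer number of steps (at least 1).
#' @export
sliding_steps <- function(species, span = species$sliding_length) {
  max(1L, as.integer(round(pi * span^2 / 8)))
}

#' Microscopic 1D step time of a species
#'
#' Time per 1-bp sliding step, `t_walk / sliding_steps(species)`.
#'
#' @inheritParams sliding_steps
#' @return Step time in seconds.
#' @export
step_time <- function(species) {
  species$t_walk / sliding_steps(species)
}
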