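#' Build a promoter architecture from a site table
#'
#' A promoter architecture is a DNA segment of length `M` bp carrying an
#' ordered set of TF binding sites. Coordinates are 0-based and half-open:
#' a site with `start = 100`, `length = 20` occupies positions 100..119 and
#' its interval is `[100, 120)`.
#'
#' @param site_table data.frame with columns `site_id`, `tf`, `start`,
#'   `length`, `energy` (energy in kT; more negative = stronger binding).
#' @param species Named list of [tf_species()] objects (names must cover every
#'   `tf` in the table), or a single `fd_species` when only one TF is used.
#' @param M Segment length in bp; must cover every site.
#' @return Object of class `fd_architecture`: list with elements `M`, `sites`
#'   (sorted by start) and `species`.
#' @examples
#' sp <- list(A = tf_species("A", 10), B = tf_species("B", 10))
#' sites <- data.frame(site_id = c("a1", "b1", "a2"), tf = c("A", "B", "A"),
#'                     start = c(0, 120, 240), length = 20, energy = -40)
#' build_architecture(sites, sp, M = 400)
#' @export
build_architecture <- function(site_table, species, M) {
  if (inherits(species, "fd_species")) {
    species <- stats::setNames(list(species), species$name)
  }
  if (length(M) != 1L || is.na(M) || M <= 0)
    stop("M must be a positive segment length", call. = FALSE)
  needed <- c("site_id", "tf", "start", "length", "energy")
  if (nrow(site_table) > 0 && !all(needed %in% names(site_table)))
    stop("site_table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (nrow(site_table) == 0L) {
    site_table <- data.frame(site_id = character(), tf = character(),
                             start = numeric(), length = numeric(),
                             energy = numeric(), stringsAsFactors = FALSE)
  }
  st <- site_table[needed]
  st$site_id <- as.character(st$site_id)
  st$tf <- as.character(st$tf)
  if (anyDuplicated(st$site_id))
    stop("duplicate site_id in site table", call. = FALSE)
  if (any(st$length < 1))
    stop("site length must be >= 1 bp", call. = FALSE)
  if (any(st$start < 0))
    stop("coordinate error: negative site start", call. = FALSE)
  if (any(st$start + st$length > M))
    stop("coordinate error: site extends beyond segment of length ", M,
         call. = FALSE)
  unknown <- setdiff(unique(st$tf), names(species))
  if (length(unknown))
    stop("reference error: unknown TF species ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (sp in species) stopifnot(inherits(sp, "fd_species"))
  st <- st[order(st$start, st$site_id), , drop = FALSE]
  rownames(st) <- NULL
  structure(list(M = M, sites = st, species = species),
            class = "fd_architecture")
}

#' @export
print.fd_architecture <- function(x, ...) {
  cat(sprintf("<fd_architecture> M=%g bp, %d sites, %d species: %s\n",
              x$M, nrow(x$sites), length(x$species),
              tryCatch(architecture_string(x), error = function(e) "")))
  if (nrow(x$sites)) print(x$sites)
  invisible(x)
}

#' Build an architecture from a pattern string
#'
#' Patterns such as `"ABA"`, `"AABAA"` or `"AA-B-AA"` are a compact notation
#' for promoter layouts: each letter places one binding site (same letter =
#' same TF species), consecutive letters are separated by `gap` bp, and `-`
#' widens the spacing to `far_spacer` bp (a spacer wide enough that the two
#' flanking sites do not interact through 1D sliding).
#'
#' @param pattern Non-empty string of letters and `-`.
#' @param site_length Site length in bp (applied to every site).
#' @param gap Spacing in bp between consecutive sites (>= 0).
#' @param flank Non-specific DNA in bp added on each side; sets `M`.
#' @param species Optional named list of [tf_species()]; species missing for a
#'   letter are created with the defaults below.
#' @param far_spacer Distance in bp inserted for `-` (default 100).
#' @param copy_number,energy,... Defaults for auto-created species and their
#'   sites; `...` is passed on to [tf_species()].
#' @return An `fd_architecture`.
#' @examples
#' from_pattern("ABA", site_length = 20, gap = 0, flank = 500)
#' from_pattern("AA-B-AA")
#' @export
from_pattern <- function(pattern, site_length = 20, gap = 0, flank = 500,
                         species = NULL, far_spacer = 100,
                         copy_number = 10, energy = fd_default_energy(),
                         ...) {
  if (length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string", call. = FALSE)
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  tokens <- strsplit(pattern, "")[[1]]
  if (!all(grepl("^[A-Za-z-]$", tokens)))
    stop("pattern may contain only letters and '-'", call. = FALSE)
  letters_seq <- tokens[tokens != "-"]
  if (!length(letters_seq)) stop("pattern contains no sites", call. = FALSE)

  starts <- numeric(0)
  cursor <- flank
  pending_far <- FALSE
  first <- TRUE
  for (tok in tokens) {
    if (tok == "-") { pending_far <- TRUE; next }
    if (!first) cursor <- cursor + if (pending_far) far_spacer else gap
    starts <- c(starts, cursor)
    cursor <- cursor + site_length
    pending_far <- FALSE
    first <- FALSE
  }
  M <- cursor + flank

  tfs <- toupper(letters_seq)
  if (is.null(species)) species <- list()
  for (tf in unique(tfs)) {
    if (is.null(species[[tf]]))
      species[[tf]] <- tf_species(tf, copy_number = copy_number, ...)
  }
  counts <- stats::ave(seq_along(tfs), tfs, FUN = seq_along)
  st <- data.frame(site_id = paste0(tolower(tfs), counts), tf = tfs,
                   start = starts, length = site_length, energy = energy,
                   stringsAsFactors = FALSE)
  build_architecture(st, species, M)
}

site_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Pairwise building-block classification
#'
#' Classifies every pair of binding sites into one of the spacing-defined
#' building blocks of facilitated-diffusion promoter logic:
#' * `switch` — overlapping sites for different TFs (mutually exclusive
#'   occupancy);
#' * `barrier` — non-overlapping sites for different TFs closer than
#'   `barrier_threshold` (a bound TF obstructs one sliding approach of the
#'   other);
#' * `cluster` — sites for the same TF closer than `cluster_threshold`
#'   (overlap allowed; the TF can slide back and forth between them);
#' * `independent` — everything else.
#'
#' The kinetic default for both thresholds is half the sliding length (45 bp
#' at `s_l = 90`), the range over which a neighbour perturbs the 1D walk.
#' Genome-census analyses conventionally use a tighter 10 bp cutoff; pass
#' `barrier_threshold = 10, cluster_threshold = 10` for that convention.
#'
#' @param arch An `fd_architecture`.
#' @param barrier_threshold Max gap (bp) for a different-TF pair to count as a
#'   barrier. Default: half the larger sliding length of the pair's species.
#' @param cluster_threshold Max gap (bp) for a same-TF pair to count as a
#'   cluster; defaults to `barrier_threshold`.
#' @return data.frame with one row per unordered site pair: `site_a`,
#'   `site_b`, `gap` (bp between the intervals; negative = overlap in bp) and
#'   `relation`.
#' @export
classify_pairs <- function(arch, barrier_threshold = NULL,
                           cluster_threshold = barrier_threshold) {
  st <- arch$sites
  n <- nrow(st)
  out <- data.frame(site_a = character(), site_b = character(),
                    gap = numeric(), relation = character(),
                    stringsAsFactors = FALSE)
  if (n < 2) return(out)
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e_i <- st$start[i] + st$length[i]
      e_j <- st$start[j] + st$length[j]
      ov <- site_overlap(st$start[i], e_i, st$start[j], e_j)
      gap <- if (ov > 0) -ov else max(st$start[j] - e_i, st$start[i] - e_j)
      same <- st$tf[i] == st$tf[j]
      s_l <- max(arch$species[[st$tf[i]]]$sliding_length,
                 arch$species[[st$tf[j]]]$sliding_length)
      b_thr <- if (is.null(barrier_threshold)) s_l / 2 else barrier_threshold
      c_thr <- if (is.null(cluster_threshold)) b_thr else cluster_threshold
      rel <- if (same) {
        if (gap < c_thr) "cluster" else "independent"
      } else if (ov > 0) {
        "switch"
      } else if (gap < b_thr) {
        "barrier"
      } else "independent"
      k <- k + 1L
      rows[[k]] <- data.frame(site_a = st$site_id[i], site_b = st$site_id[j],
                              gap = gap, relation = rel,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Nomenclature string of an architecture
#'
#' Renders an architecture as a compact string: one letter per site (letters
#' assigned in order of first appearance of each TF species, left to right),
#' `/` between overlapping neighbours, nothing between close non-overlapping
#' neighbours and `-` between neighbours at least `far_threshold` bp apart.
#' With more than 26 species, labels continue `A1`, `B1`, ...
#'
#' @param arch An `fd_architecture`.
#' @param far_threshold Gap (bp) at or beyond which neighbours are rendered
#'   with a `-` separator (default 100, matching the pattern notation).
#' @return A single string, e.g. `"ABA"` or `"AA-B-AA"`.
#' @export
architecture_string <- function(arch, far_threshold = 100) {
  st <- arch$sites
  if (!nrow(st)) return("")
  tf_order <- unique(st$tf)
  labels <- vapply(seq_along(tf_order), function(i) {
    if (i <= 26) LETTERS[i] else paste0(LETTERS[((i - 1) %% 26) + 1],
                                        (i - 1) %/% 26)
  }, character(1))
  names(labels) <- tf_order
  out <- labels[st$tf[1]]
  if (nrow(st) > 1) {
    for (i in 2:nrow(st)) {
      e_prev <- st$start[i - 1] + st$length[i - 1]
      ov <- site_overlap(st$start[i - 1], e_prev, st$start[i],
                         st$start[i] + st$length[i])
      gap <- st$start[i] - e_prev
      sep <- if (ov > 0) "/" else if (gap >= far_threshold) "-" else ""
      out <- paste0(out, sep, labels[st$tf[i]])
    }
  }
  unname(out)
}

occluded_interval <- function(arch, i) {
  sp <- arch$species[[arch$sites$tf[i]]]
  c(arch$sites$start[i] - sp$footprint_left,
    arch$sites$start[i] + arch$sites$length[i] + sp$footprint_right)
}

#' Test whether an occupancy vector is a valid configuration
#'
#' A configuration marks each site bound or unbound (the bound molecule is
#' always the site's owning species). Validity requires (i) no two bound
#' sites with overlapping occluded intervals (site interval plus steric
#' footprint) — this encodes switch mutual exclusion — and (ii) at most
#' `copy_number` simultaneously bound sites per species.
#'
#' @param arch An `fd_architecture`.
#' @param occupancy Logical vector, one element per site (in `arch$sites`
#'   order, or named by site_id).
#' @return `TRUE` or `FALSE`.
#' @export
valid_configuration <- function(arch, occupancy) {
  st <- arch$sites
  occupancy <- normalize_config(arch, occupancy)
  idx <- which(occupancy)
  if (length(idx) >= 2) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        oi <- occluded_interval(arch, i)
        oj <- occluded_interval(arch, j)
        if (site_overlap(oi[1], oi[2], oj[1], oj[2]) > 0) return(FALSE)
      }
    }
  }
  if (length(idx)) {
    bound_by <- table(st$tf[idx])
    for (tf in names(bound_by)) {
      if (bound_by[[tf]] > arch$species[[tf]]$copy_number) return(FALSE)
    }
  }
  TRUE
}

normalize_config <- function(arch, occupancy) {
  st <- arch$sites
  if (is.null(occupancy)) occupancy <- rep(FALSE, nrow(st))
  if (!is.null(names(occupancy))) {
    miss <- setdiff(names(occupancy), st$site_id)
    if (length(miss)) stop("unknown site_id: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    full <- stats::setNames(rep(FALSE, nrow(st)), st$site_id)
    full[names(occupancy)] <- occupancy
    occupancy <- full
  }
  if (length(occupancy) != nrow(st))
    stop("occupancy must have one entry per site", call. = FALSE)
  stats::setNames(as.logical(occupancy), st$site_id)
}

#' Enumerate the configuration space of an architecture
#'
#' Lists every occupancy vector satisfying the configuration invariants
#' (steric mutual exclusion and species copy-number caps), including the
#' empty "naked DNA" configuration. This is the state space of the
#' continuous-time Markov chain that the simulator walks through.
#'
#' @param arch An `fd_architecture` with at most 20 sites.
#' @return Logical matrix, one row per configuration, columns named by
#'   site_id. A zero-site architecture yields a single empty configuration.
#' @export
enumerate_configurations <- function(arch) {
  n <- nrow(arch$sites)
  if (n > 20) stop("capacity error: more than 20 sites", call. = FALSE)
  if (n == 0)
    return(matrix(logical(0), nrow = 1, ncol = 0))
  masks <- 0:(2^n - 1)
  rows <- lapply(masks, function(m) as.logical(bitwAnd(m, 2^(0:(n - 1))) > 0))
  keep <- vapply(rows, function(r) valid_configuration(arch, r), logical(1))
  out <- do.call(rbind, rows[keep])
  colnames(out) <- arch$sites$site_id
  out
}
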