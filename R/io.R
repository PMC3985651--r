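#' Read a binding-site table
#'
#' Two dialects are supported:
#' * `tsv` — tab-separated with header `site_id, tf, start, length, energy`;
#' * `bed` — 6-column BED (`chrom, start, end, name, score, strand`):
#'   `chrom` groups sites by TF species, `name` is the site_id, `score` the
#'   binding energy; `strand` is ignored (binding is not modelled as
#'   orientation dependent).
#'
#' Both dialects are 0-based half-open (BED natively so).
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return data.frame with columns `site_id, tf, start, length, energy`.
#' @export
read_sites <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    needed <- c("site_id", "tf", "start", "length", "energy")
    if (!all(needed %in% names(df)))
      stop("parse error: TSV needs header columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    out <- df[needed]
  } else {
    df <- tryCatch(
      utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(df) < 6)
      stop("parse error: BED needs 6 columns", call. = FALSE)
    out <- data.frame(site_id = as.character(df[[4]]),
                      tf = as.character(df[[1]]),
                      start = df[[2]], length = df[[3]] - df[[2]],
                      energy = df[[5]], stringsAsFactors = FALSE)
  }
  for (col in c("start", "length", "energy")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad))
      stop("parse error at line ", bad[1] + 1, ": non-numeric ", col,
           call. = FALSE)
    out[[col]] <- v
  }
  if (any(out$start < 0))
    stop("coordinate error: negative start at line ",
         which(out$start < 0)[1] + 1, call. = FALSE)
  if (any(out$length < 1))
    stop("coordinate error: non-positive site length at line ",
         which(out$length < 1)[1] + 1, call. = FALSE)
  if (anyDuplicated(out$site_id))
    stop("uniqueness error: duplicate site_id ",
         out$site_id[anyDuplicated(out$site_id)], call. = FALSE)
  out
}

#' Write a binding-site table
#'
#' Inverse of [read_sites()]; round-trips both dialects.
#'
#' @param sites data.frame with columns `site_id, tf, start, length, energy`
#'   (or an `fd_architecture`, whose site table is used).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (inherits(sites, "fd_architecture")) sites <- sites$sites
  if (format == "tsv") {
    utils::write.table(sites[c("site_id", "tf", "start", "length", "energy")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = sites$tf, start = sites$start,
                      end = sites$start + sites$length, name = sites$site_id,
                      score = sites$energy, strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with top-level keys: `pattern` or `sites` (+ optional
#' `sites_format`), `t_max`, `n_reps`, `base_seed`, `mode`,
#' `barrier_threshold`, `cluster_threshold`, `site_length`, `gap`, `flank`,
#' `outdir`, and a `species` map of per-TF blocks (`copy_number`,
#' `sliding_length`, `t_walk`, `t_3d`, `affinity_scale`, `footprint_left`,
#' `footprint_right`, `genome_length`).
#'
#' @param path YAML file.
#' @return List of class `fd_run_config` with `arch` (the built
#'   architecture) and the run settings.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  species <- list()
  for (nm in names(cfg$species)) {
    blk <- cfg$species[[nm]]
    args <- c(list(name = nm), blk)
    species[[nm]] <- do.call(tf_species, args)
  }
  arch <- if (!is.null(cfg$pattern)) {
    from_pattern(cfg$pattern,
                 site_length = cfg$site_length %||% 20,
                 gap = cfg$gap %||% 0,
                 flank = cfg$flank %||% 500,
                 species = if (length(species)) species else NULL)
  } else if (!is.null(cfg$sites)) {
    st <- read_sites(file.path(dirname(path), cfg$sites),
                     format = cfg$sites_format %||% "tsv")
    miss <- setdiff(unique(st$tf), names(species))
    if (length(miss))
      stop("config error: no species block for ",
           paste(miss, collapse = ", "), call. = FALSE)
    build_architecture(st, species,
                       M = cfg$M %||% (max(st$start + st$length) + 500))
  } else stop("config error: need 'pattern' or 'sites'", call. = FALSE)
  structure(list(arch = arch,
                 t_max = cfg$t_max %||% 3000,
                 n_reps = cfg$n_reps %||% 400,
                 base_seed = cfg$base_seed %||% 1,
                 mode = cfg$mode %||% "facilitated",
                 barrier_threshold = cfg$barrier_threshold,
                 cluster_threshold = cfg$cluster_threshold,
                 outdir = cfg$outdir %||% "."),
            class = "fd_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
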