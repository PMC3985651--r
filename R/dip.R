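# Hartigan's dip statistic.
#
# The dip of a sample is the smallest sup-norm distance between its ECDF and
# any unimodal distribution function. It is computed by the classic
# convex-minorant / concave-majorant construction: on a shrinking modal
# interval, fit the greatest convex minorant (GCM) of the ECDF from the left
# and the least concave majorant (LCM) from the right, measure the largest
# separation between the two fitted curves, and absorb the deviations of the
# ECDF from the fits on the discarded flanks; the dip is half the final
# maximal deviation. All comparisons use cross products, never slopes, so
# tied observations are safe.

# Lower convex hull touch indices of points (x[i], y0 + (i - lo)) for
# i in lo..hi; y is the count scale so consecutive points rise by 1.
hull_touch <- function(x, lo, hi, upper = FALSE) {
  idx <- integer(hi - lo + 1L)
  idx[1L] <- lo
  m <- 1L
  if (hi > lo) {
    for (i in (lo + 1L):hi) {
      while (m >= 2L) {
        a <- idx[m - 1L]; b <- idx[m]
        # keep b if slope(a,b) < slope(b,i) for lower hull (convex),
        # > for upper hull (concave); drop otherwise
        cross <- (b - a) * (x[i] - x[b]) - (i - b) * (x[b] - x[a])
        drop_b <- if (upper) cross < 0 else cross > 0
        if (!drop_b) break
        m <- m - 1L
      }
      m <- m + 1L
      idx[m] <- i
    }
  }
  idx[seq_len(m)]
}

# Piecewise-linear interpolation of hull values (count units y = index + off)
# at the x-positions of indices `at`.
hull_interp <- function(x, touch, off, at) {
  ys <- touch + off
  if (length(touch) == 1L) return(rep(ys, length(at)))
  stats::approx(x[touch], ys, xout = x[at], rule = 2, ties = "ordered")$y
}

#' Hartigan's dip statistic
#'
#' Smallest sup-norm distance between the empirical CDF of `x` and any
#' unimodal distribution function. The minimum attainable value is
#' `1/(2n)` (e.g. perfectly equally spaced data); samples split into two
#' separated clumps approach the maximum of 1/4. The statistic depends on
#' the data only through their order, so it is invariant under strictly
#' increasing transformations.
#'
#' @param x Numeric sample (n >= 2 for a meaningful value).
#' @return The dip, a number in `[0, 0.25]`. Degenerate samples (all values
#'   equal) have dip 0.
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2L || x[n] == x[1L]) return(0)
  lo <- 1L
  hi <- n
  D <- 0
  repeat {
    gcm <- hull_touch(x, lo, hi, upper = FALSE)  # fits (x_i, i - 1)
    lcm <- hull_touch(x, lo, hi, upper = TRUE)   # fits (x_i, i)
    # largest separation between the two fitted curves
    sep_g <- hull_interp(x, lcm, 0, gcm) - (gcm - 1)   # LCM above GCM touches
    sep_l <- lcm - hull_interp(x, gcm, -1, lcm)        # LCM touches above GCM
    d <- max(sep_g, sep_l)
    if (d <= D) break
    if (max(sep_g) >= max(sep_l)) {
      ig <- gcm[which.max(sep_g)]
      ih <- lcm[match(TRUE, lcm >= ig)]
      if (is.na(ih)) ih <- hi
    } else {
      ih <- lcm[which.max(sep_l)]
      ig <- gcm[max(which(gcm <= ih))]
    }
    # deviations of the ECDF from the fits on the discarded flanks
    if (ig > lo) {
      ii <- lo:ig
      D <- max(D, max(ii - hull_interp(x, gcm, -1, ii)))
    }
    if (ih < hi) {
      ii <- ih:hi
      D <- max(D, max(hull_interp(x, lcm, 0, ii) - (ii - 1)))
    }
    if (ig == lo && ih == hi) { D <- max(D, d); break }
    lo <- ig
    hi <- ih
  }
  D / (2 * n)
}

.dip_null_cache <- new.env(parent = emptyenv())

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution, using [dip_stat()] with a bootstrap null: the distribution
#' of the dip under samples of the same size from the uniform distribution
#' (the least-favourable unimodal case). The null distribution is
#' regenerated (and cached per session) under a fixed seed, so p-values are
#' reproducible.
#'
#' @param x Numeric sample with at least 4 observations.
#' @param B Number of bootstrap null samples (default 10000).
#' @param seed Seed for the bootstrap null.
#' @return List of class `fd_dip_test` with elements `statistic`, `p.value`,
#'   `n`, `B`, `method`.
#' @export
dip_test <- function(x, B = 10000, seed = 1) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 4L) stop("sample-size error: dip test needs n >= 4", call. = FALSE)
  stat <- dip_stat(x)
  key <- paste(n, B, seed, sep = "_")
  null <- .dip_null_cache[[key]]
  if (is.null(null)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(as.integer(seed))
    null <- vapply(seq_len(B), function(i) dip_stat(stats::runif(n)),
                   numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    .dip_null_cache[[key]] <- null
  }
  p <- (1 + sum(null >= stat)) / (B + 1)
  structure(list(statistic = stat, p.value = p, n = n, B = B,
                 method = "Hartigan dip test, bootstrap uniform null"),
            class = "fd_dip_test")
}

#' @export
print.fd_dip_test <- function(x, ...) {
  cat(sprintf("%s\nD = %.5f, n = %d, B = %d, p-value = %.4g\n",
              x$method, x$statistic, x$n, x$B, x$p.value))
  invisible(x)
}
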