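# Exact LP oracle for the dip statistic: a unimodal cdf may jump at its mode
# m; left of m it is convex, right of m concave. For a fixed m the smallest
# sup-norm distance to the ECDF is a linear program in the fitted values; the
# oracle minimizes over mode positions (data points plus a grid inside each
# spacing). Used only on small n to certify dip_stat().

dip_lp_mode <- function(x, m) {
  n <- length(x)
  nv <- n + 3
  iGml <- n + 1; iGmr <- n + 2; iD <- nv
  A <- NULL; b <- NULL
  add <- function(row, rhs) { A <<- rbind(A, row); b <<- c(b, rhs) }
  for (i in 1:n) {
    up <- if (x[i] == m) i / n else (i - 1) / n
    r <- numeric(nv); r[i] <- 1; r[iD] <- -1; add(r, up)
    r <- numeric(nv); r[i] <- -1; r[iD] <- -1; add(r, -i / n)
  }
  Fml <- sum(x < m) / n
  Fm <- sum(x <= m) / n
  r <- numeric(nv); r[iGml] <- 1; r[iD] <- -1; add(r, Fml)
  r <- numeric(nv); r[iGml] <- -1; r[iD] <- -1; add(r, -Fml)
  r <- numeric(nv); r[iGmr] <- 1; r[iD] <- -1; add(r, Fm)
  r <- numeric(nv); r[iGmr] <- -1; r[iD] <- -1; add(r, -Fm)
  left_idx <- which(x < m); right_idx <- which(x > m); at_idx <- which(x == m)
  chain <- c(left_idx, at_idx, iGml, iGmr, right_idx)
  for (j in 2:length(chain)) {
    r <- numeric(nv); r[chain[j - 1]] <- 1; r[chain[j]] <- -1; add(r, 0)
  }
  shape <- function(idx, xs, convex) {
    if (length(idx) < 3) return()
    for (j in 2:(length(idx) - 1)) {
      d1 <- xs[j] - xs[j - 1]; d2 <- xs[j + 1] - xs[j]
      if (d1 <= 0 || d2 <= 0) next
      sgn <- if (convex) 1 else -1
      r <- numeric(nv)
      r[idx[j - 1]] <- -d2 * sgn; r[idx[j]] <- (d1 + d2) * sgn
      r[idx[j + 1]] <- -d1 * sgn
      add(r, 0)
    }
  }
  shape(c(left_idx, at_idx, iGml), c(x[left_idx], x[at_idx], m),
        convex = TRUE)
  shape(c(iGmr, right_idx), c(m, x[right_idx]), convex = FALSE)
  cc <- numeric(nv); cc[iD] <- 1
  sol <- tryCatch(pracma::linprog(cc, A = A, b = b, maxiter = 2000),
                  error = function(e) NULL)
  if (is.null(sol) || !is.finite(sol$fval)) NA_real_ else sol$fval
}

dip_lp <- function(x, grid_per_seg = 10) {
  x <- sort(as.numeric(x)); n <- length(x)
  span <- diff(range(x))
  modes <- c(x, x[1] - 0.05 * span, x[n] + 0.05 * span)
  for (i in 1:(n - 1)) {
    if (x[i + 1] > x[i])
      modes <- c(modes, seq(x[i], x[i + 1],
                            length.out = grid_per_seg + 2)[-c(1, grid_per_seg + 2)])
  }
  vals <- vapply(modes, function(m) dip_lp_mode(x, m), numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  min(vals, na.rm = TRUE)
}
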