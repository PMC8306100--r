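#' Generalized inverse of a distribution function
#'
#' Computes \eqn{F^{-1}(p) = \inf\{x : F(x) \ge p\}} for a nondecreasing
#' \code{cdf} on \code{[lower, upper]} by bracketed bisection on the
#' predicate \eqn{F(x) \ge p}.  For strictly increasing \eqn{F} this is the
#' ordinary inverse to within \code{tol}; for flat or step cdfs it returns
#' the infimum of the level set.
#'
#' @param cdf nondecreasing function with range \code{[0,1]}.
#' @param p probability (vectorised), in \code{[0,1]}.
#' @param lower,upper support endpoints.
#' @param tol bisection tolerance (default \code{1e-12}).
#' @return numeric vector of quantiles.
#' @export
generalized_inverse <- function(cdf, p, lower = 0, upper = 1, tol = 1e-12) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]")
  vapply(p, function(pp) {
    if (pp <= 0) return(lower)
    if (cdf(lower) >= pp) return(lower)
    lo <- lower
    hi <- upper
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (cdf(mid) >= pp) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

#' Build the Rosenblatt transformation of a target density
#'
#' The Rosenblatt transformation \eqn{R} maps a d-variate target
#' distribution to the uniform distribution on \eqn{[0,1]^d} by composing
#' conditional cdfs coordinate by coordinate:
#' \eqn{z_k = F_k(x_k | x_1, \dots, x_{k-1})}.  In one dimension it is
#' simply the cdf, and the inverse is the (generalized) inverse
#' distribution function.  The Jacobian determinant of the forward map
#' equals the target pdf.
#'
#' There are \eqn{d!} such transformations, one per coordinate ordering;
#' \code{order} selects which (default the natural order).
#'
#' @param density an \code{analytic_density} or \code{grid_density}.
#' @param order permutation of \code{1:d} giving the conditioning order.
#' @return object of class \code{"rosenblatt"}: list with \code{d},
#'   \code{order}, vectorised closures \code{forward} (points to
#'   \eqn{[0,1]^d}), \code{inverse}, \code{jac_det} (equal to the target
#'   pdf), and \code{density}.
#' @export
build_rosenblatt <- function(density, order = seq_len(density$d)) {
  if (inherits(density, "analytic_density")) {
    structure(
      list(d = 1L, order = 1L,
           forward = function(x) pmin(pmax(density$cdf(x), 0), 1),
           inverse = function(z) density$idf(pmin(pmax(z, 0), 1)),
           jac_det = density$pdf,
           density = density, type = "analytic"),
      class = "rosenblatt")
  } else if (inherits(density, "grid_density")) {
    grid_rosenblatt(density, order)
  } else stop("unsupported density type")
}

#' Piecewise-linear Rosenblatt transformation of a grid density
#'
#' For a piecewise-constant grid density every conditional cdf is a
#' continuous piecewise-linear interpolation of cumulative cell masses, so
#' both the forward transformation and its inverse are evaluated by exact
#' piecewise-linear algebra (no iterative root finding).  All per-prefix
#' conditional cdf tables are precomputed; construction cost and memory are
#' linear in the total cell count.
#'
#' @inheritParams build_rosenblatt
#' @return a \code{"rosenblatt"} object (see \code{\link{build_rosenblatt}}).
#' @export
grid_rosenblatt <- function(density, order = seq_len(density$d)) {
  stopifnot(inherits(density, "grid_density"))
  d <- density$d
  if (length(order) != d || !setequal(order, seq_len(d)))
    stop("order must be a permutation of 1:", d)
  if (any(density$masses <= 0))
    stop("grid has zero-mass cells; rebuild with an epsilon floor")
  shape <- density$shape[order]
  A <- density$masses
  if (d > 1L) A <- aperm(array(A, dim = density$shape), order)

  # per-level conditional probability matrices P[[k]] (prefix-cell rows)
  # and cumulative tables C[[k]] with a leading zero column
  P <- vector("list", d)
  C <- vector("list", d)
  Sk <- A
  for (k in rev(seq_len(d))) {
    mk <- matrix(Sk, ncol = shape[k])          # rows = prefix cells
    tot <- rowSums(mk)
    P[[k]] <- mk / tot
    C[[k]] <- cbind(0, t(apply(P[[k]], 1L, cumsum)))
    C[[k]][, shape[k] + 1L] <- 1
    Sk <- if (k > 1L) apply(A, seq_len(k - 1L), sum) else sum(A)
  }

  row_of <- function(idx, k) {                 # mixed-radix prefix row id
    if (k == 1L) return(rep_len(1L, nrow(idx)))
    r <- idx[, 1L]
    if (k > 2L) for (j in 2:(k - 1L))
      r <- r + (idx[, j] - 1L) * prod(shape[seq_len(j - 1L)])
    r
  }

  forward <- function(x) {
    x <- as_points(x, d)[, order, drop = FALSE]
    n <- nrow(x)
    idx <- matrix(0L, n, d)
    z <- matrix(0, n, d)
    for (k in seq_len(d)) {
      idx[, k] <- cell_index(pmin(pmax(x[, k], 0), 1), shape[k])
      r <- row_of(idx, k)
      frac <- pmin(pmax(x[, k] * shape[k] - (idx[, k] - 1L), 0), 1)
      z[, k] <- C[[k]][cbind(r, idx[, k])] +
        frac * P[[k]][cbind(r, idx[, k])]
    }
    pmin(pmax(z, 0), 1)
  }

  inverse <- function(z) {
    z <- as_points(z, d)
    n <- nrow(z)
    x <- matrix(0, n, d)
    idx <- matrix(0L, n, d)
    for (k in seq_len(d)) {
      r <- row_of(idx, k)
      j <- integer(n)
      for (rr in unique(r)) {                  # group points by prefix cell
        sel <- which(r == rr)
        jj <- findInterval(z[sel, k], C[[k]][rr, ], all.inside = TRUE)
        j[sel] <- pmin(jj, shape[k])
      }
      pj <- P[[k]][cbind(r, j)]
      frac <- ifelse(pj > 0, (z[, k] - C[[k]][cbind(r, j)]) / pj, 0)
      x[, k] <- (j - 1L + pmin(pmax(frac, 0), 1)) / shape[k]
      idx[, k] <- j
    }
    xo <- matrix(0, n, d)
    xo[, order] <- x
    xo
  }

  structure(
    list(d = d, order = order, forward = forward, inverse = inverse,
         jac_det = function(x) grid_pdf(density, x),
         density = density, type = "grid",
         tables = list(P = P, C = C, shape = shape)),
    class = "rosenblatt")
}

#' @export
print.rosenblatt <- function(x, ...) {
  cat("Rosenblatt transformation (", x$type, "), d = ", x$d,
      ", order = (", paste(x$order, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Serialise a grid Rosenblatt transformation to JSON
#'
#' Writes the breakpoints and cumulative conditional masses defining a
#' piecewise-linear grid transformation, for reproducibility.
#'
#' @param transform a grid \code{"rosenblatt"} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
serialize_rosenblatt <- function(transform, path) {
  if (transform$type != "grid")
    stop("only grid transformations are serialisable")
  jsonlite::write_json(
    list(d = transform$d, order = transform$order,
         shape = transform$tables$shape,
         cumulative = lapply(transform$tables$C, function(m)
           unname(as.matrix(m)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sample from a target density
#'
#' Draws independent samples by inverse-transform sampling through the
#' density's own Rosenblatt inverse applied to a uniform stream.
#'
#' @param density supported target density.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return n x d matrix (vector when d = 1).
#' @export
sample_density <- function(density, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- build_rosenblatt(density)
  z <- matrix(stats::runif(n * density$d), ncol = density$d)
  x <- R$inverse(z)
  if (density$d == 1L) as.numeric(x) else x
}

#' Check that a transformation uniformises its target
#'
#' If \eqn{x \sim \rho} then \eqn{z = R(x)} must be uniform on
#' \eqn{[0,1]^d}.  This pushes a sample of the target through the forward
#' transformation and tests each coordinate of the output against the
#' uniform law (Kolmogorov-Smirnov) plus a joint binned chi-squared test.
#'
#' @param transform a \code{"rosenblatt"} object.
#' @param density the target density (used to draw the sample when
#'   \code{sample} is not supplied).
#' @param n sample size (>= 100).
#' @param seed RNG seed for the sample.
#' @param sample optional externally drawn sample from the target
#'   (vector or n x d matrix), e.g. from an independent rejection or
#'   known-distribution sampler, used as an oracle.
#' @param bins_per_axis bins per axis for the joint chi-squared test.
#' @param alpha significance level for the pass flag (default 0.01).
#' @return list with per-coordinate KS statistics and p-values, the joint
#'   chi-squared statistic, df and p-value, and a logical \code{pass}.
#' @export
verify_uniformization <- function(transform, density, n = 1e5, seed = 0,
                                  sample = NULL, bins_per_axis = 16L,
                                  alpha = 0.01) {
  if (n < 100) stop("n < 100: test underpowered")
  d <- transform$d
  x <- if (is.null(sample)) sample_density(density, n, seed)
       else sample
  z <- transform$forward(x)
  z <- as_points(z, d)
  ks_stat <- numeric(d)
  ks_p <- numeric(d)
  for (k in seq_len(d)) {
    kt <- stats::ks.test(z[, k], "punif")
    ks_stat[k] <- unname(kt$statistic)
    ks_p[k] <- kt$p.value
  }
  b <- bins_per_axis
  idx <- vapply(seq_len(d), function(k) cell_index(z[, k], b),
                integer(nrow(z)))
  idx <- matrix(idx, ncol = d)
  flat <- 1L + as.integer((idx - 1L) %*% cumprod(c(1, rep(b, d - 1L))))
  counts <- tabulate(flat, nbins = b^d)
  expected <- nrow(z) / b^d
  chisq <- sum((counts - expected)^2 / expected)
  df <- b^d - 1L
  chisq_p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  list(ks_statistic = ks_stat, ks_p = ks_p,
       chisq = chisq, df = df, chisq_p = chisq_p,
       n = nrow(z),
       pass = all(ks_p > alpha) && chisq_p > alpha)
}

#' Relate two Rosenblatt transformations of the same density
#'
#' Any two Rosenblatt transformations \eqn{R_1, R_2} of the same target are
#' linked by a uniform map \eqn{U = R_2 \circ R_1^{-1}}.  This returns that
#' composite as a \code{uniform_map} candidate together with an empirical
#' uniform-preservation diagnostic (binned chi-squared on a pushed-forward
#' uniform sample).
#'
#' @param R1,R2 \code{"rosenblatt"} objects for the same density.
#' @param n diagnostic sample size.
#' @param seed RNG seed.
#' @param bins_per_axis bins per axis for the chi-squared diagnostic.
#' @return list with \code{map} (a \code{uniform_map}) and
#'   \code{diagnostic} (chi-squared statistic, df, p-value, pass flag).
#' @export
relate_transforms <- function(R1, R2, n = 1e5, seed = 0,
                              bins_per_axis = 16L) {
  if (R1$d != R2$d) stop("dimension mismatch between transformations")
  d <- R1$d
  ev <- function(z) R2$forward(R1$inverse(z))
  U <- new_uniform_map(name = "related", d = d,
                       eval = if (d == 1L) function(x) as.numeric(ev(x))
                              else ev,
                       branches = NULL, exact_lyapunov = NULL,
                       params = list())
  set.seed(seed)
  z <- matrix(stats::runif(n * d), ncol = d)
  w <- as_points(U$eval(if (d == 1L) as.numeric(z) else z), d)
  b <- bins_per_axis
  idx <- vapply(seq_len(d), function(k) cell_index(w[, k], b),
                integer(n))
  idx <- matrix(idx, ncol = d)
  flat <- 1L + as.integer((idx - 1L) %*% cumprod(c(1, rep(b, d - 1L))))
  counts <- tabulate(flat, nbins = b^d)
  expected <- n / b^d
  chisq <- sum((counts - expected)^2 / expected)
  df <- b^d - 1L
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  list(map = U,
       diagnostic = list(chisq = chisq, df = df, p = p, pass = p > 0.01))
}
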