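# |J| for iterated or uniform maps, analytic where available
map_jacobian <- function(map, x, mode = c("analytic", "numerical")) {
  mode <- match.arg(mode)
  if (inherits(map, "uniform_map")) {
    if (mode == "analytic" && !is.null(map$branches))
      return(branch_slope(map, x))
    im <- new_iterated_map(map$name, map$d, map$eval,
                           monotone_partition =
                             if (!is.null(map$branches))
                               sort(unique(c(map$branches$lo,
                                             map$branches$hi))))
    return(numerical_jacobian(im, x))
  }
  if (mode == "analytic" && !is.null(map$jac_det)) map$jac_det(x)
  else numerical_jacobian(map, x)
}

map_breakpoints <- function(map) {
  if (inherits(map, "uniform_map")) {
    if (!is.null(map$branches))
      return(sort(unique(c(map$branches$lo, map$branches$hi))))
    return(c(0, 1))
  }
  map$monotone_partition %||% c(0, 1)
}

new_lyapunov <- function(value, mode, se = NA_real_, N = NA_integer_,
                         quad_error = NA_real_, jac_mode = NA_character_) {
  structure(list(value = value, mode = mode, se = se, N = N,
                 quad_error = quad_error, jac_mode = jac_mode),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("Lyapunov exponent (%s): %.6f nats", x$mode, x$value))
  if (is.finite(x$se)) cat(sprintf("  (se %.2g, N = %d)", x$se, x$N))
  if (is.finite(x$quad_error))
    cat(sprintf("  (quadrature error <= %.2g)", x$quad_error))
  cat("\n")
  invisible(x)
}

#' Empirical Lyapunov exponent from an orbit
#'
#' Estimates the Lyapunov exponent as the orbit average of
#' \eqn{\log|J(x_n)|}: \eqn{h \approx N^{-1} \sum_n \log|J(x_n)|}.  The
#' standard error is the per-step sample standard deviation of
#' \eqn{\log|J|} divided by \eqn{\sqrt N}; no burn-in is discarded.
#' Derivative evaluations that land exactly on a monotone-branch
#' breakpoint are replaced by a one-sided value (with a warning).
#'
#' @param map an \code{"iterated_map"} or 1-d \code{uniform_map}.
#' @param x0 starting state (default 0.3).
#' @param N orbit length (>= 1000).
#' @param jac_mode \code{"analytic"} (default; falls back if no analytic
#'   derivative is attached) or \code{"numerical"}.
#' @param guard apply the finite-precision guard (default TRUE).
#' @param seed unused for the deterministic orbit itself; kept so that all
#'   diagnostics share a seeding interface.
#' @return a \code{"lyapunov_estimate"} with \code{value}, \code{se},
#'   \code{N}.
#' @export
lyapunov_empirical <- function(map, x0 = 0.3, N = 1e4,
                               jac_mode = c("analytic", "numerical"),
                               guard = TRUE, seed = NULL) {
  jac_mode <- match.arg(jac_mode)
  if (N < 1e3) stop("N < 1000: orbit too short for a stable estimate")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(map, "uniform_map")) {
    im <- new_iterated_map(map$name, map$d, map$eval,
                           provenance = list(type = "uniform"))
    orb <- orbit(im, x0, N, guard = guard)
  } else {
    orb <- orbit(map, x0, N, guard = guard)
  }
  xs <- orb$states
  J <- map_jacobian(map, xs, jac_mode)
  bad <- !is.finite(J) | J == 0
  if (any(bad)) {
    warning(sum(bad), " derivative evaluation(s) at a breakpoint; ",
            "one-sided values substituted")
    xb <- if (map$d == 1L) pmin(pmax(xs[bad] + 1e-9, 0), 1) else xs[bad, ]
    J[bad] <- map_jacobian(map, xb, jac_mode)
  }
  lv <- log(abs(J))
  new_lyapunov(mean(lv), "empirical", se = stats::sd(lv) / sqrt(length(lv)),
               N = as.integer(N), jac_mode = jac_mode)
}

#' Theoretical Lyapunov exponent by quadrature
#'
#' Computes \eqn{h = \int \log|J(x)|\,\rho(x)\,dx} for a one-dimensional
#' map with invariant density \eqn{\rho}.  The integration interval is
#' split at the map's monotone-branch breakpoints (where \eqn{|J|} may
#' vanish, giving integrable log singularities) and at interior kinks of
#' the density; each piece is integrated adaptively.  For dimensions 2-3 a
#' seeded Monte Carlo estimate with standard error is returned.
#'
#' @param map \code{"iterated_map"} or 1-d \code{uniform_map} with an
#'   (analytic or numerical) Jacobian.
#' @param density the invariant density; defaults to the density attached
#'   to the map.
#' @param tol absolute quadrature tolerance (default 1e-9).
#' @param mc_n Monte Carlo sample size for d > 1.
#' @param seed Monte Carlo seed.
#' @return a \code{"lyapunov_estimate"}.
#' @export
lyapunov_theoretical <- function(map, density = NULL, tol = 1e-9,
                                 mc_n = 1e5, seed = 0) {
  density <- density %||% map$density
  if (is.null(density) && inherits(map, "uniform_map"))
    density <- make_analytic_density("uniform")
  if (is.null(density)) stop("no invariant density supplied or attached")
  d <- if (inherits(map, "uniform_map")) map$d else map$d
  if (d == 1L) {
    pdf <- if (inherits(density, "analytic_density")) density$pdf
           else function(x) grid_pdf(density, x)
    f <- function(x) log(abs(map_jacobian(map, x))) * pdf(x)
    cuts <- sort(unique(c(0, 1, map_breakpoints(map),
                          density_kinks(density))))
    cuts <- cuts[cuts >= 0 & cuts <= 1]
    total <- 0
    err <- 0
    for (i in seq_len(length(cuts) - 1L)) {
      if (cuts[i + 1L] - cuts[i] < 1e-14) next
      q <- stats::integrate(f, cuts[i], cuts[i + 1L],
                            rel.tol = 1e-11, abs.tol = tol,
                            subdivisions = 1000L, stop.on.error = FALSE)
      if (!q$message %in% c("OK", "roundoff error was detected"))
        stop("quadrature failed on [", cuts[i], ",", cuts[i + 1L],
             "]: ", q$message)
      total <- total + q$value
      err <- err + q$abs.error
    }
    if (!is.finite(total))
      stop("non-integrable divergence detected in log|J|")
    new_lyapunov(total, "theoretical", quad_error = err)
  } else if (d <= 3L) {
    set.seed(seed)
    x <- sample_density(density, mc_n)
    lv <- log(abs(map_jacobian(map, x)))
    new_lyapunov(mean(lv), "theoretical",
                 se = stats::sd(lv) / sqrt(length(lv)),
                 N = as.integer(mc_n))
  } else stop("quadrature supported for d <= 3 only")
}

# interior points where the pdf is non-smooth (quadrature split points)
density_kinks <- function(density) {
  if (inherits(density, "analytic_density")) {
    switch(density$family, triangular = 0.5, numeric(0))
  } else if (inherits(density, "grid_density") && density$d == 1L) {
    n <- density$shape[1L]
    seq_len(n - 1L) / n
  } else numeric(0)
}

#' Transfer-operator invariance residuals
#'
#' Verifies the fixed-point equation of the transfer (push-forward)
#' operator in one dimension:
#' \eqn{\rho(y) = \sum_{x \in M^{-1}(y)} \rho(x)/|M'(x)|}.  Inverse images
#' are enumerated branch-by-branch from the map's monotone partition, each
#' solved by bisection; the report records the residual at each evaluation
#' point.  Maps without a monotone partition (e.g. two-dimensional maps)
#' are not supported here - use the histogram-based distance check instead.
#'
#' @param map a 1-d \code{"iterated_map"} with \code{monotone_partition}.
#' @param density the invariant density to verify (defaults to the map's).
#' @param n_eval number of interior evaluation points.
#' @param pad distance of the evaluation grid from the support endpoints.
#' @return object of class \code{"invariance_report"}: data frame-bearing
#'   list with \code{table} (y, residual, n_branches), \code{max_abs},
#'   \code{rel_max} (relative to the largest evaluated density value) and
#'   \code{pass} (\code{rel_max <= 1e-6}).
#' @export
fp_residual <- function(map, density = NULL, n_eval = 101L, pad = 5e-3) {
  density <- density %||% map$density
  if (is.null(density)) stop("no density supplied or attached")
  if (map$d != 1L || is.null(map$monotone_partition))
    stop("map lacks a monotone-branch partition; use ",
         "orbit_distribution_distance for histogram-based checking")
  pdf <- if (inherits(density, "analytic_density")) density$pdf
         else function(x) grid_pdf(density, x)
  bp <- sort(unique(map$monotone_partition))
  ys <- seq(pad, 1 - pad, length.out = n_eval)
  push <- numeric(n_eval)
  nbr <- integer(n_eval)
  for (i in seq_len(length(bp) - 1L)) {
    a <- bp[i]; b <- bp[i + 1L]
    fa <- map$eval(a); fb <- map$eval(b)
    lo_v <- min(fa, fb); hi_v <- max(fa, fb)
    hit <- which(ys >= lo_v - 1e-12 & ys <= hi_v + 1e-12)
    if (length(hit) == 0L) next
    lo <- rep(a, length(hit)); hi <- rep(b, length(hit))
    increasing <- fb >= fa
    for (it in seq_len(60L)) {
      mid <- (lo + hi) / 2
      fm <- map$eval(mid)
      take_lo <- if (increasing) fm < ys[hit] else fm > ys[hit]
      lo <- ifelse(take_lo, mid, lo)
      hi <- ifelse(take_lo, hi, mid)
    }
    x <- (lo + hi) / 2
    J <- map_jacobian(map, x)
    push[hit] <- push[hit] + pdf(x) / abs(J)
    nbr[hit] <- nbr[hit] + 1L
  }
  res <- pdf(ys) - push
  tab <- data.frame(y = ys, residual = res, n_branches = nbr)
  structure(list(table = tab, max_abs = max(abs(res)),
                 rel_max = max(abs(res)) / max(pdf(ys)),
                 pass = max(abs(res)) / max(pdf(ys)) <= 1e-6),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat(sprintf(
    "Invariance residuals at %d points: max |res| = %.3g (rel %.3g) %s\n",
    nrow(x$table), x$max_abs, x$rel_max,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Ergodic average of an observable along an orbit
#'
#' Compares the orbit time-average \eqn{N^{-1}\sum_n g(x_n)} with the
#' expectation \eqn{\int g(x)\rho(x)dx} computed by quadrature under the
#' map's invariant density.
#'
#' @param map an \code{"iterated_map"} with an attached density (or pass
#'   \code{density}).
#' @param x0 starting state.
#' @param N orbit length (>= 1000).
#' @param g vectorised observable on the support.
#' @param guard apply the finite-precision guard.
#' @param density invariant density override.
#' @return list with \code{orbit_average}, \code{expectation},
#'   \code{gap} (absolute difference) and \code{N}.
#' @export
ergodic_average <- function(map, x0 = 0.3, N = 1e4, g = identity,
                            guard = TRUE, density = NULL) {
  if (N < 1e3) stop("N < 1000: orbit too short")
  density <- density %||% map$density
  if (is.null(density)) stop("no density supplied or attached")
  orb <- orbit(map, x0, N, guard = guard)
  avg <- if (map$d == 1L) mean(g(orb$states))
         else mean(apply(orb$states, 1L, g))
  if (map$d == 1L) {
    pdf <- if (inherits(density, "analytic_density")) density$pdf
           else function(x) grid_pdf(density, x)
    cuts <- sort(unique(c(0, density_kinks(density), 1)))
    expectation <- 0
    for (i in seq_len(length(cuts) - 1L))
      expectation <- expectation +
        stats::integrate(function(x) g(x) * pdf(x), cuts[i], cuts[i + 1L],
                         rel.tol = 1e-10, subdivisions = 500L)$value
  } else {
    # cell-midpoint expectation for grid densities
    stopifnot(inherits(density, "grid_density"))
    mids <- lapply(density$shape, function(n) (seq_len(n) - 0.5) / n)
    pts <- as.matrix(expand.grid(mids))
    expectation <- sum(apply(pts, 1L, g) * as.numeric(density$masses))
  }
  list(orbit_average = avg, expectation = expectation,
       gap = abs(avg - expectation), N = as.integer(N))
}

#' Distance between an orbit's empirical distribution and the target
#'
#' Bins the orbit and reports the total-variation distance between the
#' normalised histogram and the target's bin masses; in one dimension the
#' Kolmogorov-Smirnov statistic against the target cdf is also returned.
#'
#' @param orb an \code{"ifpp_orbit"} (or numeric vector / matrix of
#'   states).
#' @param density the target density.
#' @param bins bins per axis (>= 10).  For a 2-d grid density the default
#'   uses the density's own cell grid.
#' @return list with \code{tv}, and for d = 1 also \code{ks}.
#' @export
orbit_distribution_distance <- function(orb, density, bins = NULL) {
  states <- if (inherits(orb, "ifpp_orbit")) orb$states else orb
  d <- density$d
  if (d == 1L) {
    x <- as.numeric(states)
    bins <- bins %||% 100L
    if (bins < 10L) stop("bins must be >= 10")
    idx <- cell_index(pmin(pmax(x, 0), 1), bins)
    counts <- tabulate(idx, nbins = bins)
    edges <- seq_len(bins) / bins
    target <- diff(c(0, density_cdf(density, edges)))
    tv <- 0.5 * sum(abs(counts / length(x) - target))
    xs <- sort(x)
    Fx <- density_cdf(density, xs)
    n <- length(xs)
    ks <- max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1L) / n))
    list(tv = tv, ks = ks, bins = bins, n = n)
  } else {
    x <- as_points(states, d)
    if (!is.null(bins)) {
      b <- rep_len(bins, d)
    } else if (inherits(density, "grid_density")) {
      b <- density$shape
    } else stop("bins required for this density")
    idx <- matrix(vapply(seq_len(d),
                         function(k) cell_index(pmin(pmax(x[, k], 0), 1),
                                                b[k]),
                         integer(nrow(x))), ncol = d)
    flat <- 1L + as.integer((idx - 1L) %*% cumprod(c(1, b[-d])))
    counts <- tabulate(flat, nbins = prod(b))
    target <- bin_masses(density, b)
    tv <- 0.5 * sum(abs(counts / nrow(x) - target))
    list(tv = tv, bins = b, n = nrow(x))
  }
}

# target probability mass in each bin of a regular b[1] x ... x b[d] grid
bin_masses <- function(density, b) {
  stopifnot(inherits(density, "grid_density"))
  shape <- density$shape
  if (all(b == shape)) return(as.numeric(density$masses))
  if (any(shape %% b != 0))
    stop("bins must divide the density grid shape")
  m <- array(density$masses, dim = shape)
  fac <- shape %/% b
  # bin index of every cell, mixed-radix flattened
  cell_bins <- lapply(seq_along(shape),
                      function(k) (seq_len(shape[k]) - 1L) %/% fac[k] + 1L)
  grp <- as.matrix(expand.grid(cell_bins))
  flat <- 1L + as.integer((grp - 1L) %*% cumprod(c(1, b[-length(b)])))
  as.numeric(rowsum(as.numeric(m), flat))
}
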