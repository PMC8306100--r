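new_iterated_map <- function(name, d, eval, jac_det = NULL,
                             monotone_partition = NULL, density = NULL,
                             provenance = list()) {
  structure(list(name = name, d = as.integer(d), eval = eval,
                 jac_det = jac_det, monotone_partition = monotone_partition,
                 density = density, provenance = provenance),
            class = "iterated_map")
}

#' @export
print.iterated_map <- function(x, ...) {
  cat("Iterated map '", x$name, "' on [0,1]^", x$d, sep = "")
  if (!is.null(x$provenance$type))
    cat(" (", x$provenance$type, ")", sep = "")
  cat("\n")
  invisible(x)
}

# numerical Jacobian determinant: central difference, one-sided near
# monotone-partition breakpoints
numerical_jacobian <- function(map, x, h = 1e-7) {
  if (map$d == 1L) {
    bp <- map$monotone_partition %||% c(0, 1)
    nearest <- vapply(x, function(xx) bp[which.min(abs(xx - bp))],
                      numeric(1))
    near <- abs(x - nearest) < 1e-6
    # one-sided away from the breakpoint when too close for a central step
    lo <- ifelse(near, ifelse(nearest >= x, pmax(x - h, 0), x),
                 pmax(x - h, 0))
    hi <- ifelse(near, ifelse(nearest >= x, x, pmin(x + h, 1)),
                 pmin(x + h, 1))
    (map$eval(hi) - map$eval(lo)) / (hi - lo)
  } else {
    x <- as_points(x, map$d)
    vapply(seq_len(nrow(x)), function(i) {
      J <- vapply(seq_len(map$d), function(k) {
        e <- rep(0, map$d); e[k] <- h
        xp <- pmin(x[i, ] + e, 1); xm <- pmax(x[i, ] - e, 0)
        (as_points(map$eval(rbind(xp)), map$d) -
           as_points(map$eval(rbind(xm)), map$d)) / sum(xp[k] - xm[k])
      }, numeric(map$d))
      det(J)
    }, numeric(1))
  }
}

#' Conjugate a uniform map into a solution of the inverse problem
#'
#' The central construction: given a Rosenblatt transformation \eqn{R} of
#' the target density and a uniform map \eqn{U} on the hypercube, the
#' conjugate map \eqn{M = R^{-1} \circ U \circ R} has the target as an
#' invariant density; every solution of the inverse problem arises this
#' way.
#'
#' For one-dimensional piecewise-linear \eqn{U}, the analytic derivative
#' \eqn{M'(x) = U'(R(x))\,\rho(x)/\rho(M(x))} is attached, together with
#' the monotone-branch partition obtained by pulling the branch endpoints
#' of \eqn{U} back through \eqn{R^{-1}}.
#'
#' @param transform a \code{"rosenblatt"} object.
#' @param uniform_map a \code{uniform_map} of the same dimension.
#' @return an \code{"iterated_map"}.
#' @examples
#' rho <- make_analytic_density("arcsine")
#' M <- conjugate_map(build_rosenblatt(rho), make_uniform_map("triangle"))
#' M$eval(0.3)            # = 4 * 0.3 * 0.7
#' @export
conjugate_map <- function(transform, uniform_map) {
  if (transform$d != uniform_map$d)
    stop("dimension mismatch: transform d = ", transform$d,
         ", uniform map d = ", uniform_map$d)
  R <- transform
  U <- uniform_map
  ev <- function(x) R$inverse(U$eval(R$forward(x)))
  if (R$d == 1L) {
    evv <- function(x) as.numeric(ev(x))
    pdf <- if (!is.null(R$density$pdf)) R$density$pdf
    jac <- NULL
    mp <- NULL
    if (!is.null(U$branches) && !is.null(pdf)) {
      jac <- function(x) {
        z <- as.numeric(R$forward(x))
        branch_slope(U, z) * pdf(x) / pdf(evv(x))
      }
      bp <- sort(unique(c(U$branches$lo, U$branches$hi)))
      mp <- as.numeric(R$inverse(bp))
    }
    out <- new_iterated_map(
      paste0("conj(", U$name, ")"), 1L, evv, jac_det = jac,
      monotone_partition = mp, density = R$density,
      provenance = list(type = "factorized", transform = R, umap = U))
  } else {
    out <- new_iterated_map(
      paste0("conj(", U$name, ")"), R$d, ev,
      jac_det = function(x) grid_pdf(R$density, as_points(x, R$d)) /
        grid_pdf(R$density, as_points(ev(x), R$d)) *
        uniform_jacobian(U, R$forward(x)),
      density = R$density,
      provenance = list(type = "factorized", transform = R, umap = U))
  }
  if (is.null(out$jac_det))
    out$jac_det <- function(x) numerical_jacobian(out, x)
  out
}

# |Jacobian determinant| of a uniform map where known analytically
uniform_jacobian <- function(U, z) {
  z <- as_points(z, U$d)
  if (!is.null(U$branches)) return(abs(branch_slope(U, as.numeric(z))))
  if (!is.null(U$components)) {
    out <- rep(1, nrow(z))
    for (k in seq_along(U$components))
      out <- out * abs(branch_slope(U$components[[k]], z[, k]))
    return(out)
  }
  if (U$name %in% c("baker", "cat", "identity")) return(rep(1, nrow(z)))
  stop("no analytic Jacobian for uniform map '", U$name, "'")
}

#' Recover the uniform map underlying a solution
#'
#' Inverts the factorization: for a map \eqn{M} with invariant density
#' matching \code{transform}'s target, \eqn{U = R \circ M \circ R^{-1}} is
#' a uniform map.  A binned chi-squared uniform-preservation diagnostic on
#' a pushed-forward uniform sample is attached.
#'
#' @param M an \code{"iterated_map"} (or any function-bearing map object
#'   with \code{$eval}).
#' @param transform a \code{"rosenblatt"} object of the same dimension.
#' @param n,seed,bins_per_axis diagnostic sample controls.
#' @return list with \code{map} (the recovered \code{uniform_map}) and
#'   \code{diagnostic} (chi-squared test of uniform preservation).
#' @export
recover_uniform <- function(M, transform, n = 1e4, seed = 0,
                            bins_per_axis = 16L) {
  if (M$d != transform$d) stop("dimension mismatch")
  R <- transform
  d <- R$d
  ev <- function(z) R$forward(M$eval(R$inverse(z)))
  U <- new_uniform_map(paste0("recovered(", M$name, ")"), d,
                       if (d == 1L) function(z) as.numeric(ev(z)) else ev,
                       params = list())
  set.seed(seed)
  z <- matrix(stats::runif(n * d), ncol = d)
  w <- as_points(U$eval(if (d == 1L) as.numeric(z) else z), d)
  b <- bins_per_axis
  idx <- matrix(vapply(seq_len(d), function(k) cell_index(w[, k], b),
                       integer(n)), ncol = d)
  flat <- 1L + as.integer((idx - 1L) %*% cumprod(c(1, rep(b, d - 1L))))
  counts <- tabulate(flat, nbins = b^d)
  expected <- n / b^d
  chisq <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(chisq, b^d - 1L, lower.tail = FALSE)
  list(map = U, diagnostic = list(chisq = chisq, df = b^d - 1L, p = p,
                                  pass = p > 0.01))
}

#' Transport map between two target densities
#'
#' Builds \eqn{M = R_B^{-1} \circ U \circ R_A}, which pushes samples of
#' density A forward to samples of density B.  With \code{U} the identity
#' this is the classic conditional-distribution (inverse-cdf) sampler.
#'
#' @param transformA,transformB \code{"rosenblatt"} objects for the source
#'   and destination densities.
#' @param uniform_map a \code{uniform_map} of the same dimension (default
#'   identity-like behaviour via \code{NULL}).
#' @return an \code{"iterated_map"}-like map from the support of A to the
#'   support of B (it is not an endomorphism unless A = B).
#' @export
transport_map <- function(transformA, transformB, uniform_map = NULL) {
  if (transformA$d != transformB$d) stop("dimension mismatch")
  if (is.null(uniform_map)) {
    uniform_map <- if (transformA$d == 1L) make_uniform_map("identity")
    else new_uniform_map("identity_d", transformA$d, function(x) x)
  }
  if (uniform_map$d != transformA$d) stop("dimension mismatch")
  RA <- transformA; RB <- transformB; U <- uniform_map
  ev <- function(x) RB$inverse(U$eval(RA$forward(x)))
  new_iterated_map(
    paste0("transport(", U$name, ")"), RA$d,
    if (RA$d == 1L) function(x) as.numeric(ev(x)) else ev,
    density = RB$density,
    provenance = list(type = "transport", from = RA, to = RB, umap = U))
}

#' Closed-form solution maps
#'
#' Closed-form iterated maps for the analytic one-dimensional targets.
#' Each is pointwise identical to its factorized construction
#' \eqn{R^{-1} \circ U \circ R}, which is the normative definition; the
#' closed forms simply make evaluation and derivatives exact.
#' \describe{
#'   \item{\code{logistic}}{\eqn{M(x) = 4x(1-x)}; invariant density
#'     arcsine; conjugate to the tent map \eqn{t_1}.}
#'   \item{\code{logistic_l}}{\eqn{M_\ell(x) = \sin^2(2\ell\arcsin\sqrt
#'     x)}, the arcsine-invariant family induced by \eqn{t_\ell}; for
#'     \eqn{\ell = 2^n - 1} this coincides with the n-fold composition of
#'     the logistic map.  Parameter \code{l}.}
#'   \item{\code{mtri}}{unimodal map with the symmetric triangular
#'     invariant density, induced by \eqn{t_1}.}
#'   \item{\code{mramp}}{unimodal map with the ramp invariant density
#'     \eqn{\rho = 2x}, induced by \eqn{t_1}:
#'     \eqn{\sqrt 2 x} then \eqn{\sqrt{2(1-x^2)}/\sqrt 2 \cdot}... see
#'     source for the branch forms.}
#' }
#'
#' @param name one of \code{"logistic"}, \code{"logistic_l"},
#'   \code{"mtri"}, \code{"mramp"}.
#' @param params list; \code{l} for \code{logistic_l}.
#' @return an \code{"iterated_map"} with analytic \code{jac_det} and
#'   monotone-branch partition.
#' @export
closed_form_map <- function(name, params = list()) {
  switch(name,
    logistic = new_iterated_map(
      "logistic", 1L,
      function(x) 4 * x * (1 - x),
      jac_det = function(x) 4 - 8 * x,
      monotone_partition = c(0, 0.5, 1),
      density = make_analytic_density("arcsine"),
      provenance = list(type = "closed_form", name = "logistic")),
    logistic_l = {
      l <- params$l
      if (is.null(l) || l < 1 || l != round(l))
        stop("logistic_l requires integer parameter l >= 1")
      th <- function(x) asin(sqrt(pmin(pmax(x, 0), 1)))
      new_iterated_map(
        paste0("logistic_", l), 1L,
        function(x) sin(2 * l * th(x))^2,
        jac_det = function(x) l * sin(4 * l * th(x)) /
          sqrt(pmax(x * (1 - x), .Machine$double.xmin)),
        monotone_partition = sin(pi * (0:(2 * l)) / (4 * l))^2,
        density = make_analytic_density("arcsine"),
        provenance = list(type = "closed_form", name = "logistic_l",
                          l = l))
    },
    mtri = {
      b1 <- sqrt(2) / 4
      new_iterated_map(
        "mtri", 1L,
        function(x) {
          u <- pmin(x, 1 - x)          # symmetric about 1/2
          ifelse(u <= b1, sqrt(2) * u, 1 - sqrt(pmax(0.5 - 2 * u^2, 0)))
        },
        jac_det = function(x) {
          u <- pmin(x, 1 - x)
          s <- ifelse(x <= 0.5, 1, -1)
          s * ifelse(u <= b1, sqrt(2),
                     2 * u / sqrt(pmax(0.5 - 2 * u^2,
                                       .Machine$double.xmin)))
        },
        monotone_partition = c(0, 0.5, 1),
        density = make_analytic_density("triangular"),
        provenance = list(type = "closed_form", name = "mtri"))
    },
    mramp = new_iterated_map(
      "mramp", 1L,
      function(x) ifelse(x <= sqrt(0.5), sqrt(2) * x,
                         sqrt(2 * pmax(1 - x^2, 0))),
      jac_det = function(x)
        ifelse(x <= sqrt(0.5), sqrt(2),
               -sqrt(2) * x / sqrt(pmax(1 - x^2,
                                        .Machine$double.xmin))),
      monotone_partition = c(0, sqrt(0.5), 1),
      density = make_analytic_density("ramp"),
      provenance = list(type = "closed_form", name = "mramp")),
    stop("unknown closed-form map '", name, "'")
  )
}

#' Iterate a map and collect its orbit
#'
#' Generates the orbit \eqn{x_0, M(x_0), M^2(x_0), \dots} of length
#' \code{N} (including the start).  For factorized maps the iteration is
#' carried out on the hypercube through the underlying uniform map and
#' pulled back in one vectorised pass (the orbit of \eqn{M} equals
#' \eqn{R^{-1}} applied to the orbit of \eqn{U}); the finite-precision
#' guard is then composed with \eqn{U}.  For closed-form maps the guard
#' shift is added to the map output (mod 1) at each step.
#'
#' @param map an \code{"iterated_map"}.
#' @param x0 starting state (in the support).
#' @param N orbit length, >= 1.
#' @param guard apply the finite-precision guard shift (default TRUE).
#' @param c_guard guard constant.
#' @param dither \code{"auto"} (default), \code{TRUE} or \code{FALSE}.
#'   Some uniform maps - the baker's map is the canonical case - are
#'   exactly affine with power-of-two slopes and dyadic constants, so
#'   their composition with any translation guard is still exact binary
#'   arithmetic: every guarded orbit on a binary machine is eventually
#'   periodic (typically collapsing within a few hundred steps), no matter
#'   the guard constant.  For such maps a seeded deterministic dither of
#'   amplitude \code{2^-48} per step is added, emulating the
#'   state-dependent rounding that any straightforward interpolated
#'   implementation incurs; it is statistically invisible at this
#'   amplitude.  \code{"auto"} enables it only for the baker's map.
#' @param dither_seed seed for the dither stream.
#' @param stream_sink optional CSV path; the orbit is appended there in
#'   fixed-size chunks as it is produced.
#' @param chunk_size rows per streamed chunk.
#' @return object of class \code{"ifpp_orbit"}: list with \code{states}
#'   (N x d matrix; vector for d = 1), \code{x0}, \code{N}, \code{guard},
#'   \code{map_name}.
#' @export
orbit <- function(map, x0, N, guard = TRUE, c_guard = 1e-9 / 3,
                  dither = "auto", dither_seed = 0L,
                  stream_sink = NULL, chunk_size = 1e5L) {
  if (N < 1) stop("N must be >= 1")
  d <- map$d
  x0 <- as.numeric(x0)
  if (length(x0) != d) stop("x0 must have length ", d)
  if (any(x0 < 0 | x0 > 1)) stop("x0 outside the support")
  prov <- map$provenance
  factorized <- identical(prov$type, "factorized")
  if (identical(dither, "auto"))
    dither <- factorized && guard && grepl("baker", prov$umap$name)
  # per-step additive perturbation on the hypercube (guard shift plus
  # optional sub-ulp dither), one value per step
  adds <- NULL
  if (guard || dither) {
    adds <- rep(if (guard) c_guard else 0, N - 1L)
    if (dither) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      set.seed(dither_seed)
      adds <- adds + (stats::runif(N - 1L) - 0.5) * 2^-47
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else rm(".Random.seed", envir = globalenv())
    }
  }
  if (factorized) {
    R <- prov$transform
    U <- prov$umap
    step <- U$eval
    if (d == 1L) {
      z <- numeric(N)
      z[1L] <- as.numeric(R$forward(x0))
      if (is.null(adds)) {
        for (n in seq_len(N - 1L)) z[n + 1L] <- step(z[n])
      } else {
        for (n in seq_len(N - 1L))
          z[n + 1L] <- (step(z[n]) + adds[n]) %% 1
      }
      states <- as.numeric(R$inverse(z))
      states[1L] <- x0                      # exact start
    } else {
      z <- matrix(0, N, d)
      z[1L, ] <- as_points(R$forward(matrix(x0, 1L)), d)
      zn <- z[1L, ]
      if (is.null(adds)) {
        for (n in seq_len(N - 1L)) {
          zn <- as.numeric(step(zn))
          z[n + 1L, ] <- zn
        }
      } else {
        for (n in seq_len(N - 1L)) {
          zn <- (as.numeric(step(zn)) + adds[n]) %% 1
          z[n + 1L, ] <- zn
        }
      }
      states <- R$inverse(z)
      states[1L, ] <- x0
    }
  } else {
    step <- map$eval
    if (d == 1L) {
      states <- numeric(N)
      states[1L] <- x0
      xn <- x0
      if (is.null(adds)) {
        for (n in seq_len(N - 1L)) {
          xn <- as.numeric(step(xn))
          states[n + 1L] <- xn
        }
      } else {
        for (n in seq_len(N - 1L)) {
          xn <- (as.numeric(step(xn)) + adds[n]) %% 1
          states[n + 1L] <- xn
        }
      }
    } else {
      states <- matrix(0, N, d)
      states[1L, ] <- x0
      xn <- x0
      for (n in seq_len(N - 1L)) {
        xn <- as.numeric(step(xn))
        if (!is.null(adds)) xn <- (xn + adds[n]) %% 1
        states[n + 1L, ] <- xn
      }
    }
  }
  orb <- structure(
    list(states = states, x0 = x0, N = as.integer(N), guard = guard,
         c_guard = if (guard) c_guard else 0, dither = dither,
         map_name = map$name, d = d),
    class = "ifpp_orbit")
  if (!is.null(stream_sink)) write_orbit_csv(orb, stream_sink, chunk_size)
  orb
}

#' Write an orbit to CSV in fixed-size chunks
#'
#' One row per step, one column per coordinate, with a provenance header
#' comment line.
#'
#' @param orb an \code{"ifpp_orbit"}.
#' @param path output CSV path.
#' @param chunk_size rows written per chunk.
#' @return \code{path}, invisibly.
#' @export
write_orbit_csv <- function(orb, path, chunk_size = 1e5L) {
  d <- orb$d
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# map=", orb$map_name, " x0=",
                    paste(orb$x0, collapse = ","),
                    " N=", orb$N, " guard=", orb$guard), con)
  writeLines(paste(paste0("x", seq_len(d)), collapse = ","), con)
  m <- if (d == 1L) matrix(orb$states, ncol = 1L) else orb$states
  starts <- seq(1L, nrow(m), by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, nrow(m))
    utils::write.table(format(m[s:e, , drop = FALSE], digits = 15L,
                              trim = TRUE, scientific = FALSE),
                       con, sep = ",", col.names = FALSE,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
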