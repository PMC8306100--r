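# Constructor shared by all uniform-map builders.  `branches` (1D
# piecewise-linear maps only) is a data.frame(lo, hi, slope, intercept)
# covering [0,1] with contiguous intervals.
new_uniform_map <- function(name, d, eval, branches = NULL,
                            exact_lyapunov = NULL, params = list()) {
  structure(list(name = name, d = as.integer(d), eval = eval,
                 branches = branches, exact_lyapunov = exact_lyapunov,
                 params = params),
            class = "uniform_map")
}

#' @export
print.uniform_map <- function(x, ...) {
  cat("Uniform map '", x$name, "' on [0,1)^", x$d, sep = "")
  if (!is.null(x$exact_lyapunov))
    cat(", exact Lyapunov", format(x$exact_lyapunov))
  cat("\n")
  invisible(x)
}

branch_eval <- function(branches) {
  breaks <- c(branches$lo[1L], branches$hi)
  force(breaks)
  function(x) {
    x <- ifelse(x >= 1, x - floor(x), x)      # wrap inputs onto [0,1)
    i <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              nrow(branches))
    branches$slope[i] * x + branches$intercept[i]
  }
}

#' Catalog of uniform (Lebesgue-measure-preserving) maps
#'
#' Constructs a map of the unit hypercube to itself under which the uniform
#' distribution is invariant.  These are the building blocks of the
#' factorization \eqn{M = R^{-1} \circ U \circ R}: conjugating any of them
#' with a Rosenblatt transformation yields a map with the prescribed
#' invariant density.  Available maps (with exact Lyapunov exponents in
#' nats, where known):
#' \describe{
#'   \item{\code{identity}}{\eqn{I(x) = x}; h = 0.}
#'   \item{\code{translation}}{circle shift \eqn{T_c(y) = y + c \bmod 1},
#'     parameter \code{c} in \code{[0,1)}; h = 0.}
#'   \item{\code{triangle}}{tent map \eqn{t_1(x) = 1 - 2|x - 1/2|};
#'     h = log 2.}
#'   \item{\code{sawtooth}}{\eqn{s_\ell(x) = \ell x \bmod 1}, integer
#'     \code{l >= 1}; h = log \eqn{\ell}.}
#'   \item{\code{triangle_l}}{\eqn{\ell}-period triangle wave
#'     \eqn{t_\ell = t_1 \circ s_\ell} (the sawtooth folded through the
#'     tent); h = log \eqn{2\ell}.}
#'   \item{\code{asym_triangle}}{asymmetric tent with peak at \code{c} in
#'     \code{(0,1)}: \eqn{x/c} then \eqn{(1-x)/(1-c)};
#'     \eqn{h = -c\log c - (1-c)\log(1-c)}.}
#'   \item{\code{baker}}{baker's map of the unit square.}
#'   \item{\code{cat}}{Arnold cat map of the unit square (mod 1).}
#' }
#'
#' One-dimensional catalog maps carry their monotone affine branch
#' structure, from which Lebesgue invariance (the inverse-branch sum
#' \eqn{\sum 1/|slope| = 1}) can be verified directly.
#'
#' @param name map name, see Details.
#' @param params named list of parameters (\code{c} for translation and
#'   asym_triangle, \code{l} for sawtooth and triangle_l).
#' @return object of class \code{"uniform_map"}: list with \code{name},
#'   \code{d}, vectorised \code{eval}, optional \code{branches}
#'   (data frame \code{lo, hi, slope, intercept}), and
#'   \code{exact_lyapunov} (nats, or NULL).
#' @examples
#' t1 <- make_uniform_map("triangle")
#' t1$eval(c(0.25, 0.5, 0.75))   # 0.5 1.0 0.5
#' @export
make_uniform_map <- function(name, params = list()) {
  switch(name,
    identity = new_uniform_map(
      "identity", 1L, function(x) x,
      branches = data.frame(lo = 0, hi = 1, slope = 1, intercept = 0),
      exact_lyapunov = 0, params = params),
    translation = {
      cc <- params$c
      if (is.null(cc) || cc < 0 || cc >= 1)
        stop("translation requires parameter c in [0,1)")
      br <- if (cc == 0)
        data.frame(lo = 0, hi = 1, slope = 1, intercept = 0)
      else
        data.frame(lo = c(0, 1 - cc), hi = c(1 - cc, 1),
                   slope = c(1, 1), intercept = c(cc, cc - 1))
      new_uniform_map("translation", 1L,
                      function(x) (x + cc) %% 1,
                      branches = br, exact_lyapunov = 0, params = params)
    },
    triangle = new_uniform_map(
      "triangle", 1L, function(x) 1 - 2 * abs(x %% 1 - 0.5),
      branches = data.frame(lo = c(0, 0.5), hi = c(0.5, 1),
                            slope = c(2, -2), intercept = c(0, 2)),
      exact_lyapunov = log(2), params = params),
    sawtooth = {
      l <- params$l
      if (is.null(l) || l < 1 || l != round(l))
        stop("sawtooth requires integer parameter l >= 1")
      i <- seq_len(l)
      new_uniform_map("sawtooth", 1L,
                      function(x) (l * x) %% 1,
                      branches = data.frame(lo = (i - 1) / l, hi = i / l,
                                            slope = l, intercept = -(i - 1)),
                      exact_lyapunov = log(l), params = params)
    },
    triangle_l = {
      l <- params$l
      if (is.null(l) || l < 1 || l != round(l))
        stop("triangle_l requires integer parameter l >= 1")
      i <- seq_len(2 * l)
      up <- i %% 2L == 1L
      new_uniform_map("triangle_l", 1L,
                      function(x) 1 - 2 * abs((l * x) %% 1 - 0.5),
                      branches = data.frame(
                        lo = (i - 1) / (2 * l), hi = i / (2 * l),
                        slope = ifelse(up, 2 * l, -2 * l),
                        intercept = ifelse(up, -(i - 1), i)),
                      exact_lyapunov = log(2 * l), params = params)
    },
    asym_triangle = {
      cc <- params$c
      if (is.null(cc) || cc <= 0 || cc >= 1)
        stop("asym_triangle requires parameter c in (0,1)")
      new_uniform_map("asym_triangle", 1L,
                      function(x) ifelse(x <= cc, x / cc,
                                         (1 - x) / (1 - cc)),
                      branches = data.frame(
                        lo = c(0, cc), hi = c(cc, 1),
                        slope = c(1 / cc, -1 / (1 - cc)),
                        intercept = c(0, 1 / (1 - cc))),
                      exact_lyapunov = -cc * log(cc) -
                        (1 - cc) * log(1 - cc),
                      params = params)
    },
    baker = new_uniform_map(
      "baker", 2L,
      function(x) {
        x <- as_points(x, 2L)
        left <- x[, 1L] < 0.5
        cbind(ifelse(left, 2 * x[, 1L], 2 * x[, 1L] - 1),
              ifelse(left, x[, 2L] / 2, (x[, 2L] + 1) / 2))
      },
      params = params),
    cat = new_uniform_map(
      "cat", 2L,
      function(x) {
        x <- as_points(x, 2L)
        cbind((2 * x[, 1L] + x[, 2L]) %% 1, (x[, 1L] + x[, 2L]) %% 1)
      },
      params = params),
    stop("unknown uniform map '", name, "'")
  )
}

# evaluate branch slope of a 1D piecewise-linear map at points x
# (ties at interior breakpoints take the left branch)
branch_slope <- function(map, x) {
  br <- map$branches
  if (is.null(br)) stop("map '", map$name, "' has no branch structure")
  breaks <- c(br$lo[1L], br$hi)
  i <- findInterval(x, breaks, left.open = TRUE, all.inside = TRUE)
  br$slope[i]
}

#' Compose two uniform maps
#'
#' Returns \eqn{U_1 \circ U_2} (apply \code{U2} first).  The composition of
#' uniform maps is again a uniform map.  When both operands are
#' one-dimensional piecewise-linear maps, the composite's affine branch
#' structure is derived exactly, so Lebesgue invariance remains checkable
#' branch-by-branch.
#'
#' @param U1,U2 \code{uniform_map}s of equal dimension.
#' @return a \code{uniform_map}.
#' @examples
#' t3 <- make_uniform_map("triangle_l", list(l = 3))
#' t1s3 <- compose_maps(make_uniform_map("triangle"),
#'                      make_uniform_map("sawtooth", list(l = 3)))
#' max(abs(t3$eval(seq(0, 1, .001)) - t1s3$eval(seq(0, 1, .001))))
#' @export
compose_maps <- function(U1, U2) {
  if (U1$d != U2$d) stop("dimension mismatch: ", U1$d, " vs ", U2$d)
  branches <- if (!is.null(U1$branches) && !is.null(U2$branches))
    compose_branches(U1$branches, U2$branches)
  ev1 <- U1$eval
  ev2 <- U2$eval
  new_uniform_map(paste0(U1$name, "∘", U2$name), U1$d,
                  function(x) ev1(ev2(x)),
                  branches = branches,
                  exact_lyapunov = NULL,
                  params = list(outer = U1$params, inner = U2$params))
}

# exact affine-branch composition for 1D piecewise-linear maps
compose_branches <- function(br1, br2) {
  breaks1 <- sort(unique(c(br1$lo, br1$hi)))
  out <- vector("list", nrow(br2))
  for (i in seq_len(nrow(br2))) {
    a <- br2$slope[i]; b <- br2$intercept[i]
    lo <- br2$lo[i]; hi <- br2$hi[i]
    cand <- (breaks1 - b) / a
    cand <- cand[cand > lo + 1e-15 & cand < hi - 1e-15]
    cuts <- sort(unique(c(lo, cand, hi)))
    los <- cuts[-length(cuts)]
    his <- cuts[-1L]
    mid <- (los + his) / 2
    y <- a * mid + b
    y <- ifelse(y >= 1, y - floor(y), ifelse(y < 0, y - floor(y), y))
    j <- findInterval(y, c(br1$lo[1L], br1$hi), all.inside = TRUE)
    out[[i]] <- data.frame(lo = los, hi = his,
                           slope = br1$slope[j] * a,
                           intercept = br1$slope[j] * b + br1$intercept[j])
  }
  res <- do.call(rbind, out)
  res[order(res$lo), , drop = FALSE]
}

#' Coordinate-wise product of one-dimensional uniform maps
#'
#' Builds the d-dimensional uniform map
#' \eqn{U(x) = (U_1(x_1), \dots, U_d(x_d))} acting independently on each
#' coordinate.
#'
#' @param ... one-dimensional \code{uniform_map}s (or a single list of
#'   them).
#' @return a d-dimensional \code{uniform_map} with the components stored in
#'   \code{$components}.
#' @export
coordinatewise <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && !inherits(maps[[1L]], "uniform_map"))
    maps <- maps[[1L]]
  if (length(maps) == 0L) stop("no component maps supplied")
  if (any(vapply(maps, function(m) m$d, integer(1)) != 1L))
    stop("all component maps must be one-dimensional")
  d <- length(maps)
  evs <- lapply(maps, `[[`, "eval")
  U <- new_uniform_map(
    paste0("(", paste(vapply(maps, `[[`, "", "name"), collapse = ","), ")"),
    d,
    function(x) {
      x <- as_points(x, d)
      vapply(seq_len(d), function(k) evs[[k]](x[, k]), numeric(nrow(x)))
    },
    params = lapply(maps, `[[`, "params"))
  U$components <- maps
  U
}

#' Partition-and-permute construction of new uniform maps
#'
#' Partitions the domain of a one-dimensional uniform map into \code{n}
#' equal subintervals and permutes them before applying the base map.  The
#' permutation step is itself a measure-preserving piecewise translation,
#' so the result is again a uniform map; its branch invariance is
#' re-checked on construction.
#'
#' @param base a one-dimensional \code{uniform_map} with branch structure.
#' @param n_intervals number of equal subintervals.
#' @param permutation permutation of \code{1:n_intervals}; subinterval
#'   \code{i} of the domain is relocated to position
#'   \code{permutation[i]}.
#' @return a \code{uniform_map}.
#' @export
partition_permute <- function(base, n_intervals, permutation) {
  if (base$d != 1L) stop("base map must be one-dimensional")
  n <- as.integer(n_intervals)
  if (length(permutation) != n || !setequal(permutation, seq_len(n)))
    stop("permutation must be a permutation of 1:", n)
  i <- seq_len(n)
  perm_map <- new_uniform_map(
    "interval_permutation", 1L,
    local({
      shift <- (permutation - i) / n
      function(x) {
        x <- ifelse(x >= 1, x - floor(x), x)
        j <- pmin(floor(x * n) + 1L, n)
        x + shift[j]
      }
    }),
    branches = data.frame(lo = (i - 1) / n, hi = i / n, slope = 1,
                          intercept = (permutation - i) / n),
    exact_lyapunov = 0,
    params = list(n = n, permutation = permutation))
  out <- compose_maps(base, perm_map)
  if (!is.null(out$branches)) {
    chk <- branch_invariance(out, n_points = 101L)
    if (max(abs(chk$sum - 1)) > 1e-8)
      stop("permuted map failed the Lebesgue invariance recheck")
  }
  out$name <- paste0("pp(", base$name, ")")
  out
}

#' Branch-sum check of Lebesgue invariance
#'
#' For a one-dimensional piecewise-linear map, invariance of the uniform
#' distribution is equivalent to \eqn{\sum_{x \in U^{-1}(y)} 1/|U'(x)| = 1}
#' for every y.  This evaluates that inverse-branch sum on a grid of y
#' values.
#'
#' @param map a 1-d \code{uniform_map} with branches.
#' @param n_points number of interior evaluation points.
#' @return data frame with columns \code{y} and \code{sum}.
#' @export
branch_invariance <- function(map, n_points = 1000L) {
  br <- map$branches
  if (is.null(br)) stop("map has no branch structure")
  y <- seq(0.5 / n_points, 1 - 0.5 / n_points, length.out = n_points)
  s <- numeric(n_points)
  for (i in seq_len(nrow(br))) {
    v_lo <- br$slope[i] * br$lo[i] + br$intercept[i]
    v_hi <- br$slope[i] * br$hi[i] + br$intercept[i]
    ylo <- min(v_lo, v_hi)
    yhi <- max(v_lo, v_hi)
    # half-open on the wrap side so branch images tile [0,1) exactly once
    hit <- if (br$slope[i] > 0) y >= ylo & y < yhi
           else y > ylo & y <= yhi
    s[hit] <- s[hit] + 1 / abs(br$slope[i])
  }
  data.frame(y = y, sum = s)
}

#' Orbit period of a rational circle translation
#'
#' The translation \eqn{T_{N/D}} with \eqn{\gcd(N, D) = 1} is periodic
#' with period \eqn{D}; an irrational shift is aperiodic.  Decided in
#' exact integer arithmetic: floating-point shifts are never used to
#' detect periodicity.
#'
#' @param numerator,denominator the shift \code{c = numerator/denominator}
#'   with \code{0 <= c < 1}.
#' @param irrational set to \code{TRUE} to flag an irrational shift.
#' @return the integer period \code{D}, or the string \code{"aperiodic"}.
#' @examples
#' translation_period(1, 3)   # 3
#' translation_period(2, 6)   # 3
#' @export
translation_period <- function(numerator = NULL, denominator = NULL,
                               irrational = FALSE) {
  if (irrational) return("aperiodic")
  n <- as.integer(numerator)
  d <- as.integer(denominator)
  if (is.na(n) || is.na(d) || d <= 0L || n < 0L || n >= d)
    stop("shift must satisfy 0 <= numerator/denominator < 1")
  if (n == 0L) return(1L)
  g <- function(a, b) if (b == 0L) a else g(b, a %% b)
  d %/% g(n, d)
}

# exact rational orbit of T_{N/D} starting at p0/q0 (integers); returns
# numerators over the common denominator lcm(q0, D)
translation_orbit_exact <- function(numerator, denominator, steps,
                                    start_num = 0L, start_den = 1L) {
  g <- function(a, b) if (b == 0L) a else g(b, a %% b)
  den <- start_den * denominator / g(start_den, denominator)
  x <- start_num * (den / start_den)
  step <- numerator * (den / denominator)
  out <- integer(steps + 1L)
  out[1L] <- x
  for (i in seq_len(steps)) {
    x <- (x + step) %% den
    out[i + 1L] <- x
  }
  list(numerators = out, denominator = den)
}

#' Finite-precision guard shift
#'
#' On binary hardware, maps whose breakpoints and slopes have exact binary
#' representations (tent, sawtooth, baker) can collapse orbits onto
#' spurious finite sets - for the tent map every double-precision start
#' eventually reaches 0.  Composing with a tiny circle shift whose constant
#' has no finite binary representation (default \eqn{c = 1/3 \times
#' 10^{-9}}) restores generic behaviour while being indiscernible in any
#' plotted quantity.
#'
#' @param U a \code{uniform_map}.
#' @param c_guard the guard shift (default \code{1e-9/3}).
#' @return \eqn{T_{c_{guard}} \circ U} (applied to every coordinate for
#'   multi-dimensional maps).
#' @export
precision_guard <- function(U, c_guard = 1e-9 / 3) {
  if (U$d == 1L) {
    compose_maps(make_uniform_map("translation", list(c = c_guard)), U)
  } else {
    ev <- U$eval
    d <- U$d
    out <- new_uniform_map(paste0("guarded(", U$name, ")"), d,
                           function(x) (ev(x) + c_guard) %% 1,
                           params = c(U$params, list(c_guard = c_guard)))
    out$components <- U$components
    out
  }
}
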