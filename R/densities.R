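#' Analytic one-dimensional target densities
#'
#' Constructs a density on \code{[0,1]} from one of the built-in analytic
#' families, with exact closed-form pdf, cdf and inverse distribution
#' function (idf).  These are the one-dimensional targets used throughout
#' the worked examples:
#' \describe{
#'   \item{\code{uniform}}{\eqn{\rho(x) = 1}.}
#'   \item{\code{triangular}}{symmetric triangle \eqn{\rho(x) = 2 - 4|x - 1/2|}.}
#'   \item{\code{ramp}}{\eqn{\rho(x) = 2x}, with cdf \eqn{F(x) = x^2}.}
#'   \item{\code{arcsine}}{\eqn{\rho(x) = 1/(\pi\sqrt{x(1-x)})}, the
#'     equilibrium density of the logistic map; cdf
#'     \eqn{F(x) = (2/\pi)\arcsin\sqrt{x}}.}
#' }
#'
#' The pdf is verified to integrate to 1 (within \code{1e-10}) by quadrature
#' at construction time.
#'
#' @param family one of \code{"uniform"}, \code{"triangular"}, \code{"ramp"},
#'   \code{"arcsine"}.
#' @param params reserved for parameterised families; currently must be empty.
#' @return an object of class \code{c("analytic_density", "ifpp_density")}
#'   with elements \code{family}, \code{d = 1}, \code{support = c(0, 1)} and
#'   vectorised closures \code{pdf}, \code{cdf}, \code{idf}.
#' @examples
#' ramp <- make_analytic_density("ramp")
#' ramp$cdf(0.5)   # 0.25
#' ramp$idf(0.25)  # 0.5
#' @export
make_analytic_density <- function(family = c("uniform", "triangular", "ramp",
                                             "arcsine"),
                                  params = list()) {
  family <- match.arg(family)
  if (length(params) > 0L)
    stop("family '", family, "' takes no parameters")
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  fns <- switch(family,
    uniform = list(
      pdf = function(x) rep_len(1, length(x)),
      cdf = function(x) clamp01(x),
      idf = function(p) p),
    triangular = list(
      pdf = function(x) 2 - 4 * abs(x - 0.5),
      cdf = function(x) {
        x <- clamp01(x)
        ifelse(x <= 0.5, 2 * x^2, 1 - 2 * (1 - x)^2)
      },
      idf = function(p) ifelse(p <= 0.5,
                               sqrt(p / 2),
                               1 - sqrt((1 - p) / 2))),
    ramp = list(
      pdf = function(x) 2 * x,
      cdf = function(x) clamp01(x)^2,
      idf = function(p) sqrt(p)),
    arcsine = list(
      pdf = function(x) 1 / (pi * sqrt(x * (1 - x))),
      cdf = function(x) (2 / pi) * asin(sqrt(clamp01(x))),
      idf = function(p) sin(pi * p / 2)^2)
  )
  total <- stats::integrate(fns$pdf, 0, 1, rel.tol = 1e-12)$value
  if (abs(total - 1) > 1e-10)
    stop("pdf of family '", family, "' does not integrate to 1")
  structure(
    list(family = family, d = 1L, support = c(0, 1),
         pdf = fns$pdf, cdf = fns$cdf, idf = fns$idf),
    class = c("analytic_density", "ifpp_density"))
}

#' @export
print.analytic_density <- function(x, ...) {
  cat("Analytic density on [0,1], family:", x$family, "\n")
  invisible(x)
}

default_floor_eps <- function(weights) 1e-12 * max(weights)

#' Piecewise-constant grid densities on the unit hypercube
#'
#' Represents a d-dimensional density that is constant on the cells of a
#' regular grid partition of \eqn{[0,1]^d}.  Cells along each axis are
#' half-open \eqn{[i/n, (i+1)/n)}, the last closed at 1.  Axis 1 of the
#' weight array corresponds to coordinate \eqn{x_1}, axis 2 to \eqn{x_2},
#' and so on.
#'
#' The invariant-density framework assumes \eqn{\rho(x) > 0} everywhere, so
#' zero cells must be resolved: \code{floor_policy = "epsilon_floor"}
#' (default) raises every weight to at least \code{eps} before
#' normalisation, while \code{"reject_zeros"} refuses densities with any
#' zero cell.
#'
#' @param weights nonnegative numeric vector (d = 1), matrix (d = 2) or
#'   array; at least one entry must be positive.
#' @param floor_policy \code{"epsilon_floor"} or \code{"reject_zeros"}.
#' @param eps positive floor applied under \code{"epsilon_floor"}; default
#'   \code{1e-12 * max(weights)}.
#' @return object of class \code{c("grid_density", "ifpp_density")} with
#'   elements \code{d}, \code{shape}, \code{masses} (cell probabilities,
#'   summing to 1), \code{pdf_values} (cell density values), \code{pdf}
#'   (vectorised closure on points), \code{norm_const}, \code{floor_policy}.
#' @examples
#' g <- make_grid_density(c(2, 1))
#' g$pdf_values  # 4/3, 2/3
#' @export
make_grid_density <- function(weights,
                              floor_policy = c("epsilon_floor",
                                               "reject_zeros"),
                              eps = NULL) {
  floor_policy <- match.arg(floor_policy)
  w <- weights
  if (is.null(dim(w))) w <- array(as.numeric(w), dim = length(w))
  w <- array(as.numeric(w), dim = dim(w))
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and nonnegative")
  if (all(w == 0))
    stop("all-zero weights: density undefined")
  if (floor_policy == "reject_zeros") {
    if (any(w == 0))
      stop("zero cell weight under 'reject_zeros': the construction ",
           "assumes a strictly positive target density")
  } else {
    if (is.null(eps)) eps <- default_floor_eps(w)
    if (eps <= 0) stop("eps must be positive")
    w <- pmax(w, eps)
    dim(w) <- dim(weights) %||% length(weights)
  }
  shape <- dim(w)
  d <- length(shape)
  cell_vol <- 1 / prod(shape)
  norm_const <- sum(w) * cell_vol
  masses <- w / sum(w)
  pdf_values <- masses / cell_vol
  obj <- structure(
    list(d = d, shape = shape, masses = masses, pdf_values = pdf_values,
         norm_const = norm_const, floor_policy = floor_policy),
    class = c("grid_density", "ifpp_density"))
  obj$pdf <- function(x) grid_pdf(obj, x)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cell index along one axis for coordinates in [0,1]
cell_index <- function(x, n) as.integer(pmin(floor(x * n) + 1, n))

#' Evaluate a grid density at points
#'
#' @param grid a \code{grid_density}.
#' @param x numeric vector (d = 1) or matrix with one row per point.
#' @return vector of density values.
#' @export
grid_pdf <- function(grid, x) {
  x <- as_points(x, grid$d)
  idx <- vapply(seq_len(grid$d),
                function(k) cell_index(x[, k], grid$shape[k]),
                integer(nrow(x)))
  idx <- matrix(idx, ncol = grid$d)
  grid$pdf_values[idx]
}

# coerce point input to an n x d matrix
as_points <- function(x, d) {
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("points have ", ncol(x), " columns, expected ", d)
    x
  } else {
    if (d == 1L) matrix(as.numeric(x), ncol = 1L)
    else matrix(as.numeric(x), ncol = d, byrow = TRUE)
  }
}

#' @export
print.grid_density <- function(x, ...) {
  cat("Grid density on [0,1]^", x$d, ", shape ",
      paste(x$shape, collapse = "x"),
      ", floor policy ", x$floor_policy, "\n", sep = "")
  invisible(x)
}

#' Read a grid density from a greyscale image
#'
#' Builds a two-dimensional piecewise-constant density whose cell weights
#' are the pixel intensities of a greyscale image (PNG or PGM).  By the
#' default \code{"image"} orientation, the column index increases with
#' \eqn{x_1} (left to right) and the top image row sits at \eqn{x_2 = 1};
#' \code{"cartesian"} instead places row 1 at \eqn{x_2 = 0}.
#'
#' @param path path to a PNG or PGM (P2/P5) file.
#' @param orientation \code{"image"} (default) or \code{"cartesian"}.
#' @param convert if \code{TRUE}, colour PNG input is converted to
#'   luminance; otherwise colour input is an error.
#' @inheritParams make_grid_density
#' @return a 2-d \code{grid_density}.
#' @export
density_from_image <- function(path, orientation = c("image", "cartesian"),
                               convert = FALSE,
                               floor_policy = c("epsilon_floor",
                                                "reject_zeros"),
                               eps = NULL) {
  orientation <- match.arg(orientation)
  floor_policy <- match.arg(floor_policy)
  img <- read_grey_image(path, convert = convert)
  if (orientation == "image")
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  # weights[i1, i2]: i1 = column (x1), i2 = row from bottom (x2)
  make_grid_density(t(img), floor_policy = floor_policy, eps = eps)
}

read_grey_image <- function(path, convert = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] == 2L) {          # grey + alpha
        img <- img[, , 1L]
      } else if (convert) {
        img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] +
          0.0722 * img[, , 3L]
      } else {
        stop("colour image; pass convert = TRUE for luminance conversion")
      }
    }
    img
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or PGM)")
  }
}

# Minimal PGM reader (ASCII P2 and binary P5), intensities scaled to [0,1].
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") {                  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, ")")
  nc <- as.integer(read_token())
  nr <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(nc, nr, maxval)) || nc < 1L || nr < 1L || maxval < 1L)
    stop("malformed PGM header")
  n <- nr * nc
  if (magic == "P2") {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.numeric(scan(text = rest, n = n, quiet = TRUE))
  } else {
    vals <- as.numeric(readBin(con, "integer", n = n, size = 1L,
                               signed = FALSE))
  }
  if (length(vals) < n) stop("truncated PGM pixel data")
  matrix(vals / maxval, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write an intensity matrix as an ASCII PGM image
#'
#' @param img numeric matrix with values in \code{[0,1]}; rows are image
#'   rows, top first.
#' @param path output path.
#' @param maxval integer grey-level range (default 255).
#' @return \code{path}, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  lines <- c("P2", paste(ncol(img), nrow(img)), as.character(maxval),
             apply(vals, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic coin-like image fixture
#'
#' Generates a synthetic greyscale test image: a bright disk with an inner
#' relief ring on a dark background, emulating a coin photographed against
#' black.  Used as a stand-in target for the image-density demonstration;
#' it is generated code, not a photograph.
#'
#' @param n image side length in pixels.
#' @param disk_radius radius of the coin disk in unit-square coordinates.
#' @param hi,lo intensities of the disk and the background.
#' @return an \code{n x n} intensity matrix in \code{[0,1]} (rows = image
#'   rows, top first).
#' @export
synthetic_coin_image <- function(n = 64L, disk_radius = 0.35,
                                 hi = 0.9, lo = 0.04) {
  ctr <- (seq_len(n) - 0.5) / n
  dx <- outer(ctr, ctr, function(r, c) sqrt((c - 0.5)^2 + (r - 0.5)^2))
  img <- matrix(lo, n, n)
  img[dx <= disk_radius] <- hi
  ring <- dx >= 0.55 * disk_radius & dx <= 0.7 * disk_radius
  img[ring] <- 0.55                      # embossed relief ring
  img
}

#' Checkerboard grid density
#'
#' A two-dimensional grid density with alternating tile weights, the
#' standard stress-test target for two-dimensional map constructions.
#'
#' @param tiles_per_axis number of tiles along each axis (>= 1).
#' @param high,low weights of the alternating tiles; \code{high > low >= 0}.
#' @param cells_per_tile grid refinement within each tile (>= 1).
#' @inheritParams make_grid_density
#' @return a 2-d \code{grid_density}.
#' @export
make_checkerboard <- function(tiles_per_axis, high = 1, low = 0,
                              cells_per_tile = 1L,
                              floor_policy = c("epsilon_floor",
                                               "reject_zeros"),
                              eps = NULL) {
  floor_policy <- match.arg(floor_policy)
  if (tiles_per_axis < 1L) stop("tiles_per_axis must be >= 1")
  if (!(high > low && low >= 0) && !(high == low && low >= 0))
    stop("need high >= low >= 0")
  n <- tiles_per_axis * cells_per_tile
  tile <- function(i) (i - 1L) %/% cells_per_tile
  w <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse((tile(i) + tile(j)) %% 2L == 0L,
                                   high, low))
  make_grid_density(w, floor_policy = floor_policy, eps = eps)
}

#' Marginal cell masses of the leading coordinates
#'
#' Computes the marginal distribution \eqn{p_k(x_1, \dots, x_k)} of the
#' first \code{k} coordinates of a grid density by summing cell masses over
#' the remaining axes.
#'
#' @param grid a \code{grid_density}.
#' @param k number of leading coordinates to keep, \code{1 <= k <= d}.
#' @param order optional permutation of \code{1:d} giving the coordinate
#'   order in which "leading" is meant (default natural order).
#' @return object of class \code{"marginal_table"}: list with \code{k},
#'   \code{masses} (array over the first \code{k} axes, summing to 1) and
#'   \code{shape}.
#' @export
marginal_density <- function(grid, k, order = seq_len(grid$d)) {
  stopifnot(inherits(grid, "grid_density"))
  d <- grid$d
  if (length(order) != d || !setequal(order, seq_len(d)))
    stop("order must be a permutation of 1:", d)
  if (!(k >= 1L && k <= d)) stop("k out of range 1..", d)
  m <- grid$masses
  if (d > 1L) m <- aperm(array(m, dim = grid$shape), order)
  shape <- grid$shape[order]
  masses <- if (k == d) m else apply(m, seq_len(k), sum)
  masses <- array(masses, dim = shape[seq_len(k)])
  structure(list(k = k, masses = masses, shape = shape[seq_len(k)]),
            class = "marginal_table")
}

#' Conditional cell masses of one coordinate given a prefix point
#'
#' Returns the normalised conditional distribution of coordinate \code{k}
#' given that the first \code{k - 1} coordinates lie in the cells containing
#' \code{prefix}: \eqn{\rho_k(x_k | x_1, \dots, x_{k-1}) =
#' p_k(x_1,\dots,x_k) / p_{k-1}(x_1,\dots,x_{k-1})}.
#'
#' @inheritParams marginal_density
#' @param prefix numeric vector of length \code{k - 1} in \code{[0,1]^{k-1}}.
#' @return numeric vector of cell masses over axis \code{k}, summing to 1.
#' @export
conditional_density <- function(grid, k, prefix = numeric(0),
                                order = seq_len(grid$d)) {
  stopifnot(inherits(grid, "grid_density"))
  if (length(prefix) != k - 1L)
    stop("prefix must have length k - 1 = ", k - 1L)
  if (length(prefix) && (any(prefix < 0) || any(prefix > 1)))
    stop("prefix must lie in [0,1]^", k - 1L)
  pk <- marginal_density(grid, k, order)$masses
  shape <- dim(pk) %||% length(pk)
  if (k == 1L) {
    cond <- as.numeric(pk)
  } else {
    idx <- mapply(cell_index, prefix, shape[seq_len(k - 1L)])
    slice <- do.call(`[`, c(list(array(pk, dim = shape)),
                            as.list(idx), list(TRUE)))
    tot <- sum(slice)
    if (tot <= 0)
      stop("prefix cell has zero marginal mass; use an epsilon floor")
    cond <- as.numeric(slice) / tot
  }
  cond / sum(cond)
}

# 1D cdf of any supported density at points x (piecewise linear for grids)
density_cdf <- function(density, x) {
  if (inherits(density, "analytic_density")) return(density$cdf(x))
  stopifnot(density$d == 1L)
  m <- as.numeric(density$masses)
  n <- length(m)
  cum <- c(0, cumsum(m))
  i <- cell_index(pmin(pmax(x, 0), 1), n)
  cum[i] + (pmin(pmax(x, 0), 1) * n - (i - 1L)) * m[i]
}
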