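test_that("conjugating the tent map with the arcsine cdf gives 4x(1-x)", {
  ars <- make_analytic_density("arcsine")
  M <- conjugate_map(build_rosenblatt(ars), make_uniform_map("triangle"))
  xs <- seq(0.001, 0.999, length.out = 1000L)
  expect_close(M$eval(xs), 4 * xs * (1 - xs), 1e-9)
})

test_that("hand-composed conjugation values for ramp and triangle targets", {
  ramp <- make_analytic_density("ramp")
  Mr <- conjugate_map(build_rosenblatt(ramp), make_uniform_map("triangle"))
  # F(0.5) = 0.25, t1 -> 0.5, F^-1 = sqrt(0.5)
  expect_close(Mr$eval(0.5), sqrt(0.5), 1e-12)

  tri <- make_analytic_density("triangular")
  Mt <- conjugate_map(build_rosenblatt(tri), make_uniform_map("triangle"))
  # F(0.3) = 0.18, t1 -> 0.36, F^-1 = sqrt(0.18)
  expect_close(Mt$eval(0.3), sqrt(0.18), 1e-12)

  idm <- conjugate_map(build_rosenblatt(ramp), make_uniform_map("identity"))
  xs <- seq(0.01, 0.99, length.out = 200L)
  expect_close(idm$eval(xs), xs, 1e-9)
})

test_that("the analytic conjugate derivative matches finite differences", {
  tri <- make_analytic_density("triangular")
  Mt <- conjugate_map(build_rosenblatt(tri), make_uniform_map("triangle"))
  xs <- seq(0.02, 0.98, length.out = 97L)
  xs <- xs[vapply(xs, function(x)
    min(abs(x - Mt$monotone_partition)) > 1e-3, logical(1))]
  h <- 1e-7
  fd <- (Mt$eval(xs + h) - Mt$eval(xs - h)) / (2 * h)
  expect_close(Mt$jac_det(xs), fd, 1e-4)
})

test_that("the uniform map is recovered from the solution map", {
  ars <- make_analytic_density("arcsine")
  R <- build_rosenblatt(ars)
  rec <- recover_uniform(closed_form_map("logistic"), R, n = 1e4, seed = 1)
  zs <- seq(0.001, 0.999, length.out = 500L)
  t1 <- make_uniform_map("triangle")
  expect_close(rec$map$eval(zs), t1$eval(zs), 1e-9)
  expect_true(rec$diagnostic$pass)

  ramp <- make_analytic_density("ramp")
  Rr <- build_rosenblatt(ramp)
  s3 <- make_uniform_map("sawtooth", list(l = 3))
  Ms3 <- conjugate_map(Rr, s3)
  rec2 <- recover_uniform(Ms3, Rr, n = 1e4, seed = 2)
  zin <- zs[vapply(zs, function(z)
    min(abs(z - c(0, 1 / 3, 2 / 3, 1))) > 1e-6, logical(1))]
  expect_close(rec2$map$eval(zin), s3$eval(zin), 1e-9)
})

test_that("recover(conjugate(R, U), R) = U across catalog and targets", {
  dens <- list(make_analytic_density("triangular"),
               make_analytic_density("ramp"),
               make_analytic_density("arcsine"))
  umaps <- list(make_uniform_map("triangle"),
                make_uniform_map("sawtooth", list(l = 3)),
                make_uniform_map("asym_triangle", list(c = 0.3)),
                make_uniform_map("translation", list(c = 0.3)))
  zs <- seq(0.003, 0.997, length.out = 301L)
  for (d in dens) {
    R <- build_rosenblatt(d)
    for (U in umaps) {
      M <- conjugate_map(R, U)
      rec <- recover_uniform(M, R, n = 1e3, seed = 1)
      bp <- sort(unique(c(U$branches$lo, U$branches$hi)))
      keep <- vapply(zs, function(z) min(abs(z - bp)) > 1e-6, logical(1))
      expect_close(rec$map$eval(zs[keep]), U$eval(zs[keep]), 1e-8)
    }
  }
})

test_that("transport maps push one target to another", {
  unif <- make_analytic_density("uniform")
  tri <- make_analytic_density("triangular")
  ramp <- make_analytic_density("ramp")
  Ru <- build_rosenblatt(unif)
  Rt <- build_rosenblatt(tri)
  Rr <- build_rosenblatt(ramp)

  samp <- transport_map(Ru, Rt)         # identity U: inverse-cdf sampler
  ps <- seq(0.01, 0.99, length.out = 99L)
  expect_close(samp$eval(ps), tri$idf(ps), 1e-9)

  ident <- transport_map(Rr, Rr)
  expect_close(ident$eval(ps), ps, 1e-9)

  rt <- transport_map(Rr, Rt)
  expect_close(rt$eval(0.5), sqrt(0.25 / 2), 1e-12)

  # Kolmogorov-Smirnov: pushed ramp samples are triangular at the 1% level
  set.seed(13)
  x <- oracle_sample("ramp", 1e5)
  y <- rt$eval(x)
  ks <- suppressWarnings(ks.test(tri$cdf(y), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("closed forms equal their factorized constructions", {
  xs <- seq(0.001, 0.999, length.out = 1000L)
  pairs <- list(
    list(closed_form_map("logistic"), "arcsine", "triangle", list()),
    list(closed_form_map("logistic_l", list(l = 3)), "arcsine",
         "triangle_l", list(l = 3)),
    list(closed_form_map("mtri"), "triangular", "triangle", list()),
    list(closed_form_map("mramp"), "ramp", "triangle", list()))
  for (p in pairs) {
    M <- conjugate_map(build_rosenblatt(make_analytic_density(p[[2]])),
                       make_uniform_map(p[[3]], p[[4]]))
    expect_close(p[[1]]$eval(xs), M$eval(xs), 1e-9)
  }
  expect_error(closed_form_map("nope"), "unknown")
})

test_that("logistic_l coincides with logistic powers for l = 2^n - 1", {
  lg <- closed_form_map("logistic")
  xs <- seq(0, 1, length.out = 1000L)
  l1 <- closed_form_map("logistic_l", list(l = 1))
  expect_close(l1$eval(xs), lg$eval(xs), 1e-9)
  l2 <- closed_form_map("logistic_l", list(l = 2))
  expect_close(l2$eval(xs), lg$eval(lg$eval(xs)), 1e-9)
  expect_equal(lg$eval(0.5), 1)
  expect_equal(lg$eval(0), 0)
  expect_close(closed_form_map("mtri")$eval(0.3), sqrt(0.18), 1e-9)
})

test_that("orbits behave per the conjugacy lemma", {
  ramp <- make_analytic_density("ramp")
  idm <- conjugate_map(build_rosenblatt(ramp), make_uniform_map("identity"))
  ob <- orbit(idm, 0.4, 5, guard = FALSE)
  expect_close(ob$states, rep(0.4, 5), 1e-12)

  # exact rational translation returns to the start at step D = 3
  exact <- ergomap:::translation_orbit_exact(1L, 3L, 3L)
  expect_equal(exact$numerators[4L], exact$numerators[1L])

  # one-step conjugacy: R^-1(U(z)) = M(R^-1(z)) pointwise
  ars <- make_analytic_density("arcsine")
  R <- build_rosenblatt(ars)
  U <- make_uniform_map("triangle")
  M <- closed_form_map("logistic")
  set.seed(31)
  z <- runif(1e3, 0.001, 0.999)
  expect_close(R$inverse(U$eval(z)), M$eval(R$inverse(z)), 1e-9)

  expect_error(orbit(idm, 1.4, 10), "support")
})

test_that("one-step conjugacy holds for every shipped density/map pair", {
  dens <- list(make_analytic_density("triangular"),
               make_analytic_density("ramp"),
               make_analytic_density("arcsine"),
               make_grid_density(c(3, 1, 2, 2)))
  umaps <- list(make_uniform_map("triangle"),
                make_uniform_map("sawtooth", list(l = 3)),
                make_uniform_map("asym_triangle", list(c = 0.7)))
  set.seed(41)
  z <- runif(500, 0.001, 0.999)
  for (d in dens) {
    R <- build_rosenblatt(d)
    for (U in umaps) {
      M <- conjugate_map(R, U)
      expect_close(as.numeric(R$inverse(U$eval(z))),
                   M$eval(as.numeric(R$inverse(z))), 1e-9)
    }
  }
})

test_that("orbit histograms converge to the invariant density", {
  tri <- make_analytic_density("triangular")
  Mt <- conjugate_map(build_rosenblatt(tri), make_uniform_map("triangle"))
  ob <- orbit(Mt, 0.3, 1e6)
  dd <- orbit_distribution_distance(ob, tri, bins = 100L)
  expect_lt(dd$tv, 0.01)
})

test_that("orbits stream to CSV deterministically", {
  ramp <- make_analytic_density("ramp")
  M <- conjugate_map(build_rosenblatt(ramp), make_uniform_map("triangle"))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  orbit(M, 0.3, 5000, stream_sink = f1, chunk_size = 1000L)
  orbit(M, 0.3, 5000, stream_sink = f2, chunk_size = 1000L)
  expect_identical(readLines(f1), readLines(f2))
  dat <- read.csv(f1, comment.char = "#")
  expect_equal(nrow(dat), 5000L)
})
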