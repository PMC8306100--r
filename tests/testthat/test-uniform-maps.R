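catalog_1d <- function() list(
  identity = make_uniform_map("identity"),
  translation = make_uniform_map("translation", list(c = 0.3)),
  triangle = make_uniform_map("triangle"),
  sawtooth3 = make_uniform_map("sawtooth", list(l = 3)),
  triangle3 = make_uniform_map("triangle_l", list(l = 3)),
  asym03 = make_uniform_map("asym_triangle", list(c = 0.3)),
  asym09 = make_uniform_map("asym_triangle", list(c = 0.9)))

test_that("catalog maps evaluate per their defining formulas", {
  Tc <- make_uniform_map("translation", list(c = 0.3))
  expect_close(Tc$eval(0.9), 0.2, 1e-12)
  expect_equal(Tc$exact_lyapunov, 0)

  bk <- make_uniform_map("baker")
  expect_close(as.numeric(bk$eval(matrix(c(0.25, 0.5), 1))),
               c(0.5, 0.25), 1e-12)

  cat2 <- make_uniform_map("cat")
  expect_close(as.numeric(cat2$eval(matrix(c(0.5, 0.5), 1))),
               c(0.5, 0.0), 1e-12)

  tc <- make_uniform_map("asym_triangle", list(c = 0.3))
  expect_close(tc$eval(0.15), 0.5, 1e-12)
  expect_close(tc$eval(0.3), 1.0, 1e-12)
  expect_close(tc$exact_lyapunov,
               -0.3 * log(0.3) - 0.7 * log(0.7), 1e-12)
  expect_close(tc$exact_lyapunov, 0.610864, 1e-6)

  expect_equal(make_uniform_map("triangle")$exact_lyapunov, log(2))
  expect_equal(make_uniform_map("sawtooth", list(l = 5))$exact_lyapunov,
               log(5))
  expect_equal(make_uniform_map("triangle_l", list(l = 4))$exact_lyapunov,
               log(8))

  expect_error(make_uniform_map("nope"), "unknown")
  expect_error(make_uniform_map("translation", list(c = 1.5)), "\\[0,1\\)")
  expect_error(make_uniform_map("asym_triangle", list(c = 0)), "\\(0,1\\)")
  expect_error(make_uniform_map("sawtooth", list(l = 0)), "integer")
})

test_that("all 1d catalog maps preserve Lebesgue measure branch-wise", {
  for (nm in names(catalog_1d())) {
    chk <- branch_invariance(catalog_1d()[[nm]], n_points = 1000L)
    expect_close(chk$sum, 1, 1e-9)
  }
})

test_that("branch evaluation agrees with the closed-form evaluator", {
  xs <- seq(0, 0.999, length.out = 997L)
  for (m in catalog_1d()) {
    br <- m$branches
    breaks <- c(br$lo[1], br$hi)
    i <- pmin(pmax(findInterval(xs, breaks, rightmost.closed = TRUE), 1L),
              nrow(br))
    expect_close(br$slope[i] * xs + br$intercept[i], m$eval(xs), 1e-9)
  }
})

test_that("composition: t_l = t1 o s_l and translations add", {
  s3 <- make_uniform_map("sawtooth", list(l = 3))
  t1 <- make_uniform_map("triangle")
  t3 <- make_uniform_map("triangle_l", list(l = 3))
  # the l-period triangle wave folds the sawtooth through the tent:
  # t_l(x) = t1(s_l(x)) (the tent is applied last)
  comp <- compose_maps(t1, s3)
  xs <- seq(0, 1, length.out = 1e4)
  expect_close(comp$eval(xs), t3$eval(xs), 1e-12)
  # composed branch structure still sums to Lebesgue invariance
  expect_close(branch_invariance(comp, 1000L)$sum, 1, 1e-9)

  idc <- compose_maps(make_uniform_map("identity"), t1)
  expect_close(idc$eval(xs), t1$eval(xs), 1e-12)

  tq <- compose_maps(make_uniform_map("translation", list(c = 0.25)),
                     make_uniform_map("translation", list(c = 0.5)))
  expect_close(tq$eval(xs[xs < 1]),
               (xs[xs < 1] + 0.75) %% 1, 1e-12)

  expect_error(compose_maps(t1, make_uniform_map("baker")), "dimension")
})

test_that("coordinatewise products act independently per coordinate", {
  u1 <- make_uniform_map("asym_triangle", list(c = 0.3))
  u2 <- make_uniform_map("asym_triangle", list(c = 0.9))
  U <- coordinatewise(u1, u2)
  pts <- matrix(runif(60), ncol = 2)
  out <- U$eval(pts)
  expect_close(out[, 1], u1$eval(pts[, 1]), 1e-12)
  expect_close(out[, 2], u2$eval(pts[, 2]), 1e-12)

  I2 <- coordinatewise(make_uniform_map("identity"),
                       make_uniform_map("identity"))
  expect_close(I2$eval(pts), pts, 1e-12)

  expect_error(coordinatewise(list()), "no component")
})

test_that("partition-and-permute yields new uniform maps", {
  idm <- make_uniform_map("identity")
  swapped <- partition_permute(idm, 2, c(2, 1))
  xs <- seq(0, 0.999, length.out = 500L)
  expect_close(swapped$eval(xs), (xs + 0.5) %% 1, 1e-12)

  t1 <- make_uniform_map("triangle")
  same <- partition_permute(t1, 3, 1:3)
  expect_close(same$eval(xs), t1$eval(xs), 1e-12)

  perm_t1 <- partition_permute(t1, 2, c(2, 1))
  expect_true(all(abs(perm_t1$branches$slope) == 2))
  expect_close(branch_invariance(perm_t1, 1000L)$sum, 1, 1e-9)

  expect_error(partition_permute(t1, 2, c(1, 3)), "permutation")
})

test_that("rational translations are periodic with the reduced denominator", {
  expect_equal(translation_period(1, 3), 3L)
  expect_equal(translation_period(2, 6), 3L)
  expect_equal(translation_period(irrational = TRUE), "aperiodic")
  expect_error(translation_period(5, 3), "0 <=")
})

test_that("exact orbits of T_{N/D} return at step D and not before", {
  for (D in c(2:16, 31, 32, 45, 64)) {
    Ns <- which(vapply(seq_len(D - 1),
                       function(n) translation_period(n, D) == D,
                       logical(1)))
    N <- Ns[length(Ns)]
    orb <- ergomap:::translation_orbit_exact(N, D, D, start_num = 1L,
                                             start_den = 7L)
    num <- orb$numerators
    expect_equal(num[D + 1L], num[1L])
    expect_false(any(num[2:D] == num[1L]))
  }
})

test_that("the precision guard shifts by 1/3e-9 and prevents collapse", {
  g <- 1e-9 / 3
  t1 <- make_uniform_map("triangle")
  gid <- precision_guard(make_uniform_map("identity"))
  xs <- seq(0.05, 0.9, length.out = 50L)
  expect_close(gid$eval(xs), (xs + g) %% 1, 1e-15)
  gt1 <- precision_guard(t1)
  expect_close(gt1$eval(0.25), (t1$eval(0.25) + g) %% 1, 1e-15)

  # from x0 = 0.5 the unguarded tent orbit hits 0 and stays; the guarded
  # orbit keeps exploring
  x <- 0.5
  for (n in 1:60) x <- t1$eval(x)
  expect_equal(x, 0)
  y <- 0.5
  ys <- numeric(1e4)
  for (n in 1:1e4) { y <- gt1$eval(y); ys[n] <- y }
  expect_gt(length(unique(tail(ys, 1000))), 900)
  expect_gt(mean(tail(ys, 5000)), 0.3)   # equidistributing, not stuck
})

test_that("2d catalog maps preserve uniform bins empirically", {
  set.seed(77)
  n <- 1e5
  for (nm in c("baker", "cat")) {
    U <- make_uniform_map(nm)
    z <- matrix(runif(2 * n), ncol = 2)
    w <- U$eval(z)
    counts <- tabulate(pmin(floor(w[, 1] * 16) + 1, 16) +
                         16 * (pmin(floor(w[, 2] * 16) + 1, 16) - 1),
                       nbins = 256)
    chisq <- sum((counts - n / 256)^2 / (n / 256))
    expect_gt(pchisq(chisq, 255, lower.tail = FALSE), 0.01)
  }
})
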