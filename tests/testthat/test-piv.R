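# PIV engine: window correlation, passes, validation, multi-pass properties.

test_that("window correlation recovers integer and fractional offsets", {
  img <- make_speckle(speckle_spec(shape_px = c(96L, 96L), seed = 5))
  a <- img[17:80, 17:80]
  r0 <- correlate_window(a, a, 8)
  expect_true(r0$valid)
  expect_equal(c(r0$du, r0$dv), c(0, 0), tolerance = 1e-9)

  # integer-roll oracle: roll the patch content by (2, -1)
  roll <- function(m, dx, dy) {
    m <- m[, ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1, ]
  }
  rb <- correlate_window(a, roll(a, 2, -1), 8)
  expect_equal(rb$du, 2, tolerance = 0.05)
  expect_equal(rb$dv, -1, tolerance = 0.05)

  # constant patch -> invalid, not an error
  rc <- correlate_window(matrix(0.5, 32, 32), matrix(0.5, 32, 32), 8)
  expect_false(rc$valid)
})

test_that("uncorrelated noise windows are flagged at a > 95% rate", {
  set.seed(101)
  flagged <- vapply(seq_len(1000), function(i) {
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
    r <- correlate_window(a, b, 8)
    !r$valid || r$peak < 0.35 || r$peak_ratio < 1.2
  }, logical(1))
  expect_gt(mean(flagged), 0.95)
})

test_that("a single pass recovers uniform shifts and honors seeding", {
  img <- make_speckle(speckle_spec(shape_px = c(128L, 128L), seed = 6))
  cur <- warp_frame(img, function(x, y)
    list(u = rep(3, length(x)), v = rep(2, length(x))))
  f <- piv_pass(img, cur, window = 32, search = 8, spacing = 24)
  expect_true(all(abs(f$u[f$valid] - 3) < 0.05))
  expect_true(all(abs(f$v[f$valid] - 2) < 0.05))

  # an exact-truth seed leaves only a small residual
  seedf <- f; seedf$u[] <- 3; seedf$v[] <- 2; seedf$valid[] <- TRUE
  f2 <- piv_pass(img, cur, 32, 8, 24, seed_field = seedf)
  expect_true(all(abs(f2$u[f2$valid] - 3) < 0.05))

  # NULL seed behaves exactly like a zero seed
  zf <- seedf; zf$u[] <- 0; zf$v[] <- 0
  fa <- piv_pass(img, cur, 32, 8, 24, seed_field = NULL)
  fb <- piv_pass(img, cur, 32, 8, 24, seed_field = zf)
  expect_identical(fa$u, fb$u)
  expect_identical(fa$v, fb$v)
})

test_that("normalized-median validation replaces planted outliers only", {
  set.seed(21)
  u <- matrix(rnorm(81, 0, 0.02), 9, 9) + 1.5
  f <- make_field(u, u * 0)
  clean <- validate_vectors(f)
  expect_equal(sum(clean$replaced), 0)

  f$u[5, 5] <- 20
  fixed <- validate_vectors(f)
  expect_true(fixed$replaced[5, 5])
  expect_equal(sum(fixed$replaced), 1)
  expect_lt(abs(fixed$u[5, 5] - 1.5), 0.1)

  # an invalid vector with no valid neighbors stays invalid
  f2 <- make_field(u, u * 0)
  f2$valid[1:3, 1:3] <- FALSE
  out <- validate_vectors(f2)
  expect_false(out$valid[2, 2])
})

test_that("multipass converges on sinusoidal deformation and degenerates cleanly", {
  pair <- cached("challenge_pair",
                 dic_challenge_pair(2, 256, speckle_spec(shape_px = c(256L, 512L),
                                                         seed = 11, noise_sd = 0,
                                                         periodic = TRUE)))
  sch <- validation_schedule()
  f <- cached("challenge_field", multipass_piv(pair$ref, pair$def, sch))
  res <- pair$truth$resolvable(sch$window[nrow(sch)])[round(f$grid_x)]
  keep <- f$valid & matrix(rep(res, each = nrow(f$u)), nrow(f$u))
  err <- sweep(f$u, 2, pair$truth$u_at(f$grid_x))
  expect_lt(sqrt(mean(err[keep]^2)), 0.1)

  # where the deformation exceeds the final search radius, feed-forward
  # seeding is what makes recovery possible: multipass beats the single
  # final pass decisively
  big <- dic_challenge_pair(6, 256, speckle_spec(shape_px = c(256L, 512L),
                                                 seed = 12, noise_sd = 0,
                                                 periodic = TRUE))
  fm <- multipass_piv(big$ref, big$def, sch)
  f1 <- multipass_piv(big$ref, big$def, piv_schedule(16, 4, 16))
  resm <- big$truth$resolvable(16)[round(fm$grid_x)]
  res1 <- big$truth$resolvable(16)[round(f1$grid_x)]
  keepm <- fm$valid & matrix(rep(resm, each = nrow(fm$u)), nrow(fm$u))
  keep1 <- f1$valid & matrix(rep(res1, each = nrow(f1$u)), nrow(f1$u))
  errm <- sweep(fm$u, 2, big$truth$u_at(fm$grid_x))
  err1 <- sweep(f1$u, 2, big$truth$u_at(f1$grid_x))
  expect_lte(sqrt(mean(errm[keepm]^2)), sqrt(mean(err1[keep1]^2)))
  expect_lt(sqrt(mean(errm[keepm]^2)), 0.5)

  # identical frames: zero field at sub-pixel precision
  img <- make_speckle(speckle_spec(shape_px = c(128L, 128L), seed = 8))
  fz <- multipass_piv(img, img, piv_schedule(c(64, 32), c(16, 8), c(32, 24)))
  expect_lt(max(abs(fz$u[fz$valid])), 0.02)
  expect_lt(max(abs(fz$v[fz$valid])), 0.02)

  # a one-pass schedule equals the direct pass plus validation
  cur <- warp_frame(img, function(x, y)
    list(u = rep(1.25, length(x)), v = rep(-0.5, length(x))))
  direct <- validate_vectors(piv_pass(img, cur, 32, 8, 24))
  via <- multipass_piv(img, cur, piv_schedule(32, 8, 24))
  expect_identical(via$u, direct$u)
})

test_that("shift equivariance and antisymmetry hold", {
  img <- make_speckle(speckle_spec(shape_px = c(128L, 128L), seed = 13,
                                   periodic = TRUE))
  sch <- piv_schedule(c(64, 32), c(16, 8), c(32, 24))
  # exact (spectral) rigid shifts so the fixture itself carries no
  # interpolation error
  shift2d <- function(im, dx, dy) {
    im <- ardic:::warp_columns_spectral(im, rep(dx, ncol(im)))
    t(ardic:::warp_columns_spectral(t(im), rep(dy, nrow(im))))
  }
  for (s in list(c(1, 0), c(-2, 3), c(5.5, -4.25))) {
    cur <- shift2d(img, s[1], s[2])
    f <- multipass_piv(img, cur, sch)
    # drop the outer vector ring: the periodic shift wraps content there
    ok <- f$valid
    ok[c(1, nrow(ok)), ] <- FALSE
    ok[, c(1, ncol(ok))] <- FALSE
    expect_lt(max(abs(f$u[ok] - s[1])), 0.05)
    expect_lt(max(abs(f$v[ok] - s[2])), 0.05)
  }

  smoothdef <- function(x, y) list(u = 1.2 * sin(2 * pi * x / 128),
                                   v = 0.8 * cos(2 * pi * y / 128))
  cur <- warp_frame(img, smoothdef)
  fab <- multipass_piv(img, cur, sch)
  fba <- multipass_piv(cur, img, sch)
  ok <- fab$valid & fba$valid
  expect_lt(max(abs(fab$u[ok] + fba$u[ok])), 0.1)
  expect_lt(max(abs(fab$v[ok] + fba$v[ok])), 0.1)
})
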