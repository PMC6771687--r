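test_that("center of mass: single pixel, symmetry and direct-sum oracle", {
  g <- matrix(0, 10, 10); g[4, 7] <- 3
  img <- rendered_image(g, 10)
  com <- fiducial_center_of_mass(img)
  expect_equal(unname(com), c((7 - 0.5) * 10, (4 - 0.5) * 10))

  # symmetric blob -> geometric centre
  g2 <- matrix(0, 11, 11)
  g2[5:7, 5:7] <- matrix(c(1, 2, 1, 2, 5, 2, 1, 2, 1), 3, 3)
  com2 <- fiducial_center_of_mass(rendered_image(g2, 10))
  expect_equal(unname(com2), c(55, 55))

  set.seed(81)
  g3 <- matrix(runif(400), 20, 20)
  img3 <- rendered_image(g3, 10, origin = c(30, 40))
  com3 <- fiducial_center_of_mass(img3)
  X <- outer(rep(1, 20), (1:20 - 0.5) * 10 + 30)
  Y <- outer((1:20 - 0.5) * 10 + 40, rep(1, 20))
  expect_equal(unname(com3), c(sum(g3 * X) / sum(g3), sum(g3 * Y) / sum(g3)))

  expect_error(fiducial_center_of_mass(rendered_image(matrix(0, 5, 5), 10)),
               "zero")
  expect_error(fiducial_center_of_mass(img, roi = c(500, 600, 500, 600)),
               "ROI")
})

test_that("rod endpoints: horizontal rod, rotation equivariance,
           elongation gate and exhaustive-projection oracle", {
  m <- matrix(0, 10, 30); m[5, 6:25] <- 1
  ep <- fiducial_endpoints(m, pixel_size = 10)
  expect_equal(ep[1, ], c(x = 55, y = 45))
  expect_equal(ep[2, ], c(x = 245, y = 45))

  # 90-degree rotation rotates the endpoints
  ep_t <- fiducial_endpoints(t(m), pixel_size = 10)
  expect_equal(unname(ep_t[, "x"]), unname(ep[, "y"]))
  expect_equal(sort(unname(ep_t[, "y"])), sort(unname(ep[, "x"])))

  expect_error(fiducial_endpoints(matrix(1, 5, 5), 10), "not a rod")

  # noisy synthetic rod: equals exhaustive farthest-pair-along-axis scan
  set.seed(82)
  mm <- matrix(0, 40, 40)
  ang <- 0.4
  for (t_ in seq(-14, 14, by = 0.25)) {
    i <- round(20 + sin(ang) * t_ + rnorm(1, 0, 0.3))
    j <- round(20 + cos(ang) * t_ + rnorm(1, 0, 0.3))
    mm[i, j] <- 1
  }
  ep2 <- fiducial_endpoints(mm, pixel_size = 10)
  idx <- which(mm > 0)
  r <- (idx - 1) %% 40 + 1; c_ <- (idx - 1) %/% 40 + 1
  x <- (c_ - 0.5) * 10; y <- (r - 0.5) * 10
  vxx <- mean((x - mean(x))^2) + 100 / 12
  vyy <- mean((y - mean(y))^2) + 100 / 12
  vxy <- mean((x - mean(x)) * (y - mean(y)))
  th <- 0.5 * atan2(2 * vxy, vxx - vyy)
  pr <- (x - mean(x)) * cos(th) + (y - mean(y)) * sin(th)
  pts <- rbind(c(x[which.min(pr)], y[which.min(pr)]),
               c(x[which.max(pr)], y[which.max(pr)]))
  pts <- pts[order(pts[, 1], pts[, 2]), ]
  expect_equal(unname(ep2), unname(pts))
})

test_that("similarity and rigid fits recover exact parameters to
           machine precision", {
  set.seed(83)
  for (n in c(2, 5, 20)) {
    th <- runif(1, -pi, pi); s <- runif(1, 0.5, 2)
    tr <- runif(2, -1000, 1000)
    P <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Q <- t(s * R %*% t(P)) + rep(tr, each = n)
    fit <- fit_transform(point_matches(Q[, 1], Q[, 2], P[, 1], P[, 2]),
                         "similarity")
    expect_equal(fit$rotation, th, tolerance = 1e-9)
    expect_equal(fit$scale, s, tolerance = 1e-9)
    expect_equal(fit$translation, tr, tolerance = 1e-6)
    expect_lt(fit$rms_residual, 1e-8)
  }
  # rigid fit locks the scale at exactly 1
  P <- cbind(runif(6, 0, 1000), runif(6, 0, 1000))
  Q <- P * 1.3 + 10
  rig <- fit_transform(point_matches(Q[, 1], Q[, 2], P[, 1], P[, 2]),
                       "rigid")
  expect_equal(rig$scale, 1)
})

test_that("identity matches give the identity transform; degenerate
           geometry errors", {
  P <- cbind(c(0, 100, 50, 200), c(0, 0, 80, 120))
  m <- point_matches(P[, 1], P[, 2], P[, 1], P[, 2])
  fit <- fit_transform(m, "similarity")
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  expect_equal(fit$rotation, 0, tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)

  aff <- fit_transform(m, "affine")
  expect_equal(aff$params, cbind(diag(2), c(0, 0)), tolerance = 1e-9)

  col <- point_matches(c(0, 1, 2), c(0, 1, 2), c(0, 1, 2), c(0, 1, 2))
  expect_error(fit_transform(col, "affine"), "collinear")
  expect_error(fit_transform(m[1, ], "similarity"), ">= 2")
})

test_that("TPS interpolates affine configurations with ~zero bending and
           tends to the affine fit as lambda grows", {
  set.seed(84)
  P <- cbind(runif(6, 0, 1000), runif(6, 0, 1000))
  A <- matrix(c(1.2, 0.1, -0.2, 0.9), 2, 2)
  Q <- t(A %*% t(P)) + rep(c(30, -50), each = 6)
  m <- point_matches(Q[, 1], Q[, 2], P[, 1], P[, 2])
  tps <- fit_transform(m, "tps")
  expect_lt(tps$rms_residual, 1e-6)
  expect_lt(abs(tps$bending_energy), 1e-6)

  # non-affine configuration: heavy regularization approaches affine
  Q2 <- Q + cbind(rnorm(6, 0, 25), rnorm(6, 0, 25))
  m2 <- point_matches(Q2[, 1], Q2[, 2], P[, 1], P[, 2])
  aff <- fit_transform(m2, "affine")
  tps_stiff <- fit_transform(m2, "tps", lambda = 1e9)
  test_pts <- cbind(runif(20, 0, 1000), runif(20, 0, 1000))
  expect_equal(apply_transform(test_pts, tps_stiff),
               apply_transform(test_pts, aff), tolerance = 1e-2)
})

test_that("apply/invert round-trips points and rolls images under
           integer-pixel translation", {
  set.seed(85)
  P <- cbind(runif(8, 0, 2000), runif(8, 0, 2000))
  Q <- P %*% matrix(c(0.9, 0.2, -0.2, 0.9), 2, 2) + 50
  fit <- fit_transform(point_matches(Q[, 1], Q[, 2], P[, 1], P[, 2]),
                       "affine")
  pts <- cbind(runif(50, 0, 2000), runif(50, 0, 2000))
  back <- apply_transform(apply_transform(pts, fit), invert_transform(fit))
  expect_equal(back, pts, tolerance = 1e-6)

  idm <- similarity_transform()
  expect_equal(apply_transform(pts, idm), pts)

  g <- matrix(rpois(900, 2), 30, 30)
  img <- rendered_image(g, 10)
  shift <- similarity_transform(translation = c(30, -20))  # 3 px, -2 px
  warped <- apply_transform(img, shift)
  expected <- matrix(0, 30, 30)
  expected[1:(30 - 2 + 0), ] <- 0
  # index arithmetic oracle: out[i, j] = g[i + 2, j - 3]
  for (i in 1:30) for (j in 1:30) {
    si <- i + 2; sj <- j - 3
    expected[i, j] <- if (si >= 1 && si <= 30 && sj >= 1 && sj <= 30)
      g[si, sj] else 0
  }
  expect_equal(warped$grid, expected, tolerance = 1e-9)
})

test_that("overlay precision: exact cases, Rayleigh scaling and rigid
           invariance", {
  P <- cbind(c(0, 500, 1000, 200, 800), c(0, 900, 100, 600, 300))
  perfect <- point_matches(P[, 1], P[, 2], P[, 1], P[, 2])
  rep0 <- overlay_precision(perfect, model = fit_transform(perfect),
                            loo = FALSE)
  expect_equal(rep0$mean, 0, tolerance = 1e-9)
  expect_equal(rep0$median, 0, tolerance = 1e-9)

  # a pure 10 nm offset measured against the identity model
  off <- point_matches(P[, 1] + 10, P[, 2], P[, 1], P[, 2])
  rep1 <- overlay_precision(off, model = similarity_transform(),
                            loo = FALSE)
  expect_equal(rep1$distances, rep(10, 5))
  expect_equal(rep1$sd, 0)

  # overlay statistics are invariant under a common rigid motion
  set.seed(86)
  m <- simulate_landmark_matches(50, similarity_transform(0.2, 1.1,
                                                          c(100, -50)),
                                 jitter_sd = 8, seed = 7)
  r1 <- overlay_precision(m, kind = "similarity", loo = TRUE)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  refm <- t(R %*% t(cbind(m$x_ref, m$y_ref))) + rep(c(300, 400), each = 50)
  movm <- t(R %*% t(cbind(m$x_mov, m$y_mov))) + rep(c(300, 400), each = 50)
  m2 <- point_matches(refm[, 1], refm[, 2], movm[, 1], movm[, 2])
  r2 <- overlay_precision(m2, kind = "similarity", loo = TRUE)
  expect_equal(r1$median, r2$median, tolerance = 1e-6)
  expect_equal(r1$mean, r2$mean, tolerance = 1e-6)
})

test_that("leave-one-out residuals exceed in-sample residuals on average", {
  set.seed(87)
  diffs <- replicate(100, {
    m <- simulate_landmark_matches(8, similarity_transform(0.1, 1,
                                                           c(50, 20)),
                                   jitter_sd = 10,
                                   seed = sample.int(1e6, 1))
    fit <- fit_transform(m, "similarity")
    loo <- overlay_precision(m, kind = "similarity", loo = TRUE)
    ins <- overlay_precision(m, model = fit, loo = FALSE)
    mean(loo$distances) - mean(ins$distances)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("transform JSON and landmark CSV serialize round-trippably", {
  set.seed(88)
  m <- simulate_landmark_matches(6, jitter_sd = 5, seed = 3)
  fit <- fit_transform(m, "similarity")
  p <- tempfile(fileext = ".json")
  write_transform_json(fit, p)
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(obj$kind, "similarity")
  expect_equal(obj$scale, fit$scale, tolerance = 1e-12)
  p2 <- tempfile(fileext = ".csv")
  write_landmarks_csv(m, p2)
  back <- utils::read.csv(p2)
  expect_equal(back$x_ref, m$x_ref)
  unlink(c(p, p2))
})
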