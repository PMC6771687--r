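test_that("scene generation is deterministic and satisfies its geometric
           contracts", {
  sc <- scene_spec(n_endosomes = 3,
                   domains_per_endosome = dist_spec("fixed", value = 3),
                   n_fiducials = 2)
  a <- generate_scene(sc, seed = 7)
  b <- generate_scene(sc, seed = 7)
  expect_identical(a$structures, b$structures)
  c_ <- generate_scene(sc, seed = 8)
  expect_false(identical(a$structures, c_$structures))

  st <- a$structures
  expect_equal(sum(st$kind == "endosome"), 3L)
  expect_equal(sum(st$kind == "domain"), 9L)
  expect_equal(sum(st$kind == "fiducial"), 2L)
  # every domain's parent is an endosome and its centre lies on the
  # parent's membrane contour
  dom <- st[st$kind == "domain", ]
  for (i in seq_len(nrow(dom))) {
    par <- st[st$id == dom$parent[i], ]
    expect_equal(par$kind, "endosome")
    d <- sqrt((dom$x[i] - par$x)^2 + (dom$y[i] - par$y)^2)
    expect_equal(d, par$radius, tolerance = 1e-6)
  }
  # domains on one endosome do not overlap (arc separation)
  for (eid in unique(dom$parent)) {
    dd <- dom[dom$parent == eid, ]
    if (nrow(dd) < 2) next
    for (i in 1:(nrow(dd) - 1)) for (j in (i + 1):nrow(dd)) {
      gap <- sqrt((dd$x[i] - dd$x[j])^2 + (dd$y[i] - dd$y[j])^2)
      expect_gt(gap, (dd$diameter[i] + dd$diameter[j]) / 2 - 1e-6)
    }
  }
  expect_equal(mean(a$domain_truth$domain_count), 3)
})

test_that("simulated streams are deterministic, traceable and correctly
           scaled", {
  sc <- scene_spec(n_endosomes = 2,
                   domains_per_endosome = dist_spec("fixed", value = 2),
                   n_fiducials = 0, background_rate = 0, n_frames = 500)
  truth <- generate_scene(sc, seed = 9)
  em <- emitter_model()
  t1 <- simulate_localizations(truth, em, seed = 4)
  t2 <- simulate_localizations(truth, em, seed = 4)
  expect_identical(lapply(t1, plain_df), lapply(t2, plain_df))
  expect_named(t1, c("ch647", "ch561", "ch488"))

  # zero background: every localization within 5 sigma of its structure
  ch <- t1$ch488
  expect_true(all(ch$struct_id > 0))
  st <- truth$structures
  dom <- st[st$kind == "domain", ]
  for (i in seq_len(nrow(ch))) {
    s <- st[st$id == ch$struct_id[i], ]
    d <- sqrt((ch$x[i] - s$x)^2 + (ch$y[i] - s$y)^2)
    expect_lt(d, s$diameter / 2 + 5 * 10)
  }

  # localization count ~ sum over emitters of on-frames:
  # E[N] = E[emitters] * mean_on_frames (truncation negligible here)
  sc2 <- scene_spec(n_endosomes = 4,
                    domains_per_endosome = dist_spec("fixed", value = 5),
                    domain_diameter = dist_spec("fixed", value = 80),
                    n_fiducials = 0, background_rate = 0, n_frames = 5000)
  truth2 <- generate_scene(sc2, seed = 10)
  t3 <- simulate_localizations(truth2, emitter_model(), seed = 11)
  area <- sum(pi * (80 / 2)^2 * 20)
  expected <- area * 0.01 * 3
  expect_lt(abs(nrow(t3$ch488) - expected), 4 * sqrt(expected) +
              0.02 * expected)
})

test_that("filter thresholds are plausible cut points for the simulated
           photon distributions", {
  sc <- scene_spec(n_endosomes = 2, n_fiducials = 1, n_frames = 500)
  truth <- generate_scene(sc, seed = 12)
  tabs <- simulate_localizations(truth, emitter_model(), seed = 12)
  # most, but not all, localizations survive the standard thresholds
  for (pair in list(c("ch647", 3000), c("ch561", 1500), c("ch488", 450))) {
    frac <- mean(tabs[[pair[1]]]$photons >= as.numeric(pair[2]))
    expect_gt(frac, 0.8)
    expect_lt(frac, 0.999)
  }
  # FWHM values sit inside the section-imaging window
  expect_true(all(tabs$ch647$fwhm >= 250 & tabs$ch647$fwhm <= 450))
})

test_that("EM reference rasterization exports exact landmarks that
           recover the generating transform", {
  sc <- scene_spec(n_endosomes = 2, n_fiducials = 3, n_frames = 200)
  truth <- generate_scene(sc, seed = 13)
  tf <- similarity_transform(rotation = 0.35, scale = 1.06,
                             translation = c(700, -300))
  em <- make_em_reference(truth, tf, em_pixel_size = 20)
  lm <- em$landmarks
  expect_equal(nrow(lm), 3 * 3)        # centre + 2 endpoints per rod
  # landmark table equals the analytic mapping
  mapped <- apply_transform(cbind(lm$x_smlm, lm$y_smlm), tf)
  expect_equal(lm$x_em, mapped[, 1], tolerance = 1e-9)
  expect_equal(lm$y_em, mapped[, 2], tolerance = 1e-9)
  # fitting on the exported landmarks recovers the transform
  fit <- fit_transform(point_matches(lm$x_em, lm$y_em, lm$x_smlm,
                                     lm$y_smlm), "similarity")
  expect_equal(fit$rotation, 0.35, tolerance = 1e-9)
  expect_equal(fit$scale, 1.06, tolerance = 1e-9)
  expect_equal(fit$translation, c(700, -300), tolerance = 1e-6)

  # identity transform at matched pixel size: rod silhouettes coincide
  # with the SMLM-frame rod positions
  em0 <- make_em_reference(truth, similarity_transform(), 20)
  rod <- truth$structures[truth$structures$kind == "fiducial", ][1, ]
  ij <- c(1 + floor((rod$y - em0$image$origin[2]) / 20),
          1 + floor((rod$x - em0$image$origin[1]) / 20))
  expect_equal(em0$image$grid[ij[1], ij[2]], 1)
})

test_that("landmark-match simulation reproduces its stated model", {
  tf <- similarity_transform(0.2, 1.04, c(100, 50))
  m <- simulate_landmark_matches(200, tf, jitter_sd = 0, seed = 3)
  mapped <- apply_transform(cbind(m$x_mov, m$y_mov), tf)
  expect_equal(m$x_ref, mapped[, 1], tolerance = 1e-9)
  m2 <- simulate_landmark_matches(200, tf, jitter_sd = 10, seed = 3)
  expect_identical(m2$x_mov, m$x_mov)
  resid <- sqrt((m2$x_ref - mapped[, 1])^2 + (m2$y_ref - mapped[, 2])^2)
  expect_equal(stats::median(resid), rayleigh_median(10), tolerance = 0.15)
})
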