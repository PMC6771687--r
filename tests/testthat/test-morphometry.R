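test_that("IsoData: two-level image splits at the midpoint; degenerate
           and equivariance behaviour", {
  v <- c(rep(0, 500), rep(100, 500))
  expect_equal(as.numeric(isodata_threshold(v)), 50, tolerance = 0.5)
  expect_error(isodata_threshold(rep(3, 100)), "constant")

  set.seed(71)
  img <- matrix(c(rnorm(300, 30, 8), rnorm(724, 120, 20)), 32, 32)
  t0 <- as.numeric(isodata_threshold(img))
  a <- 3.7; b <- 42
  t1 <- as.numeric(isodata_threshold(a * img + b))
  bw <- attr(isodata_threshold(a * img + b), "bin_width")
  expect_equal(t1, a * t0 + b, tolerance = bw + a * attr(isodata_threshold(img), "bin_width"))
})

test_that("segmentation applies the area floor, hole filling and
           8-connectivity", {
  # components of pixel area 3 and 5 with min_area 4 -> one survivor
  m <- matrix(0, 20, 20)
  m[2:4, 2] <- 1                       # area 3
  m[10:14, 10] <- 1                    # area 5
  img <- rendered_image(m, 10)
  mask <- segment_structures(img, blur_sigma = 0, min_area = 4,
                             threshold = 0.5)
  expect_equal(mask$n, 1L)
  expect_equal(sum(mask$labels > 0), 5L)

  # ring with a hole: fill_holes counts the lumen as particle area
  ring <- matrix(0, 15, 15)
  ring[5:11, 5] <- 1; ring[5:11, 11] <- 1
  ring[5, 5:11] <- 1; ring[11, 5:11] <- 1
  rimg <- rendered_image(ring, 10)
  filled <- segment_structures(rimg, 0, 4, fill_holes = TRUE,
                               threshold = 0.5)
  expect_equal(sum(filled$labels > 0), 7 * 7)
  open_ <- segment_structures(rimg, 0, 4, fill_holes = FALSE,
                              threshold = 0.5)
  expect_equal(sum(open_$labels > 0), sum(ring))

  # diagonal-only contact is one component (8-connectivity)
  diagm <- matrix(0, 10, 10)
  diagm[cbind(2:7, 2:7)] <- 1
  dm <- segment_structures(rendered_image(diagm, 10), 0, 1,
                           threshold = 0.5)
  expect_equal(dm$n, 1L)

  # upper size window drops oversized components
  mm <- matrix(0, 30, 30)
  mm[2:3, 2:3] <- 1                    # 4 px
  mm[10:25, 10:25] <- 1                # 256 px
  sm <- segment_structures(rendered_image(mm, 10), 0, 4,
                           threshold = 0.5, max_area = 100)
  expect_equal(sm$n, 1L)

  expect_error(segment_structures(rendered_image(matrix(0, 8, 8), 10), 0),
               "constant")
})

test_that("moment-ellipse measurements match their closed forms and the
           brute-force moment oracle", {
  # 3x3 square at 10 nm/px: area 900 nm^2, diameter 2*sqrt(900/pi)
  m <- matrix(0, 9, 9); m[4:6, 4:6] <- 1
  mask <- segment_structures(rendered_image(m, 10), 0, 1, threshold = 0.5)
  rec <- measure_domains(mask)
  expect_equal(rec$area, 900)
  expect_equal(rec$major_axis, rec$minor_axis, tolerance = 1e-9)
  expect_equal(rec$diameter, 2 * sqrt(900 / pi), tolerance = 1e-9)

  # doubling the square doubles the diameter and quadruples the area
  m2 <- matrix(0, 14, 14); m2[4:9, 4:9] <- 1
  rec2 <- measure_domains(segment_structures(rendered_image(m2, 10), 0, 1,
                                             threshold = 0.5))
  expect_equal(rec2$area, 4 * rec$area)
  expect_equal(rec2$diameter, 2 * rec$diameter, tolerance = 1e-9)

  # 1x8 line: axis ratio equals the brute-force moment-eigenvalue ratio
  ln <- matrix(0, 12, 12); ln[6, 3:10] <- 1
  rec3 <- measure_domains(segment_structures(rendered_image(ln, 10), 0, 1,
                                             threshold = 0.5))
  ev <- oracle_pixel_moments(rep(6, 8), 3:10)
  expect_equal(rec3$major_axis / rec3$minor_axis, sqrt(ev[1] / ev[2]),
               tolerance = 1e-9)
  # centroid sits at the line centre in nm
  expect_equal(rec3$cx, (mean(3:10) - 0.5) * 10)
  expect_equal(rec3$cy, 55)
})

test_that("broadening correction subtracts widths in quadrature and
           floors at zero", {
  rec <- measure_domains(segment_structures(
    rendered_image({m <- matrix(0, 9, 9); m[4:6, 4:6] <- 1; m}, 10),
    0, 1, threshold = 0.5))
  out <- correct_broadening(rec, blur_sigma = 2, pixel_size = 10,
                            loc_sigma = 0)
  w2 <- (2 * sqrt(2 * log(2)))^2 * (400 + 100 / 12)
  expect_equal(out$diameter_corrected,
               sqrt(max(rec$diameter^2 - w2, 0)))
  tiny <- correct_broadening(rec, blur_sigma = 20, pixel_size = 10)
  expect_equal(tiny$diameter_corrected, 0)
})

test_that("per-endosome aggregation counts, covers and fits exactly on
           constructed scenes", {
  # one endosome blob containing 3 domains of equal area
  E <- matrix(0, 40, 40); E[5:35, 5:35] <- 1
  emask <- labeled_mask(E, 10)
  R <- matrix(0, 40, 40)
  R[8:10, 8:10] <- 1; R[20:22, 20:22] <- 2; R[30:32, 30:32] <- 3
  rmask <- labeled_mask(R, 10)
  doms <- measure_domains(rmask)
  res <- endosome_domain_stats(emask, doms, rmask)
  expect_equal(res$endosomes$domain_count, 3L)
  expect_equal(res$endosomes$rab5_covered_area, 3 * 900)
  expect_equal(res$summary$domain_count_mean, 3)
  expect_equal(res$summary$domain_count_sd, 0)
  expect_equal(res$summary$n_domains, 3L)

  # endosomes with domain counts 1, 2, 3 of identical domain area a:
  # covered-area-vs-count fit has slope a, intercept 0, r = 1
  E2 <- matrix(0, 30, 100)
  E2[5:25, 3:30] <- 1; E2[5:25, 36:63] <- 2; E2[5:25, 69:96] <- 3
  emask2 <- labeled_mask(E2, 10)
  R2 <- matrix(0, 30, 100)
  R2[8:10, 6:8] <- 1
  R2[8:10, 40:42] <- 2; R2[16:18, 50:52] <- 3
  R2[8:10, 72:74] <- 4; R2[14:16, 80:82] <- 5; R2[20:22, 88:90] <- 6
  rmask2 <- labeled_mask(R2, 10)
  res2 <- endosome_domain_stats(emask2, measure_domains(rmask2), rmask2)
  expect_equal(res2$endosomes$domain_count, 1:3)
  f <- res2$summary$fit_area_vs_count
  expect_equal(f[["slope"]], 900, tolerance = 1e-9)
  expect_equal(f[["intercept"]], 0, tolerance = 1e-6)
  expect_equal(f[["r"]], 1, tolerance = 1e-12)
  # singleton subset = the count-1 endosome's domain
  expect_equal(res2$summary$singleton_n, 1L)

  # a domain centroid just off the endosome snaps within the radius
  E3 <- matrix(0, 20, 20); E3[5:15, 5:10] <- 1
  R3 <- matrix(0, 20, 20); R3[8:10, 12:13] <- 1
  res3 <- endosome_domain_stats(labeled_mask(E3, 10),
                                measure_domains(labeled_mask(R3, 10)),
                                labeled_mask(R3, 10), snap_radius_px = 5)
  expect_equal(res3$endosomes$domain_count, 1L)
  res4 <- endosome_domain_stats(labeled_mask(E3, 10),
                                measure_domains(labeled_mask(R3, 10)),
                                labeled_mask(R3, 10), snap_radius_px = 1)
  expect_equal(res4$endosomes$domain_count, 0L)
  expect_equal(attr(res4, "n_unassigned"), 1L)
})

test_that("morphometry is deterministic and scale-invariant in intensity", {
  set.seed(72)
  g <- matrix(rpois(60 * 60, 0.3), 60, 60)
  g[20:30, 20:30] <- g[20:30, 20:30] + 8
  img <- rendered_image(g, 10)
  m1 <- segment_structures(img, 2, 4)
  m2 <- segment_structures(img, 2, 4)
  expect_identical(m1$labels, m2$labels)
  expect_equal(measure_domains(m1), measure_domains(m2))
  # global intensity scaling does not change the mask
  m3 <- segment_structures(rendered_image(5 * g, 10), 2, 4)
  expect_identical(m1$labels, m3$labels)
})

test_that("measured diameters inflate with localization error", {
  # one field of 55 nm domains per sigma; the blur floor dominates at
  # small sigma, so adjacent steps are compared with a small tolerance
  # and the overall trend must be clearly increasing
  diam_at <- function(sigma, seed) {
    sc <- scene_spec(field_size = c(4000, 4000), n_endosomes = 8,
                     endosome_radius = c(150, 250),
                     domains_per_endosome = dist_spec("fixed", value = 5),
                     domain_diameter = dist_spec("fixed", value = 55),
                     n_fiducials = 0, n_frames = 2000)
    em <- emitter_model(sigma = c(ch647 = sigma, ch561 = sigma,
                                  ch488 = sigma))
    truth <- generate_scene(sc, seed = seed)
    tabs <- simulate_localizations(truth, em, seed = seed)
    img <- median_filter_image(
      render_histogram(tabs$ch488, render_spec(10, c(0, 4000), c(0, 4000))),
      1)
    mask <- segment_structures(img, 2, 4, max_area = 2000)
    mean(measure_domains(mask)$diameter)
  }
  d <- vapply(c(2, 5, 10, 20), diam_at, numeric(1), seed = 77)
  expect_true(all(diff(d) > -2))
  expect_gt(d[4], d[1] + 4)
  expect_gt(d[3], d[1] - 1)
})
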