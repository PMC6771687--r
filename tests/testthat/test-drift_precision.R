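test_that("linking respects the radius contract on minimal pairs", {
  t <- loc_table(frame = c(0, 1), x = c(100, 100), y = c(50, 50),
                 photons = c(10, 10), fwhm = c(300, 300))
  tr <- link_consecutive(t, link_radius = 100)
  expect_equal(attr(tr, "n_tracks"), 1L)
  expect_equal(nrow(tr), 2L)

  t2 <- loc_table(frame = c(0, 1), x = c(100, 250), y = c(50, 50),
                  photons = c(10, 10), fwhm = c(300, 300))
  expect_equal(attr(link_consecutive(t2, 100), "n_tracks"), 0L)

  expect_equal(attr(link_consecutive(loc_table(), 100), "n_tracks"), 0L)
})

test_that("sparse blinking emitters yield one track each, matching the
           brute-force all-pairs linker", {
  set.seed(31)
  for (rep in 1:3) {
    n_em <- 40
    ex <- runif(n_em, 0, 20000); ey <- runif(n_em, 0, 20000)
    t0 <- sample.int(30, n_em, replace = TRUE) - 1L
    df <- data.frame(
      frame = as.integer(unlist(lapply(t0, function(s) s + 0:4))),
      x = rep(ex, each = 5) + rnorm(5 * n_em, 0, 10),
      y = rep(ey, each = 5) + rnorm(5 * n_em, 0, 10))
    tab <- loc_table(frame = df$frame, x = df$x, y = df$y,
                     photons = rep(100, nrow(df)),
                     fwhm = rep(300, nrow(df)))
    tr <- link_consecutive(tab, 100)
    expect_equal(attr(tr, "n_tracks"), n_em)
    # brute-force oracle agrees on the membership partition
    odf <- as.data.frame(tab)
    oracle <- oracle_link(odf, 100)
    expect_equal(attr(tr, "n_tracks"), length(unique(oracle[oracle > 0])))
    got <- integer(nrow(tab)); got[tr$row] <- tr$track
    # same partition up to label renaming
    expect_equal(unname(split(seq_along(got), got)[as.character(unique(got[got > 0]))]),
                 unname(split(seq_along(oracle), oracle)[as.character(unique(oracle[oracle > 0]))]))
  }
})

test_that("linking is symmetric under time reversal", {
  set.seed(32)
  tab <- random_loc_table(400)
  tr_fwd <- link_consecutive(tab, 120)
  rev_tab <- loc_table(frame = max(tab$frame) - tab$frame, x = tab$x,
                       y = tab$y, photons = tab$photons, fwhm = tab$fwhm)
  tr_rev <- link_consecutive(rev_tab, 120)
  expect_equal(attr(tr_fwd, "n_tracks"), attr(tr_rev, "n_tracks"))
  # identical membership partitions over x-coordinates
  part <- function(tr, tab) {
    s <- split(round(tr$x, 9), tr$track)
    sort(vapply(s, function(v) paste(sort(v), collapse = ","), ""))
  }
  expect_equal(part(tr_fwd, tab), part(tr_rev, rev_tab))
})

test_that("drift estimation is exact on a noiseless linear track and
           calibrated on noisy ones", {
  f <- 0:999
  ts <- track_set(track = rep(1L, 1000), frame = f,
                  x = 100 + 0.02 * f, y = 50 + 0 * f)
  dm <- estimate_linear_drift(ts, min_track_length = 100)
  expect_equal(dm$vx, 0.02, tolerance = 1e-12)
  expect_equal(dm$vy, 0, tolerance = 1e-12)

  # stationary noisy track: |v| below 3x the closed-form standard error
  set.seed(41)
  n <- 5000
  ts2 <- track_set(track = rep(1L, n), frame = 0:(n - 1),
                   x = rnorm(n, 0, 5), y = rnorm(n, 0, 5))
  dm2 <- estimate_linear_drift(ts2, min_track_length = 100)
  se_theory <- 5 / sqrt(n * (n^2 - 1) / 12)
  expect_lt(abs(dm2$vx), 3 * se_theory)
  expect_lt(abs(dm2$vy), 3 * se_theory)
  expect_equal(dm2$se_vx, se_theory, tolerance = 0.1)
})

test_that("robust slope combination shrugs off a corrupted track", {
  set.seed(42)
  f <- 0:999
  good <- lapply(1:5, function(i)
    data.frame(track = i, frame = f, x = i * 1000 + 0.02 * f + rnorm(1000, 0, 2),
               y = i * 1000 - 0.01 * f + rnorm(1000, 0, 2)))
  bad <- data.frame(track = 6, frame = f, x = 9000 + 1.5 * f,
                    y = 9000 + 0.8 * f)
  df <- rbind(do.call(rbind, good), bad)
  ts <- track_set(df$track, df$frame, df$x, df$y)
  dm <- estimate_linear_drift(ts, min_track_length = 100, robust = TRUE)
  expect_equal(dm$vx, 0.02, tolerance = 0.01)
  expect_equal(dm$vy, -0.01, tolerance = 0.01)
})

test_that("drift application is the stated coordinate map with an inverse", {
  tab <- random_loc_table(200, seed = 5)
  expect_equal(plain_df(apply_drift(tab, drift_model(0, 0))), plain_df(tab))
  m <- drift_model(0.05, -0.02)
  neg <- drift_model(-0.05, 0.02)
  back <- apply_drift(apply_drift(tab, m), neg)
  expect_equal(back$x, tab$x, tolerance = 1e-9)
  expect_equal(back$y, tab$y, tolerance = 1e-9)
  one <- loc_table(frame = 10, x = 100, y = 200, photons = 5, fwhm = 300)
  shifted <- apply_drift(one, drift_model(1, 2, frame0 = 4))
  expect_equal(shifted$x, 100 - 1 * 6)
  expect_equal(shifted$y, 200 - 2 * 6)
})

test_that("injected drift is removed exactly by the matching model", {
  tab <- random_loc_table(500, seed = 6)
  drifted <- inject_drift(tab, c(0.05, -0.03))
  restored <- apply_drift(drifted, drift_model(0.05, -0.03))
  expect_equal(restored$x, tab$x, tolerance = 1e-9)
  expect_equal(restored$y, tab$y, tolerance = 1e-9)
})

test_that("precision statistic: degenerate, equivariance and closed-form
           median behaviour", {
  ts <- track_set(track = c(1, 1, 1), frame = 0:2,
                  x = rep(5, 3), y = rep(7, 3))
  est <- estimate_precision(ts)
  expect_equal(est$per_track_sd, 0)
  expect_equal(est$median_precision, 0)

  set.seed(51)
  ts2 <- make_gaussian_tracks(500, 5, 10)
  est2 <- estimate_precision(ts2)
  ts2x2 <- track_set(ts2$track, ts2$frame, 2 * ts2$x, 2 * ts2$y)
  est2x2 <- estimate_precision(ts2x2)
  expect_equal(est2x2$per_track_sd, 2 * est2$per_track_sd,
               tolerance = 1e-9)
  expect_equal(est2x2$median_precision, 2 * est2$median_precision,
               tolerance = 1e-9)
  # translation invariance
  ts2t <- track_set(ts2$track, ts2$frame, ts2$x + 1e4, ts2$y - 2e3)
  expect_equal(estimate_precision(ts2t)$median_precision,
               est2$median_precision, tolerance = 1e-9)

  # for track length n the pooled SD is sigma * sqrt(chisq_{2(n-1)} / df):
  # median of the statistic is sigma * sqrt(qchisq(.5, df)/df)
  set.seed(52)
  big <- make_gaussian_tracks(20000, 5, 10)
  med <- estimate_precision(big)$median_precision
  expect_equal(med, 10 * sqrt(qchisq(0.5, 8) / 8), tolerance = 0.02)

  expect_error(estimate_precision(track_set(integer(), integer(),
                                            numeric(), numeric())),
               "no tracks")
})

test_that("precision pools across multiple fields of view", {
  set.seed(53)
  a <- make_gaussian_tracks(100, 5, 10)
  b <- make_gaussian_tracks(150, 5, 10)
  pooled <- estimate_precision(list(a, b))
  expect_equal(pooled$n_tracks, 250)
  expect_equal(stats::median(c(estimate_precision(a)$per_track_sd,
                               estimate_precision(b)$per_track_sd)),
               pooled$median_precision)
})
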