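# Independent oracles used by the tests. These deliberately re-derive
# each quantity by the most direct route available (exhaustive scans,
# brute-force loops, closed forms) and share no code with the package
# implementations they check.

# exhaustive intermeans scan: try every histogram split point, score by
# |candidate boundary - intermean|, return the intermean at the best split
oracle_isodata_scan <- function(v, n_bins = 256) {
  rng <- range(v)
  bw <- (rng[2] - rng[1]) / n_bins
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  bin <- pmin(n_bins, pmax(1L, 1L + floor((v - rng[1]) / bw)))
  w <- tabulate(bin, n_bins)
  cw <- cumsum(w)
  cwx <- cumsum(w * centers)
  best <- Inf
  bestT <- NA_real_
  for (k in 1:(n_bins - 1)) {
    wb <- cw[k]; wa <- cw[n_bins] - wb
    if (wb == 0 || wa == 0) next
    boundary <- (centers[k] + centers[k + 1]) / 2
    im <- (cwx[k] / wb + (cwx[n_bins] - cwx[k]) / wa) / 2
    score <- abs(boundary - im)
    if (score < best) { best <- score; bestT <- im }
  }
  bestT
}

# per-pixel sorted-neighbourhood median with explicit loops
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    out[i, j] <- stats::median(as.vector(nb))
  }
  out
}

# brute-force all-pairs mutual-nearest-neighbour linker
oracle_link <- function(df, radius) {
  track_of <- integer(nrow(df))
  next_id <- 1L
  frames <- sort(unique(df$frame))
  for (f in frames) {
    a <- which(df$frame == f)
    b <- which(df$frame == f + 1L)
    if (length(a) == 0L || length(b) == 0L) next
    for (ia in a) {
      d <- sqrt((df$x[b] - df$x[ia])^2 + (df$y[b] - df$y[ia])^2)
      jb <- b[which.min(d)]
      if (min(d) > radius) next
      dd <- sqrt((df$x[a] - df$x[jb])^2 + (df$y[a] - df$y[jb])^2)
      if (a[which.min(dd)] != ia) next          # not mutual
      if (track_of[ia] == 0L) {
        track_of[ia] <- next_id
        next_id <- next_id + 1L
      }
      track_of[jb] <- track_of[ia]
    }
  }
  track_of
}

# brute-force central moments of a set of pixels (centers, unit pixels)
oracle_pixel_moments <- function(rows, cols) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  vrr <- sum((rows - mr)^2) / n + 1 / 12
  vcc <- sum((cols - mc)^2) / n + 1 / 12
  vrc <- sum((rows - mr) * (cols - mc)) / n
  M <- matrix(c(vcc, vrc, vrc, vrr), 2, 2)
  eigen(M, symmetric = TRUE)$values
}

# closed-form Rayleigh median for isotropic per-axis Gaussian error
rayleigh_median <- function(sigma) sigma * sqrt(2 * log(2))

# build a track_set of n_tracks i.i.d. Gaussian tracks around scattered
# anchors (anchor spacing >> sigma so tracks are unambiguous)
make_gaussian_tracks <- function(n_tracks, len, sigma) {
  anchors_x <- stats::runif(n_tracks, 0, n_tracks * 50)
  anchors_y <- stats::runif(n_tracks, 0, n_tracks * 50)
  track_set(track = rep(seq_len(n_tracks), each = len),
            frame = rep(seq_len(len) - 1L, n_tracks),
            x = rep(anchors_x, each = len) +
              stats::rnorm(n_tracks * len, 0, sigma),
            y = rep(anchors_y, each = len) +
              stats::rnorm(n_tracks * len, 0, sigma))
}

# random localization table
random_loc_table <- function(n, channel = "chX", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loc_table(frame = sample.int(200, n, replace = TRUE) - 1L,
            x = stats::runif(n, 0, 5000),
            y = stats::runif(n, 0, 5000),
            photons = stats::rlnorm(n, log(2000), 0.6),
            fwhm = stats::runif(n, 200, 600),
            channel = channel)
}

# strip class/metadata attributes for plain content comparison
plain_df <- function(t) {
  d <- as.data.frame(t)
  attr(d, "metadata") <- NULL
  attr(d, "filter_log") <- NULL
  attr(d, "n_tracks") <- NULL
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}
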