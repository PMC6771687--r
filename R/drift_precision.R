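#' @title Track linking, drift correction and the localization-precision
#'   statistic
#' @name drift_precision
#' @description
#' Localizations are linked into tracks by greedy mutual-nearest-neighbour
#' matching between consecutive frames; long tracks feed a linear drift
#' estimate; per-track coordinate spread around the track mean yields the
#' localization-precision statistic (median of per-track pooled SDs).
NULL

# nearest neighbour of each (ax, ay) among (bx, by) within radius r;
# returns index into b or NA. Ties resolve to the lowest b index
# (which.min is first-match). Chunked to bound memory.
.nn_within <- function(ax, ay, bx, by, r) {
  na <- length(ax)
  nb <- length(bx)
  out <- rep(NA_integer_, na)
  if (na == 0L || nb == 0L) return(out)
  chunk <- max(1L, floor(4e6 / nb))
  r2 <- r * r
  for (s in seq(1L, na, by = chunk)) {
    e <- min(na, s + chunk - 1L)
    d2 <- outer(ax[s:e], bx, "-")^2 + outer(ay[s:e], by, "-")^2
    j <- max.col(-d2, ties.method = "first")
    hit <- d2[cbind(seq_len(e - s + 1L), j)] <= r2
    out[s:e][hit] <- j[hit]
  }
  out
}

#' Link localizations into consecutive-frame tracks
#'
#' Greedy mutual-nearest-neighbour linking: a localization in frame f and
#' one in frame f+1 are linked when each is the other's nearest neighbour
#' within `link_radius`. Chains are extended while links exist; frames in
#' a track are strictly consecutive (no gap frames) and each localization
#' belongs to at most one track. Ties in nearest-neighbour assignment
#' break to the lowest record index, making linking deterministic.
#' The table should be drift-corrected first, or the per-frame drift must
#' be small relative to `link_radius`.
#'
#' @param table a [loc_table].
#' @param link_radius maximum link distance in nm (default 104, one
#'   camera pixel).
#' @return A `data.frame` of class `"track_set"` with columns
#'   `track, row, frame, x, y` (one row per track member; `row` indexes
#'   into `table`), containing only tracks of length >= 2, with the
#'   number of tracks in attribute `n_tracks`.
#' @export
link_consecutive <- function(table, link_radius = 104) {
  stopifnot(inherits(table, "loc_table"), link_radius > 0)
  n <- nrow(table)
  empty <- data.frame(track = integer(), row = integer(),
                      frame = integer(), x = numeric(), y = numeric())
  if (n == 0L)
    return(structure(empty, n_tracks = 0L,
                     class = c("track_set", "data.frame")))
  fr <- table$frame
  by_frame <- split(seq_len(n), fr)
  frames <- as.integer(names(by_frame))
  track_of <- integer(n)        # 0 = not yet in a track
  next_track <- 1L
  # active: rows (into table) whose localization sits in the current frame
  active <- by_frame[[1]]
  for (k in seq_len(length(frames) - 1L)) {
    f <- frames[k]
    if (frames[k + 1L] != f + 1L) {      # gap: all chains terminate
      active <- by_frame[[k + 1L]]
      next
    }
    b <- by_frame[[k + 1L]]
    a <- active
    nn_ab <- .nn_within(table$x[a], table$y[a],
                        table$x[b], table$y[b], link_radius)
    nn_ba <- .nn_within(table$x[b], table$y[b],
                        table$x[a], table$y[a], link_radius)
    ia <- which(!is.na(nn_ab))
    mutual <- ia[nn_ba[nn_ab[ia]] == ia]   # a-index of mutual pairs
    for (i in mutual) {
      ra <- a[i]; rb <- b[nn_ab[i]]
      if (track_of[ra] == 0L) {
        track_of[ra] <- next_track
        next_track <- next_track + 1L
      }
      track_of[rb] <- track_of[ra]
    }
    active <- b
  }
  keep <- track_of > 0L
  if (!any(keep))
    return(structure(empty, n_tracks = 0L,
                     class = c("track_set", "data.frame")))
  out <- data.frame(track = track_of[keep], row = which(keep),
                    frame = fr[keep], x = table$x[keep], y = table$y[keep])
  out <- out[order(out$track, out$frame), , drop = FALSE]
  # renumber tracks consecutively
  out$track <- match(out$track, unique(out$track))
  rownames(out) <- NULL
  structure(out, n_tracks = max(out$track),
            class = c("track_set", "data.frame"))
}

#' Build a track set directly from per-track member coordinates
#'
#' Constructor used by simulations and tests to bypass linking.
#'
#' @param track integer track ids; `frame`, `x`, `y` parallel vectors.
#' @return A `"track_set"` as from [link_consecutive].
#' @export
track_set <- function(track, frame, x, y) {
  df <- data.frame(track = as.integer(track),
                   row = rep(NA_integer_, length(track)),
                   frame = as.integer(frame), x = x, y = y)
  df <- df[order(df$track, df$frame), , drop = FALSE]
  df$track <- match(df$track, unique(df$track))
  rownames(df) <- NULL
  structure(df, n_tracks = length(unique(df$track)),
            class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  nt <- attr(x, "n_tracks")
  cat(sprintf("<track_set> %d tracks, %d localizations", nt, nrow(x)))
  if (nt > 0) {
    len <- tabulate(x$track, nt)
    cat(sprintf("; track length %d-%d (median %.0f)",
                min(len), max(len), stats::median(len)))
  }
  cat("\n")
  invisible(x)
}

#' Linear drift model
#'
#' Framewise linear lateral drift: the stage moves at constant velocity
#' `(vx, vy)` nm/frame, so correction subtracts `v * (frame - frame0)`.
#'
#' @param vx,vy drift velocity in nm per frame (finite).
#' @param frame0 reference frame left uncorrected (default 0).
#' @param se_vx,se_vy optional standard errors of the fitted velocities.
#' @param method estimation-method tag.
#' @return A list of class `"drift_model"`.
#' @export
drift_model <- function(vx, vy, frame0 = 0, se_vx = NA_real_,
                        se_vy = NA_real_, method = "explicit") {
  stopifnot(is.finite(vx), is.finite(vy))
  structure(list(vx = vx, vy = vy, frame0 = frame0,
                 se_vx = se_vx, se_vy = se_vy, method = method),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> v = (%.5g, %.5g) nm/frame (%s)",
              x$vx, x$vy, x$method))
  if (is.finite(x$se_vx))
    cat(sprintf("; SE = (%.3g, %.3g)", x$se_vx, x$se_vy))
  cat("\n")
  invisible(x)
}

#' Estimate linear drift from long tracks
#'
#' Each qualifying track contributes its least-squares
#' displacement-vs-frame slope, weighted by its frame spread
#' `sum((f - fbar)^2)` so longer tracks dominate. By default the
#' per-track slopes are combined by the weighted median
#' (`robust = TRUE`), which is immune to occasional corrupted chains
#' from nearest-neighbour mislinks in dense fiducials; `robust = FALSE`
#' pools all demeaned points into one least-squares slope. With a single
#' qualifying track both variants reduce to that track's exact LS slope.
#' Standard errors come from the closed-form slope-variance formula
#' `SE^2 = sigma_resid^2 / sum((f - fbar)^2)`.
#'
#' @param tracks a `"track_set"`.
#' @param min_track_length minimum members for a track to qualify
#'   (default 10; use long fiducial tracks).
#' @param robust combine per-track slopes by weighted median (default)
#'   instead of pooled least squares.
#' @return A [drift_model] with `method = "track_lsq"`.
#' @export
estimate_linear_drift <- function(tracks, min_track_length = 10,
                                  robust = TRUE) {
  stopifnot(inherits(tracks, "track_set"))
  nt <- attr(tracks, "n_tracks")
  len <- tabulate(tracks$track, nt)
  ok <- which(len >= min_track_length)
  if (length(ok) == 0L)
    stop("no track of length >= ", min_track_length,
         "; supply an explicit drift_model() instead")
  sel <- tracks$track %in% ok
  tid <- match(tracks$track[sel], ok)
  f <- tracks$frame[sel]
  fm <- stats::ave(as.numeric(f), tid)
  xm <- stats::ave(tracks$x[sel], tid)
  ym <- stats::ave(tracks$y[sel], tid)
  df_ <- f - fm
  dx <- tracks$x[sel] - xm
  dy <- tracks$y[sel] - ym
  sff_t <- rowsum(df_^2, tid)[, 1]
  if (sum(sff_t) == 0) stop("zero frame spread in qualifying tracks")
  if (robust && length(ok) > 1L) {
    vx_t <- rowsum(df_ * dx, tid)[, 1] / sff_t
    vy_t <- rowsum(df_ * dy, tid)[, 1] / sff_t
    vx <- .weighted_median(vx_t, sff_t)
    vy <- .weighted_median(vy_t, sff_t)
  } else {
    vx <- sum(df_ * dx) / sum(sff_t)
    vy <- sum(df_ * dy) / sum(sff_t)
  }
  npts <- length(df_)
  dof <- max(1L, npts - 2L * length(ok))
  s2x <- sum((dx - vx * df_)^2) / dof
  s2y <- sum((dy - vy * df_)^2) / dof
  sff <- sum(sff_t)
  drift_model(vx, vy, frame0 = 0,
              se_vx = sqrt(s2x / sff), se_vy = sqrt(s2y / sff),
              method = "track_lsq")
}

.weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  unname(x[o][which(cw >= 0.5)[1]])
}

#' Apply (subtract) a linear drift model
#'
#' `x' = x - vx * (frame - frame0)`, likewise for y. The applied model is
#' recorded in the table metadata. Correcting with a negated model undoes
#' the correction.
#'
#' @param table a [loc_table].
#' @param model a [drift_model].
#' @return The corrected [loc_table].
#' @export
apply_drift <- function(table, model) {
  stopifnot(inherits(table, "loc_table"), inherits(model, "drift_model"))
  dt <- table$frame - model$frame0
  out <- table
  out$x <- table$x - model$vx * dt
  out$y <- table$y - model$vy * dt
  md <- loc_metadata(out)
  md$drift_applied <- c(vx = model$vx, vy = model$vy, frame0 = model$frame0)
  loc_metadata(out) <- md
  out
}

#' Localization-precision statistic from tracks
#'
#' For each track the per-axis unbiased sample variance of the deviations
#' from the track-mean coordinate is computed; the per-track value is the
#' pooled standard deviation `sqrt((var_x + var_y)/2)` (or the SD of the
#' Euclidean deviations with `variant = "euclidean"`). The median of the
#' per-track values over all tracks -- pooled across fields of view when
#' several track sets are supplied -- is reported as the localization
#' precision.
#'
#' @param tracks a `"track_set"`, or a list of them (pooled).
#' @param variant `"pooled_axes"` (default) or `"euclidean"`.
#' @param unbiased divisor n-1 (default) or n for the variance.
#' @param breaks histogram breaks passed to [graphics::hist] (default 50
#'   equal bins over the data range).
#' @return A list of class `"precision_estimate"`: `per_track_sd` (nm),
#'   `median_precision` (nm), `histogram` (data.frame bin_left,
#'   bin_right, count), `n_tracks`, `variant`.
#' @export
estimate_precision <- function(tracks, variant = c("pooled_axes", "euclidean"),
                               unbiased = TRUE, breaks = 50) {
  variant <- match.arg(variant)
  if (inherits(tracks, "track_set")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "track_set")))
  per_track <- unlist(lapply(tracks, function(ts) {
    if (nrow(ts) == 0L) return(numeric())
    nt <- attr(ts, "n_tracks")
    n <- tabulate(ts$track, nt)
    sx <- rowsum(ts$x, ts$track)[, 1]
    sy <- rowsum(ts$y, ts$track)[, 1]
    sxx <- rowsum(ts$x^2, ts$track)[, 1]
    syy <- rowsum(ts$y^2, ts$track)[, 1]
    div <- if (unbiased) n - 1 else n
    ssx <- pmax(0, sxx - sx^2 / n)
    ssy <- pmax(0, syy - sy^2 / n)
    if (variant == "pooled_axes") {
      sqrt((ssx / div + ssy / div) / 2)
    } else {
      sqrt((ssx + ssy) / div)
    }
  }))
  if (length(per_track) == 0L) stop("no tracks to estimate precision from")
  h <- graphics::hist(per_track, breaks = breaks, plot = FALSE)
  structure(list(per_track_sd = per_track,
                 median_precision = stats::median(per_track),
                 histogram = data.frame(
                   bin_left = utils::head(h$breaks, -1L),
                   bin_right = h$breaks[-1L],
                   count = h$counts),
                 n_tracks = length(per_track), variant = variant),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "<precision_estimate> median %.2f nm over %d tracks (%s variant)\n",
    x$median_precision, x$n_tracks, x$variant))
  invisible(x)
}

#' Write a precision histogram as CSV (and optionally PNG)
#'
#' @param est a `"precision_estimate"`.
#' @param csv_path output CSV path (bin_left, bin_right, count).
#' @param png_path optional PNG path for a base-graphics histogram.
#' @return `csv_path`, invisibly.
#' @export
write_precision_histogram <- function(est, csv_path, png_path = NULL) {
  stopifnot(inherits(est, "precision_estimate"))
  utils::write.csv(est$histogram, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 450)
    graphics::hist(est$per_track_sd, breaks = 50,
                   main = "Per-track localization precision",
                   xlab = "pooled per-track SD (nm)")
    graphics::abline(v = est$median_precision, col = "red", lwd = 2)
    grDevices::dev.off()
  }
  invisible(csv_path)
}
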