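#' Landmark point matches between two modalities
#'
#' @param x_ref,y_ref coordinates in the fixed (reference) modality, nm.
#' @param x_mov,y_mov coordinates in the moving modality, nm.
#' @param kind `"center_of_mass"` or `"endpoint"` per landmark.
#' @param fiducial_id id of the fiducial each landmark came from.
#' @return A `data.frame` of class `"point_matches"`.
#' @export
point_matches <- function(x_ref, y_ref, x_mov, y_mov,
                          kind = "center_of_mass", fiducial_id = NULL) {
  n <- length(x_ref)
  stopifnot(length(y_ref) == n, length(x_mov) == n, length(y_mov) == n,
            all(is.finite(c(x_ref, y_ref, x_mov, y_mov))))
  structure(data.frame(
    fiducial_id = if (is.null(fiducial_id)) seq_len(n) else fiducial_id,
    kind = rep_len(kind, n),
    x_ref = x_ref, y_ref = y_ref, x_mov = x_mov, y_mov = y_mov),
    class = c("point_matches", "data.frame"))
}

#' Intensity-weighted center of mass within a rectangular ROI
#'
#' @param image a [rendered_image].
#' @param roi `c(xmin, xmax, ymin, ymax)` in nm; pixels whose centers lie
#'   in the ROI contribute. `NULL` uses the whole image.
#' @return `c(x, y)` in nm.
#' @export
fiducial_center_of_mass <- function(image, roi = NULL) {
  stopifnot(inherits(image, "rendered_image"))
  g <- image$grid
  px <- image$pixel_size
  nr <- nrow(g); nc <- ncol(g)
  xc <- image$origin[1] + (seq_len(nc) - 0.5) * px
  yc <- image$origin[2] + (seq_len(nr) - 0.5) * px
  X <- matrix(xc, nr, nc, byrow = TRUE)
  Y <- matrix(yc, nr, nc)
  if (!is.null(roi)) {
    inroi <- X >= roi[1] & X <= roi[2] & Y >= roi[3] & Y <= roi[4]
    if (!any(inroi)) stop("ROI lies outside the image")
    g <- g * inroi
  }
  s <- sum(g)
  if (s <= 0) stop("zero total intensity in ROI")
  c(x = sum(g * X) / s, y = sum(g * Y) / s)
}

#' Endpoints of a rod-shaped fiducial along its principal axis
#'
#' For a single 8-connected rod component, the two pixels with extreme
#' signed projection onto the component's major principal axis are the
#' endpoints, returned with smaller x first (tie: smaller y) so channel
#' pairs match unambiguously. Components with elongation
#' (major/minor axis ratio) below `min_elongation` are rejected as not
#' rod-shaped.
#'
#' @param mask a binary matrix, or a [labeled_mask] with `label`
#'   selecting one component.
#' @param pixel_size,origin geometry (taken from a `labeled_mask`).
#' @param label component to measure when `mask` is a `labeled_mask`.
#' @param min_elongation minimum axis ratio (default 2).
#' @return A 2x2 matrix, rows = endpoints, columns = (x, y) nm.
#' @export
fiducial_endpoints <- function(mask, pixel_size = 1, origin = c(0, 0),
                               label = 1L, min_elongation = 2) {
  if (inherits(mask, "labeled_mask")) {
    bin <- mask$labels == label
    pixel_size <- mask$pixel_size
    origin <- mask$origin
  } else bin <- mask > 0
  idx <- which(bin)
  if (length(idx) < 2L) stop("component too small for endpoint extraction")
  nr <- nrow(bin)
  r <- (idx - 1L) %% nr + 1L
  c_ <- (idx - 1L) %/% nr + 1L
  x <- origin[1] + (c_ - 0.5) * pixel_size
  y <- origin[2] + (r - 0.5) * pixel_size
  vxx <- stats::var(x) * (length(x) - 1) / length(x) + pixel_size^2 / 12
  vyy <- stats::var(y) * (length(y) - 1) / length(y) + pixel_size^2 / 12
  vxy <- stats::cov(x, y) * (length(x) - 1) / length(x)
  tr <- vxx + vyy
  disc <- sqrt(max(0, (tr / 2)^2 - (vxx * vyy - vxy^2)))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  if (sqrt(l1 / l2) < min_elongation)
    stop(sprintf("component elongation %.2f < %g: not a rod",
                 sqrt(l1 / l2), min_elongation))
  theta <- 0.5 * atan2(2 * vxy, vxx - vyy)
  u <- c(cos(theta), sin(theta))
  proj <- (x - mean(x)) * u[1] + (y - mean(y)) * u[2]
  p1 <- c(x[which.min(proj)], y[which.min(proj)])
  p2 <- c(x[which.max(proj)], y[which.max(proj)])
  ends <- rbind(p1, p2)
  o <- order(ends[, 1], ends[, 2])
  ends <- ends[o, , drop = FALSE]
  dimnames(ends) <- list(NULL, c("x", "y"))
  ends
}

#' Fit a 2-D point transform from landmark matches
#'
#' Least-squares fit of the moving-to-reference mapping. `"similarity"`
#' (rotation + isotropic scale + translation) and `"rigid"` (scale locked
#' to 1) have closed-form solutions; `"affine"` is a linear
#' least-squares solve (collinear landmarks raise a conditioning error);
#' `"tps"` is a thin-plate spline with kernel `U(r) = r^2 log r` and
#' optional smoothing `lambda` (0 = exact interpolation; the affine part
#' lives in the spline's null space, so exactly-affine configurations
#' yield near-zero bending energy, and `lambda -> Inf` recovers the
#' affine fit).
#'
#' @param matches a [point_matches] (>= 2 for similarity/rigid, >= 3 for
#'   affine, >= 4 for tps).
#' @param kind `"similarity"`, `"rigid"`, `"affine"` or `"tps"`.
#' @param lambda TPS regularization (default 0).
#' @return A list of class `"transform_model"`: `kind`, `params`
#'   (2x3 matrix `A` with `ref = A %*% c(x, y, 1)` for linear kinds; the
#'   spline coefficients for tps), `matches`, `residuals` (per-landmark
#'   nm), `rms_residual`, and for similarity/rigid `rotation`, `scale`,
#'   `translation`; for tps also `bending_energy`.
#' @export
fit_transform <- function(matches, kind = c("similarity", "rigid",
                                            "affine", "tps"),
                          lambda = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(matches, "point_matches"))
  n <- nrow(matches)
  need <- c(similarity = 2L, rigid = 2L, affine = 3L, tps = 4L)[[kind]]
  if (n < need) stop(kind, " fit needs >= ", need, " matches")
  P <- cbind(matches$x_mov, matches$y_mov)
  Q <- cbind(matches$x_ref, matches$y_ref)
  out <- list(kind = kind, matches = matches, lambda = lambda)
  if (kind %in% c("similarity", "rigid")) {
    mp <- colMeans(P); mq <- colMeans(Q)
    Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
    # complex-number LS: q = a p + t, a = scale * exp(i theta)
    zp <- complex(real = Pc[, 1], imaginary = Pc[, 2])
    zq <- complex(real = Qc[, 1], imaginary = Qc[, 2])
    denom <- sum(Mod(zp)^2)
    if (denom == 0) stop("degenerate geometry: coincident landmarks")
    a <- sum(zq * Conj(zp)) / denom
    if (kind == "rigid") a <- a / Mod(a)
    s <- Mod(a); th <- Arg(a)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    A2 <- s * R
    t_ <- mq - A2 %*% mp
    out$params <- cbind(A2, t_)
    out$rotation <- th; out$scale <- s; out$translation <- as.numeric(t_)
  } else if (kind == "affine") {
    X <- cbind(P, 1)
    sv <- svd(X)$d
    if (sv[3] < max(sv) * 1e-10)
      stop("degenerate geometry: collinear landmarks for affine fit")
    B <- qr.solve(X, Q)             # 3 x 2
    out$params <- t(B)              # 2 x 3
  } else {                          # thin-plate spline
    K <- .tps_kernel(P, P)
    Pm <- cbind(1, P)
    L <- rbind(cbind(K + lambda * diag(n), Pm),
               cbind(t(Pm), matrix(0, 3, 3)))
    rhs <- rbind(Q, matrix(0, 3, 2))
    coefs <- tryCatch(qr.solve(L, rhs, tol = 1e-12),
                      error = function(e)
                        stop("degenerate TPS geometry: ", conditionMessage(e)))
    W <- coefs[seq_len(n), , drop = FALSE]
    Aff <- coefs[n + 1:3, , drop = FALSE]
    out$params <- list(W = W, affine = Aff, centers = P)
    out$bending_energy <- sum(diag(t(W) %*% K %*% W))
  }
  cls <- structure(out, class = "transform_model")
  pred <- apply_transform(Q0 <- P, cls)
  res <- sqrt(rowSums((pred - Q)^2))
  cls$residuals <- res
  cls$rms_residual <- sqrt(mean(res^2))
  cls
}

.tps_kernel <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  k <- matrix(0, nrow(A), nrow(B))
  nz <- d2 > 0
  k[nz] <- d2[nz] * log(sqrt(d2[nz]))
  k
}

#' @export
print.transform_model <- function(x, ...) {
  cat(sprintf("<transform_model> %s, %d landmarks, RMS residual %.3g nm\n",
              x$kind, nrow(x$matches), x$rms_residual))
  if (x$kind %in% c("similarity", "rigid"))
    cat(sprintf("  rotation %.4f rad, scale %.6f, translation (%.2f, %.2f)\n",
                x$rotation, x$scale, x$translation[1], x$translation[2]))
  if (x$kind == "tps")
    cat(sprintf("  bending energy %.4g (lambda = %g)\n",
                x$bending_energy, x$lambda))
  invisible(x)
}

#' Apply a fitted transform to points or resample an image
#'
#' Points (n x 2 matrix or data.frame with x, y) map exactly. A
#' [rendered_image] is resampled onto the reference grid by inverse
#' mapping with bilinear interpolation; for TPS the inverse is
#' approximated by a spline fitted on the swapped landmarks.
#'
#' @param x points or a [rendered_image].
#' @param model a `"transform_model"`.
#' @param out_geometry for images: list(pixel_size, origin, dim) of the
#'   output grid; default keeps the input geometry.
#' @return Mapped points (same shape as input) or a resampled
#'   [rendered_image].
#' @export
apply_transform <- function(x, model, out_geometry = NULL) {
  stopifnot(inherits(model, "transform_model"))
  if (inherits(x, "rendered_image"))
    return(.warp_image(x, model, out_geometry))
  isdf <- is.data.frame(x)
  P <- if (isdf) cbind(x$x, x$y) else {
    if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
  }
  out <- if (model$kind == "tps") {
    K <- .tps_kernel(P, model$params$centers)
    cbind(1, P) %*% model$params$affine + K %*% model$params$W
  } else {
    t(model$params %*% t(cbind(P, 1)))
  }
  if (isdf) {
    x$x <- out[, 1]; x$y <- out[, 2]
    x
  } else out
}

#' Invert a transform model
#'
#' Exact for similarity, rigid and affine; for TPS the inverse is a
#' spline refitted on the swapped landmark roles (an approximation, as
#' TPS has no closed-form inverse).
#' @param model a `"transform_model"`.
#' @return A `"transform_model"` mapping the other way.
#' @export
invert_transform <- function(model) {
  stopifnot(inherits(model, "transform_model"))
  m <- model$matches
  swapped <- point_matches(m$x_mov, m$y_mov, m$x_ref, m$y_ref,
                           kind = m$kind, fiducial_id = m$fiducial_id)
  if (model$kind == "tps")
    return(fit_transform(swapped, "tps", lambda = model$lambda))
  A <- model$params[, 1:2]
  t_ <- model$params[, 3]
  Ai <- solve(A)
  out <- model
  out$params <- cbind(Ai, -Ai %*% t_)
  out$matches <- swapped
  if (model$kind %in% c("similarity", "rigid")) {
    out$rotation <- -model$rotation
    out$scale <- 1 / model$scale
    out$translation <- as.numeric(-Ai %*% t_)
  }
  out
}

.warp_image <- function(img, model, out_geometry = NULL) {
  px <- out_geometry$pixel_size %||% img$pixel_size
  org <- out_geometry$origin %||% img$origin
  dm <- out_geometry$dim %||% dim(img$grid)
  inv <- invert_transform(model)
  nr <- dm[1]; nc <- dm[2]
  xc <- org[1] + (seq_len(nc) - 0.5) * px
  yc <- org[2] + (seq_len(nr) - 0.5) * px
  pts <- cbind(rep(xc, each = nr), rep(yc, nc))
  src <- apply_transform(pts, inv)
  # source position in input pixel index space (center of px i at i - 0.5)
  fi <- (src[, 2] - img$origin[2]) / img$pixel_size + 0.5
  fj <- (src[, 1] - img$origin[1]) / img$pixel_size + 0.5
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  g <- img$grid
  val <- function(i, j) {
    ok <- i >= 1 & i <= nrow(g) & j >= 1 & j <= ncol(g)
    v <- numeric(length(i))
    v[ok] <- g[cbind(i[ok], j[ok])]
    v
  }
  v <- (1 - wi) * (1 - wj) * val(i0, j0) +
       (1 - wi) * wj       * val(i0, j0 + 1) +
       wi       * (1 - wj) * val(i0 + 1, j0) +
       wi       * wj       * val(i0 + 1, j0 + 1)
  rendered_image(matrix(pmax(0, v), nr, nc), px, org)
}

#' Overlay-precision report from aligned landmarks
#'
#' Residual Euclidean distances between reference landmarks and aligned
#' moving landmarks quantify how well two channels or modalities overlay.
#' With `loo = TRUE` (default) each fiducial is scored by a fit on the
#' remaining fiducials (leave-one-out), so the precision is measured on
#' landmarks not used for the alignment; `loo = FALSE` scores in-sample
#' residuals of `model`. Reported as mean +/- SD and median +/- MAD (raw
#' median absolute deviation, no consistency constant).
#'
#' @param matches a [point_matches].
#' @param model optional prefitted `"transform_model"` (required when
#'   `loo = FALSE`).
#' @param kind transform kind for leave-one-out refits.
#' @param loo leave-one-out evaluation (default TRUE).
#' @param label channel-pair label carried into the report.
#' @return A list of class `"overlay_report"`: `distances` (nm), `mean`,
#'   `sd`, `median`, `mad`, `n_fiducials`, `label`, `mode`.
#' @export
overlay_precision <- function(matches, model = NULL, kind = "similarity",
                              loo = TRUE, label = "") {
  stopifnot(inherits(matches, "point_matches"), nrow(matches) >= 1L)
  if (loo) {
    n <- nrow(matches)
    if (n < 3L) stop("leave-one-out needs >= 3 matches")
    d <- vapply(seq_len(n), function(i) {
      fit <- fit_transform(matches[-i, , drop = FALSE], kind = kind)
      p <- apply_transform(cbind(matches$x_mov[i], matches$y_mov[i]), fit)
      sqrt((p[1] - matches$x_ref[i])^2 + (p[2] - matches$y_ref[i])^2)
    }, numeric(1))
    mode <- "leave_one_out"
  } else {
    if (is.null(model)) stop("supply a fitted model for in-sample mode")
    p <- apply_transform(cbind(matches$x_mov, matches$y_mov), model)
    d <- sqrt((p[, 1] - matches$x_ref)^2 + (p[, 2] - matches$y_ref)^2)
    mode <- "in_sample"
  }
  structure(list(distances = d, mean = mean(d), sd = stats::sd(d),
                 median = stats::median(d),
                 mad = stats::mad(d, constant = 1),
                 n_fiducials = length(unique(matches$fiducial_id)),
                 label = label, mode = mode),
            class = "overlay_report")
}

#' @export
print.overlay_report <- function(x, ...) {
  cat(sprintf("<overlay_report> %s (%s, %d fiducials, %d landmarks)\n",
              x$label, x$mode, x$n_fiducials, length(x$distances)))
  cat(sprintf("  %.1f +/- %.1f nm (mean +/- SD); %.1f +/- %.1f nm (median +/- MAD)\n",
              x$mean, x$sd, x$median, x$mad))
  invisible(x)
}

#' Serialize / restore a transform model as JSON
#' @param model a `"transform_model"`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(model, path) {
  stopifnot(inherits(model, "transform_model"))
  obj <- list(kind = model$kind, rms_residual = model$rms_residual,
              lambda = model$lambda)
  if (model$kind == "tps") {
    obj$W <- model$params$W
    obj$affine <- model$params$affine
    obj$centers <- model$params$centers
    obj$bending_energy <- model$bending_energy
  } else {
    obj$matrix <- model$params
    if (!is.null(model$scale)) {
      obj$rotation <- model$rotation
      obj$scale <- model$scale
      obj$translation <- model$translation
    }
  }
  obj$landmarks <- as.data.frame(model$matches)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write landmark matches as CSV
#' @param matches a [point_matches]; `path` output file.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(matches, path) {
  utils::write.csv(as.data.frame(matches), path, row.names = FALSE)
  invisible(path)
}
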