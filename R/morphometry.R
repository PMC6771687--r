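#' IsoData (iterative intermeans) automatic threshold
#'
#' Computes the classic IsoData threshold on an `n_bins` histogram of the
#' image: starting from the overall mean, iterate
#' `T <- (mean(values <= T) + mean(values > T)) / 2` until a fixed point.
#' The threshold is returned in image-intensity units and is equivariant
#' under affine intensity rescaling to within one bin width.
#'
#' @param image a [rendered_image] or a numeric matrix/vector.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold (numeric scalar), with the histogram bin width
#'   in attribute `bin_width`.
#' @export
isodata_threshold <- function(image, n_bins = 256) {
  v <- if (inherits(image, "rendered_image")) as.vector(image$grid)
       else as.vector(image)
  rng <- range(v)
  if (!(rng[2] > rng[1]))
    stop("constant image: IsoData threshold undefined")
  bw <- (rng[2] - rng[1]) / n_bins
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  bin <- pmin(n_bins, pmax(1L, 1L + floor((v - rng[1]) / bw)))
  w <- tabulate(bin, n_bins)
  cw <- cumsum(w)
  cwx <- cumsum(w * centers)
  total_w <- cw[n_bins]
  total_wx <- cwx[n_bins]
  t_old <- -Inf
  t_new <- sum(v) / length(v)
  iter <- 0L
  while (abs(t_new - t_old) > bw * 1e-9 && iter < 1000L) {
    t_old <- t_new
    # bins with center <= threshold count as "below"
    k <- findInterval(t_old, centers)
    if (k < 1L) k <- 1L
    if (k >= n_bins) k <- n_bins - 1L
    wb <- cw[k]; wa <- total_w - wb
    if (wb == 0 || wa == 0) break
    mu_b <- cwx[k] / wb
    mu_a <- (total_wx - cwx[k]) / wa
    t_new <- (mu_b + mu_a) / 2
    iter <- iter + 1L
  }
  structure(t_new, bin_width = bw)
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged through an igraph
# components pass.
.label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  edges <- NULL
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]       # down-right diagonal
  s <- a1 > 0L & b1 > 0L & a1 != b1
  if (any(s)) edges <- cbind(a1[s], b1[s])
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]       # down-left diagonal
  s <- a2 > 0L & b2 > 0L & a2 != b2
  if (any(s)) edges <- rbind(edges, cbind(a2[s], b2[s]))
  if (is.null(edges)) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  map <- c(0L, as.integer(comp[seq_len(k)]))
  matrix(map[lab + 1L], nr, nc)
}

#' Labeled particle mask
#'
#' Integer matrix of particle labels (0 = background) sharing the
#' geometry of the image it was segmented from.
#' @param labels integer matrix; `pixel_size` nm/px; `origin` nm;
#'   `threshold` the intensity threshold used (or `NA`).
#' @return A list of class `"labeled_mask"`.
#' @export
labeled_mask <- function(labels, pixel_size, origin = c(0, 0),
                         threshold = NA_real_) {
  stopifnot(is.matrix(labels))
  structure(list(labels = matrix(as.integer(labels), nrow(labels),
                                 ncol(labels)),
                 pixel_size = pixel_size, origin = as.numeric(origin),
                 threshold = threshold, n = max(labels)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d particles in %d x %d px (%g nm/px)\n",
              x$n, nrow(x$labels), ncol(x$labels), x$pixel_size))
  invisible(x)
}

#' Segment structures: blur, IsoData, fill holes, label, area floor
#'
#' The image-domain particle-analysis front end: Gaussian blur (sigma =
#' `blur_sigma` pixels), IsoData auto-threshold, binarize at `>=
#' threshold`, optionally fill enclosed holes (background regions not
#' connected to the image border), label 8-connected components, and
#' drop components below `min_area` pixels.
#'
#' @param image a [rendered_image].
#' @param blur_sigma Gaussian sigma in rendered pixels (default 2;
#'   0 disables blurring).
#' @param min_area minimum component area in pixels^2 (default 4).
#' @param max_area maximum component area in pixels^2 (default `Inf`);
#'   an upper size window excludes objects that are not the structures
#'   under study (e.g. rod fiducials in a nanodomain mask).
#' @param fill_holes include enclosed holes in particles (default TRUE).
#' @param threshold optional explicit threshold overriding IsoData.
#' @param n_bins histogram bins for IsoData (default 256).
#' @return A [labeled_mask]; attribute `blurred` holds the blurred
#'   [rendered_image] the threshold was computed on.
#' @export
segment_structures <- function(image, blur_sigma = 2, min_area = 4,
                               fill_holes = TRUE, threshold = NULL,
                               n_bins = 256, max_area = Inf) {
  stopifnot(inherits(image, "rendered_image"), blur_sigma >= 0)
  g <- image$grid
  if (blur_sigma > 0) {
    # EBImage kernel must fit in the image; pad small images with zeros
    ksize <- 2L * ceiling(3 * blur_sigma) + 1L
    pad <- max(0L, ksize - min(dim(g)))
    if (pad > 0L) {
      gp <- matrix(0, nrow(g) + 2L * pad, ncol(g) + 2L * pad)
      gp[pad + seq_len(nrow(g)), pad + seq_len(ncol(g))] <- g
      gb <- EBImage::gblur(gp, sigma = blur_sigma, boundary = 0)
      g <- gb[pad + seq_len(nrow(g)), pad + seq_len(ncol(g))]
    } else {
      g <- EBImage::gblur(g, sigma = blur_sigma, boundary = 0)
    }
    # filter2 is FFT-based and can leave tiny negative ripples
    g <- matrix(pmax(as.numeric(g), 0), nrow(image$grid), ncol(image$grid))
  }
  thr <- if (is.null(threshold)) as.numeric(isodata_threshold(g, n_bins))
         else threshold
  bin <- (g >= thr) * 1
  if (fill_holes && any(bin > 0))
    bin <- matrix(as.numeric(EBImage::fillHull(bin)), nrow(bin), ncol(bin))
  lab <- .label8(bin)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], max(lab))
    keep <- which(areas >= min_area & areas <= max_area)
    map <- integer(max(lab) + 1L)
    map[keep + 1L] <- seq_along(keep)
    lab <- matrix(map[lab + 1L], nrow(lab), ncol(lab))
  }
  out <- labeled_mask(lab, image$pixel_size, image$origin, threshold = thr)
  attr(out, "blurred") <- rendered_image(g, image$pixel_size, image$origin)
  out
}

# per-component pixel moments; returns list with centroids (nm),
# covariance of pixel centers (px^2, +1/12 pixel-extent term on the
# diagonal), areas (px)
.component_moments <- function(mask) {
  lab <- mask$labels
  idx <- which(lab > 0L)
  l <- lab[idx]
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr + 1L
  c_ <- (idx - 1L) %/% nr + 1L
  n <- tabulate(l, mask$n)
  sr <- rowsum(as.numeric(r), l)[, 1]
  sc <- rowsum(as.numeric(c_), l)[, 1]
  srr <- rowsum(as.numeric(r)^2, l)[, 1]
  scc <- rowsum(as.numeric(c_)^2, l)[, 1]
  src <- rowsum(as.numeric(r) * c_, l)[, 1]
  mr <- sr / n; mc <- sc / n
  vrr <- srr / n - mr^2 + 1 / 12
  vcc <- scc / n - mc^2 + 1 / 12
  vrc <- src / n - mr * mc
  list(n = n, row = mr, col = mc, vrr = vrr, vcc = vcc, vrc = vrc)
}

#' Measure labeled particles: area, centroid, moment ellipse, diameter
#'
#' Per component: area = pixel count x pixel_size^2; intensity-free
#' centroid; an ellipse whose axis ratio comes from the eigenvalues of
#' the second-central-moment matrix of the pixel centers (with the 1/12
#' pixel-extent term on the diagonal) and whose size is rescaled so the
#' ellipse area equals the component area ("area-matched" convention).
#' The reported diameter is the mean of major and minor axis; both axes
#' are exported so a different convention can be chosen downstream.
#'
#' @param mask a [labeled_mask].
#' @return A `data.frame` of class `"domain_records"`: `label, area_px,
#'   area (nm^2), cx, cy (nm), major_axis, minor_axis, diameter (nm),
#'   orientation (radians, axis angle from +x)`.
#' @export
measure_domains <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (mask$n == 0L)
    return(structure(data.frame(label = integer(), area_px = integer(),
                                area = numeric(), cx = numeric(),
                                cy = numeric(), major_axis = numeric(),
                                minor_axis = numeric(), diameter = numeric(),
                                orientation = numeric()),
                     class = c("domain_records", "data.frame")))
  mom <- .component_moments(mask)
  px <- mask$pixel_size
  # eigenvalues of [[vcc, vrc], [vrc, vrr]] (x = col, y = row)
  tr <- mom$vcc + mom$vrr
  dt <- mom$vcc * mom$vrr - mom$vrc^2
  disc <- sqrt(pmax(0, (tr / 2)^2 - dt))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 1e-12)
  ratio <- sqrt(l1 / l2)
  area_nm <- mom$n * px^2
  b <- sqrt(area_nm / (pi * ratio))   # semi-minor, nm
  a <- ratio * b                      # semi-major, nm
  theta <- 0.5 * atan2(2 * mom$vrc, mom$vcc - mom$vrr)
  structure(data.frame(
    label = seq_len(mask$n),
    area_px = mom$n,
    area = area_nm,
    cx = mask$origin[1] + (mom$col - 0.5) * px,
    cy = mask$origin[2] + (mom$row - 0.5) * px,
    major_axis = 2 * a,
    minor_axis = 2 * b,
    diameter = a + b,
    orientation = theta),
    class = c("domain_records", "data.frame"))
}

#' Correct particle diameters for analysis broadening
#'
#' Sizes measured by thresholding a blurred rendering are systematically
#' inflated: the Gaussian analysis blur, the localization error and the
#' render-pixel quantization all convolve into the apparent object. As
#' widths of convolved profiles add approximately in quadrature, the
#' corrected diameter is
#' `sqrt(max(d^2 - (2.355 * sigma_eff)^2, 0))` with
#' `sigma_eff^2 = (blur_sigma * pixel_size)^2 + pixel_size^2 / 12 +
#' loc_sigma^2` (2.355 converts an SD to a FWHM-scale width, the scale on
#' which the threshold contour sits). Axes are corrected the same way.
#' The uncorrected values stay in place; corrected ones are added as
#' `diameter_corrected`, `major_axis_corrected`, `minor_axis_corrected`.
#'
#' @param domains a `"domain_records"` from [measure_domains].
#' @param blur_sigma Gaussian blur sigma used in segmentation, in
#'   rendered pixels.
#' @param pixel_size rendered pixel size in nm.
#' @param loc_sigma localization precision SD in nm (0 to ignore).
#' @return The records with corrected-size columns appended.
#' @export
correct_broadening <- function(domains, blur_sigma, pixel_size,
                               loc_sigma = 0) {
  stopifnot(inherits(domains, "domain_records"))
  sig2 <- (blur_sigma * pixel_size)^2 + pixel_size^2 / 12 + loc_sigma^2
  w2 <- (2 * sqrt(2 * log(2)))^2 * sig2
  corr <- function(d) sqrt(pmax(d^2 - w2, 0))
  domains$diameter_corrected <- corr(domains$diameter)
  domains$major_axis_corrected <- corr(domains$major_axis)
  domains$minor_axis_corrected <- corr(domains$minor_axis)
  domains
}

#' Per-endosome domain statistics and morphometry summary
#'
#' Assigns each measured nanodomain to the endosome (connected component
#' of the combined-channel mask) containing its centroid; a centroid on
#' background snaps to the nearest endosome within `snap_radius_px`
#' pixels, else the domain is flagged unassigned and excluded (count in
#' attribute `n_unassigned`). Per endosome the covered area is the union
#' of member-domain pixels intersected with the endosome component, so
#' the coverage fraction stays in [0, 1].
#'
#' @param endosome_mask [labeled_mask] of the combined-signal endosome
#'   proxy.
#' @param domains `"domain_records"` measured from `domain_mask`.
#' @param domain_mask [labeled_mask] of the nanodomain channel.
#' @param snap_radius_px snap radius in pixels (default 5).
#' @return A list of class `"morphometry"`: `endosomes` (data.frame
#'   `endosome, endosome_area, domain_count, rab5_covered_area,
#'   coverage_fraction, domain_ids`), `domains` (the input records plus
#'   `endosome` assignment), and `summary` (a `"morphometry_summary"`:
#'   n_endosomes, mean/SD of domain count and diameter, singleton-subset
#'   diameter mean/SD, OLS fits of covered area vs count and count vs
#'   endosome area).
#' @export
endosome_domain_stats <- function(endosome_mask, domains, domain_mask,
                                  snap_radius_px = 5) {
  stopifnot(inherits(endosome_mask, "labeled_mask"),
            inherits(domain_mask, "labeled_mask"),
            inherits(domains, "domain_records"))
  E <- endosome_mask$labels
  px <- endosome_mask$pixel_size
  if (!identical(dim(E), dim(domain_mask$labels)))
    stop("masks have mismatched geometry")
  nr <- nrow(E); nc <- ncol(E)
  # centroid -> pixel -> endosome label
  ci <- pmin(nr, pmax(1L, 1L + floor((domains$cy - endosome_mask$origin[2]) / px)))
  cj <- pmin(nc, pmax(1L, 1L + floor((domains$cx - endosome_mask$origin[1]) / px)))
  assign_ <- E[cbind(ci, cj)]
  # snap unassigned centroids to the nearest endosome pixel in a window
  miss <- which(assign_ == 0L)
  for (m in miss) {
    r0 <- max(1L, ci[m] - snap_radius_px); r1 <- min(nr, ci[m] + snap_radius_px)
    c0 <- max(1L, cj[m] - snap_radius_px); c1 <- min(nc, cj[m] + snap_radius_px)
    win <- E[r0:r1, c0:c1, drop = FALSE]
    cand <- which(win > 0L)
    if (length(cand) == 0L) next
    wr <- (cand - 1L) %% nrow(win) + r0
    wc <- (cand - 1L) %/% nrow(win) + c0
    d2 <- (wr - ci[m])^2 + (wc - cj[m])^2
    best <- cand[which.min(d2)]
    if (min(d2) <= snap_radius_px^2) assign_[m] <- win[best]
  }
  domains$endosome <- assign_
  n_unassigned <- sum(assign_ == 0L)
  ne <- endosome_mask$n
  endo_area_px <- tabulate(E[E > 0L], ne)
  # covered pixels: domain-mask pixels whose domain is assigned to the
  # endosome component the pixel lies in
  R <- domain_mask$labels
  idx <- which(R > 0L & E > 0L)
  cov_px <- rep(0L, ne)
  if (length(idx) > 0L) {
    same <- assign_[R[idx]] == E[idx]
    if (any(same)) {
      tb <- table(E[idx][same])
      cov_px[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  cnt <- tabulate(domains$endosome[domains$endosome > 0L], ne)
  endosomes <- data.frame(
    endosome = seq_len(ne),
    endosome_area = endo_area_px * px^2,
    domain_count = cnt,
    rab5_covered_area = cov_px * px^2,
    coverage_fraction = ifelse(endo_area_px > 0,
                               cov_px / endo_area_px, 0),
    domain_ids = I(lapply(seq_len(ne), function(e)
      domains$label[domains$endosome == e])))
  summary <- .morphometry_summary(endosomes, domains)
  structure(list(endosomes = endosomes, domains = domains,
                 summary = summary),
            n_unassigned = n_unassigned, class = "morphometry")
}

.ols_fit <- function(x, y) {
  if (length(x) < 2L || stats::var(x) == 0)
    return(c(slope = NA_real_, intercept = NA_real_, r = NA_real_))
  fit <- stats::lm(y ~ x)
  c(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = if (stats::var(y) > 0) stats::cor(x, y) else NA_real_)
}

.morphometry_summary <- function(endosomes, domains) {
  with_dom <- endosomes[endosomes$domain_count > 0L, , drop = FALSE]
  assigned <- domains[domains$endosome > 0L, , drop = FALSE]
  singleton_endo <- with_dom$endosome[with_dom$domain_count == 1L]
  singleton <- assigned[assigned$endosome %in% singleton_endo, , drop = FALSE]
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(
    n_endosomes = nrow(with_dom),
    n_domains = nrow(assigned),
    domain_count_mean = mean(with_dom$domain_count),
    domain_count_sd = sd0(with_dom$domain_count),
    diameter_mean = mean(assigned$diameter),
    diameter_sd = sd0(assigned$diameter),
    singleton_n = nrow(singleton),
    singleton_diameter_mean = if (nrow(singleton)) mean(singleton$diameter)
                              else NA_real_,
    singleton_diameter_sd = if (nrow(singleton) > 1)
      stats::sd(singleton$diameter) else NA_real_,
    fit_area_vs_count = .ols_fit(with_dom$domain_count,
                                 with_dom$rab5_covered_area),
    fit_count_vs_area = .ols_fit(with_dom$endosome_area,
                                 with_dom$domain_count)),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("<morphometry_summary> %d endosomes, %d domains\n",
              x$n_endosomes, x$n_domains))
  cat(sprintf("  domains/endosome: %.1f +/- %.1f (mean +/- SD)\n",
              x$domain_count_mean, x$domain_count_sd))
  cat(sprintf("  domain diameter : %.1f +/- %.1f nm\n",
              x$diameter_mean, x$diameter_sd))
  if (x$singleton_n > 0)
    cat(sprintf("  singleton domains: n = %d, diameter %.1f +/- %.1f nm\n",
                x$singleton_n, x$singleton_diameter_mean,
                x$singleton_diameter_sd))
  f <- x$fit_area_vs_count
  cat(sprintf("  covered area vs count: slope %.0f nm^2/domain, r = %.3f\n",
              f[["slope"]], f[["r"]]))
  invisible(x)
}

#' @export
print.morphometry <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
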