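#' Rendering specification
#'
#' @param pixel_size rendered pixel size in nm (default 10).
#' @param xlim,ylim field extent in nm, `c(min, max)`; when `NULL` the
#'   extent is taken from the data, expanded to whole pixels.
#' @return A list of class `"render_spec"`.
#' @export
render_spec <- function(pixel_size = 10, xlim = NULL, ylim = NULL) {
  stopifnot(pixel_size > 0)
  chk <- function(l) {
    if (!is.null(l) && (length(l) != 2L || !(l[2] > l[1])))
      stop("degenerate field extent")
  }
  chk(xlim); chk(ylim)
  structure(list(pixel_size = pixel_size, xlim = xlim, ylim = ylim),
            class = "render_spec")
}

#' Rendered super-resolution image
#'
#' A 2-D intensity grid at fixed nm/pixel. `grid[i, j]` is the pixel in
#' row i (y, increasing downward) and column j (x); pixel (1,1) covers
#' the half-open square `[origin, origin + pixel_size)`.
#'
#' @param grid numeric matrix of non-negative intensities.
#' @param pixel_size nm per pixel.
#' @param origin nm offset `c(x0, y0)` of the upper-left pixel corner.
#' @return A list of class `"rendered_image"`.
#' @export
rendered_image <- function(grid, pixel_size, origin = c(0, 0)) {
  stopifnot(is.matrix(grid), pixel_size > 0, length(origin) == 2L)
  if (any(grid < 0)) stop("negative intensities")
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf(
    "<rendered_image> %d x %d px at %g nm/px, origin (%g, %g) nm, sum %g\n",
    nrow(x$grid), ncol(x$grid), x$pixel_size, x$origin[1], x$origin[2],
    sum(x$grid)))
  invisible(x)
}

#' Render a localization table as a 2-D count histogram
#'
#' Each in-field localization increments exactly one pixel, by floor
#' binning of `(coord - origin) / pixel_size`; a localization exactly on
#' an interior pixel boundary therefore lands in the higher-index pixel.
#' The grid sum equals the number of in-field localizations; the number
#' falling outside the field is recorded in attribute `n_out_of_field`.
#'
#' @param table a [loc_table].
#' @param spec a [render_spec].
#' @return A [rendered_image] of counts.
#' @export
render_histogram <- function(table, spec = render_spec()) {
  stopifnot(inherits(table, "loc_table"), inherits(spec, "render_spec"))
  px <- spec$pixel_size
  xlim <- spec$xlim %||% if (nrow(table) > 0L)
    c(floor(min(table$x) / px) * px, (floor(max(table$x) / px) + 1) * px)
  else c(0, px)
  ylim <- spec$ylim %||% if (nrow(table) > 0L)
    c(floor(min(table$y) / px) * px, (floor(max(table$y) / px) + 1) * px)
  else c(0, px)
  if (!(xlim[2] > xlim[1]) || !(ylim[2] > ylim[1]))
    stop("degenerate field extent")
  nx <- as.integer(ceiling((xlim[2] - xlim[1]) / px - 1e-9))
  ny <- as.integer(ceiling((ylim[2] - ylim[1]) / px - 1e-9))
  ix <- floor((table$x - xlim[1]) / px)
  iy <- floor((table$y - ylim[1]) / px)
  infield <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  idx <- iy[infield] * nx + ix[infield] + 1
  counts <- tabulate(idx, nbins = nx * ny)
  grid <- matrix(counts, nrow = ny, ncol = nx, byrow = TRUE)
  img <- rendered_image(grid, px, origin = c(xlim[1], ylim[1]))
  attr(img, "n_out_of_field") <- sum(!infield)
  img
}

# clipped 3x3 box sum via a zero-padded summed-area table
.box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  s <- apply(p, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  z <- matrix(0, nr + 3L, nc + 3L)
  z[2:(nr + 3L), 2:(nc + 3L)] <- s
  # window rows i-1..i+1 in padded coords = rows i..i+2 of p
  z[4:(nr + 3L), 4:(nc + 3L)] - z[4:(nr + 3L), 1:nc] -
    z[1:nr, 4:(nc + 3L)] + z[1:nr, 1:nc]
}

#' Median-filter a rendered image (0-1 pixel radius)
#'
#' Post-localization median filtering suppresses the sparse signal of
#' monomeric cytosolic molecules: isolated bright pixels vanish while
#' dense structures survive. Radius 0 is the identity; radius 1 replaces
#' each pixel by the median of its 3x3 neighbourhood, with edge pixels
#' using only the in-image part of the neighbourhood (even-sized
#' neighbourhoods take the mean of the two middle order statistics, as
#' [stats::median] does).
#'
#' @param image a [rendered_image].
#' @param radius 0 or 1 (the supported post-localization range).
#' @return The filtered [rendered_image].
#' @export
median_filter_image <- function(image, radius = 1) {
  stopifnot(inherits(image, "rendered_image"))
  if (!(radius %in% c(0, 1)))
    stop("radius must be 0 or 1")
  if (radius == 0) return(image)
  m <- image$grid
  vals <- sort(unique(as.vector(m)))
  nn <- .box3(matrix(1, nrow(m), ncol(m)))   # in-image neighbourhood size
  k1 <- floor((nn + 1) / 2)                  # lower middle order statistic
  k2 <- ceiling((nn + 1) / 2)                # upper middle order statistic
  os1 <- matrix(NA_real_, nrow(m), ncol(m))
  os2 <- os1
  for (v in vals) {
    cnt <- .box3((m <= v) * 1)
    os1[is.na(os1) & cnt >= k1] <- v
    os2[is.na(os2) & cnt >= k2] <- v
  }
  rendered_image((os1 + os2) / 2, image$pixel_size, image$origin)
}

#' Combine channels into an endosome-area proxy image
#'
#' Each channel is max-normalized to [0, 1] and the pixel-wise maximum is
#' taken, so no channel's dynamic range dominates the combined mask. The
#' operation is commutative and idempotent on normalized inputs.
#'
#' @param images a list of [rendered_image] with identical pixel size,
#'   origin and shape.
#' @return A [rendered_image] with values in [0, 1].
#' @export
combine_channels <- function(images) {
  stopifnot(is.list(images), length(images) >= 1L,
            all(vapply(images, inherits, logical(1), "rendered_image")))
  ref <- images[[1]]
  for (im in images[-1]) {
    if (!identical(dim(im$grid), dim(ref$grid)) ||
        im$pixel_size != ref$pixel_size ||
        !isTRUE(all.equal(im$origin, ref$origin)))
      stop("channel images have mismatched geometry")
  }
  norm <- lapply(images, function(im) {
    mx <- max(im$grid)
    if (mx > 0) im$grid / mx else im$grid
  })
  rendered_image(Reduce(pmax, norm), ref$pixel_size, ref$origin)
}

#' Write a rendered image or label mask as TIFF
#'
#' Images are written as 16-bit TIFF with intensities scaled to the full
#' range; the scale factor, pixel size and origin go to a JSON sidecar
#' (`<path>.json`) so values round-trip losslessly for integer counts and
#' labels.
#'
#' @param image a [rendered_image] or `"labeled_mask"`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (inherits(image, "labeled_mask")) {
    grid <- image$labels
    kind <- "labels"
  } else if (inherits(image, "rendered_image")) {
    grid <- image$grid
    kind <- "intensity"
  } else stop("unsupported image class")
  mx <- max(grid)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(grid / scale, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(kind = kind, scale = scale, pixel_size = image$pixel_size,
         origin = image$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a TIFF written by [write_image_tiff]
#'
#' @param path the `.tif` path (expects the `.json` sidecar next to it).
#' @return A [rendered_image] or `"labeled_mask"`.
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- meta$scale * tiff::readTIFF(path)
  if (identical(meta$kind, "labels")) {
    structure(list(labels = matrix(as.integer(round(m)), nrow(m), ncol(m)),
                   pixel_size = meta$pixel_size, origin = meta$origin,
                   n = max(round(m))),
              class = "labeled_mask")
  } else {
    rendered_image(m, meta$pixel_size, meta$origin)
  }
}
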