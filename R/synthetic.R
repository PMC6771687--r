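#' Distribution specification for scene parameters
#'
#' Small declarative spec used by the scene generator: `"fixed"` (value),
#' `"uniform"` (min, max), `"poisson"` (lambda, optional min),
#' `"normal"` (mean, sd) and `"lognormal"` (mean, sd on the natural
#' scale, converted internally to meanlog/sdlog).
#'
#' @param dist distribution name.
#' @param ... parameters (see above).
#' @return A list of class `"dist_spec"`.
#' @export
dist_spec <- function(dist = c("fixed", "uniform", "poisson", "normal",
                               "lognormal"), ...) {
  dist <- match.arg(dist)
  structure(c(list(dist = dist), list(...)), class = "dist_spec")
}

#' @rdname dist_spec
#' @param spec a `dist_spec`; `n` number of draws.
#' @return `sample_dist`: `n` numeric draws.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$dist,
    fixed = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    poisson = {
      x <- stats::rpois(n, spec$lambda)
      if (!is.null(spec$min)) x <- pmax(x, spec$min)
      x
    },
    normal = stats::rnorm(n, spec$mean, spec$sd),
    lognormal = {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, log(spec$mean) - s2 / 2, sqrt(s2))
    })
}

#' Scene specification for the synthetic-endosome generator
#'
#' Defines the geometry regime the simulator emulates: endosomes as
#' circles whose limiting membrane carries nanodomains (discs centred on
#' the contour), tubules as line segments leaving the membrane, a diffuse
#' luminal cargo signal, uniform cytosolic background, and rod-shaped
#' broadband fiducials (bacteria surrogates) visible in all channels.
#' Defaults follow the regime the morphometry targets: ~5 domains per
#' endosome with a mean diameter of 55 nm.
#'
#' @param field_size field extent `c(wx, wy)` in nm.
#' @param n_endosomes number of endosomes.
#' @param endosome_radius radius range `c(min, max)` nm; when a sampled
#'   domain complement needs more membrane than the sampled radius
#'   offers, the radius is raised to fit (larger endosomes carry more
#'   domains).
#' @param domains_per_endosome a [dist_spec] for the per-endosome domain
#'   count (default Poisson lambda 4.9, min 1).
#' @param domain_diameter a [dist_spec] for domain diameters in nm
#'   (default lognormal mean 55, sd 15).
#' @param domain_gap minimum edge-to-edge arc gap between domains, nm.
#' @param tubules_per_endosome a [dist_spec] (default uniform 0-2,
#'   rounded).
#' @param tubule_length range `c(min, max)` nm; `tubule_width` nm.
#' @param n_fiducials number of rods; `fiducial_length` range nm;
#'   `fiducial_width` nm.
#' @param background_rate cytosolic monomer localization rate, per um^2
#'   per frame.
#' @param n_frames acquisition frames.
#' @param drift linear stage drift `c(vx, vy)` nm/frame injected into
#'   simulated streams.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(field_size = c(6000, 6000),
                       n_endosomes = 8,
                       endosome_radius = c(100, 300),
                       domains_per_endosome = dist_spec("poisson",
                                                        lambda = 4.9,
                                                        min = 1),
                       domain_diameter = dist_spec("lognormal",
                                                   mean = 55, sd = 15),
                       domain_gap = 60,
                       tubules_per_endosome = dist_spec("uniform",
                                                        min = 0, max = 2),
                       tubule_length = c(200, 600),
                       tubule_width = 60,
                       n_fiducials = 3,
                       fiducial_length = c(1000, 3000),
                       fiducial_width = 300,
                       background_rate = 0.05,
                       n_frames = 5000,
                       drift = c(0, 0)) {
  stopifnot(all(field_size > 0), endosome_radius[1] > 0,
            endosome_radius[2] >= endosome_radius[1],
            domain_gap >= 0, n_frames >= 1)
  structure(as.list(environment()), class = "scene_spec")
}

#' Emitter and acquisition model for the localization simulator
#'
#' Emitters are placed on structures at the given densities; each emitter
#' is on for a geometrically distributed number of consecutive frames
#' (memoryless blinking surrogate) starting at a uniform frame, and every
#' on-frame yields one localization at the emitter position plus
#' isotropic Gaussian error. Rod fiducials additionally carry a few
#' persistent emitters on for the whole acquisition, mirroring the
#' continuous broadband autofluorescence that makes bacteria usable as
#' drift and registration references.
#'
#' @param density_lumen emitters per nm^2 of endosome lumen (cargo
#'   channel).
#' @param density_membrane emitters per nm of membrane contour.
#' @param density_tubule emitters per nm of tubule length.
#' @param density_domain emitters per nm^2 of nanodomain area.
#' @param density_rod emitters per nm^2 of rod area.
#' @param n_persistent_per_rod persistent (always-on) emitters per rod.
#' @param mean_on_frames mean blink duration in frames.
#' @param sigma named per-channel localization error SD in nm.
#' @param photons named list of per-channel `c(median, cv)` photon
#'   lognormal parameters (median photons, coefficient of variation).
#' @param fwhm_mean,fwhm_sd fitted-PSF FWHM distribution (nm), clipped
#'   to `fwhm_range`.
#' @param channel_map named list mapping channel to structure kinds.
#' @return A list of class `"emitter_model"`.
#' @export
emitter_model <- function(density_lumen = 0.005,
                          density_membrane = 0.15,
                          density_tubule = 0.15,
                          density_domain = 0.01,
                          density_rod = 0.002,
                          n_persistent_per_rod = 20,
                          mean_on_frames = 3,
                          sigma = c(ch647 = 10, ch561 = 10, ch488 = 10),
                          photons = list(ch647 = c(6000, 0.5),
                                         ch561 = c(3000, 0.5),
                                         ch488 = c(900, 0.5)),
                          fwhm_mean = 350, fwhm_sd = 40,
                          fwhm_range = c(260, 440),
                          channel_map = list(ch647 = "lumen",
                                             ch561 = c("membrane", "tubule"),
                                             ch488 = "domain")) {
  structure(as.list(environment()), class = "emitter_model")
}

#' Generate a ground-truth scene
#'
#' Endosomes are placed without overlap by rejection sampling; each gets
#' its domain count and diameters first, and its radius is drawn
#' uniformly but floored at the membrane length the domains need (with
#' their minimum gaps), so every sampled complement is geometrically
#' feasible. Domain centres sit on the membrane contour at angles kept
#' apart by at least the occupied arc; tubules attach to free membrane;
#' rods land in structure-free space. Deterministic under `seed`.
#'
#' @param spec a [scene_spec].
#' @param seed integer RNG seed.
#' @return A list of class `"ground_truth"`: `structures` (data.frame
#'   with columns `id, kind, parent, x, y, radius, diameter, angle,
#'   length, width`), `spec`, `seed`, `drift`, and `domain_truth`
#'   (per-endosome true count and mean diameter).
#' @export
generate_scene <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  W <- spec$field_size[1]; H <- spec$field_size[2]
  rows <- list()
  nid <- 0L
  add <- function(kind, parent = NA_integer_, x = NA_real_, y = NA_real_,
                  radius = NA_real_, diameter = NA_real_,
                  angle = NA_real_, length = NA_real_, width = NA_real_) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(id = nid, kind = kind, parent = parent,
                               x = x, y = y, radius = radius,
                               diameter = diameter, angle = angle,
                               length = length, width = width)
    nid
  }
  endo <- list()
  for (e in seq_len(spec$n_endosomes)) {
    k <- round(sample_dist(spec$domains_per_endosome, 1))
    diam <- pmax(15, sample_dist(spec$domain_diameter, k))
    need_r <- sum(diam + spec$domain_gap) / (2 * pi)
    r <- stats::runif(1, spec$endosome_radius[1], spec$endosome_radius[2])
    r <- max(r, need_r * 1.05)
    placed <- FALSE
    for (try in seq_len(2000)) {
      cx <- stats::runif(1, r + 100, W - r - 100)
      cy <- stats::runif(1, r + 100, H - r - 100)
      ok <- TRUE
      for (o in endo)
        if (sqrt((cx - o$x)^2 + (cy - o$y)^2) < r + o$r + 150) {
          ok <- FALSE; break
        }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) stop("infeasible endosome packing for this field size")
    eid <- add("endosome", x = cx, y = cy, radius = r)
    endo[[length(endo) + 1L]] <- list(x = cx, y = cy, r = r, id = eid)
    # domain angles: random order around the circle, separated by their
    # occupied arcs, with the leftover circumference split into random
    # gaps -- handles any feasible occupancy including nearly-full rings
    arcs <- (diam + spec$domain_gap) / r   # angular width incl. gap
    slack <- 2 * pi - sum(arcs)
    if (slack < 0) stop("infeasible domain packing on endosome ", e)
    ord <- if (k > 1) sample.int(k) else 1L
    gaps <- stats::runif(k)
    gaps <- gaps / sum(gaps) * slack
    start <- stats::runif(1, 0, 2 * pi)
    centers <- start + cumsum(gaps + arcs[ord]) - arcs[ord] / 2
    angles <- numeric(k)
    angles[ord] <- centers %% (2 * pi)
    for (d in seq_len(k)) {
      add("domain", parent = eid,
          x = cx + r * cos(angles[d]), y = cy + r * sin(angles[d]),
          radius = r, diameter = diam[d], angle = angles[d])
    }
    nt <- round(sample_dist(spec$tubules_per_endosome, 1))
    for (t_ in seq_len(max(0, nt))) {
      a <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, spec$tubule_length[1], spec$tubule_length[2])
      add("tubule", parent = eid, x = cx + r * cos(a), y = cy + r * sin(a),
          angle = a, length = len, width = spec$tubule_width)
    }
  }
  # rods in structure-free regions
  rods <- list()
  for (f in seq_len(spec$n_fiducials)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      # resample the rod length too: if a long bacterium does not fit
      # the remaining free space, a shorter one may
      len <- stats::runif(1, spec$fiducial_length[1], spec$fiducial_length[2])
      a <- stats::runif(1, 0, pi)
      half <- len / 2 + spec$fiducial_width
      cx <- stats::runif(1, half, W - half)
      cy <- stats::runif(1, half, H - half)
      ok <- TRUE
      for (o in endo)
        if (.point_segment_dist(o$x, o$y, cx - cos(a) * len / 2,
                                cy - sin(a) * len / 2,
                                cx + cos(a) * len / 2,
                                cy + sin(a) * len / 2) <
            o$r + spec$fiducial_width + 200) { ok <- FALSE; break }
      if (ok) for (o in rods)
        if (sqrt((cx - o$x)^2 + (cy - o$y)^2) <
            (len + o$len) / 2 + 2 * spec$fiducial_width) {
          ok <- FALSE; break
        }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) stop("infeasible fiducial packing for this field size")
    add("fiducial", x = cx, y = cy, angle = a, length = len,
        width = spec$fiducial_width)
    rods[[length(rods) + 1L]] <- list(x = cx, y = cy, len = len)
  }
  structures <- do.call(rbind, rows)
  dom <- structures[structures$kind == "domain", , drop = FALSE]
  domain_truth <- do.call(rbind, lapply(
    structures$id[structures$kind == "endosome"], function(eid) {
      dd <- dom$diameter[dom$parent == eid]
      data.frame(endosome_id = eid, domain_count = length(dd),
                 mean_diameter = mean(dd))
    }))
  structure(list(structures = structures, spec = spec, seed = seed,
                 drift = spec$drift, domain_truth = domain_truth),
            class = "ground_truth")
}

.point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  t_ <- ((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2)
  t_ <- pmin(1, pmax(0, t_))
  sqrt((px - (x1 + t_ * vx))^2 + (py - (y1 + t_ * vy))^2)
}

#' @export
print.ground_truth <- function(x, ...) {
  tb <- table(x$structures$kind)
  cat("<ground_truth>",
      paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  true domains/endosome %.2f, true mean diameter %.1f nm\n",
              mean(x$domain_truth$domain_count),
              mean(x$domain_truth$mean_diameter)))
  invisible(x)
}

# uniform samples on each structure kind; returns matrix [x, y]
.sample_on_structure <- function(s, n) {
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  switch(s$kind,
    endosome = {                    # lumen disc (radius 0.85 r)
      rr <- 0.85 * s$radius * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      cbind(s$x + rr * cos(a), s$y + rr * sin(a))
    },
    membrane = {                    # 20 nm band on the contour
      a <- stats::runif(n, 0, 2 * pi)
      rr <- s$radius + stats::runif(n, -10, 10)
      cbind(s$x + rr * cos(a), s$y + rr * sin(a))
    },
    domain = {                      # disc on the membrane contour
      rr <- s$diameter / 2 * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      cbind(s$x + rr * cos(a), s$y + rr * sin(a))
    },
    tubule = {                      # capsule from attachment point
      t_ <- stats::runif(n, 0, s$length)
      lat <- stats::runif(n, -s$width / 2, s$width / 2)
      ux <- cos(s$angle); uy <- sin(s$angle)
      cbind(s$x + t_ * ux - lat * uy, s$y + t_ * uy + lat * ux)
    },
    fiducial = {                    # rod capsule
      t_ <- stats::runif(n, -s$length / 2, s$length / 2)
      lat <- stats::runif(n, -s$width / 2, s$width / 2)
      ux <- cos(s$angle); uy <- sin(s$angle)
      cbind(s$x + t_ * ux - lat * uy, s$y + t_ * uy + lat * ux)
    },
    stop("unknown structure kind: ", s$kind))
}

# per-kind emitter count measure: area (nm^2) or length (nm)
.structure_measure <- function(s) {
  switch(s$kind,
    endosome = pi * (0.85 * s$radius)^2,
    membrane = 2 * pi * s$radius,
    domain = pi * (s$diameter / 2)^2,
    tubule = s$length,
    fiducial = s$length * s$width)
}

#' Simulate per-channel localization streams from a ground-truth scene
#'
#' Cargo (647 channel) labels the endosome lumen, transferrin-like cargo
#' (561) the membrane and tubules, the Rab5-like channel (488) the
#' nanodomains; rods emit in every channel. See [emitter_model] for the
#' blinking and noise model. Linear drift from the ground truth is added
#' to the emitted coordinates and recorded in each table's metadata.
#'
#' @param truth a [generate_scene] result.
#' @param model an [emitter_model].
#' @param seed RNG seed.
#' @return Named list of [loc_table], one per channel.
#' @export
simulate_localizations <- function(truth, model = emitter_model(),
                                   seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(model, "emitter_model"))
  set.seed(seed + 1L)
  spec <- truth$spec
  st <- truth$structures
  nfr <- spec$n_frames
  # rod autofluorescence arises from the same molecules in every
  # channel: sample each rod's emitter positions once, shared across
  # channels (blink schedules stay channel-specific)
  rod_rows <- which(st$kind == "fiducial")
  rod_pos <- lapply(rod_rows, function(i) {
    s <- st[i, ]
    nb <- stats::rpois(1, model$density_rod * .structure_measure(s))
    list(blink = .sample_on_structure(s, nb),
         persistent = .sample_on_structure(s, model$n_persistent_per_rod))
  })
  names(rod_pos) <- as.character(st$id[rod_rows])
  out <- list()
  for (ch in names(model$channel_map)) {
    kinds <- model$channel_map[[ch]]
    frames <- integer(0); xs <- numeric(0); ys <- numeric(0)
    sid <- integer(0)
    emit_struct <- function(srow, density, fixed_pos = NULL) {
      if (is.null(fixed_pos)) {
        ne <- stats::rpois(1, density * .structure_measure(srow))
        pos <- .sample_on_structure(srow, ne)
      } else {
        pos <- fixed_pos$blink
        ne <- nrow(pos)
      }
      non <- stats::rgeom(ne, 1 / model$mean_on_frames) + 1L
      t0 <- floor(stats::runif(ne, 0, pmax(1, nfr - non + 1)))
      if (!is.null(fixed_pos) && nrow(fixed_pos$persistent) > 0L) {
        pos <- rbind(pos, fixed_pos$persistent)
        np <- nrow(fixed_pos$persistent)
        non <- c(non, rep(nfr, np))
        t0 <- c(t0, rep(0, np))
        ne <- ne + np
      }
      if (ne == 0L) return(NULL)
      reps <- as.integer(non)
      f <- unlist(lapply(seq_len(ne),
                         function(i) seq.int(t0[i],
                                             min(nfr - 1L,
                                                 t0[i] + reps[i] - 1L))))
      k <- unlist(lapply(seq_len(ne), function(i)
        rep.int(i, min(reps[i], nfr - t0[i]))))
      frames <<- c(frames, as.integer(f))
      xs <<- c(xs, pos[k, 1])
      ys <<- c(ys, pos[k, 2])
      sid <<- c(sid, rep.int(srow$id, length(f)))
      NULL
    }
    for (i in seq_len(nrow(st))) {
      srow <- st[i, ]
      if (srow$kind == "fiducial") {
        emit_struct(srow, model$density_rod,
                    fixed_pos = rod_pos[[as.character(srow$id)]])
      } else if (srow$kind %in% kinds) {
        dens <- switch(srow$kind,
                       domain = model$density_domain,
                       tubule = model$density_tubule)
        emit_struct(srow, dens)
      } else if (srow$kind == "endosome") {
        # lumen and membrane signals derive from the endosome geometry
        if ("lumen" %in% kinds)
          emit_struct(srow, model$density_lumen)
        if ("membrane" %in% kinds) {
          srow2 <- srow; srow2$kind <- "membrane"
          emit_struct(srow2, model$density_membrane)
        }
      }
    }
    # uniform cytosolic monomer background
    area_um2 <- prod(spec$field_size) / 1e6
    nbg <- stats::rpois(1, spec$background_rate * area_um2 * nfr)
    if (nbg > 0) {
      frames <- c(frames, floor(stats::runif(nbg, 0, nfr)))
      xs <- c(xs, stats::runif(nbg, 0, spec$field_size[1]))
      ys <- c(ys, stats::runif(nbg, 0, spec$field_size[2]))
      sid <- c(sid, rep.int(0L, nbg))
    }
    n <- length(frames)
    sg <- model$sigma[[ch]]
    xs <- xs + stats::rnorm(n, 0, sg)
    ys <- ys + stats::rnorm(n, 0, sg)
    ph <- model$photons[[ch]]
    s2 <- log(1 + ph[2]^2)
    photons <- stats::rlnorm(n, log(ph[1]), sqrt(s2))
    fwhm <- pmin(model$fwhm_range[2],
                 pmax(model$fwhm_range[1],
                      stats::rnorm(n, model$fwhm_mean, model$fwhm_sd)))
    if (any(truth$drift != 0)) {
      xs <- xs + truth$drift[1] * frames
      ys <- ys + truth$drift[2] * frames
    }
    out[[ch]] <- loc_table(frame = frames, x = xs, y = ys,
                           photons = photons, fwhm = fwhm,
                           channel = ch, n_frames = nfr,
                           struct_id = sid,
                           metadata = list(
                             sigma_true = sg,
                             drift_true = truth$drift,
                             field_size = spec$field_size))
  }
  out
}

#' Inject linear drift into a localization table
#'
#' `x <- x + vx * frame`, likewise y; the injected velocity is recorded
#' in the metadata so tests can recover it as ground truth. Applying
#' [apply_drift] with the same velocities restores the original table.
#'
#' @param table a [loc_table].
#' @param velocity `c(vx, vy)` nm/frame.
#' @return The drifted [loc_table].
#' @export
inject_drift <- function(table, velocity) {
  stopifnot(inherits(table, "loc_table"), all(is.finite(velocity)))
  out <- table
  out$x <- table$x + velocity[1] * table$frame
  out$y <- table$y + velocity[2] * table$frame
  md <- loc_metadata(out)
  md$drift_true <- velocity
  loc_metadata(out) <- md
  out
}

#' Construct a similarity transform directly from parameters
#'
#' @param rotation radians; `scale` > 0; `translation` `c(tx, ty)` nm.
#' @return A `"transform_model"` of kind similarity (no landmarks).
#' @export
similarity_transform <- function(rotation = 0, scale = 1,
                                 translation = c(0, 0)) {
  stopifnot(scale > 0)
  R <- matrix(c(cos(rotation), sin(rotation),
                -sin(rotation), cos(rotation)), 2, 2)
  structure(list(kind = "similarity", params = cbind(scale * R, translation),
                 rotation = rotation, scale = scale,
                 translation = translation, lambda = 0,
                 matches = point_matches(numeric(0), numeric(0),
                                         numeric(0), numeric(0)),
                 residuals = numeric(0), rms_residual = 0),
            class = "transform_model")
}

#' Rasterize an EM-style reference image and export true landmarks
#'
#' Structures and rods are drawn as intensity silhouettes in EM-pixel
#' coordinates under the supplied SMLM-to-EM transform (rods brightest,
#' then membranes, tubules, lumen), emulating a low-magnification EM
#' overview in which bacteria fiducials are visible. The exact
#' transformed rod endpoints and centroids are exported as the
#' ground-truth landmark table.
#'
#' @param truth a [generate_scene] result.
#' @param transform a `"transform_model"` mapping SMLM nm to EM-frame nm.
#' @param em_pixel_size EM pixel size in nm (default 20).
#' @param pad field padding in nm around the transformed field.
#' @return A list: `image` (a [rendered_image] in the EM frame),
#'   `landmarks` (data.frame `fiducial_id, kind, x_smlm, y_smlm, x_em,
#'   y_em` in nm).
#' @export
make_em_reference <- function(truth, transform = similarity_transform(),
                              em_pixel_size = 20, pad = 500) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(transform, "transform_model"))
  W <- truth$spec$field_size[1]; H <- truth$spec$field_size[2]
  corners <- apply_transform(cbind(c(0, W, 0, W), c(0, 0, H, H)), transform)
  x0 <- min(corners[, 1]) - pad; x1 <- max(corners[, 1]) + pad
  y0 <- min(corners[, 2]) - pad; y1 <- max(corners[, 2]) + pad
  nc <- ceiling((x1 - x0) / em_pixel_size)
  nr <- ceiling((y1 - y0) / em_pixel_size)
  xc <- x0 + (seq_len(nc) - 0.5) * em_pixel_size
  yc <- y0 + (seq_len(nr) - 0.5) * em_pixel_size
  pts <- cbind(rep(xc, each = nr), rep(yc, nc))
  inv <- invert_transform(transform)
  src <- apply_transform(pts, inv)     # EM pixel centers in SMLM nm
  val <- numeric(nrow(pts))
  st <- truth$structures
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    v <- switch(s$kind,
      endosome = {
        d <- sqrt((src[, 1] - s$x)^2 + (src[, 2] - s$y)^2)
        0.3 * (d < 0.85 * s$radius) + 0.6 * (abs(d - s$radius) < 15)
      },
      domain = 0.0,
      tubule = {
        dx <- cos(s$angle) * s$length; dy <- sin(s$angle) * s$length
        d <- .point_segment_dist(src[, 1], src[, 2], s$x, s$y,
                                 s$x + dx, s$y + dy)
        0.5 * (d < s$width / 2)
      },
      fiducial = {
        hx <- cos(s$angle) * s$length / 2
        hy <- sin(s$angle) * s$length / 2
        d <- .point_segment_dist(src[, 1], src[, 2], s$x - hx, s$y - hy,
                                 s$x + hx, s$y + hy)
        1.0 * (d < s$width / 2)
      })
    if (is.numeric(v) && length(v) == length(val)) val <- pmax(val, v)
  }
  img <- rendered_image(matrix(val, nr, nc), em_pixel_size,
                        origin = c(x0, y0))
  rods <- st[st$kind == "fiducial", , drop = FALSE]
  lm <- do.call(rbind, lapply(seq_len(nrow(rods)), function(i) {
    s <- rods[i, ]
    hx <- cos(s$angle) * s$length / 2
    hy <- sin(s$angle) * s$length / 2
    p <- rbind(c(s$x, s$y), c(s$x - hx, s$y - hy), c(s$x + hx, s$y + hy))
    kind <- c("center_of_mass", "endpoint", "endpoint")
    q <- apply_transform(p, transform)
    data.frame(fiducial_id = s$id, kind = kind,
               x_smlm = p[, 1], y_smlm = p[, 2],
               x_em = q[, 1], y_em = q[, 2])
  }))
  list(image = img, landmarks = lm)
}

#' Simulate jittered landmark matches under a known transform
#'
#' Generates `n` reference points, maps them through `transform` and adds
#' isotropic Gaussian jitter of `jitter_sd` nm per axis to the reference
#' side, emulating fiducial localization error between two aligned
#' modalities. Used to validate overlay-precision statistics against the
#' Rayleigh closed form.
#'
#' @param n number of fiducials.
#' @param transform the true moving-to-reference `"transform_model"`.
#' @param jitter_sd per-axis Gaussian jitter SD in nm.
#' @param field extent `c(wx, wy)` nm the moving points are drawn from.
#' @param seed RNG seed.
#' @return A [point_matches] with the jittered reference coordinates.
#' @export
simulate_landmark_matches <- function(n, transform = similarity_transform(),
                                      jitter_sd = 10,
                                      field = c(10000, 10000), seed = 1) {
  set.seed(seed + 2L)
  mov <- cbind(stats::runif(n, 0, field[1]), stats::runif(n, 0, field[2]))
  ref <- apply_transform(mov, transform)
  ref <- ref + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
  point_matches(ref[, 1], ref[, 2], mov[, 1], mov[, 2],
                kind = "center_of_mass", fiducial_id = seq_len(n))
}

#' Bundled scene presets
#'
#' `"paper-like"` reproduces the regime the morphometry statistics come
#' from: three channels, ~5 domains of ~55 nm mean diameter per endosome,
#' rod fiducials, linear drift of (0.02, -0.01) nm/frame.
#'
#' @param name preset name.
#' @param n_endosomes,n_frames optional overrides.
#' @return A list with elements `scene` (a [scene_spec]) and `emitter`
#'   (an [emitter_model]).
#' @export
scene_preset <- function(name = "paper-like", n_endosomes = 8,
                         n_frames = 5000) {
  if (!identical(name, "paper-like"))
    stop("unknown preset: ", name)
  list(scene = scene_spec(n_endosomes = n_endosomes, n_frames = n_frames,
                          domain_diameter = dist_spec("fixed", value = 55),
                          drift = c(0.02, -0.01)),
       emitter = emitter_model())
}

#' Write a ground-truth scene to JSON + CSV
#'
#' @param truth a `"ground_truth"`; `dir` output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(truth$structures,
                   file.path(dir, "structures.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, drift = truth$drift,
         field_size = truth$spec$field_size,
         n_frames = truth$spec$n_frames,
         domain_truth = truth$domain_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
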