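#' Run configuration
#'
#' Builds the configuration driving the analysis workflows, either from
#' arguments or from a YAML file (`read_run_config`). Any field can be
#' overridden; unknown fields are an error.
#'
#' @param channels named list; each element is either a file path to a
#'   localization table or the string `"simulate"` (the synthetic preset
#'   supplies the stream). Must name the nanodomain channel via
#'   `domain_channel`.
#' @param preset `NULL` or `"paper-like"`: simulate inputs from the
#'   bundled preset instead of reading files.
#' @param domain_channel channel carrying the nanodomain marker
#'   (median-filtered before combination; default `"ch488"`).
#' @param filter named list of [filter_spec] per channel (defaults: the
#'   250-450 nm FWHM window with standard per-dye photon thresholds
#'   3000/1500/450 for ch647/ch561/ch488).
#' @param pixel_size rendered pixel size nm (default 10).
#' @param blur_sigma,min_area,median_radius morphometry parameters
#'   (defaults 2 px, 4 px^2, 1 px).
#' @param domain_max_area upper particle-size window for the nanodomain
#'   mask, in pixels^2 (default 2000, i.e. an equivalent disc of about
#'   0.5 um -- excludes rod fiducials, which emit broadband and would
#'   otherwise enter the nanodomain channel).
#' @param drift_correction `"auto"` (estimate from long tracks),
#'   `"none"`, or a `c(vx, vy)` override.
#' @param link_radius nm for track linking (default 104).
#' @param min_track_length frames for drift-qualifying tracks
#'   (default 100).
#' @param registration_kind transform kind for overlay QC.
#' @param em_pixel_size nm (default 20).
#' @param out_dir output directory.
#' @param seed integer seed driving all randomness of a run.
#' @param n_endosomes,n_frames preset-size overrides.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(channels = list(ch647 = "simulate",
                                       ch561 = "simulate",
                                       ch488 = "simulate"),
                       preset = "paper-like",
                       domain_channel = "ch488",
                       filter = NULL,
                       pixel_size = 10,
                       blur_sigma = 2,
                       min_area = 4,
                       median_radius = 1,
                       domain_max_area = 2000,
                       drift_correction = "auto",
                       link_radius = 104,
                       min_track_length = 100,
                       registration_kind = "similarity",
                       em_pixel_size = 20,
                       out_dir = tempfile("smlmpipe_"),
                       seed = 1,
                       n_endosomes = 8,
                       n_frames = 5000) {
  cfg <- mget(names(formals(sys.function())))
  if (is.null(filter)) {
    thr <- c(ch647 = 3000, ch561 = 1500, ch488 = 450)
    cfg$filter <- lapply(names(channels), function(ch)
      filter_spec(250, 450, photon_min = if (ch %in% names(thr))
        thr[[ch]] else 0))
    names(cfg$filter) <- names(channels)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file; scalar fields map directly, `filter` entries as
#'   lists `(fwhm_min, fwhm_max, photon_min)`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$filter))
    y$filter <- lapply(y$filter, function(f)
      filter_spec(f$fwhm_min %||% 250, f$fwhm_max %||% 450,
                  f$photon_min %||% 0))
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

# FNV-1a hash of the deparsed config, for provenance headers
.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]   # paths are not science
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 268435456
  sprintf("%07x", h)
}

.provenance <- function(config) {
  sprintf("# smlmpipe %s | config %s | seed %d",
          as.character(utils::packageVersion("smlmpipe")),
          .config_hash(config), config$seed)
}

.write_csv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.csv(df, con, row.names = FALSE)
}

.log_line <- function(log_path, ...) {
  msg <- sprintf(...)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE,
                              sep = "")
  message(msg)
}

# load or simulate the per-channel tables; returns list(tables, truth)
.acquire_channels <- function(config) {
  if (!is.null(config$preset)) {
    ps <- scene_preset(config$preset, n_endosomes = config$n_endosomes,
                       n_frames = config$n_frames)
    truth <- generate_scene(ps$scene, seed = config$seed)
    tables <- simulate_localizations(truth, ps$emitter, seed = config$seed)
    tables <- tables[names(config$channels)]
    list(tables = tables, truth = truth)
  } else {
    tables <- lapply(names(config$channels), function(ch)
      read_localizations(config$channels[[ch]], channel = ch))
    names(tables) <- names(config$channels)
    list(tables = tables, truth = NULL)
  }
}

# filter + drift-correct one channel; returns list(table, drift, log)
.preprocess_channel <- function(table, fspec, config, log_path, ch) {
  filtered <- filter_localizations(table, fspec)
  fl <- attr(filtered, "filter_log")
  .log_line(log_path,
            "[%s] filter: kept %d | removed %d (FWHM), %d (photons)",
            ch, fl[["kept"]], fl[["fwhm_removed"]], fl[["photon_removed"]])
  dm <- NULL
  if (identical(config$drift_correction, "auto")) {
    # drift is estimated on the unfiltered table: photon thresholds chop
    # the persistent fiducial chains the estimator relies on
    tracks <- link_consecutive(table, config$link_radius)
    dm <- tryCatch(estimate_linear_drift(tracks, config$min_track_length),
                   error = function(e) NULL)
    if (is.null(dm)) {
      .log_line(log_path, "[%s] drift: no qualifying track; uncorrected", ch)
    } else {
      filtered <- apply_drift(filtered, dm)
      .log_line(log_path, "[%s] drift: v = (%.4g, %.4g) nm/frame", ch,
                dm$vx, dm$vy)
    }
  } else if (is.numeric(config$drift_correction)) {
    dm <- drift_model(config$drift_correction[1], config$drift_correction[2])
    filtered <- apply_drift(filtered, dm)
  }
  list(table = filtered, drift = dm)
}

# Fiducial-exclusion mask from temporal persistence: a rendered-count
# pixel can only reach ~1% of the acquisition length if a persistent
# (fiducial) emitter sits there -- blinking biology is on for a few
# frames. Returns a logical matrix (TRUE = fiducial territory), dilated
# by ~300 nm so the rod body between persistent spots (and its blinking
# autofluorescence) is excluded along with them.
.detect_fiducial_mask <- function(images, n_frames, frac = 0.01,
                                  dilate_px = 30) {
  thr <- max(20, frac * n_frames)
  hot <- Reduce(`|`, lapply(images, function(im) im$grid >= thr))
  if (!any(hot)) return(hot)
  brush <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "disc")
  EBImage::dilate(hot * 1, brush) > 0
}

#' Run the endosomal nanodomain analysis workflow
#'
#' Per channel: filter on FWHM/photons, estimate and correct linear drift
#' from long (fiducial) tracks, render at `pixel_size` nm; the nanodomain
#' channel is median-filtered (radius `median_radius`); channels are
#' max-combined into the endosome-area proxy; both the combined image and
#' the nanodomain image pass the blur / IsoData / fill-holes / area-floor
#' segmentation; domains are measured as area-matched moment ellipses and
#' aggregated per endosome. All stage parameters and discard counts are
#' logged; outputs (CSV tables, JSON summary, TIFF images, PNG figures)
#' carry a provenance header and are byte-reproducible for a fixed
#' config + seed.
#'
#' @param config a [run_config].
#' @return Invisibly, a list: `morphometry` (see
#'   [endosome_domain_stats]), `precision` (per-channel
#'   `"precision_estimate"`), `drift` (per-channel [drift_model]),
#'   `truth` (when simulated), `out_dir`.
#' @export
run_domain_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$channels) < 2L)
    stop("domain analysis needs >= 2 channels (cargo + nanodomain marker)")
  if (!(config$domain_channel %in% names(config$channels)))
    stop("domain_channel not among channels")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(.provenance(config), "\n", file = log_path, sep = "")
  prov <- .provenance(config)
  acq <- .acquire_channels(config)
  # shared field extent so channel images are combinable
  allxy <- do.call(rbind, lapply(acq$tables, function(t) cbind(t$x, t$y)))
  px <- config$pixel_size
  rspec <- render_spec(px,
                       xlim = c(0, (floor(max(allxy[, 1]) / px) + 1) * px),
                       ylim = c(0, (floor(max(allxy[, 2]) / px) + 1) * px))
  images <- list(); drifts <- list(); precisions <- list()
  for (ch in names(acq$tables)) {
    pre <- .preprocess_channel(acq$tables[[ch]], config$filter[[ch]],
                               config, log_path, ch)
    drifts[[ch]] <- pre$drift
    tracks <- link_consecutive(pre$table, config$link_radius)
    if (attr(tracks, "n_tracks") > 0L)
      precisions[[ch]] <- estimate_precision(tracks)
    img <- render_histogram(pre$table, rspec)
    .log_line(log_path, "[%s] render: %d in-field, %d out-of-field", ch,
              sum(img$grid), attr(img, "n_out_of_field"))
    if (ch == config$domain_channel && config$median_radius > 0) {
      img <- median_filter_image(img, config$median_radius)
      .log_line(log_path, "[%s] median filter radius %d px applied", ch,
                config$median_radius)
    }
    images[[ch]] <- img
    write_image_tiff(img, file.path(config$out_dir,
                                    sprintf("render_%s.tif", ch)))
  }
  # fiducial rods are drift/registration references, not biology:
  # exclude their (temporally persistent) pixels from morphometry
  nfr <- max(vapply(acq$tables, function(t)
    loc_metadata(t)$n_frames %||% (max(t$frame) + 1L), 0L))
  fid <- .detect_fiducial_mask(images, nfr)
  if (any(fid)) {
    .log_line(log_path, "fiducial exclusion: %d px masked", sum(fid))
    images <- lapply(images, function(im) {
      im$grid[fid] <- 0
      im
    })
  }
  combined <- combine_channels(images)
  endo_mask <- segment_structures(combined, config$blur_sigma,
                                  config$min_area)
  dom_img <- images[[config$domain_channel]]
  dom_mask <- segment_structures(dom_img, config$blur_sigma,
                                 config$min_area,
                                 max_area = config$domain_max_area)
  .log_line(log_path,
            "segment: %d endosome components (T=%.4g), %d domains (T=%.4g)",
            endo_mask$n, endo_mask$threshold, dom_mask$n,
            dom_mask$threshold)
  domains <- measure_domains(dom_mask)
  loc_sig <- if (!is.null(precisions[[config$domain_channel]]))
    precisions[[config$domain_channel]]$median_precision else 0
  domains <- correct_broadening(domains, config$blur_sigma, px, loc_sig)
  morph <- endosome_domain_stats(endo_mask, domains, dom_mask)
  .log_line(log_path, "morphometry: %d unassigned domain(s) excluded",
            attr(morph, "n_unassigned"))
  # outputs
  write_image_tiff(endo_mask, file.path(config$out_dir, "endosome_mask.tif"))
  write_image_tiff(dom_mask, file.path(config$out_dir, "domain_mask.tif"))
  .write_csv_prov(morph$domains, file.path(config$out_dir,
                                           "domain_records.csv"), prov)
  endos <- morph$endosomes
  endos$domain_ids <- vapply(endos$domain_ids, paste, "", collapse = ";")
  .write_csv_prov(endos, file.path(config$out_dir, "endosome_records.csv"),
                  prov)
  sm <- morph$summary
  sm_df <- data.frame(
    n_endosomes = sm$n_endosomes, n_domains = sm$n_domains,
    domain_count_mean = sm$domain_count_mean,
    domain_count_sd = sm$domain_count_sd,
    diameter_mean = sm$diameter_mean, diameter_sd = sm$diameter_sd,
    singleton_n = sm$singleton_n,
    singleton_diameter_mean = sm$singleton_diameter_mean,
    singleton_diameter_sd = sm$singleton_diameter_sd,
    area_vs_count_slope = sm$fit_area_vs_count[["slope"]],
    area_vs_count_r = sm$fit_area_vs_count[["r"]],
    count_vs_area_slope = sm$fit_count_vs_area[["slope"]],
    count_vs_area_r = sm$fit_count_vs_area[["r"]])
  .write_csv_prov(sm_df, file.path(config$out_dir, "summary.csv"), prov)
  jsonlite::write_json(unclass(sm), file.path(config$out_dir,
                                              "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (ch in names(precisions))
    write_precision_histogram(
      precisions[[ch]],
      file.path(config$out_dir, sprintf("precision_%s.csv", ch)))
  .plot_morphometry(morph, file.path(config$out_dir, "morphometry.png"))
  if (!is.null(acq$truth))
    write_ground_truth(acq$truth, file.path(config$out_dir, "truth"))
  invisible(list(morphometry = morph, precision = precisions,
                 drift = drifts, truth = acq$truth,
                 images = images, combined = combined,
                 out_dir = config$out_dir))
}

.plot_morphometry <- function(morph, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  if (nrow(morph$domains) > 0)
    graphics::hist(morph$domains$diameter, breaks = 20,
                   main = "Domain diameters", xlab = "diameter (nm)")
  e <- morph$endosomes[morph$endosomes$domain_count > 0, ]
  if (nrow(e) > 1) {
    graphics::plot(e$domain_count, e$rab5_covered_area / 1e3,
                   xlab = "domains per endosome",
                   ylab = "covered area (10^3 nm^2)",
                   main = "Covered area vs domain count")
    graphics::abline(stats::lm(I(rab5_covered_area / 1e3) ~ domain_count,
                               data = e), col = "red")
  }
}

# Segment rod fiducials in an image and extract landmarks. Rod bodies
# are contiguous at low counts (broadband autofluorescence) while the
# background is isolated single localizations, so a fixed low threshold
# after a light blur separates them; elongation then tells rods from
# round cellular structures. IsoData is unsuitable here: with persistent
# emitters present it isolates only their ultra-bright pixels. Returns
# data.frame id, kind, x, y.
.extract_rod_landmarks <- function(image, threshold = 0.3,
                                   min_area_px = 1000,
                                   min_elongation = 2) {
  mask <- segment_structures(image, blur_sigma = 1, min_area = min_area_px,
                             threshold = threshold)
  if (mask$n == 0L) return(NULL)
  rec <- measure_domains(mask)
  rec <- rec[rec$major_axis / rec$minor_axis >= min_elongation, ,
             drop = FALSE]
  if (nrow(rec) == 0L) return(NULL)
  out <- list()
  for (i in seq_len(nrow(rec))) {
    sub <- mask$labels == rec$label[i]
    roi_img <- rendered_image(image$grid * sub, image$pixel_size,
                              image$origin)
    com <- fiducial_center_of_mass(roi_img)
    out[[length(out) + 1L]] <- data.frame(
      id = rec$label[i], kind = "center_of_mass", x = com[1], y = com[2])
    ep <- tryCatch(fiducial_endpoints(sub, mask$pixel_size, mask$origin,
                                      min_elongation = min_elongation),
                   error = function(e) NULL)
    if (!is.null(ep))
      out[[length(out) + 1L]] <- data.frame(
        id = rec$label[i], kind = c("endpoint", "endpoint"),
        x = ep[, 1], y = ep[, 2])
  }
  do.call(rbind, out)
}

# Coarse fiducial correspondence between unaligned modalities: try every
# ordered pair-to-pair assignment of CoMs as a 2-point similarity
# hypothesis and keep the one aligning the most fiducials within `tol`
# (the automated stand-in for picking corresponding bacteria by eye).
.coarse_align <- function(cr, cm, tol = 300) {
  nr <- nrow(cr); nm <- nrow(cm)
  if (nr < 2L || nm < 2L) return(NULL)
  best <- NULL; best_score <- -1
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
    for (k in seq_len(nm)) for (l in seq_len(nm)) {
      if (k == l) next
      fit <- tryCatch(fit_transform(point_matches(
        c(cr$x[i], cr$x[j]), c(cr$y[i], cr$y[j]),
        c(cm$x[k], cm$x[l]), c(cm$y[k], cm$y[l])), "similarity"),
        error = function(e) NULL)
      if (is.null(fit) || fit$scale < 0.5 || fit$scale > 2) next
      mapped <- apply_transform(cbind(cm$x, cm$y), fit)
      d <- vapply(seq_len(nr), function(a)
        min(sqrt((mapped[, 1] - cr$x[a])^2 + (mapped[, 2] - cr$y[a])^2)),
        numeric(1))
      score <- sum(d < tol)
      if (score > best_score) { best_score <- score; best <- fit }
    }
  }
  if (best_score < 2) NULL else best
}

# pair landmarks of two channels by fiducial proximity of their CoMs;
# `pre` is an optional coarse transform (moving -> reference) used only
# for the pairing decisions, never for the stored coordinates
.match_rod_landmarks <- function(lm_ref, lm_mov, max_dist = 1000,
                                 pre = NULL) {
  cr <- lm_ref[lm_ref$kind == "center_of_mass", ]
  cm <- lm_mov[lm_mov$kind == "center_of_mass", ]
  if (nrow(cr) == 0L || nrow(cm) == 0L) return(NULL)
  map_pts <- function(x, y) {
    if (is.null(pre)) cbind(x, y)
    else apply_transform(cbind(x, y), pre)
  }
  cmm <- map_pts(cm$x, cm$y)
  rows <- list()
  for (i in seq_len(nrow(cr))) {
    d <- sqrt((cmm[, 1] - cr$x[i])^2 + (cmm[, 2] - cr$y[i])^2)
    j <- which.min(d)
    if (d[j] > max_dist) next
    rows[[length(rows) + 1L]] <-
      data.frame(fid = cr$id[i], kind = "center_of_mass",
                 x_ref = cr$x[i], y_ref = cr$y[i],
                 x_mov = cm$x[j], y_mov = cm$y[j])
    er <- lm_ref[lm_ref$kind == "endpoint" & lm_ref$id == cr$id[i], ]
    em <- lm_mov[lm_mov$kind == "endpoint" & lm_mov$id == cm$id[j], ]
    if (nrow(er) == 2L && nrow(em) == 2L) {
      # endpoints come in deterministic x-then-y order; pair by index in
      # the (coarsely aligned) common frame, flipping if that is closer
      emm <- map_pts(em$x, em$y)
      d1 <- sum((er$x - emm[, 1])^2 + (er$y - emm[, 2])^2)
      d2 <- sum((er$x - rev(emm[, 1]))^2 + (er$y - rev(emm[, 2]))^2)
      if (d2 < d1) em <- em[2:1, ]
      rows[[length(rows) + 1L]] <-
        data.frame(fid = cr$id[i], kind = "endpoint",
                   x_ref = er$x, y_ref = er$y,
                   x_mov = em$x, y_mov = em$y)
    }
  }
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)
  point_matches(df$x_ref, df$y_ref, df$x_mov, df$y_mov,
                kind = df$kind, fiducial_id = df$fid)
}

#' Run the overlay quality-control workflow
#'
#' Simulates (or loads) the channel streams, renders them, extracts rod
#' landmarks (center-of-mass and, for elongated rods, endpoint pairs),
#' fits the channel-to-channel transforms against the reference channel
#' and the SMLM-to-EM transform against a synthetic EM overview, and
#' reports leave-one-out overlay precision per pair as mean +/- SD and
#' median +/- MAD.
#'
#' @param config a [run_config]; the first channel is the fixed
#'   reference.
#' @param n_fiducials number of rods in the simulated scene (default 6).
#' @param channel_jitter_sd extra per-axis landmark jitter between
#'   channels in nm (default 10), emulating chromatic residuals.
#' @return Invisibly, a named list of `"overlay_report"` (one per channel
#'   pair, plus `"smlm_to_em"`), written also as CSV + JSON under
#'   `config$out_dir`.
#' @export
run_overlay_qc <- function(config = run_config(), n_fiducials = 6,
                           channel_jitter_sd = 10) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- .provenance(config)
  log_path <- file.path(config$out_dir, "overlay_qc.log")
  cat(prov, "\n", file = log_path, sep = "")
  ps <- scene_preset(config$preset %||% "paper-like",
                     n_endosomes = config$n_endosomes,
                     n_frames = config$n_frames)
  ps$scene$n_fiducials <- n_fiducials
  # fiducial-rich QC fields are larger than analysis crops: several
  # micron-scale bacteria must fit between the cellular structures
  ps$scene$field_size <- pmax(ps$scene$field_size,
                              c(3000, 3000) * ceiling(sqrt(n_fiducials)))
  truth <- generate_scene(ps$scene, seed = config$seed)
  tables <- simulate_localizations(truth, ps$emitter, seed = config$seed)
  if (length(tables) < 2L) stop("overlay QC needs >= 2 channels")
  set.seed(config$seed + 17L)
  px <- config$pixel_size
  W <- ps$scene$field_size
  rspec <- render_spec(px, xlim = c(0, W[1]), ylim = c(0, W[2]))
  lms <- list()
  for (ch in names(tables)) {
    pre <- .preprocess_channel(tables[[ch]], config$filter[[ch]],
                               config, log_path, ch)
    tab <- pre$table
    # per-channel chromatic jitter on the landmark scale: shift the
    # whole channel by a small random offset (reference channel exempt)
    if (ch != names(tables)[1]) {
      off <- stats::rnorm(2, 0, channel_jitter_sd)
      tab$x <- tab$x + off[1]; tab$y <- tab$y + off[2]
    }
    img <- render_histogram(tab, rspec)
    lm <- .extract_rod_landmarks(img)
    if (is.null(lm) || nrow(lm[lm$kind == "center_of_mass", ]) < 2L)
      stop("insufficient rod fiducials detected in channel ", ch)
    # per-landmark localization jitter between channels
    lm$x <- lm$x + stats::rnorm(nrow(lm), 0, channel_jitter_sd / 2)
    lm$y <- lm$y + stats::rnorm(nrow(lm), 0, channel_jitter_sd / 2)
    lms[[ch]] <- lm
  }
  reports <- list()
  ref_ch <- names(tables)[1]
  for (ch in setdiff(names(tables), ref_ch)) {
    matches <- .match_rod_landmarks(lms[[ref_ch]], lms[[ch]])
    if (is.null(matches) || nrow(matches) < 3L)
      stop("insufficient matched fiducials for pair ", ref_ch, "-", ch)
    lab <- sprintf("%s_to_%s", ch, ref_ch)
    reports[[lab]] <- overlay_precision(matches, kind =
                                          config$registration_kind,
                                        loo = TRUE, label = lab)
    .log_line(log_path, "[%s] median %.1f nm over %d landmarks", lab,
              reports[[lab]]$median, length(reports[[lab]]$distances))
  }
  # SMLM-to-EM: synthetic EM overview under a known transform
  em_true <- similarity_transform(rotation = 0.3, scale = 1.04,
                                  translation = c(800, -400))
  em <- make_em_reference(truth, em_true, config$em_pixel_size)
  em_lm <- .extract_rod_landmarks(em$image, threshold = 0.8,
                                  min_area_px = 300)
  smlm_lm <- lms[[ref_ch]]
  if (!is.null(em_lm)) {
    em_lm$x <- em_lm$x + stats::rnorm(nrow(em_lm), 0, channel_jitter_sd)
    em_lm$y <- em_lm$y + stats::rnorm(nrow(em_lm), 0, channel_jitter_sd)
    coarse <- .coarse_align(em_lm[em_lm$kind == "center_of_mass", ],
                            smlm_lm[smlm_lm$kind == "center_of_mass", ])
    matches <- .match_rod_landmarks(em_lm, smlm_lm, max_dist = 1000,
                                    pre = coarse)
    if (!is.null(matches) && nrow(matches) >= 3L) {
      reports[["smlm_to_em"]] <- overlay_precision(
        matches, kind = config$registration_kind, loo = TRUE,
        label = "smlm_to_em")
      .log_line(log_path, "[smlm_to_em] median %.1f nm",
                reports[["smlm_to_em"]]$median)
    }
  }
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(pair = r$label, n_fiducials = r$n_fiducials,
               n_landmarks = length(r$distances), mean = r$mean,
               sd = r$sd, median = r$median, mad = r$mad)))
  .write_csv_prov(tab, file.path(config$out_dir, "overlay_precision.csv"),
                  prov)
  jsonlite::write_json(lapply(reports, function(r)
    r[c("label", "mode", "mean", "sd", "median", "mad", "n_fiducials")]),
    file.path(config$out_dir, "overlay_precision.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(reports)
}

#' Parameter-recovery benchmark over a truth grid
#'
#' For each cell of a (domain count K, domain diameter, localization
#' sigma) grid, simulates `n_endosomes` endosomes in fields of
#' `endosomes_per_field`, runs the full domain-analysis pipeline, and
#' tabulates the bias and RMSE of the recovered per-endosome domain count
#' and mean diameter against the generator truth.
#'
#' @param K_values true domain counts to sweep.
#' @param diameters true domain diameters (nm).
#' @param sigmas localization error SDs (nm).
#' @param n_endosomes endosomes per condition (default 50).
#' @param endosomes_per_field endosomes per simulated field (default 10).
#' @param seed base seed.
#' @param out_dir optional output directory for the CSV + plot.
#' @return A data.frame of class `"recovery_benchmark"`: one row per
#'   grid cell with true and recovered means, bias and RMSE.
#' @export
run_recovery_benchmark <- function(K_values = 1:8, diameters = 55,
                                   sigmas = 5, n_endosomes = 50,
                                   endosomes_per_field = 10, seed = 1,
                                   out_dir = NULL) {
  grid <- expand.grid(K = K_values, diameter = diameters, sigma = sigmas)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    K <- grid$K[g]; diam <- grid$diameter[g]; sg <- grid$sigma[g]
    counts <- numeric(0); diams <- numeric(0)
    true_counts <- numeric(0); true_diams <- numeric(0)
    nfields <- ceiling(n_endosomes / endosomes_per_field)
    for (fld in seq_len(nfields)) {
      res <- .analyze_fixed_field(K, diam, sg, endosomes_per_field,
                                  seed = seed + 1000L * g + fld)
      counts <- c(counts, res$counts)
      diams <- c(diams, res$diams)
      true_counts <- c(true_counts, res$true_counts)
      true_diams <- c(true_diams, res$true_diams)
    }
    rows[[g]] <- data.frame(
      K = K, diameter = diam, sigma = sg,
      n_endosomes = length(counts),
      true_count_mean = mean(true_counts),
      recovered_count_mean = mean(counts),
      count_bias = mean(counts) - mean(true_counts),
      count_rmse = sqrt(mean((counts - true_counts)^2)),
      true_diameter_mean = mean(true_diams),
      recovered_diameter_mean = mean(diams, na.rm = TRUE),
      diameter_bias = mean(diams, na.rm = TRUE) - mean(true_diams),
      diameter_rmse = sqrt(mean((diams - true_diams)^2, na.rm = TRUE)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_benchmark", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "recovery_benchmark.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "recovery_benchmark.png"),
                   width = 600, height = 450)
    graphics::plot(out$K, out$recovered_count_mean,
                   xlab = "true domains per endosome",
                   ylab = "recovered mean count", pch = 19)
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
  }
  out
}

# simulate one field with fixed K and diameter and return per-endosome
# recovered counts/diameters aligned with truth
.analyze_fixed_field <- function(K, diameter, sigma, n_endosomes, seed,
                                 n_frames = 3000) {
  sc <- scene_spec(field_size = c(5000, 5000),
                   n_endosomes = n_endosomes,
                   endosome_radius = c(150, 300),
                   domains_per_endosome = dist_spec("fixed", value = K),
                   domain_diameter = dist_spec("fixed", value = diameter),
                   n_fiducials = 0,
                   n_frames = n_frames)
  em <- emitter_model(sigma = c(ch647 = sigma, ch561 = sigma,
                                ch488 = sigma))
  truth <- generate_scene(sc, seed = seed)
  tabs <- simulate_localizations(truth, em, seed = seed)
  px <- 10
  rspec <- render_spec(px, xlim = c(0, 5000), ylim = c(0, 5000))
  imgs <- lapply(tabs, render_histogram, spec = rspec)
  imgs[["ch488"]] <- median_filter_image(imgs[["ch488"]], 1)
  combined <- combine_channels(imgs)
  endo_mask <- segment_structures(combined, 2, 4)
  dom_mask <- segment_structures(imgs[["ch488"]], 2, 4, max_area = 2000)
  domains <- measure_domains(dom_mask)
  domains <- correct_broadening(domains, blur_sigma = 2, pixel_size = px,
                                loc_sigma = sigma)
  morph <- endosome_domain_stats(endo_mask, domains, dom_mask)
  # align recovered endosome components with true endosomes by centroid
  st <- truth$structures
  te <- st[st$kind == "endosome", ]
  E <- endo_mask$labels
  ne <- endo_mask$n
  counts <- diams <- rep(NA_real_, nrow(te))
  if (ne > 0L) {
    mom <- .component_moments(endo_mask)
    excx <- endo_mask$origin[1] + (mom$col - 0.5) * px
    excy <- endo_mask$origin[2] + (mom$row - 0.5) * px
    for (i in seq_len(nrow(te))) {
      # the component containing the true centre is the endosome body;
      # fall back to the nearest component centroid
      ci <- pmin(nrow(E), pmax(1L, 1L + floor(te$y[i] / px)))
      cj <- pmin(ncol(E), pmax(1L, 1L + floor(te$x[i] / px)))
      j <- E[ci, cj]
      if (j == 0L) {
        d <- sqrt((excx - te$x[i])^2 + (excy - te$y[i])^2)
        j <- which.min(d)
        if (d[j] >= te$radius[i] + 200) j <- 0L
      }
      if (j > 0L) {
        counts[i] <- morph$endosomes$domain_count[j]
        dd <- morph$domains$diameter_corrected[morph$domains$endosome == j]
        diams[i] <- if (length(dd)) mean(dd) else NA_real_
      } else counts[i] <- 0
    }
  } else counts[] <- 0
  tc <- truth$domain_truth$domain_count
  td <- truth$domain_truth$mean_diameter
  list(counts = counts, diams = diams, true_counts = tc, true_diams = td)
}
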