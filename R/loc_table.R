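#' Single-molecule localization table
#'
#' The universal currency of the pipeline: one row per fitted
#' single-molecule detection. Coordinates are stored in nanometres in the
#' camera frame (origin at the upper-left corner of the field, y
#' increasing downward); frames are 0-based.
#'
#' @param frame integer acquisition-frame index (0-based, `>= 0`).
#' @param x,y position in nm; must be finite.
#' @param photons fitted signal amplitude in photons (`> 0`).
#' @param fwhm fitted PSF full width at half maximum in nm (`> 0`).
#' @param channel channel label, a single string.
#' @param pixel_size_nm optical camera pixel size in nm (metadata only;
#'   default 104 nm).
#' @param n_frames total number of acquisition frames, if known.
#' @param struct_id optional integer id of the generating ground-truth
#'   structure (used by the simulator; `NA` for real data).
#' @param metadata optional named list merged into the table metadata.
#'
#' @return A `data.frame` of class `"loc_table"` with columns
#'   `frame, x, y, photons, fwhm` (plus `struct_id` when supplied),
#'   ordered by non-decreasing frame, carrying a `metadata` attribute
#'   (list with at least `channel` and `pixel_size_nm`).
#' @export
loc_table <- function(frame = integer(), x = numeric(), y = numeric(),
                      photons = numeric(), fwhm = numeric(),
                      channel = "ch0", pixel_size_nm = 104,
                      n_frames = NULL, struct_id = NULL,
                      metadata = list()) {
  n <- length(frame)
  stopifnot(length(x) == n, length(y) == n,
            length(photons) == n, length(fwhm) == n)
  frame <- as.integer(frame)
  if (n > 0L) {
    if (anyNA(frame) || any(frame < 0L))
      stop("frame indices must be non-negative integers")
    if (!all(is.finite(x)) || !all(is.finite(y)))
      stop("x and y must be finite")
    if (any(!is.finite(photons)) || any(photons <= 0))
      stop("photons must be positive")
    if (any(!is.finite(fwhm)) || any(fwhm <= 0))
      stop("fwhm must be positive")
  }
  df <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y),
                   photons = as.numeric(photons), fwhm = as.numeric(fwhm))
  if (!is.null(struct_id)) df$struct_id <- as.integer(struct_id)
  if (is.unsorted(df$frame)) df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  md <- list(channel = as.character(channel)[1],
             pixel_size_nm = pixel_size_nm)
  if (!is.null(n_frames)) md$n_frames <- as.integer(n_frames)
  md[names(metadata)] <- metadata
  structure(df, metadata = md, class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<loc_table> %d localizations, channel '%s'\n",
              nrow(x), md$channel))
  if (nrow(x) > 0L)
    cat(sprintf("  frames %d-%d; x [%.1f, %.1f] nm; y [%.1f, %.1f] nm\n",
                min(x$frame), max(x$frame), min(x$x), max(x$x),
                min(x$y), max(x$y)))
  invisible(x)
}

loc_metadata <- function(table) attr(table, "metadata")

`loc_metadata<-` <- function(table, value) {
  attr(table, "metadata") <- value
  table
}

.loc_required_cols <- c("frame", "x", "y", "photons", "fwhm")

#' Read a localization table from a text file
#'
#' Two dialects are supported: `"csv"`, comma-separated with a mandatory
#' header line naming at least `frame, x, y, photons, fwhm`; and
#' `"whitespace"`, a headerless whitespace-delimited table whose columns
#' are mapped positionally to (frame, x, y, photons, fwhm).
#' Gzip-compressed files are accepted by `.gz` extension.
#'
#' @param path path to the file.
#' @param dialect `"csv"` or `"whitespace"`.
#' @param channel channel label to attach; defaults to the file's
#'   `# channel:` header comment (csv dialect) or the base file name.
#' @param units `"nm"` (default) or `"pixel"`; pixel-unit coordinates are
#'   converted to nm using `pixel_size_nm` and the conversion is recorded
#'   in the metadata.
#' @param pixel_size_nm camera pixel size used for unit conversion and
#'   stored as metadata (default 104).
#' @param frame_base 0 or 1: the frame-index base used in the file.
#'   1-based frames are normalized to 0-based on read.
#' @return A [loc_table].
#' @export
read_localizations <- function(path, dialect = c("csv", "whitespace"),
                               channel = NULL, units = c("nm", "pixel"),
                               pixel_size_nm = 104, frame_base = 0) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  header_meta <- list()
  if (dialect == "csv") {
    head_lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                            n = 20L)
    cmt <- grep("^#", head_lines, value = TRUE)
    for (line in cmt) {
      kv <- sub("^#\\s*", "", line)
      m <- regmatches(kv, regexec("^([A-Za-z_.]+)\\s*[:=]\\s*(.*)$", kv))[[1]]
      if (length(m) == 3L) header_meta[[m[2]]] <- m[3]
    }
    df <- utils::read.csv(con, comment.char = "#",
                          stringsAsFactors = FALSE)
    missing_cols <- setdiff(.loc_required_cols, names(df))
    if (length(missing_cols) > 0L)
      stop("missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
  } else {
    df <- utils::read.table(con, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 5L)
      stop("whitespace dialect needs >= 5 columns ",
           "(frame, x, y, photons, fwhm); got ", ncol(df))
    df <- df[, 1:5]
    names(df) <- .loc_required_cols
  }
  for (cn in .loc_required_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric value in column '%s' at data row %d",
                     cn, bad[1]))
      df[[cn]] <- vn
    }
  }
  if (!is.null(header_meta$pixel_size_nm))
    pixel_size_nm <- as.numeric(header_meta$pixel_size_nm)
  if (units == "pixel") {
    df$x <- df$x * pixel_size_nm
    df$y <- df$y * pixel_size_nm
    header_meta$unit_conversion <-
      sprintf("pixel -> nm at %g nm/px", pixel_size_nm)
  }
  if (frame_base == 1) df$frame <- df$frame - 1L
  if (is.null(channel))
    channel <- header_meta$channel %||%
      sub("\\.(csv|txt|tsv)(\\.gz)?$", "", basename(path))
  loc_table(frame = df$frame, x = df$x, y = df$y,
            photons = df$photons, fwhm = df$fwhm,
            channel = channel, pixel_size_nm = pixel_size_nm,
            struct_id = df$struct_id,
            metadata = header_meta[setdiff(names(header_meta),
                                           c("channel", "pixel_size_nm"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a localization table to a text file
#'
#' The native `"csv"` dialect round-trips losslessly with
#' [read_localizations]: a `# channel:` / `# pixel_size_nm:` comment
#' header, then a header line, then one row per localization with full
#' double precision.
#'
#' @param table a [loc_table].
#' @param path output path (`.gz` extension writes gzip).
#' @param dialect `"csv"` or `"whitespace"`.
#' @param allow_empty write a header-only file for an empty table
#'   (default `FALSE`: empty tables are an error).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, dialect = c("csv", "whitespace"),
                                allow_empty = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "loc_table"))
  if (nrow(table) == 0L && !allow_empty)
    stop("refusing to write an empty table (set allow_empty = TRUE)")
  md <- loc_metadata(table)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- as.data.frame(table)
  if (dialect == "csv") {
    writeLines(c(sprintf("# channel: %s", md$channel),
                 sprintf("# pixel_size_nm: %s",
                         format(md$pixel_size_nm, digits = 17))), con)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(format(df[, .loc_required_cols], digits = 17,
                              trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Record-level filter specification
#'
#' Thresholds applied to localization tables before rendering, mirroring
#' standard SMLM post-processing: a closed PSF-width (FWHM) window that
#' rejects out-of-focus fits, and a minimum photon count that rejects dim
#' fits. Typical section-imaging settings are a 250-450 nm FWHM window
#' (250-650 nm for whole cells) with photon thresholds of 3000 (AF647),
#' 1500 (AF568) and 450 (Dronpa, GFP).
#'
#' @param fwhm_min,fwhm_max FWHM window in nm; `fwhm_min < fwhm_max`.
#' @param photon_min minimum photon count (`>= 0`).
#' @param boundary `"inclusive"` (default: records exactly at a threshold
#'   are kept) or `"exclusive"`.
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(fwhm_min = 250, fwhm_max = 450, photon_min = 0,
                        boundary = c("inclusive", "exclusive")) {
  boundary <- match.arg(boundary)
  if (!(fwhm_min < fwhm_max)) stop("fwhm_min must be < fwhm_max")
  if (photon_min < 0) stop("photon_min must be >= 0")
  structure(list(fwhm_min = fwhm_min, fwhm_max = fwhm_max,
                 photon_min = photon_min, boundary = boundary),
            class = "filter_spec")
}

#' Standard per-dye photon thresholds
#'
#' Named vector of the standard amplitude thresholds in photons:
#' 3000 (AF647), 1500 (AF568), 450 (Dronpa and GFP).
#' @export
photon_thresholds <- c(AF647 = 3000, AF568 = 1500, Dronpa = 450, GFP = 450)

#' Filter a localization table on FWHM and photon count
#'
#' Keeps records with `fwhm` inside the window and `photons` at or above
#' the threshold (boundaries per `spec$boundary`; inclusive by default so
#' exactly-at-threshold fits are not silently dropped). The number of
#' records removed by each criterion is attached as the `filter_log`
#' attribute. Filtering is idempotent and an empty result is legal.
#'
#' @param table a [loc_table].
#' @param spec a [filter_spec].
#' @return The filtered [loc_table]; attribute `filter_log` is a named
#'   integer vector `c(fwhm_removed=, photon_removed=, kept=)` counting
#'   each criterion's rejections (records failing both count in both).
#' @export
filter_localizations <- function(table, spec) {
  stopifnot(inherits(table, "loc_table"), inherits(spec, "filter_spec"))
  if (spec$boundary == "inclusive") {
    ok_fwhm <- table$fwhm >= spec$fwhm_min & table$fwhm <= spec$fwhm_max
    ok_phot <- table$photons >= spec$photon_min
  } else {
    ok_fwhm <- table$fwhm > spec$fwhm_min & table$fwhm < spec$fwhm_max
    ok_phot <- table$photons > spec$photon_min
  }
  keep <- ok_fwhm & ok_phot
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  md <- loc_metadata(table)
  md$filter <- unclass(spec)
  out <- structure(out, metadata = md, class = class(table))
  attr(out, "filter_log") <- c(fwhm_removed = sum(!ok_fwhm),
                               photon_removed = sum(!ok_phot),
                               kept = sum(keep))
  out
}

#' Concatenate localization tables of one channel
#'
#' @param ... `loc_table` objects sharing a channel label.
#' @return A single [loc_table] ordered by frame.
#' @export
bind_localizations <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "loc_table")) tabs <- tabs[[1]]
  stopifnot(all(vapply(tabs, inherits, logical(1), "loc_table")))
  chans <- unique(vapply(tabs, function(t) loc_metadata(t)$channel, ""))
  if (length(chans) > 1L)
    stop("cannot concatenate tables from different channels: ",
         paste(chans, collapse = ", "))
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  loc_table(frame = df$frame, x = df$x, y = df$y, photons = df$photons,
            fwhm = df$fwhm, channel = chans,
            struct_id = df$struct_id,
            metadata = loc_metadata(tabs[[1]])[
              setdiff(names(loc_metadata(tabs[[1]])), "channel")])
}
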