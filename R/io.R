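# File formats and display utilities: multi-page TIFF z-stacks, two-column
# wavelength CSVs, endpoint/polygon/window CSVs, histograms, MIPs, and the
# display percentile clip.

#' Read / write a 3-D voxel grid as multi-page TIFF
#'
#' One TIFF page per z-plane, axis order `(z, y, x)`.  Two storage modes:
#' `"uint16"` stores integer values 0-65535 exactly (the native format of
#' 16-bit camera data); `"float32"` stores arbitrary values on an affine
#' scale recorded in a small YAML sidecar (`<path>.meta.yaml`), with
#' quantization about 1e-9 of the data range -- far below any analysis
#' tolerance.  `read_stack()` restores the scale automatically when the
#' sidecar is present.  `NA` values are stored as the minimum and flagged
#' in the sidecar; keep validity masks alongside floating-point maps.
#'
#' @param path TIFF file path.
#' @param grid 3-D numeric array `(nz, ny, nx)`.
#' @param dtype `"uint16"` or `"float32"`.
#' @return `read_stack()` returns the 3-D array; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF stack: ", path)
  meta_path <- paste0(path, ".meta.yaml")
  scaled <- file.exists(meta_path)
  # uint16 pages are read as exact integers; float32 pages are read in
  # normalized [0, 1] form and restored via the sidecar's affine scale
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !scaled)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1L]])
  if (length(shp) != 2L)
    stop("expected single-sample (grayscale) pages in ", path)
  for (p in pages) if (!identical(dim(p), shp))
    stop("inconsistent page shapes in ", path)
  nz <- length(pages)
  out <- array(0, dim = c(nz, shp[1L], shp[2L]))
  for (z in seq_len(nz)) out[z, , ] <- pages[[z]]
  if (scaled) {
    meta <- yaml::read_yaml(meta_path)
    out <- meta$lo + out * (meta$hi - meta$lo)
  }
  out
}

#' @rdname read_stack
#' @export
write_stack <- function(grid, path, dtype = c("uint16", "float32")) {
  dtype <- match.arg(dtype)
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  d <- dim(grid)
  meta_path <- paste0(path, ".meta.yaml")
  if (dtype == "uint16") {
    if (any(is.na(grid))) stop("uint16 stacks cannot carry NA")
    if (any(grid < 0 | grid > 65535) ||
        any(grid != round(grid)))
      stop("uint16 stacks need integer values in 0..65535")
    pages <- lapply(seq_len(d[1L]),
                    function(z) matrix(grid[z, , ], d[2L], d[3L]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
    if (file.exists(meta_path)) unlink(meta_path)
  } else {
    has_na <- any(is.na(grid))
    lo <- min(grid, na.rm = TRUE)
    hi <- max(grid, na.rm = TRUE)
    if (!is.finite(lo) || !is.finite(hi)) stop("no finite values to write")
    if (hi == lo) hi <- lo + 1
    g <- grid
    g[is.na(g)] <- lo
    scaled <- (g - lo) / (hi - lo)
    pages <- lapply(seq_len(d[1L]),
                    function(z) matrix(scaled[z, , ], d[2L], d[3L]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    yaml::write_yaml(list(dtype = "float32", lo = lo, hi = hi,
                          has_na = has_na), meta_path)
  }
  invisible(path)
}

# uint16 pages come back as integers 0..65535 with as.is = TRUE; float32
# pages come back as integers 0..2^32-1, rescaled above via the sidecar.

#' Write / read a spectrum or filter curve as two-column CSV
#'
#' Format: header `wavelength_nm,value`, one row per grid sample,
#' wavelengths ascending (bin centers).  The grid is reconstructed from
#' the uniform wavelength spacing on read.
#'
#' @param spec An [emission_spectrum()].
#' @param filt A [filter_curve()].
#' @param path CSV path.
#' @param kind Optional `"sine"`/`"cosine"` tag applied on read.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "emission_spectrum"))
  .write_wl_csv(spec$grid, spec$intensity, path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  r <- .read_wl_csv(path)
  emission_spectrum(r$grid, r$value)
}

#' @rdname write_spectrum_csv
#' @export
write_filter_csv <- function(filt, path) {
  stopifnot(inherits(filt, "filter_curve"))
  .write_wl_csv(filt$grid, filt$transmission, path)
}

#' @rdname write_spectrum_csv
#' @export
read_filter_csv <- function(path, kind = NULL) {
  r <- .read_wl_csv(path)
  filter_curve(r$grid, r$value, kind = kind)
}

.write_wl_csv <- function(grid, value, path) {
  utils::write.csv(data.frame(wavelength_nm = wavelengths(grid),
                              value = value),
                   path, row.names = FALSE)
  invisible(path)
}

.read_wl_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read curve CSV: ", path)
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("curve CSV needs columns wavelength_nm,value: ", path)
  w <- d$wavelength_nm
  n <- length(w)
  if (n < 2L || is.unsorted(w, strictly = TRUE))
    stop("wavelengths must be ascending: ", path)
  dw <- diff(w)
  if (max(dw) - min(dw) > 1e-6 * mean(dw))
    stop("wavelengths must be uniformly spaced bin centers: ", path)
  delta <- mean(dw)
  grid <- wavelength_grid(w[1L] - delta / 2, w[n] + delta / 2, n)
  list(grid = grid, value = d$value)
}

#' Read / write named phasor endpoints as CSV
#'
#' Format: `name,G,S`.  Used for pure-species positions obtained from
#' solution measurements or simulations.
#'
#' @param points Named list of [phasor_point()]s, or a data frame with
#'   columns `name,G,S`.
#' @param path CSV path.
#' @return `read_endpoints_csv()` returns a named list of phasor points.
#' @export
write_endpoints_csv <- function(points, path) {
  if (is.data.frame(points)) {
    d <- points
  } else {
    d <- data.frame(name = names(points),
                    G = vapply(points, `[[`, numeric(1), 1L),
                    S = vapply(points, `[[`, numeric(1), 2L))
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endpoints_csv
#' @export
read_endpoints_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read endpoints CSV: ", path)
  d <- utils::read.csv(path)
  stopifnot(all(c("name", "G", "S") %in% names(d)))
  out <- lapply(seq_len(nrow(d)), function(i) phasor_point(d$G[i], d$S[i]))
  names(out) <- d$name
  out
}

#' Read / write phasor polygons as CSV
#'
#' Format: `name,vertex_index,G,S`; rows of one name form one polygon in
#' vertex order.  Colors are assigned on read from a default palette and
#' can be overridden afterwards.
#'
#' @param polygons List of [phasor_polygon()]s.
#' @param path CSV path.
#' @return `read_polygons_csv()` returns a list of phasor polygons.
#' @export
write_polygons_csv <- function(polygons, path) {
  rows <- do.call(rbind, lapply(polygons, function(p) {
    data.frame(name = p$name,
               vertex_index = seq_len(nrow(p$vertices)),
               G = p$vertices[, 1L], S = p$vertices[, 2L])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygons_csv
#' @export
read_polygons_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read polygons CSV: ", path)
  d <- utils::read.csv(path)
  stopifnot(all(c("name", "vertex_index", "G", "S") %in% names(d)))
  nms <- unique(d$name)
  pal <- grDevices::hcl.colors(max(length(nms), 2L), "Dark 3")
  out <- lapply(seq_along(nms), function(i) {
    di <- d[d$name == nms[i], ]
    di <- di[order(di$vertex_index), ]
    phasor_polygon(cbind(di$G, di$S), name = nms[i], color = pal[i])
  })
  out
}

#' Read / write wavelength windows as CSV
#'
#' Format: `label,lambda_lo_nm,lambda_hi_nm`, half-open windows
#' `[lo, hi)` in row order.
#'
#' @param windows Data frame with those columns.
#' @param path CSV path.
#' @return `read_windows_csv()` returns the data frame.
#' @export
write_windows_csv <- function(windows, path) {
  windows <- as.data.frame(windows)
  stopifnot(all(c("label", "lambda_lo_nm", "lambda_hi_nm")
                %in% names(windows)))
  utils::write.csv(windows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read windows CSV: ", path)
  d <- utils::read.csv(path)
  stopifnot(all(c("label", "lambda_lo_nm", "lambda_hi_nm") %in% names(d)))
  d
}

#' Write a phasor histogram as CSV / render it as PNG
#'
#' The CSV is the raw `bins x bins` count matrix (rows index G, columns
#' S).  The PNG maps log-scaled counts through a sequential colormap;
#' both are display artifacts, never analysis inputs.
#'
#' @param h A [phasor_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "phasor_histogram"))
  utils::write.table(h$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
write_histogram_png <- function(h, path) {
  stopifnot(inherits(h, "phasor_histogram"))
  v <- log1p(h$counts)
  v <- v / max(v, 1e-12)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256L, "Inferno")) / 255
  idx <- pmin(floor(v * 255) + 1L, 256L)
  img <- array(0, dim = c(h$bins, h$bins, 3L))
  # image rows run top-to-bottom: flip S so +S points up
  for (ch in 1:3)
    img[, , ch] <- t(matrix(pal[ch, idx], h$bins, h$bins))[h$bins:1, ]
  png::writePNG(img, path)
  invisible(path)
}

#' Maximum intensity projection
#'
#' @param grid 3-D array `(nz, ny, nx)`.
#' @param axis Projection axis (default `"z"`).
#' @return 2-D matrix of per-pixel maxima.
#' @export
mip <- function(grid, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  d <- switch(axis, z = 1L, y = 2L, x = 3L)
  apply(grid, setdiff(1:3, d), max)
}

#' Display percentile clip
#'
#' Clips values above the `(100 - upper_percent)` percentile to that
#' percentile, brightening the display of dim structures.  Display-only:
#' never feed the clipped image back into analysis.
#'
#' @param image Numeric array or matrix.
#' @param upper_percent Percent of brightest voxels to clip (default 5;
#'   0 leaves the image unchanged).
#' @return Clipped copy of `image`.
#' @export
percentile_clip <- function(image, upper_percent = 5) {
  stopifnot(is.numeric(image), upper_percent >= 0, upper_percent < 100)
  if (upper_percent == 0) return(image)
  cut <- stats::quantile(image, 1 - upper_percent / 100, na.rm = TRUE,
                         names = FALSE)
  pmin(image, cut)
}

#' Serialize / load a phasor field as TIFF stacks
#'
#' Writes `<stem>_G.tif`, `<stem>_S.tif` (float32 with sidecars) and
#' `<stem>_mask.tif` (uint16, 0/1).
#'
#' @param f A [phasor_field()].
#' @param stem Output path stem.
#' @return `read_phasor_field()` returns a [phasor_field()] (threshold and
#'   offset metadata are not round-tripped through TIFF).
#' @export
write_phasor_field <- function(f, stem) {
  stopifnot(inherits(f, "phasor_field"))
  write_stack(f$G, paste0(stem, "_G.tif"), dtype = "float32")
  write_stack(f$S, paste0(stem, "_S.tif"), dtype = "float32")
  write_stack(array(as.numeric(f$valid), dim = f$shape),
              paste0(stem, "_mask.tif"), dtype = "uint16")
  invisible(stem)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(stem) {
  G <- read_stack(paste0(stem, "_G.tif"))
  S <- read_stack(paste0(stem, "_S.tif"))
  valid <- read_stack(paste0(stem, "_mask.tif")) > 0
  G[!valid] <- NA_real_
  S[!valid] <- NA_real_
  phasor_field(G, S, valid)
}

#' Serialize / load a filter triplet as TIFF stacks
#'
#' Writes `<stem>_sin.tif`, `<stem>_cos.tif`, `<stem>_open.tif` (uint16
#' for integer-valued noisy data, float32 otherwise) plus a sidecar
#' `<stem>_config.yaml` recording grid, camera, and seed.
#'
#' @param t A `triplet_stack`.
#' @param stem Output path stem.
#' @return `read_triplet()` returns a `triplet_stack`.
#' @export
write_triplet <- function(t, stem) {
  stopifnot(is.list(t))
  dt <- if (all(t$I_total == round(t$I_total)) &&
            all(t$I_total >= 0 & t$I_total <= 65535) &&
            all(t$I_sin == round(t$I_sin)) &&
            all(t$I_cos == round(t$I_cos))) "uint16" else "float32"
  write_stack(t$I_sin, paste0(stem, "_sin.tif"), dtype = dt)
  write_stack(t$I_cos, paste0(stem, "_cos.tif"), dtype = dt)
  write_stack(t$I_total, paste0(stem, "_open.tif"), dtype = dt)
  side <- list(
    grid = list(lambda_min = t$grid$lambda_min,
                lambda_max = t$grid$lambda_max,
                n_samples = t$grid$n_samples),
    camera = unclass(t$camera),
    noiseless = isTRUE(t$noiseless))
  yaml::write_yaml(side, paste0(stem, "_config.yaml"))
  invisible(stem)
}

#' @rdname write_triplet
#' @export
read_triplet <- function(stem) {
  side_path <- paste0(stem, "_config.yaml")
  grid <- NULL; camera <- NULL; noiseless <- FALSE
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    grid <- wavelength_grid(side$grid$lambda_min, side$grid$lambda_max,
                            side$grid$n_samples)
    camera <- do.call(camera_model, side$camera)
    noiseless <- isTRUE(side$noiseless)
  }
  structure(list(I_sin = read_stack(paste0(stem, "_sin.tif")),
                 I_cos = read_stack(paste0(stem, "_cos.tif")),
                 I_total = read_stack(paste0(stem, "_open.tif")),
                 camera = camera, grid = grid, noiseless = noiseless),
            class = "triplet_stack")
}
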