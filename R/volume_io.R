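# DICOM series discovery, loading, and gap checking.

#' Per-slice acquisition metadata
#'
#' Validating constructor for the metadata record attached to every slice of
#' a [layered_volume()]. `window_center` / `window_width` are the DICOM VOI
#' parameters driving the sigmoid display transform; `slice_location` (mm) is
#' the spatial Z coordinate used for sorting and gap detection.
#'
#' @param width,height slice size in pixels.
#' @param slice_thickness slice thickness in mm.
#' @param pixel_spacing length-2 numeric, mm per pixel (row, col).
#' @param modality DICOM modality string (e.g. `"MR"`).
#' @param acquisition_date acquisition date string (`YYYYMMDD`).
#' @param bits_allocated stored bit depth (e.g. 16).
#' @param window_center,window_width VOI window center / width in intensity
#'   units; `window_width` must be positive.
#' @param slice_location spatial Z location in mm.
#' @param series_number integer acquisition series id.
#' @param series_description free-text series label.
#' @return A list of class `"SliceMetadata"`.
#' @export
slice_metadata <- function(width, height, slice_thickness = 1,
                           pixel_spacing = c(1, 1), modality = "MR",
                           acquisition_date = "20130101", bits_allocated = 16,
                           window_center, window_width, slice_location,
                           series_number = 1L,
                           series_description = "series") {
  stopifnot(width > 0, height > 0, bits_allocated > 0,
            length(pixel_spacing) == 2, all(pixel_spacing > 0))
  if (!is.finite(window_width) || window_width <= 0)
    stop("window_width must be positive")
  structure(list(width = width, height = height,
                 slice_thickness = slice_thickness,
                 pixel_spacing = pixel_spacing, modality = modality,
                 acquisition_date = acquisition_date,
                 bits_allocated = as.integer(bits_allocated),
                 window_center = window_center, window_width = window_width,
                 slice_location = slice_location,
                 series_number = as.integer(series_number),
                 series_description = series_description),
            class = "SliceMetadata")
}

#' Z-ordered stack of slices in named processing layers
#'
#' The container every pipeline stage works on: a list of named layers
#' (`source`, and after preprocessing `original`, `debiased`, `filtered`,
#' `preprocessed`), each a Z-ordered list of equally sized intensity matrices,
#' plus the per-slice [slice_metadata()]. Z indices are 1-based (`1..z_max`).
#' Layers are append-only: a partial result, once stored, is never
#' overwritten.
#'
#' @param source list of numeric matrices, already Z-sorted.
#' @param metadata list of [slice_metadata()], aligned with `source`.
#' @param missing_slices integer Z indices that were inserted as empty slices.
#' @return An object of class `"LayeredVolume"`.
#' @export
layered_volume <- function(source, metadata, missing_slices = integer(0)) {
  stopifnot(length(source) == length(metadata), length(source) >= 1)
  dims <- vapply(source, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share one width and height")
  structure(list(layers = list(source = source), metadata = metadata,
                 z_max = length(source),
                 missing_slices = as.integer(missing_slices)),
            class = "LayeredVolume")
}

#' @export
print.LayeredVolume <- function(x, ...) {
  d <- dim(x$layers$source[[1]])
  cat(sprintf("LayeredVolume: %d slices of %dx%d, layers: %s\n", x$z_max,
              d[1], d[2], paste(names(x$layers), collapse = ", ")))
  if (length(x$missing_slices))
    cat("  missing slices inserted at Z =",
        paste(x$missing_slices, collapse = ", "), "\n")
  invisible(x)
}

#' Fetch one layer of a volume as a list of slices or a 3D array
#'
#' @param volume a [layered_volume()].
#' @param name layer name.
#' @param as_array return a `(rows, cols, z)` array instead of a list.
#' @return List of matrices, or a 3D numeric array.
#' @export
get_layer <- function(volume, name, as_array = FALSE) {
  if (!name %in% names(volume$layers))
    stop("no layer '", name, "' in volume")
  sl <- volume$layers[[name]]
  if (!as_array) return(sl)
  array(unlist(sl, use.names = FALSE),
        dim = c(dim(sl[[1]]), length(sl)))
}

#' Append a named processing layer to a volume
#'
#' Layers are append-only; storing over an existing name is an error, so a
#' partial result can never be silently overwritten.
#'
#' @inheritParams get_layer
#' @param slices list of matrices (length `z_max`) or a 3D array.
#' @return The volume with the new layer.
#' @export
add_layer <- function(volume, name, slices) {
  if (name %in% names(volume$layers))
    stop("layer '", name, "' already exists (layers are append-only)")
  if (is.array(slices) && length(dim(slices)) == 3)
    slices <- lapply(seq_len(dim(slices)[3]), function(z) slices[, , z])
  stopifnot(length(slices) == volume$z_max)
  volume$layers[[name]] <- slices
  volume
}

dcm_paths <- function(folder) {
  if (!dir.exists(folder)) stop("folder does not exist: ", folder)
  list.files(folder, full.names = TRUE, no.. = TRUE)
}

read_folder_headers <- function(folder) {
  paths <- dcm_paths(folder)
  out <- list()
  for (p in paths) {
    r <- tryCatch(dcm_read_slice(p), error = function(e) {
      warning("skipping unreadable file ", basename(p), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(r)) { r$path <- p; out[[length(out) + 1L]] <- r }
  }
  if (!length(out)) stop("empty folder: no readable DICOM files in ", folder)
  out
}

#' List the acquisition series present in a DICOM folder
#'
#' Reads every DICOM file's header, groups files by `SeriesNumber`, and
#' returns one entry per distinct series with its description, file count,
#' and a representative image (the first file of the series), so that a user
#' can choose which acquisition to segment.
#'
#' @param folder path containing one DICOM file per slice.
#' @return A list of class `"series_listing"`; each element has
#'   `series_number`, `series_description`, `n_files`, and `representative`
#'   (an intensity matrix). Entries are ordered by series number.
#' @export
discover_series <- function(folder) {
  slices <- read_folder_headers(folder)
  sn <- vapply(slices, function(s) s$meta$series_number, integer(1))
  entries <- lapply(sort(unique(sn)), function(k) {
    in_series <- slices[sn == k]
    list(series_number = k,
         series_description = in_series[[1]]$meta$series_description,
         n_files = length(in_series),
         representative = in_series[[1]]$pixels)
  })
  structure(entries, class = "series_listing")
}

#' @export
print.series_listing <- function(x, ...) {
  cat("DICOM acquisition series:\n")
  for (e in x)
    cat(sprintf("  [%d] %-30s (%d files)\n", e$series_number,
                e$series_description, e$n_files))
  invisible(x)
}

#' Load one acquisition series into a layered volume
#'
#' Loads all files of the given series, sorts them ascending by
#' `SliceLocation`, and stores the raw pixel data bit-identically in layer
#' `"source"` with aligned metadata. Loading is invariant to the on-disk file
#' order.
#'
#' @param folder path containing one DICOM file per slice.
#' @param series_number which series to load; defaults to the only series
#'   present (an error if the folder holds several).
#' @return A [layered_volume()].
#' @export
load_series <- function(folder, series_number = NULL) {
  slices <- read_folder_headers(folder)
  sn <- vapply(slices, function(s) s$meta$series_number, integer(1))
  if (is.null(series_number)) {
    u <- unique(sn)
    if (length(u) > 1)
      stop("folder holds series ", paste(sort(u), collapse = ", "),
           "; pick one with series_number=")
    series_number <- u
  }
  slices <- slices[sn == series_number]
  if (!length(slices)) stop("series ", series_number, " not found in ", folder)
  loc <- vapply(slices, function(s) s$meta$slice_location, numeric(1))
  if (anyDuplicated(loc))
    stop("duplicate SliceLocation within series: Z = ",
         paste(unique(loc[duplicated(loc)]), collapse = ", "))
  ord <- order(loc)
  slices <- slices[ord]
  meta <- lapply(slices, function(s) {
    m <- s$meta
    # a header without VOI parameters would leave the sigmoid transform
    # undefined; fall back to the slice's own intensity range
    if (is.na(m$window_center) || is.na(m$window_width) ||
        m$window_width <= 0) {
      rng <- range(s$pixels)
      m$window_center <- mean(rng)
      m$window_width <- max(diff(rng), 1)
      warning("missing WindowCenter/WindowWidth at Z = ", m$slice_location,
              "; using the slice's own intensity range", call. = FALSE)
    }
    do.call(slice_metadata, m)
  })
  layered_volume(lapply(slices, `[[`, "pixels"), meta)
}

#' Detect and pad missing slices
#'
#' Checks that the sorted slice locations are evenly spaced. The common step
#' is inferred as the median of adjacent location differences; a difference
#' above 1.5x the step is a gap. All-zero slices are inserted at the inferred
#' positions (no interpolation is ever attempted), `missing_slices` records
#' their Z indices, and the user is notified via `message()`.
#'
#' @param volume a [layered_volume()] fresh from [load_series()].
#' @return The volume, possibly with empty slices inserted.
#' @export
check_gaps <- function(volume) {
  if (length(volume$layers) > 1)
    stop("check_gaps must run before preprocessing (source layer only)")
  loc <- vapply(volume$metadata, `[[`, numeric(1), "slice_location")
  z <- length(loc)
  if (z < 3) return(volume)
  d <- diff(loc)
  # lower median: robust to outlying wide gaps even when they are half the
  # differences (an even-count plain median would average into a gap)
  step <- unname(stats::quantile(d, 0.5, type = 1))
  if (step <= 0) stop("corrupted series: non-increasing slice locations")
  ratio <- d / step
  if (any(abs(ratio - round(ratio)) > 0.05) || any(round(ratio) < 1))
    stop("corrupted series: no common step divides the slice spacing")
  if (all(round(ratio) == 1)) return(volume)
  shape <- dim(volume$layers$source[[1]])
  src <- list(); meta <- list(); missing <- integer(0)
  push <- function(s, m) {
    src[[length(src) + 1L]] <<- s
    meta[[length(meta) + 1L]] <<- m
  }
  push(volume$layers$source[[1]], volume$metadata[[1]])
  for (i in seq_len(z - 1)) {
    k <- round(ratio[i])
    if (k > 1) for (j in seq_len(k - 1)) {
      m <- volume$metadata[[i]]
      m$slice_location <- loc[i] + j * d[i] / k
      push(matrix(0, shape[1], shape[2]), m)
      missing <- c(missing, length(src))
    }
    push(volume$layers$source[[i + 1]], volume$metadata[[i + 1]])
  }
  message(length(missing), " missing slice(s) detected and inserted empty ",
          "at Z = ", paste(missing, collapse = ", "),
          "; the series may be corrupted -- please verify.")
  layered_volume(src, meta, missing_slices = missing)
}
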