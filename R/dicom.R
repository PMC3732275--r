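# Minimal single-frame DICOM codec (explicit VR, little endian).
#
# Supports exactly what the import module needs: uncompressed monochrome
# 16-bit slices, one file per slice, with the header fields used by the
# pipeline (SeriesNumber, SeriesDescription, SliceLocation, WindowCenter,
# WindowWidth, PixelSpacing, SliceThickness, BitsAllocated, Modality,
# AcquisitionDate, Rows, Columns). Anything else is skipped on read.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"
DCM_IMPL_UID <- "1.2.826.0.1.3680043.9.7433.1"

uint16_to_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

raw_to_uint16 <- function(r) {
  m <- matrix(as.integer(r), nrow = 2)
  m[1, ] + 256L * m[2, ]
}

uint32_to_raw <- function(v) {
  out <- raw(4)
  for (i in 1:4) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# one explicit-VR data element as a raw vector
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    val <- charToRaw(value)
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    if (length(val) %% 2 == 1) val <- c(val, pad)
  } else val <- value
  head_ <- c(uint16_to_raw(group), uint16_to_raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head_, raw(2), uint32_to_raw(length(val)), val)
  } else {
    c(head_, uint16_to_raw(length(val)), val)
  }
}

dcm_ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE,
                                   digits = 10), collapse = "\\")

#' @keywords internal
#' @noRd
dcm_write_slice <- function(path, pixels, meta) {
  px <- as.integer(round(pmin(pmax(t(pixels), 0), 65535)))  # row-major
  body <- c(
    dcm_element(0x0008, 0x0022, "DA", meta$acquisition_date),
    dcm_element(0x0008, 0x0060, "CS", meta$modality),
    dcm_element(0x0008, 0x103E, "LO", meta$series_description),
    dcm_element(0x0018, 0x0050, "DS", dcm_ds(meta$slice_thickness)),
    dcm_element(0x0020, 0x0011, "IS", format(meta$series_number)),
    dcm_element(0x0020, 0x1041, "DS", dcm_ds(meta$slice_location)),
    dcm_element(0x0028, 0x0002, "US", uint16_to_raw(1L)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", uint16_to_raw(nrow(pixels))),
    dcm_element(0x0028, 0x0011, "US", uint16_to_raw(ncol(pixels))),
    dcm_element(0x0028, 0x0030, "DS", dcm_ds(meta$pixel_spacing)),
    dcm_element(0x0028, 0x0100, "US", uint16_to_raw(meta$bits_allocated)),
    dcm_element(0x0028, 0x0101, "US", uint16_to_raw(meta$bits_allocated)),
    dcm_element(0x0028, 0x0102, "US", uint16_to_raw(meta$bits_allocated - 1L)),
    dcm_element(0x0028, 0x0103, "US", uint16_to_raw(0L)),
    dcm_element(0x0028, 0x1050, "DS", dcm_ds(meta$window_center)),
    dcm_element(0x0028, 0x1051, "DS", dcm_ds(meta$window_width)),
    dcm_element(0x7FE0, 0x0010, "OW", uint16_to_raw(px))
  )
  meta_grp <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", DCM_SOP_MR),
    dcm_element(0x0002, 0x0003, "UI",
                paste0(DCM_IMPL_UID, ".", abs(meta$series_number), ".",
                       format(round(meta$slice_location * 1000)))),
    dcm_element(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", DCM_IMPL_UID)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(0x0002, 0x0000, "UL", uint32_to_raw(length(meta_grp))),
           con)
  writeBin(meta_grp, con)
  writeBin(body, con)
  invisible(path)
}

# Parse one DICOM file; returns list(meta = SliceMetadata-ish list,
# pixels = matrix) or signals an error for unreadable files.
#' @keywords internal
#' @noRd
dcm_read_slice <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 160 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  fields <- list()
  pixels_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(at) as.integer(buf[at]) + 256L * as.integer(buf[at + 1L])
  u32 <- function(at) sum(as.numeric(buf[at + 0:3]) * 256^(0:3))
  while (pos + 8L <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) DICOM encoding in ", path)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (vstart + len - 1L > length(buf)) stop("truncated DICOM file: ", path)
    val <- if (len > 0) buf[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    if (key == "7FE0,0010") pixels_raw <- val
    else fields[[key]] <- val
    pos <- vstart + len
  }
  str_of <- function(key) {
    v <- fields[[key]]
    if (is.null(v)) return(NA_character_)
    trimws(rawToChar(v[v != as.raw(0L)]))
  }
  num_of <- function(key) {
    s <- str_of(key)
    if (is.na(s)) return(NA_real_)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us_of <- function(key) {
    v <- fields[[key]]
    if (is.null(v)) return(NA_integer_)
    raw_to_uint16(v)[1]
  }
  rows <- us_of("0028,0010"); cols <- us_of("0028,0011")
  if (is.na(rows) || is.na(cols) || is.null(pixels_raw))
    stop("DICOM file without image data: ", path)
  px <- matrix(raw_to_uint16(pixels_raw), nrow = rows, ncol = cols,
               byrow = TRUE)
  meta <- list(
    width = cols, height = rows,
    slice_thickness = num_of("0018,0050")[1],
    pixel_spacing = num_of("0028,0030"),
    modality = str_of("0008,0060"),
    acquisition_date = str_of("0008,0022"),
    bits_allocated = us_of("0028,0100"),
    window_center = num_of("0028,1050")[1],
    window_width = num_of("0028,1051")[1],
    slice_location = num_of("0020,1041")[1],
    series_number = as.integer(num_of("0020,0011")[1]),
    series_description = str_of("0008,103E")
  )
  list(meta = meta, pixels = px)
}
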