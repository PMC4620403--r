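# Minimal DICOM support: uncompressed explicit-VR little-endian monochrome
# images, one file per slice. Only the tags this tool needs are handled
# (InstanceNumber, Rows/Columns, PixelSpacing, bit depth, PixelData); other
# elements are skipped. Enough for LGE-CMR short-axis exports of that flavor
# and for writing synthetic phantom series.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_element <- function(group, element, vr, value_raw) {
  hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- writeBin(length(value_raw), raw(), size = 4, endian = "little")
    c(hdr, charToRaw(vr), as.raw(c(0, 0)), len, value_raw)
  } else {
    len <- writeBin(length(value_raw), raw(), size = 2, endian = "little")
    c(hdr, charToRaw(vr), len, value_raw)
  }
}

dcm_str_element <- function(group, element, vr, s, pad = as.raw(0x20)) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1) v <- c(v, pad)  # UI pads with NUL, text VRs with space
  dcm_element(group, element, vr, v)
}

dcm_us_element <- function(group, element, v) {
  dcm_element(group, element, "US", writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

#' Write one grayscale slice as a DICOM file
#'
#' Explicit-VR little-endian, MONOCHROME2, 16 bits allocated.
#'
#' @param si non-negative integer-valued matrix; values must fit
#'   `bits_stored` bits.
#' @param path output file.
#' @param instance_number DICOM InstanceNumber (slice ordering key).
#' @param pixel_spacing_mm `(row, col)` spacing in mm.
#' @param bits_stored stored bit depth (default 12).
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(si, path, instance_number = 1L,
                              pixel_spacing_mm = c(1, 1), bits_stored = 12L) {
  si <- round(as.matrix(si))
  if (any(si < 0) || any(si >= 2^bits_stored)) {
    stop(sprintf("signal intensities must lie in [0, %d)", 2^bits_stored))
  }
  ts <- dcm_str_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE, pad = as.raw(0))
  meta <- c(
    dcm_element(0x0002, 0x0000, "UL",
                writeBin(length(ts), raw(), size = 4, endian = "little")),
    ts
  )
  body <- c(
    dcm_str_element(0x0008, 0x0060, "CS", "MR"),
    dcm_str_element(0x0020, 0x0013, "IS", as.character(as.integer(instance_number))),
    dcm_us_element(0x0028, 0x0002, 1L),
    dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us_element(0x0028, 0x0010, nrow(si)),
    dcm_us_element(0x0028, 0x0011, ncol(si)),
    dcm_str_element(0x0028, 0x0030, "DS",
                    paste(format(pixel_spacing_mm, trim = TRUE), collapse = "\\")),
    dcm_us_element(0x0028, 0x0100, 16L),
    dcm_us_element(0x0028, 0x0101, as.integer(bits_stored)),
    dcm_us_element(0x0028, 0x0102, as.integer(bits_stored) - 1L),
    dcm_us_element(0x0028, 0x0103, 0L),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(t(si)), raw(), size = 2, endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

#' Read one DICOM slice
#'
#' Supports uncompressed explicit-VR little-endian monochrome files only;
#' other transfer syntaxes raise an error. A warning is emitted when pixel
#' values exceed the declared stored bit depth.
#'
#' @param path DICOM file.
#' @return list with `si` (matrix), `instance_number`, `pixel_spacing_mm`,
#'   `bits_stored`.
#' @export
read_dicom_slice <- function(path) {
  buf <- readBin(path, raw(), n = file.info(path)$size)
  pos <- 1L
  if (length(buf) >= 132L && rawToChar(buf[129:132]) == "DICM") pos <- 133L

  u16 <- function(i) readBin(buf[i:(i + 1)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(buf[i:(i + 3)], "integer", size = 4, endian = "little")

  tags <- list()
  while (pos + 7L <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported DICOM encoding (implicit VR or non-little-endian)")
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_at <- pos + 8L
    }
    if (len < 0 || val_at + len - 1L > length(buf)) stop("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, element)
    if (key == "0002,0010") {
      v <- buf[val_at:(val_at + len - 1L)]
      ts <- trimws(rawToChar(v[v != as.raw(0)]))  # strip NUL padding
      if (ts != TS_EXPLICIT_LE) {
        stop(sprintf("unsupported transfer syntax: %s", ts))
      }
    }
    if (key %in% c("0020,0013", "0028,0010", "0028,0011", "0028,0030",
                   "0028,0100", "0028,0101", "7fe0,0010")) {
      tags[[key]] <- list(vr = vr, raw = buf[val_at:(val_at + len - 1L)])
    }
    pos <- val_at + len
    if (key == "7fe0,0010") break
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop(sprintf("DICOM file lacks %s (%s)", what, key))
    tags[[key]]
  }
  as_u16s <- function(x) readBin(x$raw, "integer", n = length(x$raw) / 2,
                                 size = 2, signed = FALSE, endian = "little")
  rows <- as_u16s(need("0028,0010", "Rows"))[1]
  cols <- as_u16s(need("0028,0011", "Columns"))[1]
  bits_alloc <- as_u16s(need("0028,0100", "BitsAllocated"))[1]
  if (bits_alloc != 16L) stop("only 16 bits-allocated pixel data is supported")
  bits_stored <- if (!is.null(tags[["0028,0101"]])) {
    as_u16s(tags[["0028,0101"]])[1]
  } else 16L
  inst <- if (!is.null(tags[["0020,0013"]])) {
    as.integer(trimws(rawToChar(tags[["0020,0013"]]$raw)))
  } else NA_integer_
  spacing <- if (!is.null(tags[["0028,0030"]])) {
    as.numeric(strsplit(trimws(rawToChar(tags[["0028,0030"]]$raw)), "\\\\")[[1]])
  } else c(1, 1)

  px <- need("7fe0,0010", "PixelData")
  vals <- as_u16s(px)
  if (length(vals) < rows * cols) stop("PixelData shorter than Rows x Columns")
  si <- matrix(vals[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  if (any(si >= 2^bits_stored)) {
    warning(sprintf("pixel values exceed the declared %d-bit depth", bits_stored),
            call. = FALSE)
  }
  list(si = si, instance_number = inst,
       pixel_spacing_mm = spacing, bits_stored = bits_stored)
}

#' Read a DICOM series directory
#'
#' Reads every regular file in `dir` as a DICOM slice and orders the result
#' by InstanceNumber (falling back to file-name order when absent).
#'
#' @param dir directory containing one DICOM file per slice.
#' @return list of slices as returned by [read_dicom_slice()], ordered.
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  has_dicm <- vapply(files, function(f) {
    if (file.info(f)$size < 132) return(FALSE)
    hdr <- readBin(f, raw(), n = 132)
    rawToChar(hdr[129:132]) == "DICM"
  }, logical(1))
  files <- files[has_dicm | grepl("\\.dcm$", files, ignore.case = TRUE)]
  if (length(files) == 0L) stop(sprintf("no DICOM files in directory: %s", dir))
  slices <- lapply(files, read_dicom_slice)
  inst <- vapply(slices, function(s) s$instance_number, integer(1))
  if (!anyNA(inst)) slices <- slices[order(inst)]
  slices
}
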