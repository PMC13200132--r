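# Minimal single-frame DICOM support. Only what orbital MR exports need:
# explicit-VR little-endian Part 10 files, monochrome, one frame, with
# Rows/Columns/BitsAllocated/PixelRepresentation and optional
# RescaleSlope/RescaleIntercept honoured. No R DICOM reader is imported, so
# the byte-level parsing lives here; everything beyond this subset is
# rejected loudly rather than misread.

dcm_tag <- function(group, element) sprintf("%04x,%04x", group, element)

read_uint <- function(raw, signed = FALSE) {
  n <- length(raw)
  val <- sum(as.numeric(raw) * 256^(seq_len(n) - 1))  # little endian
  if (signed && val >= 256^n / 2) val <- val - 256^n
  val
}

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path, call. = FALSE)

  elems <- list()
  repeat {
    hdr <- readBin(con, "raw", n = 8L)
    if (length(hdr) < 8L) break
    group <- read_uint(hdr[1:2]); element <- read_uint(hdr[3:4])
    vr <- rawToChar(hdr[5:6])
    if (vr %in% .dcm_long_vrs) {
      len <- read_uint(readBin(con, "raw", n = 4L))
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- read_uint(hdr[7:8])
    } else {
      stop("implicit-VR or unsupported DICOM encoding in ", path, call. = FALSE)
    }
    if (len == 0xFFFFFFFF)
      stop("undefined-length DICOM elements are not supported", call. = FALSE)
    body <- readBin(con, "raw", n = len)
    elems[[dcm_tag(group, element)]] <- list(vr = vr, bytes = body)
  }

  get_num <- function(tag, default = NULL) {
    e <- elems[[tag]]
    if (is.null(e)) return(default)
    if (e$vr %in% c("US", "SS"))
      read_uint(e$bytes, signed = e$vr == "SS")
    else as.numeric(trimws(rawToChar(e$bytes)))  # DS/IS
  }

  rows <- get_num(dcm_tag(0x0028, 0x0010))
  cols <- get_num(dcm_tag(0x0028, 0x0011))
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns", call. = FALSE)
  frames <- get_num(dcm_tag(0x0028, 0x0008), default = 1)
  if (frames != 1) stop("multi-frame DICOM is not supported", call. = FALSE)
  spp <- get_num(dcm_tag(0x0028, 0x0002), default = 1)
  if (spp != 1) stop("RGB input not supported; supply a grayscale raster", call. = FALSE)
  bits <- get_num(dcm_tag(0x0028, 0x0100), default = 16)
  if (!bits %in% c(8, 16)) stop("only 8/16-bit DICOM pixel data supported", call. = FALSE)
  signed <- get_num(dcm_tag(0x0028, 0x0103), default = 0) == 1
  slope <- get_num(dcm_tag(0x0028, 0x1053), default = 1)
  intercept <- get_num(dcm_tag(0x0028, 0x1052), default = 0)

  pd <- elems[[dcm_tag(0x7fe0, 0x0010)]]
  if (is.null(pd)) stop("DICOM file lacks PixelData", call. = FALSE)
  nbytes <- bits / 8
  need <- rows * cols * nbytes
  if (length(pd$bytes) < need) stop("truncated DICOM PixelData", call. = FALSE)
  b <- matrix(as.numeric(pd$bytes[seq_len(need)]), nrow = nbytes)
  v <- colSums(b * 256^(seq_len(nbytes) - 1))
  if (signed) v <- ifelse(v >= 256^nbytes / 2, v - 256^nbytes, v)
  # PixelData is row-major (rows of the image stored consecutively)
  matrix(slope * v + intercept, nrow = rows, ncol = cols, byrow = TRUE)
}

# Writer used to build test fixtures and round-trip checks; explicit-VR
# little endian, unsigned 16-bit monochrome.
write_dicom_gray <- function(pixels, path, slope = 1, intercept = 0) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels < 65536))
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  elem_short <- function(group, element, vr, bytes) {
    if (length(bytes) %% 2L) bytes <- c(bytes, as.raw(if (vr == "UI") 0 else 32))
    c(u16(group), u16(element), charToRaw(vr), u16(length(bytes)), bytes)
  }
  elem_long <- function(group, element, vr, bytes) {
    len <- length(bytes)
    c(u16(group), u16(element), charToRaw(vr), as.raw(c(0, 0)),
      as.raw(c(len %% 256, len %/% 256 %% 256, len %/% 65536 %% 256, len %/% 16777216)),
      bytes)
  }
  str_bytes <- function(s) charToRaw(s)
  v <- as.integer(round(t(pixels)))  # row-major order
  pix <- as.raw(rbind(v %% 256L, v %/% 256L))
  body <- c(
    elem_short(0x0008, 0x0060, "CS", str_bytes("MR")),
    elem_short(0x0028, 0x0002, "US", u16(1)),
    elem_short(0x0028, 0x0004, "CS", str_bytes("MONOCHROME2")),
    elem_short(0x0028, 0x0010, "US", u16(nrow(pixels))),
    elem_short(0x0028, 0x0011, "US", u16(ncol(pixels))),
    elem_short(0x0028, 0x0100, "US", u16(16)),
    elem_short(0x0028, 0x0101, "US", u16(16)),
    elem_short(0x0028, 0x0102, "US", u16(15)),
    elem_short(0x0028, 0x0103, "US", u16(0)),
    elem_short(0x0028, 0x1052, "DS", str_bytes(format(intercept))),
    elem_short(0x0028, 0x1053, "DS", str_bytes(format(slope))),
    elem_long(0x7fe0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
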