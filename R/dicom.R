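## Minimal DICOM Part-10 reader/writer (Explicit VR Little Endian,
## uncompressed, single-frame grayscale). Covers the attributes a cine
## cardiac-MR pipeline needs: geometry (ImagePositionPatient,
## ImageOrientationPatient, PixelSpacing), cine ordering (TriggerTime,
## InstanceNumber), identification UIDs and 16-bit PixelData. The phantom
## writer emits files through this module so the reader is exercised against
## the real on-disk format (cross-checked against pydicom in the test suite).

.dcm_explicit_le <- "1.2.840.10008.1.2.1"
.dcm_sc_class <- "1.2.840.10008.5.1.4.1.1.7"     # secondary capture

.tag_bytes <- function(group, elem) {
  c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"))
}

.pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

## one explicit-VR element
.dcm_element <- function(group, elem, vr, value) {
  val <- switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    OB = as.raw(value),
    OW = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UI = .pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    DS = .pad_even(charToRaw(paste(sprintf("%.10g", value), collapse = "\\"))),
    IS = .pad_even(charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\"))),
    .pad_even(charToRaw(paste(value, collapse = "\\"))))   # CS/LO/SH/...
  long <- vr %in% c("OB", "OW", "SQ", "UN", "UT")
  hdr <- c(.tag_bytes(group, elem), charToRaw(vr))
  if (long) {
    hdr <- c(hdr, as.raw(c(0, 0)),
             writeBin(length(val), raw(), size = 4, endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(length(val), raw(), size = 2, endian = "little"))
  }
  c(hdr, val)
}

#' Write a single-frame grayscale DICOM file
#'
#' Emits an uncompressed Explicit-VR little-endian Part-10 file with the
#' spatial metadata needed for 3D reconstruction. Pixels are written as
#' unsigned 16-bit; values are clamped to [0, 65535] and rounded.
#'
#' @param path output file.
#' @param pixels numeric matrix (rows x cols), row = image Y (top to
#'   bottom), col = image X.
#' @param pixel_spacing length-2 (row, col) spacing in mm.
#' @param image_position length-3 ImagePositionPatient (mm): patient-space
#'   coordinates of the centre of the first (top-left) pixel.
#' @param image_orientation length-6 direction cosines (row direction then
#'   column direction).
#' @param instance_number integer InstanceNumber.
#' @param trigger_time cine trigger time in ms (optional).
#' @param series_uid,sop_uid,study_uid DICOM UIDs (deterministic defaults).
#' @param series_description free-text label (e.g. "short_axis").
#' @return `path`, invisibly.
#' @export
write_dicom_frame <- function(path, pixels, pixel_spacing, image_position,
                              image_orientation = c(1, 0, 0, 0, 1, 0),
                              instance_number = 1L, trigger_time = NULL,
                              series_uid = "2.25.1", sop_uid = "2.25.1.1",
                              study_uid = "2.25.0",
                              series_description = "cine") {
  pixels <- round(pmin(pmax(pixels, 0), 65535))
  ## PixelData is row-major in DICOM: all columns of row 1, then row 2, ...
  px <- as.integer(t(pixels))
  ds <- c(
    .dcm_element(0x0008, 0x0016, "UI", .dcm_sc_class),
    .dcm_element(0x0008, 0x0018, "UI", sop_uid),
    .dcm_element(0x0008, 0x0060, "CS", "MR"),
    .dcm_element(0x0008, 0x103E, "LO", series_description),
    if (!is.null(trigger_time)) .dcm_element(0x0018, 0x1060, "DS", trigger_time),
    .dcm_element(0x0020, 0x000D, "UI", study_uid),
    .dcm_element(0x0020, 0x000E, "UI", series_uid),
    .dcm_element(0x0020, 0x0013, "IS", instance_number),
    .dcm_element(0x0020, 0x0032, "DS", image_position),
    .dcm_element(0x0020, 0x0037, "DS", image_orientation),
    .dcm_element(0x0028, 0x0002, "US", 1L),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", nrow(pixels)),
    .dcm_element(0x0028, 0x0011, "US", ncol(pixels)),
    .dcm_element(0x0028, 0x0030, "DS", pixel_spacing),
    .dcm_element(0x0028, 0x0100, "US", 16L),
    .dcm_element(0x0028, 0x0101, "US", 16L),
    .dcm_element(0x0028, 0x0102, "US", 15L),
    .dcm_element(0x0028, 0x0103, "US", 0L),
    .dcm_element(0x7FE0, 0x0010, "OW", px))
  meta_body <- c(
    .dcm_element(0x0002, 0x0001, "OB", c(0, 1)),
    .dcm_element(0x0002, 0x0002, "UI", .dcm_sc_class),
    .dcm_element(0x0002, 0x0003, "UI", sop_uid),
    .dcm_element(0x0002, 0x0010, "UI", .dcm_explicit_le),
    .dcm_element(0x0002, 0x0012, "UI", "2.25.999"))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

.read_u16 <- function(r, i) readBin(r[i:(i + 1)], "integer", size = 2,
                                    endian = "little", signed = FALSE)
.read_u32 <- function(r, i) readBin(r[i:(i + 3)], "integer", size = 4,
                                    endian = "little")

#' Read a DICOM file (Explicit VR Little Endian)
#'
#' Parses the attributes used by the cine pipeline and returns them in a
#' named list; unknown tags are skipped. Compressed or non-explicit-LE
#' transfer syntaxes raise an error (see the DICOM library caveat in the
#' package docs).
#'
#' @param path DICOM file.
#' @return list with elements `pixels` (rows x cols matrix), `rows`, `cols`,
#'   `pixel_spacing`, `image_position`, `image_orientation`,
#'   `instance_number`, `trigger_time`, `series_uid`, `study_uid`,
#'   `series_description`, `modality`.
#' @export
read_dicom_frame <- function(path) {
  r <- readBin(path, raw(), n = file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stopf("%s is not a DICOM Part-10 file", path)
  i <- 133L
  out <- list()
  ts <- NULL
  str_of <- function(v) {
    while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
      v <- v[-length(v)]
    rawToChar(v)
  }
  nums_of <- function(v) as.numeric(strsplit(str_of(v), "\\\\")[[1]])
  while (i + 7 <= length(r)) {
    group <- .read_u16(r, i); elem <- .read_u16(r, i + 2)
    if (group > 0x0002 && !is.null(ts) && ts != .dcm_explicit_le)
      stopf("unsupported transfer syntax %s (only Explicit VR Little Endian)", ts)
    vr <- rawToChar(r[(i + 4):(i + 5)])
    if (grepl("^[A-Z][A-Z]$", vr)) {
      if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
        len <- .read_u32(r, i + 8); vstart <- i + 12L
      } else {
        len <- .read_u16(r, i + 6); vstart <- i + 8L
      }
    } else stopf("non-explicit-VR element at offset %d in %s", i, path)
    if (len < 0 || vstart + len - 1 > length(r))
      stopf("truncated DICOM element in %s", path)
    val <- if (len > 0) r[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    switch(key,
      "0002,0010" = ts <- str_of(val),
      "0008,0060" = out$modality <- str_of(val),
      "0008,103E" = out$series_description <- str_of(val),
      "0018,1060" = out$trigger_time <- nums_of(val),
      "0020,000D" = out$study_uid <- str_of(val),
      "0020,000E" = out$series_uid <- str_of(val),
      "0020,0013" = out$instance_number <- as.integer(nums_of(val)),
      "0020,0032" = out$image_position <- nums_of(val),
      "0020,0037" = out$image_orientation <- nums_of(val),
      "0028,0010" = out$rows <- .read_u16(val, 1),
      "0028,0011" = out$cols <- .read_u16(val, 1),
      "0028,0030" = out$pixel_spacing <- nums_of(val),
      "7FE0,0010" = out$pixel_raw <- val,
      NULL)
    i <- vstart + len
  }
  if (!is.null(out$pixel_raw)) {
    if (is.null(out$rows) || is.null(out$cols))
      stopf("PixelData without Rows/Columns in %s", path)
    px <- readBin(out$pixel_raw, "integer", n = out$rows * out$cols,
                  size = 2, endian = "little", signed = FALSE)
    out$pixels <- matrix(px, nrow = out$rows, ncol = out$cols, byrow = TRUE)
    out$pixel_raw <- NULL
  }
  out
}
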