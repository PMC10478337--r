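# Minimal explicit-VR little-endian DICOM writer used to build test fixtures
# in code (independent of the package's reader).

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else v <- value
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(dcm_u16(group), dcm_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      dcm_u32(length(v)), v)
  } else {
    c(dcm_u16(group), dcm_u16(elem), charToRaw(vr), dcm_u16(length(v)), v)
  }
}

# write one CT slice; pixels: integer matrix (stored values), nc x nr
write_test_dicom <- function(path, pixels, slope = 1, intercept = -1024,
                             pixel_spacing = c(1, 1), thickness = 5,
                             instance = 1, zpos = NA,
                             series_uid = "1.2.3.4.5") {
  nr <- ncol(pixels); nc <- nrow(pixels)  # rows x cols in DICOM terms
  body <- c(
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    if (!is.na(zpos))
      dcm_element(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", zpos)),
    dcm_element(0x0018, 0x0050, "DS", as.character(thickness)),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(nr)),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(nc)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(1)),
    dcm_element(0x0028, 0x1052, "DS", as.character(intercept)),
    dcm_element(0x0028, 0x1053, "DS", as.character(slope)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                         endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# small deterministic phantom shared across tests
test_phantom <- function(seed = 5, distractors = 3) {
  generate_phantom(phantom_spec(seed = seed, distractor_count = distractors))
}
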