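# Minimal DICOM series reader: uncompressed little-endian explicit or
# implicit VR, enough for CT input (pixel data, rescale slope/intercept,
# pixel spacing, slice ordering and spacing, series consistency). Compressed
# transfer syntaxes are rejected with a clear error.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
read_u32 <- function(raw, off) {
  as.numeric(read_u16(raw, off)) + 65536 * read_u16(raw, off + 2)
}

# parse one file, returning the tags of interest
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  off <- 0L
  explicit <- TRUE
  ts <- DICOM_EXPLICIT_LE
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    off <- 132L
    # file meta group (0002,xxxx) is always explicit little endian
    meta <- parse_elements(raw, off, explicit = TRUE, stop_after_group2 = TRUE)
    ts <- trimws(meta$elements[["0002,0010"]] %||% DICOM_EXPLICIT_LE)
    ts <- gsub("[^0-9.]", "", ts)
    off <- meta$offset
    if (!ts %in% c(DICOM_EXPLICIT_LE, DICOM_IMPLICIT_LE))
      stop("unsupported DICOM transfer syntax '", ts, "' in ", basename(path),
           " (only uncompressed little endian is supported)")
    explicit <- identical(ts, DICOM_EXPLICIT_LE)
  } else {
    # headerless file: guess explicit by checking for a plausible VR
    vr <- tryCatch(rawToChar(raw[5:6]), error = function(e) "")
    explicit <- vr %in% c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                          "LT","OB","OW","PN","SH","SL","SQ","SS","ST","TM","UI",
                          "UL","UN","US","UT")
  }
  parsed <- parse_elements(raw, off, explicit = explicit)
  parsed$elements
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_elements <- function(raw, off, explicit, stop_after_group2 = FALSE) {
  n <- length(raw)
  els <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= n) {
    group <- read_u16(raw, off)
    elem <- read_u16(raw, off + 2)
    if (stop_after_group2 && group != 2L) break
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% long_vrs) {
        len <- read_u32(raw, off + 8)
        hdr <- 12L
      } else {
        len <- read_u16(raw, off + 6)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- read_u32(raw, off + 4)
      hdr <- 8L
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (len == 4294967295) {  # undefined length (sequence): skip to delimiter
      off <- skip_undefined(raw, off + hdr)
      next
    }
    val_off <- off + hdr
    if (val_off + len > n) break
    body <- raw[(val_off + 1):(val_off + len)]
    els[[tag]] <- decode_element(tag, vr, body)
    off <- val_off + as.integer(len)
  }
  list(elements = els, offset = off)
}

skip_undefined <- function(raw, off) {
  n <- length(raw)
  while (off + 8 <= n) {
    group <- read_u16(raw, off)
    elem <- read_u16(raw, off + 2)
    len <- read_u32(raw, off + 4)
    if (group == 0xFFFE && elem == 0xE0DD) return(off + 8L)
    off <- off + 8L + if (len == 4294967295) 0L else as.integer(len)
  }
  n
}

decode_element <- function(tag, vr, body) {
  if (tag == "7fe0,0010") return(body)  # raw pixel data
  us_tags <- c("0028,0010", "0028,0011", "0028,0100", "0028,0103")
  if (tag %in% us_tags) {
    if (!is.na(vr) && vr %in% c("US", "SS")) return(read_u16(body, 0))
    if (is.na(vr)) return(read_u16(body, 0))
  }
  rawToChar(body[body != as.raw(0)])  # strings may be NUL-padded
}

dicom_numeric <- function(els, tag) {
  v <- els[[tag]]
  if (is.null(v)) return(NULL)
  if (is.numeric(v)) return(v)
  out <- suppressWarnings(as.numeric(strsplit(trimws(gsub(" ", "", v)),
                                              "\\\\")[[1]]))
  if (any(is.na(out))) NULL else out
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir)
  parsed <- lapply(files, function(f) {
    tryCatch(parse_dicom_file(f), error = function(e) {
      stop("failed to parse DICOM file ", basename(f), ": ",
           conditionMessage(e))
    })
  })
  has_pix <- vapply(parsed, function(p) !is.null(p[["7fe0,0010"]]), logical(1))
  parsed <- parsed[has_pix]; files <- files[has_pix]
  if (!length(parsed)) stop("no DICOM files with pixel data in ", dir)

  series <- vapply(parsed, function(p)
    trimws(gsub(" ", "", p[["0020,000e"]] %||% "")), character(1))
  if (length(unique(series[series != ""])) > 1)
    stop("directory contains a mixed DICOM series: ",
         paste(unique(series[series != ""]), collapse = ", "))

  rows <- vapply(parsed, function(p) p[["0028,0010"]] %||% NA_integer_, numeric(1))
  cols <- vapply(parsed, function(p) p[["0028,0011"]] %||% NA_integer_, numeric(1))
  if (any(is.na(rows)) || any(is.na(cols)))
    stop("incomplete DICOM series: missing Rows/Columns")
  if (length(unique(rows)) > 1 || length(unique(cols)) > 1)
    stop("incomplete DICOM series: inconsistent slice dimensions")

  zpos <- vapply(parsed, function(p) {
    ipp <- dicom_numeric(p, "0020,0032")
    if (!is.null(ipp) && length(ipp) >= 3) ipp[3] else NA_real_
  }, numeric(1))
  inst <- vapply(parsed, function(p) {
    v <- dicom_numeric(p, "0020,0013")
    if (!is.null(v)) v[1] else NA_real_
  }, numeric(1))
  ord <- if (!any(is.na(zpos))) order(zpos) else order(inst)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  nr <- rows[1]; nc <- cols[1]
  nz <- length(parsed)
  vox <- array(0, c(nc, nr, nz))
  for (s in seq_len(nz)) {
    p <- parsed[[s]]
    bits <- p[["0028,0100"]] %||% 16
    signed <- (p[["0028,0103"]] %||% 1) == 1
    body <- p[["7fe0,0010"]]
    if (bits == 16) {
      stored <- readBin(body, "integer", n = nr * nc, size = 2,
                        signed = signed, endian = "little")
      if (!signed) stored[stored < 0] <- stored[stored < 0] + 65536
    } else if (bits == 8) {
      stored <- as.integer(body[seq_len(nr * nc)])
    } else stop("unsupported BitsAllocated: ", bits)
    slope <- (dicom_numeric(p, "0028,1053") %||% 1)[1]
    icpt <- (dicom_numeric(p, "0028,1052") %||% 0)[1]
    vox[, , s] <- matrix(stored * slope + icpt, nrow = nc)
  }

  ps <- dicom_numeric(parsed[[1]], "0028,0030") %||% c(1, 1)
  dz <- if (nz >= 2 && !any(is.na(zpos))) mean(abs(diff(zpos)))
        else (dicom_numeric(parsed[[1]], "0018,0088") %||%
              dicom_numeric(parsed[[1]], "0018,0050") %||% 1)[1]
  if (!is.finite(dz) || dz <= 0) dz <- 1
  hu_volume(vox, spacing = c(ps[min(2, length(ps))], ps[1], dz))
}
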