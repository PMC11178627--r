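# Construct minimal single-frame DICOM files byte by byte (explicit VR
# little endian), independently of the package's parser.

dcmElem <- function(group, elem, vr, valueRaw) {
  if (length(valueRaw) %% 2L == 1L)
    valueRaw <- c(valueRaw, as.raw(if (vr %in% c("DS", "IS", "CS")) 0x20
                                   else 0x00))
  tag <- as.raw(c(bitwAnd(group, 255L), bitwShiftR(group, 8L),
                  bitwAnd(elem, 255L), bitwShiftR(elem, 8L)))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    len <- length(valueRaw)
    lenRaw <- as.raw(c(bitwAnd(len, 255L), bitwAnd(bitwShiftR(len, 8L), 255L),
                       bitwAnd(bitwShiftR(len, 16L), 255L),
                       bitwAnd(bitwShiftR(len, 24L), 255L)))
    c(tag, charToRaw(vr), as.raw(c(0, 0)), lenRaw, valueRaw)
  } else {
    len <- length(valueRaw)
    c(tag, charToRaw(vr),
      as.raw(c(bitwAnd(len, 255L), bitwShiftR(len, 8L))), valueRaw)
  }
}

dcmUS <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

dcmUint16LE <- function(vals) {
  out <- raw(2L * length(vals))
  out[seq(1, length(out), 2)] <- as.raw(bitwAnd(vals, 255L))
  out[seq(2, length(out), 2)] <- as.raw(bitwShiftR(vals, 8L))
  out
}

# values: integer matrix (row-major frame), 16-bit unsigned
writeTestDicom <- function(path, values, photometric = "MONOCHROME2",
                           slope = NULL, intercept = NULL) {
  body <- c(
    dcmElem(0x0028L, 0x0004L, "CS", charToRaw(photometric)),
    dcmElem(0x0028L, 0x0010L, "US", dcmUS(nrow(values))),
    dcmElem(0x0028L, 0x0011L, "US", dcmUS(ncol(values))),
    dcmElem(0x0028L, 0x0100L, "US", dcmUS(16L)),
    dcmElem(0x0028L, 0x0101L, "US", dcmUS(16L)),
    dcmElem(0x0028L, 0x0103L, "US", dcmUS(0L)))
  if (!is.null(intercept))
    body <- c(body, dcmElem(0x0028L, 0x1052L, "DS",
                            charToRaw(as.character(intercept))))
  if (!is.null(slope))
    body <- c(body, dcmElem(0x0028L, 0x1053L, "DS",
                            charToRaw(as.character(slope))))
  pix <- dcmUint16LE(as.integer(t(values)))   # row-major pixel order
  body <- c(body, dcmElem(0x7FE0L, 0x0010L, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
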