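# Minimal single-frame DICOM reader: uncompressed little-endian pixel data,
# implicit or explicit VR. Parses only the tags needed to decode and
# normalise one grayscale frame; sequences and encapsulated transfer
# syntaxes are rejected.

.le16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])

.le32 <- function(raw4) {
    as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
        65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

.explicitVRs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                  "IS", "LO", "LT", "OB", "OD", "OF", "OW", "PN", "SH",
                  "SL", "SQ", "SS", "ST", "TM", "UI", "UL", "UN", "US",
                  "UT")
.longVRs <- c("OB", "OD", "OF", "OW", "SQ", "UC", "UR", "UT", "UN")

.readDicomMatrix <- function(path) {
    raw <- readBin(path, "raw", n = file.info(path)$size)
    pos <- 1L
    if (length(raw) >= 132L &&
        rawToChar(raw[129:132]) == "DICM") pos <- 133L
    tags <- new.env(parent = emptyenv())
    pixelRaw <- NULL
    while (pos + 7L <= length(raw)) {
        group <- .le16(raw[pos:(pos + 1L)])
        elem <- .le16(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
        vr <- rawToChar(raw[pos:(pos + 1L)])
        if (vr %in% .explicitVRs) {
            if (vr %in% .longVRs) {
                len <- .le32(raw[(pos + 4L):(pos + 7L)])
                pos <- pos + 8L
            } else {
                len <- .le16(raw[(pos + 2L):(pos + 3L)])
                pos <- pos + 4L
            }
        } else {
            vr <- NA_character_
            len <- .le32(raw[pos:(pos + 3L)])
            pos <- pos + 4L
        }
        if (len == 4294967295)   # undefined length (sequences, encapsulated)
            stop("unsupported DICOM encoding (undefined-length element) in ",
                 path)
        if (pos + len - 1L > length(raw))
            stop("truncated DICOM file: ", path)
        val <- raw[pos:(pos + len - 1L)]
        pos <- pos + as.integer(len)
        key <- sprintf("%04x%04x", group, elem)
        if (key == "7fe00010") {
            pixelRaw <- val
            break
        }
        assign(key, val, envir = tags)
    }
    getTag <- function(key, default = NULL) {
        if (exists(key, envir = tags)) get(key, envir = tags) else default
    }
    asUS <- function(key, default = NULL) {
        v <- getTag(key)
        if (is.null(v)) return(default)
        .le16(v[1:2])
    }
    asStr <- function(key, default = "") {
        v <- getTag(key)
        if (is.null(v)) return(default)
        trimws(rawToChar(v))
    }
    asNum <- function(key, default) {
        s <- asStr(key, "")
        if (!nzchar(s)) default else as.numeric(s)
    }
    rows <- asUS("00280010"); cols <- asUS("00280011")
    if (is.null(rows) || is.null(cols) || is.null(pixelRaw))
        stop("not a decodable single-frame DICOM image: ", path)
    bits <- asUS("00280100", 16L)
    signed <- identical(asUS("00280103", 0L), 1L)
    photometric <- asStr("00280004", "MONOCHROME2")
    slope <- asNum("00281053", 1)
    intercept <- asNum("00281052", 0)
    vals <- if (bits <= 8L) {
        as.integer(pixelRaw[seq_len(rows * cols)])
    } else {
        readBin(pixelRaw, "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
    }
    if (bits > 8L && !signed) {
        # readBin size-2 unsigned is supported directly
        vals <- readBin(pixelRaw, "integer", n = rows * cols, size = 2L,
                        signed = FALSE, endian = "little")
    }
    vals <- slope * vals + intercept
    mn <- min(vals); mx <- max(vals)
    if (mx <= mn) {
        warning("DICOM frame has zero dynamic range; returning all zeros: ",
                path)
        out <- matrix(0, rows, cols)
    } else {
        out <- matrix((vals - mn) / (mx - mn), nrow = rows, byrow = TRUE)
    }
    if (startsWith(photometric, "MONOCHROME1")) out <- 1 - out
    out
}
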