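# Minimal DICOM Part-10 reader/writer, explicit VR little endian only.
#
# Covers exactly what RT Ion Plan spot maps need: flat elements of the
# common string/numeric VRs plus nested sequences (SQ) with defined or
# undefined lengths. Files are written with defined lengths and the
# explicit-VR-little-endian transfer syntax (1.2.840.10008.1.2.1); other
# transfer syntaxes are rejected on read.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
RTION_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.8"
SPOTQA_IMPL_UID <- "2.25.312787406510101317"

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
DICOM_STR_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                   "ST", "TM", "UI", "UT")

new_uid <- function() {
  # UUID-derived numeric UID under the 2.25 arc
  paste0("2.25.", paste0(sample(0:9, 30, replace = TRUE), collapse = ""))
}

# ---- encoding -------------------------------------------------------------

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) {
  # writeBin has no unsigned 32-bit type; values stay far below 2^31 here
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

pad_even <- function(bytes, pad) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

encode_value <- function(vr, value) {
  if (vr %in% c("UI")) {
    pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0))
  } else if (vr %in% DICOM_STR_VRS) {
    pad_even(charToRaw(paste(value, collapse = "\\")), charToRaw(" "))
  } else if (vr %in% c("DS")) {
    pad_even(charToRaw(paste(vapply(value, format_ds, character(1)), collapse = "\\")),
             charToRaw(" "))
  } else if (vr %in% c("IS")) {
    pad_even(charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\")),
             charToRaw(" "))
  } else if (vr == "FL") {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr == "UL") {
    uint32_raw(value)
  } else if (vr == "US") {
    uint16_raw(value)
  } else if (vr == "OB") {
    pad_even(as.raw(value), as.raw(0))
  } else {
    qa_abort(paste0("unsupported VR for writing: ", vr), "qa_format_error")
  }
}

# DS values are limited to 16 bytes
format_ds <- function(x) {
  s <- formatC(x, format = "g", digits = 10)
  if (nchar(s) > 16) s <- formatC(x, format = "g", digits = 16 - 7)
  s
}

dicom_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") {
    items <- lapply(value, function(item) {
      payload <- do.call(c, item)
      c(uint16_raw(c(0xFFFE, 0xE000)), uint32_raw(length(payload)), payload)
    })
    if (length(items) > 0) do.call(c, items) else raw(0)
  } else {
    encode_value(vr, value)
  }
  hdr <- c(uint16_raw(c(group, element)), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), uint32_raw(length(body)), body)
  } else {
    if (length(body) > 65534) qa_abort("value too long for short VR", "qa_format_error")
    c(hdr, uint16_raw(length(body)), body)
  }
}

# elements: list of raw vectors already in ascending tag order
dicom_file_raw <- function(dataset_elements, sop_instance_uid) {
  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", c(0, 1)),
    dicom_element(0x0002, 0x0002, "UI", RTION_SOP_CLASS),
    dicom_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dicom_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
    dicom_element(0x0002, 0x0012, "UI", SPOTQA_IMPL_UID)
  )
  c(raw(128), charToRaw("DICM"),
    dicom_element(0x0002, 0x0000, "UL", length(meta)),
    meta,
    do.call(c, dataset_elements))
}

# ---- decoding -------------------------------------------------------------

read_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1)], "integer", size = 2, signed = FALSE, endian = "little")
}
read_u32 <- function(bytes, pos) {
  v <- readBin(bytes[pos:(pos + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

decode_value <- function(vr, bytes) {
  n <- length(bytes)
  if (vr %in% c("UI", DICOM_STR_VRS)) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    sub("[ ]+$", "", s)
  } else if (vr == "DS") {
    s <- sub("[ ]+$", "", rawToChar(bytes[bytes != as.raw(0)]))
    as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr == "IS") {
    s <- sub("[ ]+$", "", rawToChar(bytes[bytes != as.raw(0)]))
    as.integer(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr == "FL") {
    readBin(bytes, "numeric", n = n / 4, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, "numeric", n = n / 8, size = 8, endian = "little")
  } else if (vr == "UL") {
    vapply(seq_len(n / 4), function(i) read_u32(bytes, 4 * i - 3), numeric(1))
  } else if (vr == "US") {
    vapply(seq_len(n / 2), function(i) read_u16(bytes, 2 * i - 1), numeric(1))
  } else {
    bytes
  }
}

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# parse one dataset from `pos` up to `end` (exclusive); returns
# list(elements = named list, pos = next position)
parse_dataset <- function(bytes, pos, end) {
  elements <- list()
  while (pos < end) {
    group <- read_u16(bytes, pos); element <- read_u16(bytes, pos + 2)
    pos <- pos + 4
    if (group == 0xFFFE) {
      len <- read_u32(bytes, pos); pos <- pos + 4
      if (element %in% c(0xE00D, 0xE0DD)) break  # item/sequence delimiter
      qa_abort("unexpected item tag outside a sequence", "qa_format_error")
    }
    vr <- rawToChar(bytes[pos:(pos + 1)]); pos <- pos + 2
    if (!grepl("^[A-Z]{2}$", vr)) {
      qa_abort("not explicit-VR little-endian (implicit VR is unsupported)",
               "qa_format_error")
    }
    if (vr %in% DICOM_LONG_VRS) {
      pos <- pos + 2  # reserved
      len <- read_u32(bytes, pos); pos <- pos + 4
    } else {
      len <- read_u16(bytes, pos); pos <- pos + 2
    }
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else pos + len
      items <- list()
      while (pos < sq_end) {
        ig <- read_u16(bytes, pos); ie <- read_u16(bytes, pos + 2)
        ilen <- read_u32(bytes, pos + 4)
        pos <- pos + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break  # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000)) {
          qa_abort("malformed sequence item", "qa_format_error")
        }
        item_end <- if (ilen == 4294967295) sq_end else pos + ilen
        parsed <- parse_dataset(bytes, pos, item_end)
        items[[length(items) + 1]] <- parsed$elements
        pos <- parsed$pos
      }
      elements[[tag_key(group, element)]] <- items
    } else {
      if (len == 4294967295) {
        qa_abort("undefined length outside SQ is unsupported", "qa_format_error")
      }
      val <- if (len > 0) decode_value(vr, bytes[pos:(pos + len - 1)]) else
        decode_value(vr, raw(0))
      pos <- pos + len
      elements[[tag_key(group, element)]] <- val
    }
  }
  list(elements = elements, pos = pos)
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    qa_abort(paste0("not a DICOM Part-10 file: ", path), "qa_format_error")
  }
  pos <- 133
  # file meta group: always explicit VR LE; group length bounds it
  g <- read_u16(bytes, pos); e <- read_u16(bytes, pos + 2)
  if (!(g == 2 && e == 0)) qa_abort("missing file meta group length", "qa_format_error")
  vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
  len <- read_u16(bytes, pos + 6)
  meta_len <- read_u32(bytes, pos + 8)
  pos <- pos + 8 + len
  meta <- parse_dataset(bytes, pos, pos + meta_len)
  ts <- meta$elements[["0002,0010"]]
  if (!identical(ts, DICOM_TS_EXPLICIT_LE)) {
    qa_abort(paste0("unsupported transfer syntax: ", ts), "qa_format_error")
  }
  parse_dataset(bytes, meta$pos, length(bytes) + 1)$elements
}
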