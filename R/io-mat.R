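# MAT-style container (Level 5 MAT-file). One numeric array per variable,
# column-major like R, so no axis permutation is needed. Variables are written
# as zlib-compressed miCOMPRESSED elements (R's memCompress(type = "gzip")
# emits RFC1950 zlib streams, which is the stream type this format uses);
# numeric arrays whose values fit are stored compactly as 16-bit integers with
# class double, which readers convert transparently. The reader accepts
# compressed and uncompressed elements and integer or float storage.

mat_mi <- c(INT8 = 1, UINT8 = 2, INT16 = 3, UINT16 = 4, INT32 = 5,
            UINT32 = 6, SINGLE = 7, DOUBLE = 9, MATRIX = 14, COMPRESSED = 15)

mat_elem <- function(type, data_raw) {
  n <- length(data_raw)
  pad <- (8 - n %% 8) %% 8
  c(writeBin(as.integer(c(type, n)), raw(), size = 4, endian = "little"),
    data_raw, raw(pad))
}

mat_numeric_payload <- function(v) {
  if (all(is.finite(v)) && all(v == round(v)) && all(v >= -32768) &&
      all(v <= 32767))
    mat_elem(mat_mi["INT16"],
             writeBin(as.integer(v), raw(), size = 2, endian = "little"))
  else
    mat_elem(mat_mi["DOUBLE"],
             writeBin(as.double(v), raw(), size = 8, endian = "little"))
}

mat_matrix_element <- function(name, a) {
  dims <- dim(a)
  if (is.null(dims)) dims <- length(a)
  flags <- raw(8)
  flags[1] <- as.raw(6)  # mxDOUBLE_CLASS
  body <- c(
    mat_elem(mat_mi["UINT32"], flags),
    mat_elem(mat_mi["INT32"],
             writeBin(as.integer(dims), raw(), size = 4, endian = "little")),
    mat_elem(mat_mi["INT8"], charToRaw(name)),
    mat_numeric_payload(as.vector(a)))
  c(writeBin(as.integer(c(mat_mi["MATRIX"], length(body))), raw(),
             size = 4, endian = "little"), body)
}

write_mat <- function(path, arrays, compress = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by gaitmat on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116
  hdr[is.na(hdr)] <- as.raw(0x20)
  writeBin(hdr, con)
  writeBin(raw(8), con)                                   # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeChar("IM", con, eos = NULL)                        # little-endian
  for (nm in names(arrays)) {
    el <- mat_matrix_element(nm, arrays[[nm]])
    if (compress) {
      z <- memCompress(el, type = "gzip")
      writeBin(as.integer(c(mat_mi["COMPRESSED"], length(z))), con,
               size = 4, endian = "little")
      writeBin(z, con)
    } else writeBin(el, con)
  }
  invisible(NULL)
}

mat_read_tag <- function(bytes, pos) {
  word <- readBin(bytes[pos + 0:3], "integer", 1, size = 4, endian = "little")
  # small data element format: upper 16 bits hold the byte count
  if (bitwAnd(word, -65536L) != 0L) {
    list(type = bitwAnd(word, 65535L), nbytes = bitwShiftR(word, 16),
         data_at = pos + 4, next_at = pos + 8)
  } else {
    nbytes <- readBin(bytes[pos + 4:7], "integer", 1, size = 4,
                      endian = "little")
    list(type = word, nbytes = nbytes, data_at = pos + 8,
         next_at = pos + 8 + nbytes + (8 - nbytes %% 8) %% 8)
  }
}

mat_decode_numeric <- function(bytes, type, nbytes) {
  switch(as.character(type),
    "1" = readBin(bytes, "integer", nbytes, size = 1, endian = "little"),
    "2" = readBin(bytes, "integer", nbytes, size = 1, signed = FALSE,
                  endian = "little"),
    "3" = readBin(bytes, "integer", nbytes / 2, size = 2, endian = "little"),
    "4" = readBin(bytes, "integer", nbytes / 2, size = 2, signed = FALSE,
                  endian = "little"),
    "5" = readBin(bytes, "integer", nbytes / 4, size = 4, endian = "little"),
    "6" = {
      v <- readBin(bytes, "integer", nbytes / 4, size = 4, endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = readBin(bytes, "double", nbytes / 4, size = 4, endian = "little"),
    "9" = readBin(bytes, "double", nbytes / 8, size = 8, endian = "little"),
    stop("format error: unsupported MAT data type ", type))
}

mat_parse_matrix <- function(bytes) {
  pos <- 1L
  flags_tag <- mat_read_tag(bytes, pos)
  pos <- flags_tag$next_at
  dims_tag <- mat_read_tag(bytes, pos)
  dims <- readBin(bytes[dims_tag$data_at + seq_len(dims_tag$nbytes) - 1],
                  "integer", dims_tag$nbytes / 4, size = 4, endian = "little")
  pos <- dims_tag$next_at
  name_tag <- mat_read_tag(bytes, pos)
  name <- rawToChar(bytes[name_tag$data_at + seq_len(name_tag$nbytes) - 1])
  pos <- name_tag$next_at
  data_tag <- mat_read_tag(bytes, pos)
  vals <- mat_decode_numeric(
    bytes[data_tag$data_at + seq_len(data_tag$nbytes) - 1],
    data_tag$type, data_tag$nbytes)
  a <- if (length(dims) > 1L) array(vals, dim = dims) else vals
  list(name = name, value = a)
}

read_mat <- function(path, keys = NULL) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 128)
  if (length(hdr) < 128)
    stop("format error: truncated MAT header")
  endian <- rawToChar(hdr[127:128])
  if (endian != "IM")
    stop("format error: big-endian MAT files are not supported")
  out <- list()
  pos <- 128
  while (pos < sz) {
    tag <- readBin(con, "raw", 8)
    if (length(tag) < 8) break
    type <- readBin(tag[1:4], "integer", 1, size = 4, endian = "little")
    nbytes <- readBin(tag[5:8], "integer", 1, size = 4, endian = "little")
    body <- readBin(con, "raw", nbytes)
    pad <- (8 - nbytes %% 8) %% 8
    if (pad) readBin(con, "raw", pad)
    pos <- pos + 8 + nbytes + pad
    if (type == mat_mi["COMPRESSED"])
      { body <- memDecompress(body, type = "gzip")
        inner <- mat_read_tag(body, 1L)
        body <- body[inner$data_at + seq_len(inner$nbytes) - 1]
        type <- inner$type }
    if (type != mat_mi["MATRIX"]) next
    m <- mat_parse_matrix(body)
    out[[m$name]] <- m$value
  }
  if (!is.null(keys)) {
    missing <- setdiff(keys, names(out))
    if (length(missing))
      stop("format error: container lacks key(s): ",
           paste(missing, collapse = ", "))
    out <- out[keys]
  }
  out
}
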