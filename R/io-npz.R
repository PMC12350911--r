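# NPZ-style container: a ZIP archive holding one .npy array per key.
# Entries are written with the "stored" (uncompressed) method so that frames
# of a C-order tensor are seekable for lazy access; the reader also accepts
# deflated entries (as produced by other tools) by inflating them through a
# constructed gzip wrapper.

npy_dtype_map <- list(
  "<f8" = list(what = "double",  size = 8L, signed = TRUE),
  "<f4" = list(what = "double",  size = 4L, signed = TRUE),
  "<i8" = list(what = "integer", size = 8L, signed = TRUE),
  "<i4" = list(what = "integer", size = 4L, signed = TRUE),
  "<i2" = list(what = "integer", size = 2L, signed = TRUE),
  "<u2" = list(what = "integer", size = 2L, signed = FALSE),
  "|u1" = list(what = "integer", size = 1L, signed = FALSE),
  "|i1" = list(what = "integer", size = 1L, signed = TRUE)
)

npy_header <- function(descr, shape, fortran = FALSE) {
  shp <- if (length(shape) == 1L) sprintf("(%d,)", shape)
         else sprintf("(%s)", paste(shape, collapse = ", "))
  dict <- sprintf("{'descr': '%s', 'fortran_order': %s, 'shape': %s, }",
                  descr, if (fortran) "True" else "False", shp)
  base <- 10L + nchar(dict) + 1L           # magic+version+len + dict + \n
  pad <- (64L - base %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")
  c(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)),
    writeBin(as.integer(nchar(header)), raw(), size = 2, endian = "little"),
    charToRaw(header))
}

# Serialize an R array to .npy bytes in C (row-major) order.
npy_bytes <- function(a, dtype = "auto") {
  shape <- dim(a)
  if (is.null(shape)) shape <- length(a)
  ac <- if (length(shape) > 1L) aperm(a, rev(seq_along(shape))) else a
  v <- as.vector(ac)
  if (dtype == "auto") {
    dtype <- if (is.integer(a) ||
                 (all(is.finite(v)) && all(v == round(v)) &&
                  all(abs(v) <= .Machine$integer.max))) "<i4" else "<f8"
  }
  dt <- npy_dtype_map[[dtype]]
  if (is.null(dt)) stop("unsupported npy dtype: ", dtype)
  data <- if (dt$what == "double")
    writeBin(as.double(v), raw(), size = dt$size, endian = "little")
  else
    writeBin(as.integer(v), raw(), size = dt$size, endian = "little")
  c(npy_header(dtype, shape), data)
}

npy_parse_header <- function(con) {
  magic <- readBin(con, "raw", 6L)
  if (length(magic) < 6L || any(magic != as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("format error: not an npy stream")
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L)
    readBin(con, "integer", 1L, size = 4, endian = "little")
  else
    readBin(con, "integer", 1L, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.numeric(strsplit(gsub("\\s|,$", "", shp), ",")[[1L]])
  if (length(shape) == 0L || any(is.na(shape))) shape <- integer(0)
  list(descr = descr, fortran = fortran, shape = shape,
       data_offset = 8L + (if (as.integer(ver[1L]) >= 2L) 4L else 2L) + hlen)
}

npy_decode_values <- function(data, descr, n) {
  dt <- npy_dtype_map[[descr]]
  if (is.null(dt)) stop("unsupported npy dtype: ", descr)
  if (dt$what == "double")
    readBin(data, "double", n, size = dt$size, endian = "little")
  else if (dt$size %in% c(1L, 2L))
    readBin(data, "integer", n, size = dt$size, signed = dt$signed,
            endian = "little")
  else
    readBin(data, "integer", n, size = dt$size, endian = "little")
}

npy_read_bytes <- function(bytes) {
  con <- rawConnection(bytes)
  on.exit(close(con))
  h <- npy_parse_header(con)
  n <- prod(h$shape)
  vals <- npy_decode_values(readBin(con, "raw", n * npy_dtype_map[[h$descr]]$size),
                            h$descr, n)
  if (length(h$shape) > 1L) {
    if (h$fortran) array(vals, dim = h$shape)
    else aperm(array(vals, dim = rev(h$shape)), rev(seq_along(h$shape)))
  } else vals
}

# --- minimal ZIP (stored method) -------------------------------------------

zip_write_stored <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(num_to_u32le(x), con)
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- .crc32_raw(data)
    offsets[i] <- pos
    writeBin(c(as.raw(c(0x50, 0x4b, 0x03, 0x04))), con)
    u16(20); u16(0); u16(0); u16(0); u16(0)       # version, flags, method, time, date
    u32(crcs[i]); u32(length(data)); u32(length(data))
    u16(length(name)); u16(0)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + 30 + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    writeBin(as.raw(c(0x50, 0x4b, 0x01, 0x02)), con)
    u16(20); u16(20); u16(0); u16(0); u16(0); u16(0)
    u32(crcs[i]); u32(length(entries[[i]])); u32(length(entries[[i]]))
    u16(length(name)); u16(0); u16(0); u16(0); u16(0)
    u32(0); u32(offsets[i])
    writeBin(name, con)
    pos <- pos + 46 + length(name)
  }
  writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06)), con)
  u16(0); u16(0); u16(length(entries)); u16(length(entries))
  u32(pos - cd_start); u32(cd_start); u16(0)
  invisible(NULL)
}

num_to_u32le <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

u32le_to_num <- function(r)
  sum(as.numeric(r) * c(1, 256, 65536, 16777216))

# Parse the central directory of a zip file. Returns a data.frame of entries
# with the offset of each entry's data payload.
zip_entries <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  tail_n <- min(sz, 65557)
  seek(con, sz - tail_n)
  tail <- readBin(con, "raw", tail_n)
  sig <- as.raw(c(0x50, 0x4b, 0x05, 0x06))
  eocd <- NA
  for (i in (length(tail) - 21):1)
    if (tail[i] == sig[1] && tail[i + 1] == sig[2] &&
        tail[i + 2] == sig[3] && tail[i + 3] == sig[4]) { eocd <- i; break }
  if (is.na(eocd)) stop("format error: no zip end-of-central-directory")
  n <- sum(as.integer(tail[eocd + 10:11]) * c(1, 256))
  cd_off <- u32le_to_num(tail[eocd + 16:19])
  seek(con, cd_off)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- readBin(con, "raw", 46)
    if (u32le_to_num(hdr[1:4]) != 0x02014b50)
      stop("format error: bad central directory entry")
    method <- sum(as.integer(hdr[11:12]) * c(1, 256))
    csize <- u32le_to_num(hdr[21:24])
    usize <- u32le_to_num(hdr[25:28])
    nlen <- sum(as.integer(hdr[29:30]) * c(1, 256))
    elen <- sum(as.integer(hdr[31:32]) * c(1, 256))
    clen <- sum(as.integer(hdr[33:34]) * c(1, 256))
    crc <- u32le_to_num(hdr[17:20])
    lho <- u32le_to_num(hdr[43:46])
    name <- rawToChar(readBin(con, "raw", nlen))
    if (elen + clen > 0) readBin(con, "raw", elen + clen)
    out[[i]] <- data.frame(name = name, method = method, csize = csize,
                           usize = usize, crc = crc, lho = lho,
                           stringsAsFactors = FALSE)
  }
  ents <- do.call(rbind, out)
  # resolve data offsets from local headers
  ents$data_offset <- NA_real_
  for (i in seq_len(nrow(ents))) {
    seek(con, ents$lho[i])
    lh <- readBin(con, "raw", 30)
    nlen <- sum(as.integer(lh[27:28]) * c(1, 256))
    elen <- sum(as.integer(lh[29:30]) * c(1, 256))
    ents$data_offset[i] <- ents$lho[i] + 30 + nlen + elen
  }
  ents
}

zip_read_entry <- function(path, entry) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, entry$data_offset)
  data <- readBin(con, "raw", entry$csize)
  if (entry$method == 0) return(data)
  if (entry$method == 8) {
    # wrap raw deflate in a gzip container so memDecompress can inflate it
    gz <- c(as.raw(c(0x1f, 0x8b, 0x08, 0, 0, 0, 0, 0, 0, 3)), data,
            num_to_u32le(entry$crc), num_to_u32le(entry$usize))
    return(memDecompress(gz, type = "gzip"))
  }
  stop("format error: unsupported zip compression method ", entry$method)
}

write_npz <- function(path, arrays, dtype = "auto") {
  entries <- lapply(arrays, npy_bytes, dtype = dtype)
  names(entries) <- paste0(names(arrays), ".npy")
  zip_write_stored(path, entries)
}

read_npz <- function(path, keys = NULL) {
  ents <- zip_entries(path)
  ents$key <- sub("\\.npy$", "", ents$name)
  if (is.null(keys)) keys <- ents$key
  missing <- setdiff(keys, ents$key)
  if (length(missing))
    stop("format error: container lacks key(s): ", paste(missing, collapse = ", "))
  out <- lapply(keys, function(k)
    npy_read_bytes(zip_read_entry(path, ents[ents$key == k, ])))
  names(out) <- keys
  out
}

# Lazy handle for a stored npy entry holding a C-order rank-3 tensor: frame i
# occupies a contiguous byte range and can be read with one seek.
npz_open_lazy <- function(path, key = "arr_0") {
  ents <- zip_entries(path)
  ents$key <- sub("\\.npy$", "", ents$name)
  e <- ents[ents$key == key, ]
  if (nrow(e) == 0L) stop("format error: container lacks key 'arr_0'")
  if (e$method != 0) return(NULL)  # compressed entry: not seekable
  con <- file(path, "rb")
  seek(con, e$data_offset)
  h <- npy_parse_header(con)
  close(con)
  if (h$fortran || length(h$shape) != 3L) return(NULL)
  list(path = path, container = "npz",
       offset = e$data_offset + h$data_offset, descr = h$descr,
       dim = as.integer(h$shape),
       itemsize = npy_dtype_map[[h$descr]]$size)
}

npz_read_frames <- function(handle, idx) {
  hw <- prod(handle$dim[2:3])
  con <- file(handle$path, "rb")
  on.exit(close(con))
  out <- array(0, dim = c(length(idx), handle$dim[2L], handle$dim[3L]))
  for (k in seq_along(idx)) {
    i <- idx[k]
    seek(con, handle$offset + (i - 1) * hw * handle$itemsize)
    vals <- npy_decode_values(readBin(con, "raw", hw * handle$itemsize),
                              handle$descr, hw)
    # C-order frame: x fastest -> fill W x H then transpose
    out[k, , ] <- t(matrix(vals, nrow = handle$dim[3L]))
  }
  out
}
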