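#' Read and write MAT-style single-matrix files
#'
#' A minimal Level-5 MAT-file implementation covering the layout used by
#' CPSC2018-style distributions: one file per record holding one real
#' double-precision 2-D matrix (leads x samples, millivolts).  Written
#' files carry a 128-byte text header, a little-endian indicator, and a
#' single `miMATRIX` element (array flags, dimensions, name, real data).
#'
#' @param signal numeric matrix (leads x samples)
#' @param path output file path
#' @param name MATLAB variable name (default `"ECG"`)
#' @return `write_ecg_mat()`: `path`, invisibly. `read_ecg_mat()`: a list
#'   with elements `name` and `data` (the matrix).
#' @export
write_ecg_mat <- function(signal, path, name = "ECG") {
  signal <- as.matrix(signal)
  con <- file(path, "wb")
  on.exit(close(con))
  # 128-byte header: 116 text bytes, 8 subsystem bytes, version, endian "IM"
  txt <- sprintf("MATLAB 5.0 MAT-file, created by ecgmtnet on %s",
                 format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(txt)
  length(hdr) <- 116L
  hdr[hdr == as.raw(0L)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8L), con)
  writeBin(as.integer(c(256L)), con, size = 2L, endian = "little")  # 0x0100
  writeBin(charToRaw("IM"), con)

  name_raw <- charToRaw(name)
  name_pad <- (8L - length(name_raw) %% 8L) %% 8L
  data_bytes <- 8L * length(signal)
  data_pad <- (8L - data_bytes %% 8L) %% 8L
  # subelements: flags (8+8), dims (8+8), name (8+len+pad), real (8+len+pad)
  total <- 16L + 16L + 8L + length(name_raw) + name_pad + 8L + data_bytes + data_pad

  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w32(c(14L, total))                 # miMATRIX element tag
  w32(c(6L, 8L)); w32(c(6L, 0L))     # array flags: miUINT32 x2, mxDOUBLE_CLASS
  w32(c(5L, 8L)); w32(dim(signal))   # dimensions: miINT32, [nrow ncol]
  w32(c(1L, length(name_raw)))       # array name: miINT8
  writeBin(name_raw, con)
  if (name_pad) writeBin(raw(name_pad), con)
  w32(c(9L, data_bytes))             # real part: miDOUBLE
  writeBin(as.numeric(signal), con, size = 8L, endian = "little")
  if (data_pad) writeBin(raw(data_pad), con)
  invisible(path)
}

#' @rdname write_ecg_mat
#' @export
read_ecg_mat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), n = 124L)
  if (length(hdr) < 124L) stop(path, ": truncated MAT header")
  version <- readBin(con, integer(), n = 1L, size = 2L, endian = "little")
  endian <- rawToChar(readBin(con, raw(), n = 2L))
  if (endian != "IM")
    stop(path, ": only little-endian MAT files are supported")
  r32 <- function(n = 1L) readBin(con, integer(), n = n, size = 4L, endian = "little")
  tag <- r32(2L)
  if (tag[1L] != 14L) stop(path, ": expected a miMATRIX element, got type ", tag[1L])

  read_sub <- function() {
    t0 <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
    if (length(t0) == 0L) return(NULL)
    small_len <- bitwAnd(bitwShiftR(t0, 16L), 0xFFFFL)
    if (small_len > 0L) {  # small-element format: type+len packed in one word
      type <- bitwAnd(t0, 0xFFFFL)
      bytes <- readBin(con, raw(), n = 4L)
      list(type = type, size = small_len, data = bytes[seq_len(small_len)])
    } else {
      size <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
      bytes <- readBin(con, raw(), n = size)
      pad <- (8L - size %% 8L) %% 8L
      if (pad) readBin(con, raw(), n = pad)
      list(type = t0, size = size, data = bytes)
    }
  }

  flags <- read_sub()
  mat_class <- as.integer(flags$data[1L])
  if (mat_class != 6L)
    stop(path, ": only double-precision matrices are supported (class ",
         mat_class, ")")
  dims_el <- read_sub()
  dims <- readBin(dims_el$data, integer(), n = dims_el$size / 4L,
                  size = 4L, endian = "little")
  name_el <- read_sub()
  name <- rawToChar(name_el$data)
  data_el <- read_sub()
  if (data_el$type != 9L)
    stop(path, ": expected miDOUBLE data, got type ", data_el$type)
  vals <- readBin(data_el$data, numeric(), n = data_el$size / 8L,
                  size = 8L, endian = "little")
  list(name = name, data = matrix(vals, nrow = dims[1L], ncol = dims[2L]))
}
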