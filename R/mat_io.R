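# Minimal MAT v5 (Level 5 MAT-file) writer/reader for the dataset container.
# Supports exactly what the container needs: n-dimensional double arrays and
# 2-D character arrays, written little-endian in the uncompressed long
# element format.  Readable by standard MAT-file tools.

MI_INT8 <- 1L; MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_DOUBLE <- 9L
MI_UINT16 <- 4L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L; MX_CHAR_CLASS <- 4L

pad8 <- function(n) (8L - n %% 8L) %% 8L

write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
}

write_padding <- function(con, nbytes) {
  if (pad8(nbytes) > 0)
    writeBin(raw(pad8(nbytes)), con)
}

# Serialize one named array as a miMATRIX element into a raw vector.
mat_element_raw <- function(name, value) {
  buf <- rawConnection(raw(0), "wb")
  on.exit(close(buf))
  if (is.character(value)) {
    n <- length(value)
    width <- if (n) max(nchar(value, type = "chars"), 0L) else 0L
    dims <- c(n, width)
    codes <- matrix(32L, nrow = max(n, 0L), ncol = width)
    for (i in seq_len(n)) {
      ci <- utf8ToInt(value[i])
      if (length(ci)) codes[i, seq_along(ci)] <- ci
    }
    cls <- MX_CHAR_CLASS
    data_type <- MI_UINT16
    data_bytes <- 2L * length(codes)
  } else {
    value <- as.array(value)
    dims <- dim(value) %||% length(value)
    if (length(dims) < 2) dims <- c(1L, length(value))
    cls <- MX_DOUBLE_CLASS
    data_type <- MI_DOUBLE
    data_bytes <- 8L * length(value)
  }
  # array flags
  write_tag(buf, MI_UINT32, 8L)
  writeBin(as.integer(c(cls, 0L)), buf, size = 4L, endian = "little")
  # dimensions
  write_tag(buf, MI_INT32, 4L * length(dims))
  writeBin(as.integer(dims), buf, size = 4L, endian = "little")
  write_padding(buf, 4L * length(dims))
  # name
  nm <- utf8ToInt(name)
  write_tag(buf, MI_INT8, length(nm))
  if (length(nm)) writeBin(as.raw(nm), buf)
  write_padding(buf, length(nm))
  # real data
  write_tag(buf, data_type, data_bytes)
  if (is.character(value)) {
    if (length(codes))
      writeBin(as.integer(codes), buf, size = 2L, endian = "little")
  } else {
    if (length(value))
      writeBin(as.numeric(value), buf, size = 8L, endian = "little")
  }
  write_padding(buf, data_bytes)
  rawConnectionValue(buf)
}

#' Write named arrays to a MAT v5 file
#'
#' Low-level writer behind [write_container()].  Numeric values are stored as
#' double arrays (scalars and vectors as 1 x n), character vectors as 2-D
#' char arrays padded with spaces.
#'
#' @param vars named list of numeric arrays and character vectors.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_mat <- function(vars, path) {
  assert_that(length(names(vars)) == length(vars) && all(nzchar(names(vars))),
              "format_error", "all MAT variables must be named")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_fmt("io_error",
                    "cannot open '%s' for writing", path))
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by erpsynth %s",
                  format(Sys.Date()))
  hdr <- utf8ToInt(desc)[1:min(nchar(desc), 116)]
  writeBin(as.raw(c(hdr, rep(32L, 116 - length(hdr)))), con)
  writeBin(raw(8), con)                       # subsystem offset
  writeBin(as.integer(c(256L)), con, size = 2L, endian = "little")
  writeBin(charToRaw("IM"), con)              # endian indicator
  for (nm in names(vars)) {
    el <- mat_element_raw(nm, vars[[nm]])
    write_tag(con, MI_MATRIX, length(el))
    writeBin(el, con)
  }
  invisible(path)
}

read_tag <- function(con) {
  word <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(word) == 0) return(NULL)
  small <- bitwAnd(word, -65536L)  # upper 16 bits
  if (small != 0L) {
    list(type = bitwAnd(word, 65535L), nbytes = bitwShiftR(word, 16L),
         small = TRUE)
  } else {
    nb <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    list(type = word, nbytes = nb, small = FALSE)
  }
}

read_subelement <- function(con) {
  tag <- read_tag(con)
  if (is.null(tag)) return(NULL)
  dat <- readBin(con, "raw", n = tag$nbytes)
  if (tag$small) {
    readBin(con, "raw", n = 4L - tag$nbytes)
  } else {
    readBin(con, "raw", n = pad8(tag$nbytes))
  }
  c(tag, list(data = dat))
}

parse_matrix_element <- function(el_raw) {
  con <- rawConnection(el_raw, "rb")
  on.exit(close(con))
  flags <- read_subelement(con)
  cls <- as.integer(readBin(flags$data[1:4], "integer", size = 4L,
                            endian = "little"))
  dims_el <- read_subelement(con)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4L,
                  size = 4L, endian = "little")
  name_el <- read_subelement(con)
  name <- rawToChar(name_el$data)
  pr <- read_subelement(con)
  if (cls == MX_DOUBLE_CLASS) {
    stopifnot(pr$type == MI_DOUBLE)
    v <- readBin(pr$data, "double", n = length(pr$data) / 8L, size = 8L,
                 endian = "little")
    value <- array(v, dim = dims)
    if (length(dims) == 2 && all(dims == 1)) value <- v
  } else if (cls == MX_CHAR_CLASS) {
    codes <- if (pr$type == MI_UINT16) {
      readBin(pr$data, "integer", n = length(pr$data) / 2L, size = 2L,
              signed = FALSE, endian = "little")
    } else {
      # miUINT8 / miUTF8 single-byte encodings (as written by other tools)
      as.integer(pr$data)
    }
    m <- matrix(codes, nrow = dims[1], ncol = dims[2])
    value <- vapply(seq_len(dims[1]), function(i)
      sub(" +$", "", intToUtf8(m[i, ])), character(1))
  } else {
    stop_fmt("format_error", "unsupported MAT array class %d for '%s'",
             cls, name)
  }
  list(name = name, value = value)
}

#' Read named arrays from a MAT v5 file
#'
#' @param path a MAT v5 file written by [write_mat()] or another writer using
#'   uncompressed double/char arrays.
#' @return named list of arrays / character vectors.
#' @export
read_mat <- function(path) {
  assert_that(file.exists(path), "io_error", "file '%s' does not exist", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 128L)
  assert_that(length(hdr) == 128L, "format_error",
              "'%s' is too short to be a MAT v5 file", path)
  endian <- rawToChar(hdr[127:128])
  assert_that(endian %in% c("IM", "MI"), "format_error",
              "'%s' has no MAT v5 endian indicator", path)
  out <- list()
  repeat {
    tag <- read_tag(con)
    if (is.null(tag)) break
    assert_that(tag$type != MI_COMPRESSED, "format_error",
                "compressed MAT elements are not supported")
    assert_that(tag$type == MI_MATRIX, "format_error",
                "unexpected top-level MAT element type %d", tag$type)
    el <- readBin(con, "raw", n = tag$nbytes)
    parsed <- parse_matrix_element(el)
    out[[parsed$name]] <- parsed$value
  }
  out
}
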