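# Minimal MATLAB v5 (Level 5 MAT-file) reader: real numeric matrices only,
# uncompressed or zlib-compressed data elements. This covers the layout of the
# public "sEMG for Basic Hand Movements" archive (per-class trial matrices).
# v7.3 (HDF5) containers are not supported.

.mi_types <- c(miINT8 = 1L, miUINT8 = 2L, miINT16 = 3L, miUINT16 = 4L,
               miINT32 = 5L, miUINT32 = 6L, miSINGLE = 7L, miDOUBLE = 9L,
               miMATRIX = 14L, miCOMPRESSED = 15L, miUTF8 = 16L)

.read_mi_numeric <- function(raw, type, n, endian) {
  switch(as.character(type),
    "1" = as.numeric(readBin(raw, "integer", n, size = 1L, signed = TRUE, endian = endian)),
    "2" = as.numeric(readBin(raw, "integer", n, size = 1L, signed = FALSE, endian = endian)),
    "3" = as.numeric(readBin(raw, "integer", n, size = 2L, signed = TRUE, endian = endian)),
    "4" = as.numeric(readBin(raw, "integer", n, size = 2L, signed = FALSE, endian = endian)),
    "5" = as.numeric(readBin(raw, "integer", n, size = 4L, endian = endian)),
    "6" = as.numeric(readBin(raw, "integer", n, size = 4L, endian = endian)),
    "7" = readBin(raw, "double", n, size = 4L, endian = endian),
    "9" = readBin(raw, "double", n, size = 8L, endian = endian),
    stop("unsupported MAT data type ", type))
}

.mi_elsize <- function(type) {
  switch(as.character(type), "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L,
         "5" = 4L, "6" = 4L, "7" = 4L, "9" = 8L,
         stop("unsupported MAT data type ", type))
}

# Parse one tagged data element starting at offset `pos` (1-based) of `buf`.
# Returns list(type, data = raw payload, next_pos).
.read_element <- function(buf, pos, endian) {
  word1 <- readBin(buf[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = endian)
  small <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  if (small != 0L) {  # small data element: type/size packed in 4 bytes
    type <- bitwAnd(word1, 0xFFFFL)
    size <- small
    data <- buf[(pos + 4L):(pos + 3L + size)]
    list(type = type, data = data, next_pos = pos + 8L)
  } else {
    type <- word1
    size <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L, endian = endian)
    data <- if (size > 0L) buf[(pos + 8L):(pos + 7L + size)] else raw(0)
    pad <- if (type == .mi_types[["miCOMPRESSED"]]) 0L else (8L - size %% 8L) %% 8L
    list(type = type, data = data, next_pos = pos + 8L + size + pad)
  }
}

# Parse a miMATRIX payload into list(name, value) (value = numeric matrix),
# or NULL for unsupported array classes.
.parse_matrix <- function(payload, endian) {
  pos <- 1L
  flags_el <- .read_element(payload, pos, endian)
  pos <- flags_el$next_pos
  flags_word <- readBin(flags_el$data[1:4], "integer", 1L, size = 4L, endian = endian)
  array_class <- bitwAnd(flags_word, 0xFFL)
  is_complex <- bitwAnd(flags_word, 0x800L) != 0L
  dims_el <- .read_element(payload, pos, endian)
  pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) %/% 4L,
                  size = 4L, endian = endian)
  name_el <- .read_element(payload, pos, endian)
  pos <- name_el$next_pos
  name <- rawToChar(name_el$data[name_el$data != as.raw(0L)])
  if (!array_class %in% 6:13) return(list(name = name, value = NULL))
  data_el <- .read_element(payload, pos, endian)
  n <- length(data_el$data) %/% .mi_elsize(data_el$type)
  vals <- .read_mi_numeric(data_el$data, data_el$type, n, endian)
  if (is_complex) warning("imaginary part of variable '", name, "' discarded")
  if (length(dims) == 2L) {
    value <- matrix(vals, nrow = dims[1L], ncol = dims[2L])  # column-major
  } else {
    value <- array(vals, dim = dims)
  }
  list(name = name, value = value)
}

#' Read numeric variables from a MATLAB v5 file
#'
#' Parses a Level 5 MAT-file and returns its real numeric array variables.
#' zlib-compressed data elements are decompressed; non-numeric variables
#' (cells, structs, char arrays, sparse) are skipped with a warning. MATLAB
#' v7.3 (HDF5-based) files are not supported.
#'
#' @param path Path to a `.mat` file.
#' @return Named list of numeric matrices/arrays.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128L) stop("not a MAT v5 file (too short): ", path)
  magic <- rawToChar(buf[127:128])
  endian <- if (magic == "IM") "little" else if (magic == "MI") "big" else
    stop("not a MAT v5 file (bad endian indicator): ", path)
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(buf)) {
    el <- .read_element(buf, pos, endian)
    pos <- el$next_pos
    if (el$type == .mi_types[["miCOMPRESSED"]]) {
      inner <- memDecompress(el$data, type = "gzip")
      el <- .read_element(inner, 1L, endian)
    }
    if (el$type != .mi_types[["miMATRIX"]]) next
    parsed <- .parse_matrix(el$data, endian)
    if (is.null(parsed$value)) {
      warning("skipping unsupported variable '", parsed$name, "'")
    } else {
      out[[parsed$name]] <- parsed$value
    }
  }
  out
}

.hand_movement_prefixes <- c(cyl = "CY", tip = "TI", hook = "HO",
                             palm = "PA", spher = "SP", lat = "LA")

#' Read an sEMG basic-hand-movements archive
#'
#' Reads a MATLAB v5 container holding per-class trial matrices named
#' `<prefix>_ch1` / `<prefix>_ch2` with prefixes `cyl`, `tip`, `hook`, `palm`,
#' `spher`, `lat` (rows = trials, columns = samples), the layout used by the
#' public basic-hand-movements recordings (2 channels, 500 Hz, 6 s trials).
#' Prefixes are mapped to the class labels CY, TI, HO, PA, SP, LA.
#'
#' @param path Path to the `.mat` file.
#' @param rate Sampling rate in Hz (the archive's recordings are 500 Hz).
#' @param subject Subject identifier attached to all returned recordings.
#' @return List of two-channel `"emg_recording"` objects, one per trial per
#'   class.
#' @export
read_hand_movements_mat <- function(path, rate = 500, subject = 1L) {
  vars <- read_mat5(path)
  needed <- as.vector(outer(names(.hand_movement_prefixes),
                            c("_ch1", "_ch2"), paste0))
  missing <- setdiff(needed, names(vars))
  if (length(missing) > 0L)
    stop("archive is missing variables ", paste(missing, collapse = ", "),
         "; found: ", paste(names(vars), collapse = ", "))
  recs <- list()
  for (prefix in names(.hand_movement_prefixes)) {
    label <- .hand_movement_prefixes[[prefix]]
    ch1 <- vars[[paste0(prefix, "_ch1")]]
    ch2 <- vars[[paste0(prefix, "_ch2")]]
    if (!identical(dim(ch1), dim(ch2)))
      stop("channel matrices for class ", label, " have different shapes")
    for (t in seq_len(nrow(ch1))) {
      row <- cbind(ch1 = ch1[t, ], ch2 = ch2[t, ])
      if (!all(is.finite(row)))
        stop("non-finite samples in class ", label, ", trial ", t)
      recs[[length(recs) + 1L]] <-
        recording(row, rate = rate, label = label, subject = subject,
                  trial = t)
    }
  }
  recs
}
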