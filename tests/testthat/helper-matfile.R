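# Minimal MAT v5 writer used to build .mat fixtures at test time (binary
# fixtures are generated, not checked in). Real double matrices only; one
# variable per data element, optionally zlib-compressed.

mat5_matrix_element <- function(name, m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  # array flags: miUINT32 x 2; class mxDOUBLE_CLASS = 6, no flags
  writeBin(c(6L, 8L), con, size = 4L, endian = "little")
  writeBin(c(6L, 0L), con, size = 4L, endian = "little")
  # dimensions: miINT32 x 2
  writeBin(c(5L, 8L), con, size = 4L, endian = "little")
  writeBin(dim(m), con, size = 4L, endian = "little")
  # name: miINT8, padded to an 8-byte boundary
  nm <- charToRaw(name)
  writeBin(c(1L, length(nm)), con, size = 4L, endian = "little")
  writeBin(nm, con)
  pad <- (8L - length(nm) %% 8L) %% 8L
  if (pad > 0L) writeBin(raw(pad), con)
  # real data: miDOUBLE, column-major
  writeBin(c(9L, 8L * length(m)), con, size = 4L, endian = "little")
  writeBin(as.vector(m), con, size = 8L, endian = "little")
  rawConnectionValue(con)
}

write_mat5 <- function(path, vars, compress = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- charToRaw("MATLAB 5.0 MAT-file, generated test fixture")
  writeBin(c(desc, raw(116L - length(desc))), con)   # text header
  writeBin(raw(8L), con)                             # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)               # version 0x0100
  writeBin(charToRaw("IM"), con)                     # little-endian indicator
  for (nm in names(vars)) {
    payload <- mat5_matrix_element(nm, vars[[nm]])
    # full miMATRIX element, tag included
    tag <- writeBin(c(14L, length(payload)), raw(), size = 4L,
                    endian = "little")
    el <- c(tag, payload)
    if (compress) {
      # MATLAB compresses the complete tagged element
      z <- memCompress(el, "gzip")
      writeBin(c(15L, length(z)), con, size = 4L, endian = "little")
      writeBin(z, con)
    } else {
      writeBin(el, con)
    }
  }
  invisible(path)
}

# the six per-class variable pairs expected by read_hand_movements_mat(),
# filled with reproducible values: trials x samples matrices
hand_movement_vars <- function(n_trials = 3L, n_samples = 100L, seed = 99L) {
  set.seed(seed)
  prefixes <- c("cyl", "tip", "hook", "palm", "spher", "lat")
  vars <- list()
  for (p in prefixes) for (ch in 1:2)
    vars[[paste0(p, "_ch", ch)]] <-
      matrix(rnorm(n_trials * n_samples, sd = 0.01), n_trials, n_samples)
  vars
}
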