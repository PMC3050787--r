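# Minimal baseline TIFF codec: 8-bit/channel, uncompressed, chunky
# (interleaved) RGB/RGBA/greyscale, single image per file.  No R TIFF
# package is available in the target environment, and micrograph fixtures
# only need this subset; anything else is rejected with a format error.
# Little-endian and big-endian files are both read; files are written
# little-endian ("II").

TIFF_TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
              photometric = 262L, strip_offsets = 273L, samples = 277L,
              rows_per_strip = 278L, strip_bytes = 279L, planar = 284L,
              extra_samples = 338L)

read_tiff_rgb <- function(path) {
  if (!file.exists(path)) pv_io_error("cannot read TIFF '%s': no such file", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) pv_format_error("'%s' is not a TIFF file", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   pv_format_error("'%s' is not a TIFF file", path))
  rd_int <- function(offset, size, n = 1L) # offset 0-based
    readBin(raw[(offset + 1L):(offset + size * n)], "integer",
            n = n, size = size, endian = endian, signed = size >= 4L)
  if (rd_int(2, 2) != 42L) pv_format_error("'%s' is not a TIFF file", path)
  ifd <- rd_int(4, 4)
  n_entries <- rd_int(ifd, 2)
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd + 2L + (e - 1L) * 12L
    tag <- rd_int(off, 2)
    type <- rd_int(off + 2L, 2)
    count <- rd_int(off + 4L, 4)
    size <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
    if (is.na(size)) next  # ignore RATIONALs etc.
    vals <- if (size * count <= 4L) rd_int(off + 8L, size, count)
            else rd_int(rd_int(off + 8L, 4), size, count)
    tags[[as.character(tag)]] <- vals
  }
  get_tag <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  W <- get_tag(TIFF_TAG["width"]); H <- get_tag(TIFF_TAG["length"])
  if (is.null(W) || is.null(H))
    pv_format_error("TIFF '%s' lacks image dimensions", path)
  comp <- get_tag(TIFF_TAG["compression"], 1L)
  if (comp != 1L)
    pv_format_error("TIFF '%s': compression %d unsupported (uncompressed only)",
                    path, comp)
  bits <- get_tag(TIFF_TAG["bits"], 1L)
  if (any(bits != 8L))
    pv_format_error("TIFF '%s': %s bits/sample unsupported (8-bit only)",
                    path, paste(unique(bits), collapse = "/"))
  spp <- get_tag(TIFF_TAG["samples"], 1L)
  photometric <- get_tag(TIFF_TAG["photometric"], 1L)
  if (spp < 3L || photometric != 2L)
    pv_format_error("TIFF '%s' is not an RGB image (greyscale input rejected)",
                    path)
  planar <- get_tag(TIFF_TAG["planar"], 1L)
  if (planar != 1L)
    pv_format_error("TIFF '%s': planar configuration unsupported", path)
  offsets <- get_tag(TIFF_TAG["strip_offsets"])
  counts <- get_tag(TIFF_TAG["strip_bytes"])
  if (is.null(offsets) || is.null(counts))
    pv_format_error("TIFF '%s' lacks strip layout tags", path)
  data <- unlist(lapply(seq_along(offsets), function(s)
    raw[(offsets[s] + 1L):(offsets[s] + counts[s])]), use.names = FALSE)
  if (length(data) < H * W * spp)
    pv_format_error("TIFF '%s': truncated pixel data", path)
  px <- as.integer(data[seq_len(H * W * spp)])
  # chunky layout: sample fastest, then column, then row
  arr <- aperm(array(px, dim = c(spp, W, H)), c(3, 2, 1))
  arr[, , 1:3, drop = FALSE]  # strip alpha/extra samples
}

write_tiff_rgb <- function(pixels, path) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  data <- as.raw(aperm(pixels, c(3, 2, 1)))  # chunky RGB, row-major
  n_data <- length(data)
  header_size <- 8L
  data_offset <- header_size
  bits_offset <- data_offset + n_data
  if (bits_offset %% 2L == 1L) bits_offset <- bits_offset + 1L
  ifd_offset <- bits_offset + 6L
  con <- tryCatch(file(path, "wb"), error = function(e)
    pv_io_error("cannot write TIFF '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); w2(42L); w4(ifd_offset)
  writeBin(data, con)
  if (bits_offset > data_offset + n_data) writeBin(as.raw(0), con)
  w2(c(8L, 8L, 8L))                        # BitsPerSample value block
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  w2(10L)                                  # number of IFD entries
  entry(TIFF_TAG[["width"]], 3L, 1L, W)
  entry(TIFF_TAG[["length"]], 3L, 1L, H)
  entry(TIFF_TAG[["bits"]], 3L, 3L, bits_offset)
  entry(TIFF_TAG[["compression"]], 3L, 1L, 1L)
  entry(TIFF_TAG[["photometric"]], 3L, 1L, 2L)
  entry(TIFF_TAG[["strip_offsets"]], 4L, 1L, data_offset)
  entry(TIFF_TAG[["samples"]], 3L, 1L, 3L)
  entry(TIFF_TAG[["rows_per_strip"]], 3L, 1L, H)
  entry(TIFF_TAG[["strip_bytes"]], 4L, 1L, n_data)
  entry(TIFF_TAG[["planar"]], 3L, 1L, 1L)
  w4(0L)                                   # no next IFD
  invisible(path)
}
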