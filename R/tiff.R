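# Minimal baseline TIFF codec for calibrated microscopy stacks.
#
# Scope (deliberately narrow, matching the package's I/O contract):
#   write: little-endian, uncompressed, one strip per slice, grayscale
#          8/16/32-bit unsigned or 8-bit RGB (chunky), X/YResolution as
#          pixels-per-micron RATIONALs and an ImageJ-style ImageDescription
#          carrying the z spacing.
#   read:  either byte order, uncompressed, PlanarConfiguration 1, any
#          strip layout, 8/16/32-bit unsigned grayscale or 8-bit RGB.
# Anything else (compression, tiles, floats, palettes) is rejected with a
# format error rather than guessed at.

TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

rd_int <- function(buf, pos, size, endian, signed = FALSE) {
  readBin(buf[pos:(pos + size - 1L)], "integer", n = 1L, size = size,
          signed = signed, endian = endian)
}

rd_u4 <- function(buf, pos, endian) {
  v <- rd_int(buf, pos, 4L, endian, signed = TRUE)
  if (v < 0) v <- v + 2^32
  v
}

tiff_format_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Parse one IFD entry's values into a numeric (or character) vector.
tiff_tag_values <- function(buf, pos, endian) {
  tag <- rd_int(buf, pos, 2L, endian)
  type <- rd_int(buf, pos + 2L, 2L, endian)
  count <- rd_u4(buf, pos + 4L, endian)
  if (type < 1L || type > 12L) return(list(tag = tag, values = NULL))
  size <- TIFF_TYPE_SIZE[type]
  nbytes <- size * count
  vpos <- if (nbytes <= 4) pos + 8L else rd_u4(buf, pos + 8L, endian) + 1L
  if (type == 2L) { # ASCII
    raw <- buf[vpos:(vpos + count - 1L)]
    raw <- raw[seq_len(max(which(raw != as.raw(0)), 0L))]
    return(list(tag = tag, values = rawToChar(raw)))
  }
  vals <- numeric(count)
  for (i in seq_len(count)) {
    p <- vpos + (i - 1L) * size
    vals[i] <- switch(as.character(type),
      "1" = as.integer(buf[p]),
      "3" = rd_int(buf, p, 2L, endian),
      "4" = rd_u4(buf, p, endian),
      "5" = { # RATIONAL
        num <- rd_u4(buf, p, endian); den <- rd_u4(buf, p + 4L, endian)
        if (den == 0) NA_real_ else num / den
      },
      "6" = rd_int(buf, p, 1L, endian, signed = TRUE),
      "8" = rd_int(buf, p, 2L, endian, signed = TRUE),
      "9" = rd_int(buf, p, 4L, endian, signed = TRUE),
      NA_real_)
  }
  list(tag = tag, values = vals)
}

# Read a whole multi-page TIFF.  Returns list(pages = list of (H,W) numeric
# matrices or (H,W,3) arrays, bits, samples, dx, dy, dz) where dx/dy/dz are
# NA when the file carries no calibration.
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 8L) tiff_format_error("'%s' is not a TIFF file", path)
  order_tag <- rawToChar(buf[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   tiff_format_error("'%s' is not a TIFF file", path))
  if (rd_int(buf, 3L, 2L, endian) != 42L)
    tiff_format_error("'%s' is not a TIFF file", path)
  ifd_off <- rd_u4(buf, 5L, endian)

  pages <- list()
  bits_all <- NULL; samples_all <- NULL
  dx <- NA_real_; dy <- NA_real_; dz <- NA_real_
  while (ifd_off != 0) {
    pos <- ifd_off + 1L
    n_entries <- rd_int(buf, pos, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- tiff_tag_values(buf, pos + 2L + (i - 1L) * 12L, endian)
      tags[[as.character(e$tag)]] <- e$values
    }
    get <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- get(256); H <- get(257)
    if (is.null(W) || is.null(H))
      tiff_format_error("TIFF page lacks width/height tags")
    compression <- get(259, 1)
    if (compression != 1)
      tiff_format_error("compressed TIFF (compression %d) is not supported",
                        as.integer(compression))
    photometric <- get(262, 1)
    samples <- as.integer(get(277, 1))
    bits <- as.integer(get(258, 1))
    if (length(unique(bits)) != 1L)
      tiff_format_error("heterogeneous bits per sample are not supported")
    bits <- bits[1]
    if (get(284, 1) != 1)
      tiff_format_error("planar TIFF layout is not supported")
    sfmt <- get(339, rep(1, samples))
    if (any(sfmt != 1))
      tiff_format_error("only unsigned integer samples are supported (SampleFormat %s)",
                        paste(sfmt, collapse = ","))
    if (photometric == 2L) {
      if (samples != 3L || bits != 8L)
        tiff_format_error("only 8-bit 3-sample RGB is supported")
    } else if (photometric %in% c(0L, 1L)) {
      if (samples != 1L)
        tiff_format_error("multi-sample grayscale is not supported")
      if (!bits %in% c(8L, 16L, 32L))
        tiff_format_error("unsupported bit depth %d (want 8, 16 or 32)", bits)
    } else {
      tiff_format_error("unsupported photometric interpretation %d",
                        as.integer(photometric))
    }
    offsets <- get(273); counts <- get(279)
    if (is.null(offsets) || is.null(counts))
      tiff_format_error("TIFF page lacks strip tags")
    strip_raw <- raw(sum(counts))
    at <- 0L
    for (i in seq_along(offsets)) {
      if (counts[i] == 0) next
      strip_raw[(at + 1L):(at + counts[i])] <-
        buf[(offsets[i] + 1L):(offsets[i] + counts[i])]
      at <- at + counts[i]
    }
    npix <- W * H * samples
    v <- if (bits == 32L) {
      x <- readBin(strip_raw, "integer", n = npix, size = 4L, endian = endian)
      x <- as.numeric(x); x[x < 0] <- x[x < 0] + 2^32; x
    } else {
      as.numeric(readBin(strip_raw, "integer", n = npix, size = bits %/% 8L,
                         signed = FALSE, endian = endian))
    }
    if (length(v) < npix)
      tiff_format_error("truncated TIFF pixel data")
    page <- if (samples == 1L) {
      t(matrix(v, nrow = W, ncol = H)) # file is row-major, x fastest
    } else {
      aperm(array(v, dim = c(3L, W, H)), c(3L, 2L, 1L))
    }
    pages[[length(pages) + 1L]] <- page
    bits_all <- c(bits_all, bits); samples_all <- c(samples_all, samples)

    xres <- get(282); yres <- get(283)
    if (!is.null(xres) && is.finite(xres) && xres > 0) dx <- 1 / xres
    if (!is.null(yres) && is.finite(yres) && yres > 0) dy <- 1 / yres
    desc <- get(270)
    if (is.character(desc)) {
      m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
      if (length(m) == 2L) dz <- as.numeric(m[2])
    }
    ifd_off <- rd_u4(buf, pos + 2L + n_entries * 12L, endian)
  }
  if (length(pages) == 0L) tiff_format_error("TIFF file has no pages")
  if (length(unique(bits_all)) != 1L ||
      length(unique(samples_all)) != 1L ||
      length(unique(vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"),
                           ""))) != 1L)
    tiff_format_error("TIFF pages differ in shape or depth")
  list(pages = pages, bits = bits_all[1], samples = samples_all[1],
       dx = dx, dy = dy, dz = dz)
}

wr2 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                 endian = "little")
wr4 <- function(con, v) {
  v <- as.numeric(v)
  v[v >= 2^31] <- v[v >= 2^31] - 2^32 # two's complement for unsigned LONG
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}

tiff_entry <- function(con, tag, type, count, value, is_offset = FALSE) {
  wr2(con, tag); wr2(con, type); wr4(con, count)
  if (is_offset || type == 4L) {
    wr4(con, value)
  } else if (type == 3L) {
    wr2(con, value); wr2(con, 0L)
  } else stop("internal: unsupported inline entry type")
}

# Write a multi-page TIFF.  `data`: (H,W,Z) array for grayscale or
# (H,W,3,Z) for 8-bit RGB.  Values must already fit the requested depth.
write_tiff <- function(path, data, bits, dx = NA, dy = NA, dz = NA) {
  rgb <- length(dim(data)) == 4L
  if (rgb && (dim(data)[3] != 3L || bits != 8L))
    stop("RGB output must be (H, W, 3, Z) at 8 bits")
  d <- dim(data)
  H <- d[1]; W <- d[2]; Z <- d[length(d)]
  samples <- if (rgb) 3L else 1L
  bytes_px <- bits %/% 8L
  strip_size <- H * W * samples * bytes_px

  has_res <- is.finite(dx) && is.finite(dy)
  desc <- sprintf("ImageJ=1.53\nimages=%d\nslices=%d\nunit=micron\nspacing=%s\nloop=false\n",
                  Z, Z, format(if (is.finite(dz)) dz else 1, digits = 12))
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  # per-page IFD entry count: 256 257 258 259 262 273 277 278 279 (+339 gray)
  n_base <- if (rgb) 9L else 10L
  if (has_res) n_base <- n_base + 3L   # 282 283 296
  # page 1 additionally carries 270 (ImageDescription)
  aux_size <- function(first) {
    s <- 0L
    if (has_res) s <- s + 16L               # two RATIONALs
    if (rgb) s <- s + 6L                    # BitsPerSample (3 x SHORT)
    if (first) s <- s + length(desc_raw)
    s
  }
  ifd_size <- function(first) 2L + (n_base + (if (first) 1L else 0L)) * 12L + 4L

  # layout: header | page1: pixels aux ifd | page2: pixels aux ifd | ...
  offs <- vector("list", Z)
  at <- 8L
  for (z in seq_len(Z)) {
    first <- z == 1L
    strip_off <- at
    aux_off <- at + strip_size
    ifd_off <- aux_off + aux_size(first)
    offs[[z]] <- list(strip = strip_off, aux = aux_off, ifd = ifd_off)
    at <- ifd_off + ifd_size(first)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); wr2(con, 42L); wr4(con, offs[[1]]$ifd)
  for (z in seq_len(Z)) {
    first <- z == 1L
    o <- offs[[z]]
    # pixel data, row-major (x fastest); channel fastest for RGB
    sl <- if (rgb) data[, , , z, drop = FALSE] else data[, , z, drop = FALSE]
    v <- if (rgb) as.vector(aperm(array(sl, d[1:3]), c(3, 2, 1)))
         else as.vector(t(matrix(sl, H, W)))
    if (bits == 32L) {
      wr4(con, v)
    } else {
      v <- as.integer(v) # writeBin truncates to low bytes, correct for unsigned
      writeBin(v, con, size = bytes_px, endian = "little")
    }
    # aux area
    aux_at <- o$aux
    res_off <- bits3_off <- desc_off <- NA
    if (has_res) { res_off <- aux_at; wr4(con, c(10^7, round(10^7 * dx)))
                   wr4(con, c(10^7, round(10^7 * dy))); aux_at <- aux_at + 16L }
    if (rgb) { bits3_off <- aux_at; wr2(con, c(8L, 8L, 8L)); aux_at <- aux_at + 6L }
    if (first) { desc_off <- aux_at; writeBin(desc_raw, con) }
    # IFD, tags ascending
    wr2(con, n_base + (if (first) 1L else 0L))
    tiff_entry(con, 256L, 4L, 1L, W)
    tiff_entry(con, 257L, 4L, 1L, H)
    if (rgb) tiff_entry(con, 258L, 3L, 3L, bits3_off, is_offset = TRUE)
    else tiff_entry(con, 258L, 3L, 1L, bits)
    tiff_entry(con, 259L, 3L, 1L, 1L)
    tiff_entry(con, 262L, 3L, 1L, if (rgb) 2L else 1L)
    if (first) tiff_entry(con, 270L, 2L, length(desc_raw), desc_off,
                          is_offset = TRUE)
    tiff_entry(con, 273L, 4L, 1L, o$strip)
    tiff_entry(con, 277L, 3L, 1L, samples)
    tiff_entry(con, 278L, 4L, 1L, H)
    tiff_entry(con, 279L, 4L, 1L, strip_size)
    if (has_res) {
      tiff_entry(con, 282L, 5L, 1L, res_off, is_offset = TRUE)
      tiff_entry(con, 283L, 5L, 1L, res_off + 8L, is_offset = TRUE)
      tiff_entry(con, 296L, 3L, 1L, 1L) # no absolute unit; microns in desc
    }
    if (!rgb) tiff_entry(con, 339L, 3L, 1L, 1L)
    wr4(con, if (z < Z) offs[[z + 1L]]$ifd else 0L)
  }
  invisible(path)
}
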