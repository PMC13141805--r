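# Minimal single-strip uncompressed grayscale TIFF writer, used to build
# fixtures carrying scale metadata (ImageDescription MPP entries, resolution
# tags) that tiff::writeTIFF cannot embed. Little-endian, baseline tags only.
write_minimal_tiff <- function(path, width = 8, height = 8,
                               description = NULL,
                               xres = NULL, res_unit = c("none", "inch", "cm")) {
  res_unit <- match.arg(res_unit)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  pixels <- as.raw(rep(128, width * height))
  data_offset <- 8L
  ifd_offset <- data_offset + length(pixels)

  entries <- list(
    list(tag = 256L, type = 3L, count = 1L, value = width),
    list(tag = 257L, type = 3L, count = 1L, value = height),
    list(tag = 258L, type = 3L, count = 1L, value = 8L),
    list(tag = 259L, type = 3L, count = 1L, value = 1L),
    list(tag = 262L, type = 3L, count = 1L, value = 1L),
    list(tag = 273L, type = 4L, count = 1L, value = data_offset),
    list(tag = 277L, type = 3L, count = 1L, value = 1L),
    list(tag = 278L, type = 3L, count = 1L, value = height),
    list(tag = 279L, type = 4L, count = 1L, value = length(pixels))
  )
  extra <- raw(0)
  n_fixed <- length(entries) +
    (!is.null(description)) + (!is.null(xres)) * 2L
  extra_offset <- ifd_offset + 2L + 12L * n_fixed + 4L
  if (!is.null(description)) {
    dbytes <- c(charToRaw(description), as.raw(0))
    entries <- c(entries, list(list(tag = 270L, type = 2L,
                                    count = length(dbytes),
                                    value = extra_offset + length(extra))))
    extra <- c(extra, dbytes)
  }
  if (!is.null(xres)) {
    rat <- raw(8)
    num <- as.integer(round(xres * 10000)); den <- 10000L
    rcon <- rawConnection(raw(0), "wb")
    writeBin(c(num, den), rcon, size = 4, endian = "little")
    rat <- rawConnectionValue(rcon); close(rcon)
    entries <- c(entries, list(
      list(tag = 282L, type = 5L, count = 1L,
           value = extra_offset + length(extra))))
    extra <- c(extra, rat)
    unit_code <- switch(res_unit, none = 1L, inch = 2L, cm = 3L)
    entries <- c(entries, list(list(tag = 296L, type = 3L, count = 1L,
                                    value = unit_code)))
  }
  entries <- entries[order(vapply(entries, `[[`, integer(1), "tag"))]

  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_offset)
  writeBin(pixels, con)
  # IFD
  w16(length(entries))
  for (e in entries) {
    w16(e$tag); w16(e$type); w32(e$count)
    if (e$type == 3L && e$count == 1L) {
      w16(e$value); w16(0L)
    } else {
      w32(e$value)
    }
  }
  w32(0L)                                 # no next IFD
  if (length(extra)) writeBin(extra, con)
  invisible(path)
}
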