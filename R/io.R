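# Volume I/O. Axis order is fixed as (z, y, x); TIFF pages map to z
# slices, the dominant microscopy convention. Reading goes through the
# tiff package (grayscale 8/16-bit unsigned or 32-bit float pages).
# Writing emits 32-bit float samples; because libtiff wrappers commonly
# restrict float samples to [0, 1], the writer assembles the (baseline,
# little-endian, one strip per page) TIFF directly so arbitrary
# intensity ranges survive a round trip bit-exactly at float precision.
# MRC (mode 2, float32) is read and written natively as well.

vol_ext <- function(path) tolower(tools::file_ext(path))

#' Read a 3-D volume from TIFF or MRC
#'
#' Multi-page grayscale TIFF (pages = z slices) or MRC, dispatched on
#' the file extension. Integer sample formats are promoted to float;
#' values are returned as stored (no rescaling). Single-page (2-D)
#' images and negative intensities are rejected.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.mrc`.
#' @return a `Volume3D` in (z, y, x) order.
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- vol_ext(path)
    a <- switch(ext,
        tif = , tiff = read_tiff_volume(path),
        mrc = read_mrc(path),
        stop("unsupported volume format '.", ext, "' (use .tif/.tiff/.mrc)"))
    if (any(a < 0))
        stop("negative intensities in ", path,
             "; volumes must be non-negative")
    Volume3D(a)
}

read_tiff_volume <- function(path) {
    # as.is = TRUE keeps integer samples unscaled but is refused for
    # float samples, which are returned as stored either way
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                          tiff::readTIFF(path, all = TRUE, as.is = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
        stop("'", path, "' has a single page: expected a 3-D z-stack ",
             "(multi-page TIFF, one page per z slice)")
    shp <- dim(pages[[1]])
    if (length(shp) != 2L)
        stop("only single-channel grayscale TIFF pages are supported")
    if (!all(vapply(pages, function(p) identical(dim(p), shp), TRUE)))
        stop("TIFF pages differ in shape")
    a <- array(0, c(length(pages), shp))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    a
}

#' Write a 3-D volume as TIFF or MRC
#'
#' 32-bit float output in both formats, dispatched on the extension
#' (`.tif`/`.tiff` gives a multi-page grayscale TIFF with one page per z
#' slice; `.mrc` gives MRC mode 2). Round-trips with [readVolume()]
#' bit-exactly at float32 precision.
#'
#' @param vol a `Volume3D` or 3-D array.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
    a <- as_arr(vol, "volume")
    ext <- vol_ext(path)
    switch(ext,
        tif = , tiff = write_tiff_f32(a, path),
        mrc = write_mrc(a, path),
        stop("unsupported volume format '.", ext, "' (use .tif/.tiff/.mrc)"))
    invisible(path)
}

# --- minimal baseline TIFF writer (little-endian, float32, grayscale) ---

tiff_entry <- function(tag, type, count, value) {
    # returns raw(12): tag(2) type(2) count(4) value/offset(4)
    con <- rawConnection(raw(0), "wb")
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
    } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    out <- rawConnectionValue(con)
    close(con)
    out
}

write_tiff_f32 <- function(a, path) {
    d <- dim(a)                     # (z, y, x)
    nz <- d[1]; h <- d[2]; w <- d[3]
    strip_bytes <- w * h * 4L
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("II"), con)
    writeBin(42L, con, size = 2, endian = "little")
    data_start <- 8L
    first_ifd <- data_start + nz * strip_bytes
    writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
    for (z in seq_len(nz))          # pixel data, row-major within a page
        writeBin(as.numeric(t(a[z, , , drop = TRUE])), con, size = 4,
                 endian = "little")
    n_entries <- 10L
    ifd_size <- 2L + n_entries * 12L + 4L
    for (z in seq_len(nz)) {
        strip_off <- data_start + (z - 1L) * strip_bytes
        next_ifd <- if (z < nz) first_ifd + z * ifd_size else 0L
        writeBin(n_entries, con, size = 2, endian = "little")
        writeBin(tiff_entry(256L, 3L, 1L, w), con)          # ImageWidth
        writeBin(tiff_entry(257L, 3L, 1L, h), con)          # ImageLength
        writeBin(tiff_entry(258L, 3L, 1L, 32L), con)        # BitsPerSample
        writeBin(tiff_entry(259L, 3L, 1L, 1L), con)         # no compression
        writeBin(tiff_entry(262L, 3L, 1L, 1L), con)         # min-is-black
        writeBin(tiff_entry(273L, 4L, 1L, strip_off), con)  # StripOffsets
        writeBin(tiff_entry(277L, 3L, 1L, 1L), con)         # SamplesPerPixel
        writeBin(tiff_entry(278L, 3L, 1L, h), con)          # RowsPerStrip
        writeBin(tiff_entry(279L, 4L, 1L, strip_bytes), con) # byte counts
        writeBin(tiff_entry(339L, 3L, 1L, 3L), con)         # IEEE float
        writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    }
    invisible(path)
}

# --- MRC mode 2 (float32) ---

read_mrc <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
    nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
    mode <- hdr_int[4]
    if (mode != 2L)
        stop("only MRC mode 2 (float32) is supported; got mode ", mode)
    seek(con, 92)
    nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    seek(con, 1024 + nsymbt)
    v <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                 endian = "little")
    if (length(v) != nx * ny * nz) stop("truncated MRC data in ", path)
    a <- array(v, c(nx, ny, nz))    # x fastest on disk
    aperm(a, c(3, 2, 1))            # -> (z, y, x)
}

write_mrc <- function(a, path) {
    d <- dim(a)                     # (z, y, x)
    con <- file(path, "wb")
    on.exit(close(con))
    int4 <- function(x) writeBin(as.integer(x), con, size = 4,
                                 endian = "little")
    flt4 <- function(x) writeBin(as.numeric(x), con, size = 4,
                                 endian = "little")
    int4(c(d[3], d[2], d[1]))       # nx ny nz
    int4(2L)                        # mode 2 = float32
    int4(c(0L, 0L, 0L))             # nxstart nystart nzstart
    int4(c(d[3], d[2], d[1]))       # mx my mz
    flt4(c(d[3], d[2], d[1]))       # cella (1 A per voxel placeholder)
    flt4(c(90, 90, 90))             # cellb
    int4(c(1L, 2L, 3L))             # mapc mapr maps
    flt4(c(min(a), max(a), mean(a)))
    int4(c(0L, 0L))                 # ispg, nsymbt
    int4(rep(0L, 25))               # extra
    flt4(c(0, 0, 0))                # origin
    writeBin(charToRaw("MAP "), con)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
    flt4(stats::sd(a))
    int4(0L)                        # nlabl
    writeBin(raw(800), con)         # labels
    flt4(as.vector(aperm(a, c(3, 2, 1))))  # x fastest, then y, then z
    invisible(path)
}
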