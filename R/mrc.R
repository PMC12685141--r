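# Minimal MRC2014 volume/stack I/O. Writing uses mode 2 (float32) with
# the voxel size carried in the cell dimensions; reading accepts modes
# 0/1/2 and normalizes byte order.

#' Write a volume or image stack as MRC2014 (mode 2)
#'
#' @param x A `tomo_volume`, or a 2D/3D numeric array.
#' @param path Output path.
#' @param voxel_size Angstrom per voxel (taken from a `tomo_volume`
#'   automatically).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_size = NULL) {
  if (inherits(x, "tomo_volume")) {
    voxel_size <- x$voxel_size
    x <- x$density
  }
  if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
  d <- dim(x)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                    # nx ny nz
  wi(2)                    # mode 2 = float32
  wi(c(0, 0, 0))           # nxstart
  wi(d)                    # mx my mz
  wf(d * voxel_size)       # cella
  wf(c(90, 90, 90))        # cellb
  wi(c(1, 2, 3))           # mapc mapr maps
  wf(c(min(x), max(x), mean(x)))
  wi(c(0, 0))              # ispg, nsymbt
  wi(rep(0, 25))           # extra
  wf(c(0, 0, 0))           # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(x))
  wi(0)                    # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume or image stack
#'
#' @param path File path.
#' @return List with `data` (2D or 3D array), `voxel_size` (Angstrom,
#'   from cella/mx), `mode`, `dim`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("truncated MRC header")
  ri <- function(off, n, endian) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                         "integer", n = n, size = 4, endian = endian)
  rf <- function(off, n, endian) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                         "numeric", n = n, size = 4, endian = endian)
  endian <- "little"
  nxyz <- ri(0, 3, endian)
  if (any(nxyz <= 0) || any(nxyz > 1e6)) {
    endian <- "big"
    nxyz <- ri(0, 3, endian)
    if (any(nxyz <= 0) || any(nxyz > 1e6)) stop("malformed MRC header: implausible nx/ny/nz")
  }
  mode <- ri(12, 1, endian)
  if (!mode %in% c(0, 1, 2)) stop(sprintf("unsupported MRC mode %d (need 0, 1 or 2)", mode))
  mxyz <- ri(28, 3, endian)
  cella <- rf(40, 3, endian)
  if (mxyz[1] <= 0) stop("malformed MRC header: non-positive mx")
  voxel <- cella[1] / mxyz[1]
  n <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endian)
  )
  if (length(data) < n) stop("truncated MRC data section")
  dim(data) <- nxyz
  if (nxyz[3] == 1) dim(data) <- nxyz[1:2]
  list(data = data, voxel_size = voxel, mode = mode, dim = nxyz)
}
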