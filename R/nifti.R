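#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Minimal NIfTI-1 reader/writer. Only what the pipeline needs: 3D volumes,
## little/big endian detection, gzip via connections, sform/qform affines,
## scl_slope/scl_inter scaling. Written by hand because the installed R stack
## carries no NIfTI package.
## ---------------------------------------------------------------------------

.niiDatatypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L, 256L, 512L, 768L),
  what   = c("integer", "integer", "integer", "double", "double",
             "integer", "integer", "integer"),
  size   = c(1L, 2L, 4L, 4L, 8L, 1L, 2L, 4L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE)

.isGz <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

.readNiftiRaw <- function(path) {
  open_fn <- if (.isGz(path)) gzfile else file
  con <- open_fn(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rd <- function(off, what, n, size) # off is 0-based byte offset
    readBin(hdr[(off + 1L):(off + n * size)], what, n, size, endian = endian)
  dim0     <- rd(40L, "integer", 8L, 2L)
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim   <- rd(76L, "double", 8L, 4L)
  voxoff   <- rd(108L, "double", 1L, 4L)
  sclslope <- rd(112L, "double", 1L, 4L)
  sclinter <- rd(116L, "double", 1L, 4L)
  qform    <- rd(252L, "integer", 1L, 2L)
  sform    <- rd(254L, "integer", 1L, 2L)
  quat     <- rd(256L, "double", 6L, 4L)
  srow     <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
  magic    <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)

  ndim <- dim0[1L]
  if (ndim > 3L && any(dim0[seq(5L, 1L + ndim)] > 1L))
    stop("expected 3D volume, got ", ndim, "D: ", path)
  d <- pmax(dim0[2:4], 1L)

  spec <- .niiDatatypes[.niiDatatypes$code == datatype, ]
  if (nrow(spec) == 0L) stop("unsupported NIfTI datatype code: ", datatype)

  nvox <- prod(d)
  ## data starts at vox_offset; header read consumed 348 bytes
  skip <- as.integer(round(voxoff)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  vals <- readBin(con, spec$what, nvox, spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data: ", path)
  if (!is.na(sclslope) && sclslope != 0 && !(sclslope == 1 && sclinter == 0))
    vals <- vals * sclslope + sclinter

  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  affine <- NULL
  if (sform > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform > 0L) {
    b <- quat[1]; c_ <- quat[2]; d_ <- quat[3]
    a2 <- 1 - b * b - c_ * c_ - d_ * d_
    a <- if (a2 < 0) 0 else sqrt(a2)
    R <- matrix(c(
      a * a + b * b - c_ * c_ - d_ * d_, 2 * (b * c_ - a * d_), 2 * (b * d_ + a * c_),
      2 * (b * c_ + a * d_), a * a + c_ * c_ - b * b - d_ * d_, 2 * (c_ * d_ - a * b),
      2 * (b * d_ - a * c_), 2 * (c_ * d_ + a * b), a * a + d_ * d_ - b * b - c_ * c_),
      nrow = 3L, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    S <- diag(c(spacing[1], spacing[2], spacing[3] * qfac))
    affine <- rbind(cbind(R %*% S, quat[4:6]), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(spacing, 1))
  }
  list(data = array(vals, d), spacing = spacing, affine = affine)
}

.writeNiftiRaw <- function(data, spacing, affine, path, datatype) {
  spec <- .niiDatatypes[.niiDatatypes$code == datatype, ]
  gz <- grepl("\\.gz$", path)
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  d <- dim(data)
  wb_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wb_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  wb_f32 <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  wb_raw <- function(n) writeBin(raw(n), con)
  wb_chr <- function(s, n) {
    r <- charToRaw(s); r <- c(r, raw(n - length(r))); writeBin(r[seq_len(n)], con)
  }

  wb_i32(348L)                               # sizeof_hdr
  wb_raw(36L)                                # data_type..dim_info
  wb_i16(c(3L, d[1], d[2], d[3], 1L, 1L, 1L, 1L))  # dim
  wb_f32(c(0, 0, 0)); wb_i16(0L)             # intent
  wb_i16(datatype)                           # datatype
  wb_i16(spec$size * 8L)                     # bitpix
  wb_i16(0L)                                 # slice_start
  wb_f32(c(1, spacing[1], spacing[2], spacing[3], 0, 0, 0, 0))  # pixdim
  wb_f32(352)                                # vox_offset
  wb_f32(1); wb_f32(0)                       # scl_slope, scl_inter
  wb_i16(0L); wb_raw(1L)                     # slice_end, slice_code
  writeBin(as.raw(10L), con)                 # xyzt_units = mm | unknown time
  wb_f32(c(0, 0, 0, 0))                      # cal_max..toffset
  wb_i32(c(0L, 0L))                          # glmax, glmin
  wb_chr("mantis", 80L)                      # descrip
  wb_raw(24L)                                # aux_file
  wb_i16(0L); wb_i16(1L)                     # qform_code=0, sform_code=1
  wb_f32(c(0, 0, 0, 0, 0, 0))                # quaternion
  wb_f32(affine[1, ]); wb_f32(affine[2, ]); wb_f32(affine[3, ])
  wb_raw(16L)                                # intent_name
  wb_chr("n+1", 4L)                          # magic (includes trailing \0)
  wb_raw(4L)                                 # extension indicator

  if (spec$what == "integer") {
    writeBin(as.integer(data), con, spec$size, endian = "little")
  } else {
    writeBin(as.double(data), con, spec$size, endian = "little")
  }
  invisible(path)
}
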