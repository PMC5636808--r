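## Minimal NIfTI-1 input/output. The pre-installed R stack has no NIfTI
## reader, so the single-file (.nii / .nii.gz) little-endian subset of the
## format needed here is implemented directly: 348-byte header, float32 /
## float64 / int16 data, no extensions, identity orientation (inputs are
## assumed co-registered).

.niftiOpen <- function(path, mode) {
    if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param data numeric array (3 or 4 dimensions).
#' @param path output path ending in .nii or .nii.gz.
#' @param pixdim voxel sizes, mm (length 3).
#' @param datatype "float64" (default), "float32" or "int16".
#' @return the path, invisibly.
#' @export
writeNifti <- function(data, path, pixdim = c(1, 1, 1),
                       datatype = c("float64", "float32", "int16")) {
    datatype <- match.arg(datatype)
    nd <- length(dim(data))
    if (nd < 3L || nd > 4L) stop("'data' must be a 3D or 4D array")
    dims <- dim(data)
    con <- .niftiOpen(path, "wb")
    on.exit(close(con))
    w_i <- function(x, size) writeBin(as.integer(x), con, size = size,
        endian = "little")
    w_f <- function(x) writeBin(as.numeric(x), con, size = 4L,
        endian = "little")
    code <- switch(datatype, float64 = 64L, float32 = 16L, int16 = 4L)
    bitpix <- switch(datatype, float64 = 64L, float32 = 32L, int16 = 16L)

    w_i(348L, 4)                        # sizeof_hdr
    writeBin(raw(36L), con)             # data_type..dim_info
    w_i(c(nd, dims, rep(1L, 7L - nd)), 2)  # dim[8]
    w_f(c(0, 0, 0))                     # intent_p1..p3
    w_i(0L, 2)                          # intent_code
    w_i(code, 2)                        # datatype
    w_i(bitpix, 2)                      # bitpix
    w_i(0L, 2)                          # slice_start
    w_f(c(1, pixdim, rep(1, 7L - 1L - length(pixdim))))  # pixdim[8]
    w_f(352)                            # vox_offset
    w_f(c(1, 0))                        # scl_slope, scl_inter
    w_i(0L, 2)                          # slice_end
    writeBin(raw(2L), con)              # slice_code, xyzt_units
    w_f(c(0, 0, 0))                     # cal_max, cal_min, slice_duration
    w_f(0)                              # toffset
    w_i(c(0L, 0L), 4)                   # glmax, glmin
    writeBin(raw(104L), con)            # descrip, aux_file
    w_i(c(0L, 1L), 2)                   # qform_code = 0, sform_code = 1
    w_f(rep(0, 6))                      # quaternions
    w_f(c(pixdim[1], 0, 0, 0))          # srow_x
    w_f(c(0, pixdim[2], 0, 0))          # srow_y
    w_f(c(0, 0, pixdim[3], 0))          # srow_z
    writeBin(raw(16L), con)             # intent_name
    writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
    writeBin(raw(4L), con)              # extension flag

    if (datatype == "int16")
        writeBin(as.integer(round(as.vector(data))), con, size = 2L,
            endian = "little")
    else
        writeBin(as.numeric(as.vector(data)), con,
            size = if (datatype == "float64") 8L else 4L,
            endian = "little")
    invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Supports the subset written by [writeNifti()] plus uint8/int32 data and
#' either endianness; scl_slope/scl_inter are applied when set.
#'
#' @param path .nii or .nii.gz file.
#' @return list with \code{data} (array) and \code{pixdim}.
#' @export
readNifti <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    con <- .niftiOpen(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", n = 348L)
    rdInt <- function(off, size, n, endian)
        readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, endian = endian)
    endian <- "little"
    if (rdInt(0L, 4L, 1L, "little") != 348L) {
        if (rdInt(0L, 4L, 1L, "big") == 348L) endian <- "big"
        else stop("not a NIfTI-1 file: ", path)
    }
    rdI <- function(off, size, n) rdInt(off, size, n, endian)
    rdF <- function(off, n) readBin(hdr[(off + 1L):(off + 4L * n)],
        "numeric", n = n, size = 4L, endian = endian)
    dim0 <- rdI(40L, 2L, 8L)
    nd <- dim0[1]
    dims <- dim0[2:(1 + nd)]
    datatype <- rdI(70L, 2L, 1L)
    pixdim <- rdF(76L, 8L)[2:4]
    voxOffset <- rdF(108L, 1L)
    sclSlope <- rdF(112L, 1L)
    sclInter <- rdF(116L, 1L)
    toSkip <- voxOffset - 348L
    if (toSkip > 0) readBin(con, "raw", n = as.integer(toSkip))
    n <- prod(dims)
    vals <- switch(as.character(datatype),
        "2" = as.numeric(readBin(con, "integer", n = n, size = 1L,
            signed = FALSE)),
        "4" = as.numeric(readBin(con, "integer", n = n, size = 2L,
            endian = endian)),
        "8" = as.numeric(readBin(con, "integer", n = n, size = 4L,
            endian = endian)),
        "16" = readBin(con, "numeric", n = n, size = 4L, endian = endian),
        "64" = readBin(con, "numeric", n = n, size = 8L, endian = endian),
        stop("unsupported NIfTI datatype code: ", datatype))
    if (!is.na(sclSlope) && sclSlope != 0 && !(sclSlope == 1 &&
        sclInter == 0))
        vals <- vals * sclSlope + sclInter
    list(data = array(vals, dim = dims), pixdim = pixdim)
}

#' Read an FSL-style gradient table
#'
#' @param bvecPath 3-row whitespace-separated direction file.
#' @param bvalPath 1-row b-value file.
#' @return list with \code{directions} (K x 3, unnormalised as stored) and
#'   \code{bvals} (length K).
#' @export
readGradientTable <- function(bvecPath, bvalPath) {
    bv <- as.matrix(utils::read.table(bvecPath))
    if (nrow(bv) != 3L) stop("'", bvecPath, "' must have 3 rows")
    bvals <- as.numeric(utils::read.table(bvalPath))
    if (length(bvals) != ncol(bv))
        stop("bvec/bval dimensions disagree")
    list(directions = t(bv), bvals = bvals)
}

#' Write an FSL-style gradient table
#'
#' @param scheme a [GradientScheme-class].
#' @param prefix output prefix; writes \code{<prefix>.bvec} and
#'   \code{<prefix>.bval}.
#' @return the two paths, invisibly.
#' @export
writeGradientTable <- function(scheme, prefix) {
    bvec <- paste0(prefix, ".bvec")
    bval <- paste0(prefix, ".bval")
    utils::write.table(format(t(directions(scheme)), digits = 10),
        bvec, row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(paste(rep(bValue(scheme), nDirections(scheme)),
        collapse = " "), bval)
    invisible(c(bvec, bval))
}
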