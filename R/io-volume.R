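## Volume round-tripping: NRRD, NIfTI and a raw + JSON-sidecar dialect.
##
## NRRD files are written/parsed directly (text header + raw/gzip data,
## uint8, fastest-axis-first — matching R's column-major layout); NIfTI
## goes through RNifti.  The raw dialect is a headerless uint8 block
## `<stem>.raw` with a JSON sidecar `<stem>.json` holding shape, spacing,
## origin and byte order.

#' Read and write occupancy volumes
#'
#' Supported formats are chosen by extension: `.nrrd` (raw or gzip
#' encoding), `.nii` / `.nii.gz` (via RNifti), and `.raw` with a JSON
#' sidecar.  A write followed by a read restores mask, shape, spacing
#' and origin bit-exactly for NRRD and raw (headers store full `double`
#' precision); NIfTI stores spacing and origin as 32-bit floats, so
#' round-trips are exact only to float precision.
#'
#' @param grid A [VoxelGrid-class].
#' @param path Output/input file path.
#' @param encoding For NRRD: `"gzip"` (default) or `"raw"`.
#' @return `writeVolume()` returns `path` invisibly; `readVolume()`
#'   returns a [VoxelGrid-class].
#' @examples
#' g <- VoxelGrid(array(runif(8^3) > 0.5, c(8, 8, 8)), spacing = 0.02)
#' f <- tempfile(fileext = ".nrrd")
#' writeVolume(g, f)
#' identical(gridMask(readVolume(f)), gridMask(g))
#' @export
writeVolume <- function(grid, path, encoding = c("gzip", "raw")) {
  stopifnot(is(grid, "VoxelGrid"))
  encoding <- match.arg(encoding)
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    writeNrrd(grid, path, encoding)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    writeNiftiVolume(grid, path)
  } else if (grepl("\\.raw$", lower)) {
    writeRawVolume(grid, path)
  } else {
    stop("unsupported volume format for '", path,
         "' (expected .nrrd, .nii, .nii.gz or .raw)")
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return(readNrrd(path))
  if (grepl("\\.nii(\\.gz)?$", lower)) return(readNiftiVolume(path))
  if (grepl("\\.raw$", lower)) return(readRawVolume(path))
  stop("unsupported volume format for '", path,
       "' (expected .nrrd, .nii, .nii.gz or .raw)")
}

fmtNum <- function(x) sprintf("%.17g", x)

writeNrrd <- function(grid, path, encoding) {
  sh <- gridShape(grid)
  sp <- grid@spacing; org <- grid@origin
  hdr <- c(
    "NRRD0004",
    "type: uint8",
    "dimension: 3",
    paste("sizes:", paste(sh, collapse = " ")),
    "space dimension: 3",
    paste0("space directions: (", fmtNum(sp[1]), ",0,0) (0,",
           fmtNum(sp[2]), ",0) (0,0,", fmtNum(sp[3]), ")"),
    paste0("space origin: (", paste(fmtNum(org), collapse = ","), ")"),
    "endian: little",
    paste("encoding:", encoding))
  payload <- as.raw(as.integer(grid@mask))
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines("", con, sep = "\n")
  writeBin(payload, con)
}

readNrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  sep <- which(bytes[-length(bytes)] == as.raw(10) &
               bytes[-1] == as.raw(10))
  if (length(sep) == 0L)
    stop("malformed NRRD (no header/data separator) in: ", path)
  sep <- sep[1]
  hdr <- strsplit(rawToChar(bytes[seq_len(sep - 1L)]), "\n")[[1]]
  if (!grepl("^NRRD", hdr[1]))
    stop("not an NRRD file (bad magic) in: ", path)
  field <- function(name) {
    ln <- grep(paste0("^", name, ": *"), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    sub(paste0("^", name, ": *"), "", ln[1])
  }
  type <- field("type")
  if (!type %in% c("uint8", "uchar", "unsigned char"))
    stop("unsupported NRRD type '", type, "' in: ", path)
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  if (length(sizes) != 3L)
    stop("expected a 3D NRRD in: ", path)
  parseVecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(m, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  spacing <- c(0, 0, 0)
  dirs <- field("space directions")
  if (!is.null(dirs)) {
    vs <- parseVecs(dirs)
    for (a in 1:3) {
      off <- vs[[a]][-a]
      if (any(abs(off) > 1e-12))
        stop("non-axis-aligned NRRD space directions in: ", path)
      spacing[a] <- vs[[a]][a]
    }
  } else {
    sps <- field("spacings")
    if (is.null(sps)) stop("NRRD lacks spacing information in: ", path)
    spacing <- as.numeric(strsplit(sps, " +")[[1]])
  }
  origin <- c(0, 0, 0)
  so <- field("space origin")
  if (!is.null(so)) origin <- parseVecs(so)[[1]]
  enc <- field("encoding")
  payload <- bytes[(sep + 2L):length(bytes)]
  if (identical(enc, "gzip")) {
    payload <- tryCatch(memDecompress(payload, type = "gzip"),
                        error = function(e)
                          stop("corrupt gzip payload in: ", path))
  } else if (!identical(enc, "raw")) {
    stop("unsupported NRRD encoding '", enc, "' in: ", path)
  }
  if (length(payload) != prod(sizes))
    stop("truncated NRRD payload (", length(payload), " of ",
         prod(sizes), " voxels) in: ", path)
  VoxelGrid(array(payload != as.raw(0), dim = sizes), spacing, origin)
}

writeNiftiVolume <- function(grid, path) {
  arr <- array(as.integer(grid@mask), dim = gridShape(grid))
  attr(arr, "pixdim") <- grid@spacing
  img <- RNifti::asNifti(arr, datatype = "uint8")
  mat <- diag(4)
  diag(mat)[1:3] <- grid@spacing
  mat[1:3, 4] <- grid@origin
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
}

readNiftiVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("failed to read NIfTI file: ", path, " (",
                         conditionMessage(e), ")"))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume in: ", path)
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf)[1:3])
  origin <- xf[1:3, 4]
  ## RNifti's xform flips to LAS-style conventions for negative
  ## determinants; our volumes are written axis-aligned with positive
  ## spacing, so take magnitudes.
  VoxelGrid(arr != 0, spacing, as.numeric(origin))
}

rawSidecar <- function(path) sub("\\.raw$", ".json", path)

writeRawVolume <- function(grid, path) {
  meta <- list(format = "drillscore-raw-v1",
               dtype = "uint8", byte_order = "little",
               shape = gridShape(grid),
               spacing = grid@spacing, origin = grid@origin)
  jsonlite::write_json(meta, rawSidecar(path), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  writeBin(as.raw(as.integer(grid@mask)), path)
}

readRawVolume <- function(path) {
  sc <- rawSidecar(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for raw volume: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  sizes <- as.integer(meta$shape)
  payload <- readBin(path, "raw", n = file.info(path)$size)
  if (length(payload) != prod(sizes))
    stop("truncated raw payload (", length(payload), " of ",
         prod(sizes), " voxels) in: ", path)
  VoxelGrid(array(payload != as.raw(0), dim = sizes),
            as.numeric(meta$spacing), as.numeric(meta$origin))
}
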