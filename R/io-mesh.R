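#' Write a triangle mesh to PLY or OBJ
#'
#' `writeMeshPLY()` writes binary little-endian PLY (float vertices,
#' int face indices); `writeMeshOBJ()` writes plain-text Wavefront OBJ.
#' Both preserve the mesh orientation.
#'
#' @param mesh A [TriangleMesh-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMeshPLY <- function(mesh, path) {
  stopifnot(is(mesh, "TriangleMesh"))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  hdr <- c("ply",
           "format binary_little_endian 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (nv > 0)
    writeBin(as.numeric(t(mesh@vertices)), con, size = 4L,
             endian = "little")
  if (nf > 0) {
    idx0 <- t(mesh@faces) - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(idx0[, i]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname writeMeshPLY
#' @export
writeMeshOBJ <- function(mesh, path) {
  stopifnot(is(mesh, "TriangleMesh"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh@vertices) > 0)
    writeLines(sprintf("v %.9g %.9g %.9g", mesh@vertices[, 1],
                       mesh@vertices[, 2], mesh@vertices[, 3]), con)
  if (nrow(mesh@faces) > 0)
    writeLines(sprintf("f %d %d %d", mesh@faces[, 1], mesh@faces[, 2],
                       mesh@faces[, 3]), con)
  invisible(path)
}
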