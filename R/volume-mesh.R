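## Iso-surface extraction from a voxel occupancy field.
##
## The extractor is a serial marching-tetrahedra walk: every grid cell is
## split into six tetrahedra sharing the main diagonal, each tetrahedron
## is triangulated by its inside/outside sign pattern at the 0.5
## iso-level, and surface vertices are placed by linear interpolation
## along the crossed edges.  Shared edge vertices are deduplicated, so the
## result is watertight, and triangle orientation is fixed so normals
## point away from the material.

## Six tetrahedra around the 0-7 cube diagonal; cube corners are numbered
## 1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0) 5:(0,0,1) 6:(1,0,1) 7:(1,1,1)
## 8:(0,1,1); every tet contains corners 1 and 7.
TET_DECOMP <- rbind(
  c(1L, 2L, 3L, 7L),
  c(1L, 3L, 4L, 7L),
  c(1L, 4L, 8L, 7L),
  c(1L, 8L, 5L, 7L),
  c(1L, 5L, 6L, 7L),
  c(1L, 6L, 2L, 7L))

CUBE_OFFSETS <- rbind(
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
  c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))

## Triangulation of one tetrahedron by the 4-bit inside pattern.  Each
## triangle is three (inside, outside) local-vertex pairs; orientation is
## fixed geometrically afterwards.
tetCaseTable <- local({
  cases <- vector("list", 16L)
  for (code in 0:15) {
    ins <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) != 0L)
    out <- setdiff(1:4, ins)
    tris <- list()
    if (length(ins) == 1L) {
      tris <- list(rbind(c(ins, out[1]), c(ins, out[2]), c(ins, out[3])))
    } else if (length(ins) == 3L) {
      tris <- list(rbind(c(ins[1], out), c(ins[2], out), c(ins[3], out)))
    } else if (length(ins) == 2L) {
      a <- ins[1]; b <- ins[2]; c <- out[1]; d <- out[2]
      quad <- rbind(c(a, c), c(a, d), c(b, d), c(b, c))
      tris <- list(quad[c(1, 2, 3), , drop = FALSE],
                   quad[c(1, 3, 4), , drop = FALSE])
    }
    cases[[code + 1L]] <- tris
  }
  cases
})

## Separable 3-point box smoothing along every axis (values stay in [0,1]).
boxSmooth3 <- function(f) {
  d <- dim(f)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 3L) next
    g <- f
    idx <- function(range) {
      args <- rep(list(quote(expr = )), 3)
      args[[axis]] <- range
      do.call(`[`, c(list(f), args, list(drop = FALSE)))
    }
    mid <- (idx(1:(n - 2)) + idx(2:(n - 1)) + idx(3:n)) / 3
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- 2:(n - 1)
    g <- do.call(`[<-`, c(list(g), args, list(mid)))
    ## zero-padded boundary slabs
    args[[axis]] <- 1L
    g <- do.call(`[<-`, c(list(g), args, list((idx(1L) + idx(2L)) / 3)))
    args[[axis]] <- n
    g <- do.call(`[<-`, c(list(g), args, list((idx(n - 1L) + idx(n)) / 3)))
    f <- g
  }
  f
}

#' Extract a triangle surface mesh from an occupancy grid
#'
#' Extracts the 0.5 iso-surface of the mask as a closed, consistently
#' oriented triangle mesh with vertex coordinates in world cm.  The mask
#' is zero-padded before extraction, so material touching the grid
#' boundary still produces a closed surface.
#'
#' With `smooth = TRUE` the binary field is first anti-aliased with a
#' separable 3-voxel box filter; the interpolated vertices then track the
#' underlying smooth geometry much more closely, which matters when the
#' mesh is used for quantitative area/volume measurements.  The raw
#' binary field (`smooth = FALSE`, default) preserves single-voxel
#' features that smoothing would erase.
#'
#' @param grid A [VoxelGrid-class].
#' @param smooth Logical; anti-alias the binary field before extraction.
#' @return A [TriangleMesh-class].  An all-`FALSE` or all-`TRUE` mask has
#'   no iso-surface inside the volume and yields an empty mesh (0 faces);
#'   test with [isEmptyMesh()].
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' mesh <- extractSurfaceMesh(VoxelGrid(m, spacing = 0.1))
#' isEmptyMesh(mesh)
#' meshArea(mesh) > 0
#' @export
extractSurfaceMesh <- function(grid, smooth = FALSE) {
  mask <- grid@mask
  emptyMesh <- new("TriangleMesh",
                   vertices = matrix(numeric(0), 0, 3),
                   faces = matrix(integer(0), 0, 3))
  if (!any(mask) || all(mask)) return(emptyMesh)

  pad <- 2L
  d <- dim(mask)
  np <- d + 2L * pad
  f <- array(0, dim = np)
  f[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
    (pad + 1):(pad + d[3])] <- as.numeric(mask)
  if (smooth) f <- boxSmooth3(f)

  iso <- 0.5
  inside <- f > iso

  ## active cells: those whose 8 corners are not uniformly in/out
  nc <- np - 1L
  cornerShift <- CUBE_OFFSETS %*% c(1L, np[1], np[1] * np[2])
  base <- which(array(TRUE, dim = nc))                # linear ids over cells
  ## cell (i,j,k) -> padded-vertex linear id of corner 1
  k0 <- (base - 1L) %/% (nc[1] * nc[2])
  j0 <- ((base - 1L) %/% nc[1]) %% nc[2]
  i0 <- (base - 1L) %% nc[1]
  v0 <- 1L + i0 + j0 * np[1] + k0 * np[1] * np[2]
  insCount <- integer(length(v0))
  for (c in 1:8) insCount <- insCount + inside[v0 + cornerShift[c]]
  act <- which(insCount > 0L & insCount < 8L)
  if (length(act) == 0L) return(emptyMesh)
  v0 <- v0[act]

  cornerIds <- matrix(0L, length(v0), 8L)
  cornerF <- matrix(0, length(v0), 8L)
  for (c in 1:8) {
    cornerIds[, c] <- v0 + cornerShift[c]
    cornerF[, c] <- f[cornerIds[, c]]
  }

  ## padded-vertex id -> world position
  nv12 <- np[1] * np[2]
  idPos <- function(id) {
    i <- (id - 1L) %% np[1]
    j <- ((id - 1L) %/% np[1]) %% np[2]
    k <- (id - 1L) %/% nv12
    cbind(grid@origin[1] + (i - pad) * grid@spacing[1],
          grid@origin[2] + (j - pad) * grid@spacing[2],
          grid@origin[3] + (k - pad) * grid@spacing[3])
  }

  NV <- as.numeric(prod(np))
  keyAcc <- list(); posAcc <- list(); refAcc <- list()
  nTri <- 0L

  for (t in seq_len(nrow(TET_DECOMP))) {
    tet <- TET_DECOMP[t, ]
    F4 <- cornerF[, tet, drop = FALSE]
    B4 <- F4 > iso
    code <- B4 %*% c(1L, 2L, 4L, 8L)
    for (cs in c(1:14)) {                 # codes 1..14 produce triangles
      rows <- which(code == cs)
      if (length(rows) == 0L) next
      tris <- tetCaseTable[[cs + 1L]]
      ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) != 0L)
      out <- setdiff(1:4, ins)
      ## orientation reference: outside centroid minus inside centroid
      ci <- 0; co <- 0
      posOf <- function(localv) idPos(cornerIds[rows, tet[localv]])
      for (v in ins) ci <- ci + posOf(v) / length(ins)
      for (v in out) co <- co + posOf(v) / length(out)
      ref <- co - ci
      for (tri in tris) {
        keys <- matrix(0, length(rows), 3L)
        pos <- vector("list", 3L)
        for (e in 1:3) {
          aL <- tri[e, 1]; bL <- tri[e, 2]
          ga <- cornerIds[rows, tet[aL]]
          gb <- cornerIds[rows, tet[bL]]
          fa <- F4[rows, aL]; fb <- F4[rows, bL]
          tt <- (iso - fa) / (fb - fa)
          pa <- idPos(ga); pb <- idPos(gb)
          pos[[e]] <- pa + tt * (pb - pa)
          keys[, e] <- pmin(ga, gb) * NV + pmax(ga, gb)
        }
        keyAcc[[length(keyAcc) + 1L]] <- keys
        posAcc[[length(posAcc) + 1L]] <- pos
        refAcc[[length(refAcc) + 1L]] <- ref
        nTri <- nTri + length(rows)
      }
    }
  }
  if (nTri == 0L) return(emptyMesh)

  allKeys <- do.call(rbind, keyAcc)                       # T x 3
  p1 <- do.call(rbind, lapply(posAcc, `[[`, 1))
  p2 <- do.call(rbind, lapply(posAcc, `[[`, 2))
  p3 <- do.call(rbind, lapply(posAcc, `[[`, 3))
  ref <- do.call(rbind, refAcc)

  ## orient: normal . (outside - inside) must be positive
  e1 <- p2 - p1; e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  flip <- (nx * ref[, 1] + ny * ref[, 2] + nz * ref[, 3]) < 0

  faceKeys <- allKeys
  faceKeys[flip, ] <- allKeys[flip, c(1, 3, 2)]

  uk <- unique(as.vector(allKeys))
  vidx <- match(as.vector(faceKeys), uk)
  faces <- matrix(vidx, ncol = 3L)

  ## vertex positions: first occurrence of each key
  firstRow <- match(uk, as.vector(allKeys))
  stackPos <- rbind(p1, p2, p3)
  T <- nrow(allKeys)
  ## as.vector(allKeys) runs column-wise: rows 1..T are edge 1, etc.
  lookup <- function(fr) {
    col <- (fr - 1L) %/% T + 1L
    row <- (fr - 1L) %% T + 1L
    stackPos[row + (col - 1L) * T, , drop = FALSE]
  }
  verts <- lookup(firstRow)

  ## drop degenerate (zero-area) triangles
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!deg, , drop = FALSE]

  new("TriangleMesh", vertices = verts, faces = faces)
}

#' Mesh measurements
#'
#' `meshArea()` returns the total surface area (cm^2), `meshVolume()` the
#' signed enclosed volume (cm^3; positive for outward-oriented closed
#' meshes), and `meshIsClosed()` checks watertightness (every undirected
#' edge shared by exactly two faces).
#'
#' @param mesh A [TriangleMesh-class].
#' @return A single numeric (or logical for `meshIsClosed`).
#' @export
meshArea <- function(mesh) {
  if (isEmptyMesh(mesh)) return(0)
  v <- mesh@vertices; fc <- mesh@faces
  e1 <- v[fc[, 2], , drop = FALSE] - v[fc[, 1], , drop = FALSE]
  e2 <- v[fc[, 3], , drop = FALSE] - v[fc[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname meshArea
#' @export
meshVolume <- function(mesh) {
  if (isEmptyMesh(mesh)) return(0)
  v <- mesh@vertices; fc <- mesh@faces
  a <- v[fc[, 1], , drop = FALSE]
  b <- v[fc[, 2], , drop = FALSE]
  c <- v[fc[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' @rdname meshArea
#' @export
meshIsClosed <- function(mesh) {
  if (isEmptyMesh(mesh)) return(TRUE)
  fc <- mesh@faces
  ed <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2L)
}
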