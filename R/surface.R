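# LA isosurface extraction and closest-point queries against the mesh.
#
# The isosurface of the binary LA label (level 0.5 between label and
# background) is extracted by marching tetrahedra on the 6-tetrahedron
# decomposition of each grid cube, with surface vertices at the midpoints
# of sign-changing cube edges.  The decomposition shares the main cube
# diagonal, so adjacent cubes agree on shared faces and the mesh is
# watertight.

# 1-based cube corner offsets, corner ids 1..8
.cubeCorners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# six tetrahedra around the 1-7 diagonal
.cubeTets <- list(c(1L, 6L, 2L, 7L), c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L),
                  c(1L, 4L, 8L, 7L), c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L))

# per-occupancy-code triangle assembly; each triangle is a list of corner
# pairs (edges of the tetrahedron, local vertex ids 1..4) whose midpoints
# form the triangle
.tetCases <- local({
  single <- function(v) {
    o <- setdiff(1:4, v)
    list(list(c(v, o[1]), c(v, o[2]), c(v, o[3])))
  }
  double <- function(v, w) {
    o <- setdiff(1:4, c(v, w))
    a <- o[1]; b <- o[2]
    e <- list(c(v, a), c(v, b), c(w, b), c(w, a))
    list(list(e[[1]], e[[2]], e[[3]]), list(e[[1]], e[[3]], e[[4]]))
  }
  cases <- vector("list", 15L)
  for (v in 1:4) {
    cases[[2^(v - 1)]] <- single(v)            # one vertex inside
    cases[[15L - 2^(v - 1)]] <- single(v)      # one vertex outside
  }
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in pairs)
    cases[[2^(p[1] - 1) + 2^(p[2] - 1)]] <- double(p[1], p[2])
  cases
})

# marching tetrahedra on a logical mask; returns vertices (world mm) and
# 1-based triangle indices
.marchingTets <- function(mask, spacing, origin) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)
  m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  dp <- dim(m)
  originP <- origin - spacing   # world of padded voxel (1,1,1), 0-based (0,0,0)

  n1 <- dp[1] - 1L; n2 <- dp[2] - 1L; n3 <- dp[3] - 1L
  S <- array(0L, c(n1, n2, n3))
  for (c8 in 1:8) {
    o <- .cubeCorners[c8, ]
    S <- S + m[(1:n1) + o[1], (1:n2) + o[2], (1:n3) + o[3]]
  }
  active <- which(S > 0L & S < 8L)
  if (!length(active))
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  base <- arrayInd(active, c(n1, n2, n3))

  cornerLin <- function(c8) {
    o <- .cubeCorners[c8, ]
    (base[, 1] + o[1]) + (base[, 2] + o[2] - 1L) * dp[1] +
      (base[, 3] + o[3] - 1L) * dp[1] * dp[2]
  }
  vals <- vapply(1:8, function(c8) m[cornerLin(c8)],
                 logical(nrow(base)))
  cornerPos <- function(c8) {
    o <- .cubeCorners[c8, ]
    cbind(originP[1] + (base[, 1] + o[1] - 1L) * spacing[1],
          originP[2] + (base[, 2] + o[2] - 1L) * spacing[2],
          originP[3] + (base[, 3] + o[3] - 1L) * spacing[3])
  }

  triA <- list(); triB <- list(); triC <- list(); k <- 0L
  for (tet in .cubeTets) {
    B <- vals[, tet, drop = FALSE]
    code <- B[, 1] + 2L * B[, 2] + 4L * B[, 3] + 8L * B[, 4]
    for (cc in unique(code)) {
      if (cc == 0L || cc == 15L) next
      rows <- which(code == cc)
      for (tri in .tetCases[[cc]]) {
        k <- k + 1L
        mids <- lapply(tri, function(edge) {
          a <- tet[edge[1]]; b <- tet[edge[2]]
          (cornerPos(a)[rows, , drop = FALSE] +
             cornerPos(b)[rows, , drop = FALSE]) / 2
        })
        triA[[k]] <- mids[[1]]; triB[[k]] <- mids[[2]]; triC[[k]] <- mids[[3]]
      }
    }
  }
  A <- do.call(rbind, triA); B <- do.call(rbind, triB)
  C <- do.call(rbind, triC)

  # weld shared vertices: all coordinates are multiples of h/2
  allV <- rbind(A, B, C)
  iv <- round(sweep(sweep(allV, 2L, originP, "-"), 2L, spacing / 2, "/")) + 4
  hash <- iv[, 1] + iv[, 2] * 2^17 + iv[, 3] * 2^34
  uh <- unique(hash)
  idx <- match(hash, uh)
  verts <- allV[match(uh, hash), , drop = FALSE]
  ntri <- nrow(A)
  faces <- cbind(idx[seq_len(ntri)],
                 idx[ntri + seq_len(ntri)],
                 idx[2L * ntri + seq_len(ntri)])
  # drop degenerate slivers
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

#' Extract the left-atrial isosurface
#'
#' Triangulates the 0.5-level isosurface between the LA label and
#' everything else, with vertices in world mm.  Surface vertices lie at
#' midpoints of grid edges crossing the label boundary, so every vertex is
#' within half a voxel of the true boundary.
#'
#' @param vol A [LabelVolume-class] with a nonempty LA label.
#' @return A [SurfaceMesh-class].
#' @export
extractLASurface <- function(vol) {
  stopifnot(is(vol, "LabelVolume"))
  mask <- .roleMask(vol, "LA")
  if (!any(mask)) stop("the LA label is empty")
  mt <- .marchingTets(mask, vol@spacing, vol@origin)
  new("SurfaceMesh", vertices = mt$vertices,
      faces = matrix(as.integer(mt$faces), ncol = 3L))
}

# precomputed per-face data for closest-point queries
.meshPrep <- function(mesh) {
  V <- mesh@vertices; Fc <- mesh@faces
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  cen <- (A + B + C) / 3
  rad2 <- pmax(rowSums((A - cen)^2), rowSums((B - cen)^2),
               rowSums((C - cen)^2))
  list(A = A, B = B, C = C, cen = cen, maxRad = sqrt(max(rad2)))
}

# closest point on each triangle of a set to point p (Ericson regions)
.pointTriClosest <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(A, 2L, p, "-") * -1
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(B, 2L, p, "-") * -1
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(C, 2L, p, "-") * -1
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  n <- nrow(A)
  out <- matrix(NA_real_, n, 3L)
  done <- logical(n)

  m <- d1 <= 0 & d2 <= 0                              # vertex A
  out[m, ] <- A[m, , drop = FALSE]; done <- done | m
  m <- !done & d3 >= 0 & d4 <= d3                     # vertex B
  out[m, ] <- B[m, , drop = FALSE]; done <- done | m
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0            # edge AB
  if (any(m)) {
    t <- d1[m] / (d1[m] - d3[m])
    out[m, ] <- A[m, , drop = FALSE] + ab[m, , drop = FALSE] * t
  }
  done <- done | m
  m <- !done & d6 >= 0 & d5 <= d6                     # vertex C
  out[m, ] <- C[m, , drop = FALSE]; done <- done | m
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0            # edge AC
  if (any(m)) {
    t <- d2[m] / (d2[m] - d6[m])
    out[m, ] <- A[m, , drop = FALSE] + ac[m, , drop = FALSE] * t
  }
  done <- done | m
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0   # edge BC
  if (any(m)) {
    t <- (d4[m] - d3[m]) / ((d4[m] - d3[m]) + (d5[m] - d6[m]))
    out[m, ] <- B[m, , drop = FALSE] +
      (C[m, , drop = FALSE] - B[m, , drop = FALSE]) * t
  }
  done <- done | m
  m <- !done                                          # interior
  if (any(m)) {
    denom <- va[m] + vb[m] + vc[m]
    bad <- denom == 0
    denom[bad] <- 1
    v <- vb[m] / denom; w <- vc[m] / denom
    pt <- A[m, , drop = FALSE] + ab[m, , drop = FALSE] * v +
      ac[m, , drop = FALSE] * w
    if (any(bad)) pt[bad, ] <- A[m, , drop = FALSE][bad, ]
    out[m, ] <- pt
  }
  d2out <- rowSums(sweep(out, 2L, p, "-")^2)
  list(points = out, d2 = d2out)
}

# closest points on a mesh for a set of query points; uses a centroid
# prefilter so only nearby triangles get the exact test
.closestOnMesh <- function(Q, prep) {
  Q <- .asPolyline(Q)
  n <- nrow(Q)
  feet <- matrix(0, n, 3L)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    q <- Q[i, ]
    dc2 <- (prep$cen[, 1] - q[1])^2 + (prep$cen[, 2] - q[2])^2 +
      (prep$cen[, 3] - q[3])^2
    bound <- sqrt(min(dc2)) + 2 * prep$maxRad + 1e-9
    cand <- which(dc2 <= bound^2)
    res <- .pointTriClosest(q, prep$A[cand, , drop = FALSE],
                            prep$B[cand, , drop = FALSE],
                            prep$C[cand, , drop = FALSE])
    j <- which.min(res$d2)
    feet[i, ] <- res$points[j, ]
    dist[i] <- sqrt(res$d2[j])
  }
  list(points = feet, dist = dist)
}
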