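# Centerline extraction and confluence demarcation.
#
# Each labelled venous structure gets one centerline polyline, computed as
# the minimal path between the farthest-apart voxel pair on the
# 26-connected voxel graph, with edge costs penalising proximity to the
# label boundary (exact Euclidean distance transform), followed by
# orthogonal-slab recentring and light smoothing.  On tubular labels this
# tracks the medial axis to within a voxel.

.edt <- function(mask, spacing) {
  array(edt3d_cpp(as.logical(mask), dim(mask), as.numeric(spacing)),
        dim = dim(mask))
}

.neighborOffsets <- function(connectivity = 26L, half = TRUE) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1,
                               KEEP.OUT.ATTRS = FALSE))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    off <- off[rowSums(abs(off)) == 1L, , drop = FALSE]
  if (half) {
    keep <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
      (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
    off <- off[keep, , drop = FALSE]
  }
  off
}

# undirected voxel adjacency for the voxels at linear indices `lin`
# (1-based); returns edge endpoints as indices into `lin` plus edge
# lengths in mm
.voxelEdges <- function(lin, dims, spacing, connectivity = 26L) {
  idmap <- integer(prod(dims))
  idmap[lin] <- seq_along(lin)
  ijk <- arrayInd(lin, dims)
  off <- .neighborOffsets(connectivity, half = TRUE)
  from <- integer(0); to <- integer(0); len <- numeric(0)
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    ok <- ijk[, 1] + o[1] >= 1L & ijk[, 1] + o[1] <= dims[1] &
          ijk[, 2] + o[2] >= 1L & ijk[, 2] + o[2] <= dims[2] &
          ijk[, 3] + o[3] >= 1L & ijk[, 3] + o[3] <= dims[3]
    nlin <- lin[ok] + o[1] + o[2] * nx + o[3] * nxy
    nid <- idmap[nlin]
    hit <- nid > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nid[hit])
    len <- c(len, rep(sqrt(sum((o * spacing)^2)), sum(hit)))
  }
  list(from = from, to = to, len = len)
}

# 6-connected component sizes of the voxel set
.componentSizes <- function(lin, dims, spacing) {
  ed <- .voxelEdges(lin, dims, spacing, connectivity = 6L)
  g <- igraph::make_graph(rbind(ed$from, ed$to), n = length(lin),
                          directed = FALSE)
  sort(igraph::components(g)$csize, decreasing = TRUE)
}

# trace the centerline of one labelled structure; returns a polyline in
# world mm ordered end-to-end
.traceTube <- function(mask, spacing, origin, role) {
  lin <- which(mask)
  if (!length(lin))
    stop(sprintf("centerline extraction: label for role '%s' is empty",
                 role))
  dims <- dim(mask)
  if (length(lin) == 1L)
    stop(sprintf(
      "centerline extraction: label for role '%s' has a single voxel", role))
  cs <- .componentSizes(lin, dims, spacing)
  if (length(cs) > 1L)
    stop(sprintf(
      "centerline extraction: label for role '%s' is disconnected (6-connectivity component sizes: %s)",
      role, paste(cs, collapse = ", ")))

  dt <- .edt(mask, spacing)[lin]
  ed <- .voxelEdges(lin, dims, spacing, connectivity = 26L)
  g <- igraph::make_graph(rbind(ed$from, ed$to), n = length(lin),
                          directed = FALSE)

  # farthest pair in plain geodesic length, seeded at the most interior voxel
  start <- which.max(dt)
  dA <- igraph::distances(g, v = start, weights = ed$len)[1, ]
  A <- which.max(dA)
  dB <- igraph::distances(g, v = A, weights = ed$len)[1, ]
  B <- which.max(dB)

  # minimal path with centrality-weighted costs
  wCost <- ed$len / ((dt[ed$from] + dt[ed$to]) / 2)^2
  vpath <- igraph::shortest_paths(g, from = A, to = B, weights = wCost,
                                  output = "vpath")$vpath[[1]]
  idx <- as.integer(vpath)
  ijk <- arrayInd(lin[idx], dims)
  P <- sweep(sweep(ijk - 1, 2L, spacing, "*"), 2L, origin, "+")

  h <- max(spacing)
  maxDT <- max(dt)
  if (maxDT > 1.05 * min(spacing) && nrow(P) >= 6L) {
    # The minimal path parametrizes the tube but enters each end through
    # a diagonal dive from a rim corner.  Rebuild the geometry as the
    # sliding centroid of the label voxels over one-voxel arc-length
    # bins (the standard moving-centroid centerline): interior bins are
    # full cross-sections, so their centroids sit on the medial axis.
    ijkAll <- arrayInd(lin, dims)
    V <- sweep(sweep(ijkAll - 1, 2L, spacing, "*"), 2L, origin, "+")
    Psm <- .smoothPolyline(P, 9L)
    cs <- .cumArc(Psm)
    # station of each voxel = station of its nearest path point
    st <- numeric(nrow(V))
    pp2 <- rowSums(Psm^2)
    chunk <- 20000L
    for (s0 in seq(1L, nrow(V), by = chunk)) {
      ii <- s0:min(nrow(V), s0 + chunk - 1L)
      D2 <- outer(rowSums(V[ii, , drop = FALSE]^2), pp2, "+") -
        2 * tcrossprod(V[ii, , drop = FALSE], Psm)
      st[ii] <- cs[max.col(-D2, ties.method = "first")]
    }
    rng <- range(st)
    nb <- max(3L, ceiling((rng[2] - rng[1]) / h))
    bin <- pmin(nb, 1L + floor((st - rng[1]) / (rng[2] - rng[1]) * nb))
    Q <- do.call(rbind, lapply(split(seq_along(bin), bin), function(ii)
      colMeans(V[ii, , drop = FALSE])))
    m <- nrow(Q)
    if (m >= 4L) {
      # The dive scrambles voxel stations over roughly two tube radii of
      # path length at each end, so bins there mix tilted partial
      # cross-sections.  Correct each endpoint to the centroid of the
      # outermost one-voxel slab along the interior axis direction,
      # chord-replace the contaminated zone, and recentre the replaced
      # points with the now-stable tangent (recovers curvature; the
      # orthogonal slab has no lateral bias).
      zone <- 2 * maxDT + 2 * h
      rcap2 <- (maxDT + 2 * h)^2
      fixEnd <- function(Q, head) {
        m <- nrow(Q)
        if (!head) Q <- Q[m:1L, , drop = FALSE]   # work head-first
        csQ <- .cumArc(Q)
        # the zigzag inflates stations inside the contaminated stretch,
        # so cut by bin count (bins are ~1 voxel of station each)
        iIn <- min(m - 2L, as.integer(ceiling(2.5 * maxDT / h)) + 1L)
        if (iIn < 2L) iIn <- min(m - 2L, 2L)
        iFar <- min(m, 2L * iIn)
        Tin <- if (iFar > iIn) Q[iFar, ] - Q[iIn, ]
               else Q[m, ] - Q[1L, ]
        Tin <- Tin / sqrt(sum(Tin^2))             # points inward
        ref <- Q[iIn, ]
        W1 <- V[, 1] - ref[1]; W2 <- V[, 2] - ref[2]; W3 <- V[, 3] - ref[3]
        along <- W1 * Tin[1] + W2 * Tin[2] + W3 * Tin[3]
        perp2 <- W1^2 + W2^2 + W3^2 - along^2
        sel <- perp2 <= rcap2 & along <= 0
        if (any(sel)) {
          amin <- min(along[sel])
          endSel <- sel & along <= amin + h
          if (sum(endSel) < 2L) endSel <- sel & along <= amin + 2 * h
          if (sum(endSel) >= 2L) {
            tip <- colMeans(V[endSel, , drop = FALSE])
            Q[1L, ] <- tip
            if (iIn > 2L) {
              span <- Q[iIn, ] - tip
              for (i in 2:(iIn - 1L))
                Q[i, ] <- tip + span * csQ[i] / csQ[iIn]
              # one orthogonal recentring pass over the replaced points
              for (i in 2:(iIn - 1L)) {
                A1 <- V[, 1] - Q[i, 1]; A2 <- V[, 2] - Q[i, 2]
                A3 <- V[, 3] - Q[i, 3]
                al <- A1 * Tin[1] + A2 * Tin[2] + A3 * Tin[3]
                pp <- A1^2 + A2^2 + A3^2 - al^2
                s2 <- abs(al) <= h & pp <= rcap2
                if (sum(s2) >= 2L) Q[i, ] <- colMeans(V[s2, , drop = FALSE])
              }
            }
          }
        }
        if (!head) Q <- Q[nrow(Q):1L, , drop = FALSE]
        Q
      }
      Q <- fixEnd(Q, head = TRUE)
      Q <- fixEnd(Q, head = FALSE)
      # recentring can fold stations near the tips; restore monotone order
      st2 <- .closestOnPolyline(.smoothPolyline(Q, 9L), Q)$station
      Q <- Q[order(st2), , drop = FALSE]
    }
    P <- .smoothPolyline(Q, 3L)
    keep <- c(TRUE, sqrt(rowSums(diff(P)^2)) > 1e-6)
    P <- P[keep, , drop = FALSE]
  }
  P
}

#' Extract the centerline tree of the venous structures
#'
#' Computes one centerline polyline per labelled venous structure (the
#' confluence channel, the four pulmonary veins and the vertical vein).
#' Vein polylines are ordered from their free end toward the confluence.
#'
#' @param vol A [LabelVolume-class].
#' @param roles Character vector of venous roles to trace; default all of
#'   `PVC, LUPV, RUPV, LIPV, RIPV, VV`.  An empty label among the
#'   requested roles is an error naming the role, as is a label that is
#'   not a single 6-connected component.
#' @return A [CenterlineTree-class].
#' @seealso [findJunctions()], [demarcateConfluence()]
#' @export
extractCenterlineTree <- function(vol, roles = NULL) {
  stopifnot(is(vol, "LabelVolume"))
  if (is.null(roles)) roles <- .venousRoles
  roles <- match.arg(roles, .venousRoles, several.ok = TRUE)
  if (!"PVC" %in% roles)
    stop("the main channel role 'PVC' must be among the traced roles")
  spacing <- vol@spacing; origin <- vol@origin
  branches <- list()
  for (role in roles) {
    mask <- .roleMask(vol, role)
    branches[[role]] <- .traceTube(mask, spacing, origin, role)
  }
  # orient vein branches free-end-first (toward-confluence last)
  pvcLin <- which(.roleMask(vol, "PVC"))
  pvcCentroid <- colMeans(voxelToWorld(vol, arrayInd(pvcLin,
                                                    dim(vol@voxels)) - 1))
  for (role in setdiff(roles, "PVC")) {
    b <- branches[[role]]
    dFirst <- sum((b[1L, ] - pvcCentroid)^2)
    dLast <- sum((b[nrow(b), ] - pvcCentroid)^2)
    if (dFirst < dLast)
      branches[[role]] <- b[nrow(b):1L, , drop = FALSE]
  }
  new("CenterlineTree", branches = branches, junctions = list(),
      spacing = spacing)
}

#' Locate junction nodes on the main venous channel
#'
#' Finds where each vein branch attaches to the main channel (voxels of
#' the vein label 26-adjacent to the main label), maps each attachment to
#' an arc-length station on the main centerline, and clusters stations
#' closer than `tol` into junction nodes.  In the supracardiac layout this
#' yields the node where the right upper and inferior pulmonary veins join
#' and the node where the vertical vein and the ipsilateral veins join.
#'
#' @param tree A [CenterlineTree-class] from [extractCenterlineTree()].
#' @param vol The [LabelVolume-class] the tree was extracted from.
#' @param mainRole Role of the main channel (default `"PVC"`).
#' @param tol Station clustering tolerance in mm; default
#'   `max(2, 4 * max(spacing))`.
#' @return A list of junction nodes, each with elements `point` (world
#'   mm, on the main centerline), `roles` (the main role plus the
#'   attaching roles) and `station` (arc-length position).  A vein branch
#'   present in the tree that never touches the main label is a topology
#'   error naming the role.
#' @export
findJunctions <- function(tree, vol, mainRole = "PVC", tol = NULL) {
  stopifnot(is(tree, "CenterlineTree"), is(vol, "LabelVolume"))
  if (!mainRole %in% names(tree@branches))
    stop(sprintf("main role '%s' is not a branch of the tree", mainRole))
  if (is.null(tol)) tol <- max(2, 4 * max(vol@spacing))
  M <- tree@branches[[mainRole]]
  dims <- dim(vol@voxels)
  mainMask <- .roleMask(vol, mainRole)
  off <- .neighborOffsets(26L, half = FALSE)
  nx <- dims[1]; nxy <- dims[1] * dims[2]

  others <- setdiff(names(tree@branches), mainRole)
  att <- list()
  for (role in others) {
    lin <- which(.roleMask(vol, role))
    ijk <- arrayInd(lin, dims)
    touches <- logical(length(lin))
    for (r in seq_len(nrow(off))) {
      o <- off[r, ]
      ok <- ijk[, 1] + o[1] >= 1L & ijk[, 1] + o[1] <= dims[1] &
            ijk[, 2] + o[2] >= 1L & ijk[, 2] + o[2] <= dims[2] &
            ijk[, 3] + o[3] >= 1L & ijk[, 3] + o[3] <= dims[3]
      nlin <- lin[ok] + o[1] + o[2] * nx + o[3] * nxy
      touches[ok] <- touches[ok] | mainMask[nlin]
    }
    if (!any(touches))
      stop(sprintf(
        "topology error: role '%s' never touches the main channel '%s'",
        role, mainRole))
    # the attachment station comes from the junction-side end of the vein
    # centerline (branches are ordered free-end-first), which lies on the
    # vein axis and therefore maps onto the main channel more accurately
    # than the adjacency-voxel centroid; the centroid breaks ties when the
    # branch end is ambiguous between skeleton voxels
    b <- tree@branches[[role]]
    attachPt <- b[nrow(b), , drop = FALSE]
    st <- .closestOnPolyline(M, attachPt)$station
    if (!is.finite(st)) {
      centroid <- colMeans(voxelToWorld(vol, ijk[touches, , drop = FALSE] - 1))
      st <- .closestOnPolyline(M, matrix(centroid, 1L))$station
    }
    att[[role]] <- st
  }
  if (!length(att)) return(structure(list(), class = "junctionSet"))

  stations <- unlist(att)
  ord <- order(stations)
  rolesOrd <- names(stations)[ord]
  stOrd <- stations[ord]
  groups <- cumsum(c(TRUE, diff(stOrd) > tol))
  junctions <- lapply(split(seq_along(stOrd), groups), function(ii) {
    s <- mean(stOrd[ii])
    list(point = as.numeric(.pointAtStation(M, s)),
         roles = c(mainRole, rolesOrd[ii]),
         station = s)
  })
  names(junctions) <- NULL
  structure(junctions, class = "junctionSet")
}

#' Demarcate the confluence between the two junction planes
#'
#' Clips the main-channel centerline by the planes orthogonal to the local
#' channel tangent at the two junction nodes: the node where the two
#' contralateral pulmonary veins join, and the node where the vertical
#' vein joins with the ipsilateral upper vein.  The resulting sub-polyline
#' is the confluence segment; its arc length is recorded.
#'
#' @param tree A [CenterlineTree-class].
#' @param junctions Junction set from [findJunctions()].
#' @param mainRole Role of the main channel (default `"PVC"`).
#' @return A [ConfluenceSegment-class], ordered from the paired-vein
#'   junction toward the vertical-vein junction.
#' @export
demarcateConfluence <- function(tree, junctions, mainRole = "PVC") {
  stopifnot(is(tree, "CenterlineTree"))
  M <- tree@branches[[mainRole]]
  jVV <- NULL; jPair <- NULL
  for (j in junctions) if ("VV" %in% j$roles) jVV <- j
  if (is.null(jVV))
    stop("topology error: no junction involving the vertical vein (VV)")
  pair <- if ("LUPV" %in% jVV$roles) c("RUPV", "RIPV") else c("LUPV", "LIPV")
  for (j in junctions) if (all(pair %in% j$roles)) jPair <- j
  if (is.null(jPair))
    stop(sprintf("topology error: no junction joining %s",
                 paste(pair, collapse = " and ")))
  h <- max(tree@spacing)
  sA <- jPair$station; sB <- jVV$station
  if (abs(sA - sB) < 2 * h)
    stop("degenerate-confluence error: the junction planes coincide or ",
         "delimit a segment shorter than 2 voxels")
  slo <- min(sA, sB); shi <- max(sA, sB)
  cs <- .cumArc(M)
  mid <- which(cs > slo & cs < shi)
  P <- rbind(.pointAtStation(M, slo), M[mid, , drop = FALSE],
             .pointAtStation(M, shi))
  keep <- c(TRUE, sqrt(rowSums(diff(P)^2)) > 1e-9)
  P <- P[keep, , drop = FALSE]
  if (sA > sB) P <- P[nrow(P):1L, , drop = FALSE]
  new("ConfluenceSegment", points = P, arcLen = arcLength(P),
      endRoles = list(first = setdiff(jPair$roles, mainRole),
                      last = setdiff(jVV$roles, mainRole)))
}
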