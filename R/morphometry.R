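# The quantitative morphologic parameters: projection of the confluence
# onto the LA surface (corresponding confluence, CCL), 100-point DBLC
# sampling (mDBLC), voxel-count volumes, BSA indexing and the
# threshold-based risk class.

#' Project the confluence centerline onto the LA surface
#'
#' Maps each point of the demarcated confluence centerline to its closest
#' point on the LA surface mesh (Euclidean closest-point projection) and
#' connects the ordered images into the corresponding confluence.  The
#' corresponding confluence length (CCL) is the arc length of that curve.
#' The centerline is resampled densely before projection and the projected
#' curve is lightly smoothed to suppress voxel-facet jitter; the smoothing
#' window is small relative to any anatomical curvature, so CCL is
#' unaffected beyond the voxel scale.
#'
#' @param seg A [ConfluenceSegment-class].
#' @param mesh A [SurfaceMesh-class] in the same world frame.
#' @param maxDist Sanity bound (mm) on the projection distance; exceeding
#'   it raises a warning (default 50).
#' @param nResample Number of centerline stations projected; default
#'   `max(101, 2 * npoints - 1)`.
#' @param smoothWindow Moving-average window (points) applied to the
#'   projected curve; endpoints are preserved.  Default 7.
#' @return A [CorrespondenceSet-class] holding the projected curve and
#'   CCL; complete it with [sampleDBLC()].
#' @export
projectConfluence <- function(seg, mesh, maxDist = 50, nResample = NULL,
                              smoothWindow = 7L) {
  stopifnot(is(seg, "ConfluenceSegment"), is(mesh, "SurfaceMesh"))
  if (nrow(mesh@faces) == 0L)
    stop("cannot project onto an empty mesh")
  if (is.null(nResample))
    nResample <- max(101L, 2L * nrow(seg@points) - 1L)
  pts <- .resamplePolyline(seg@points, nResample)
  prep <- .meshPrep(mesh)
  proj <- .closestOnMesh(pts, prep)
  if (max(proj$dist) > maxDist)
    warning(sprintf(
      "projection distance %.1f mm exceeds the sanity bound of %g mm",
      max(proj$dist), maxDist))
  curve <- .smoothPolyline(proj$points, smoothWindow)
  keep <- c(TRUE, sqrt(rowSums(diff(curve)^2)) > 1e-9)
  curve <- curve[keep, , drop = FALSE]
  if (nrow(curve) < 2L)
    stop("degenerate projection: the projected curve collapsed to a point")
  new("CorrespondenceSet", curve = curve,
      samples = matrix(0, 0, 3), partners = matrix(0, 0, 3),
      dblc = numeric(0), ccl = arcLength(curve), mdblc = numeric(0))
}

#' Sample the distance between the LA and the confluence
#'
#' Places 100 sample points `p_i` on the corresponding confluence at equal
#' arc-length intervals (both endpoints included, station spacing
#' CCL/99), finds for each the closest point `q_i` on the confluence
#' centerline, and records the per-point distances DBLC_i = |p_i - q_i|
#' and their mean mDBLC.
#'
#' @param cs A [CorrespondenceSet-class] from [projectConfluence()].
#' @param seg The [ConfluenceSegment-class] that was projected.
#' @return The completed [CorrespondenceSet-class].
#' @export
sampleDBLC <- function(cs, seg) {
  stopifnot(is(cs, "CorrespondenceSet"), is(seg, "ConfluenceSegment"))
  if (cs@ccl <= 0 || nrow(cs@curve) < 2L)
    stop("degenerate correspondence: CCL is zero")
  p <- .resamplePolyline(cs@curve, 100L)
  cl <- .closestOnPolyline(seg@points, p)
  new("CorrespondenceSet", curve = cs@curve, samples = p,
      partners = cl$points, dblc = cl$dist, ccl = cs@ccl,
      mdblc = mean(cl$dist))
}

#' Voxel-count volume of a labelled structure
#'
#' Volume estimated by counting voxels in the segmentation area:
#' `count * sx * sy * sz / 1000` cm^3.  No partial-volume correction is
#' applied.
#'
#' @param vol A [LabelVolume-class].
#' @param role Schema role, e.g. `"LA"` or `"PVC"`.
#' @return Volume in cm^3 (0 for an empty label).
#' @export
voxelVolume <- function(vol, role) {
  stopifnot(is(vol, "LabelVolume"))
  role <- match.arg(role, .requiredRoles)
  count <- sum(vol@voxels == vol@schema[[role]])
  count * prod(vol@spacing) / 1000
}

#' Threshold-based PPVS risk class
#'
#' Dichotomizes the two morphologic markers at their clinical thresholds
#' (iTVLC 20 cm^3/m^2 and CCL/mDBLC ratio 7.7 by default): both at or
#' above threshold is low risk, exactly one is medium, neither is high.
#' Increasing either marker never raises the risk tier.
#'
#' @param itvlc Indexed total volume of LA and confluence, cm^3/m^2.
#' @param ratio CCL/mDBLC ratio.
#' @param thresholds Numeric length 2: `c(itvlc, ratio)` cutoffs.
#' @return Character vector in `{"low", "medium", "high"}` (vectorized
#'   over the inputs).
#' @examples
#' classifyRisk(21, 8.0)   # "low"
#' classifyRisk(21, 5.0)   # "medium"
#' classifyRisk(15, 5.0)   # "high"
#' @export
classifyRisk <- function(itvlc, ratio, thresholds = c(20.0, 7.7)) {
  if (any(!is.finite(itvlc)) || any(!is.finite(ratio)))
    stop("risk classification needs finite inputs")
  nMet <- (itvlc >= thresholds[1]) + (ratio >= thresholds[2])
  c("high", "medium", "low")[nMet + 1L]
}

#' Assemble the morphologic parameters
#'
#' Combines the measured volumes and lengths with the body surface area
#' into the indexed metrics: iLA = V_LA/BSA, iPVC = V_PVC/BSA,
#' iTVLC = iLA + iPVC (cm^3/m^2), the CCL/mDBLC ratio, and the risk
#' class.
#'
#' @param vLA,vPVC Volumes in cm^3.
#' @param ccl Corresponding confluence length, mm.
#' @param mdblc Mean distance between LA and confluence, mm; must be > 0.
#' @param bsa Body surface area in m^2; must be > 0.
#' @param thresholds Risk thresholds passed to [classifyRisk()].
#' @return A [MorphoMetrics-class].
#' @examples
#' m <- computeMetrics(vLA = 10, vPVC = 5, ccl = 11.4, mdblc = 1.5,
#'                     bsa = 0.5)
#' m@ratio   # 7.6
#' @export
computeMetrics <- function(vLA, vPVC, ccl, mdblc, bsa,
                           thresholds = c(20.0, 7.7)) {
  if (bsa <= 0) stop("BSA must be > 0")
  if (mdblc <= 0) stop("mDBLC must be > 0")
  if (vLA < 0 || vPVC < 0) stop("volumes must be >= 0")
  iLA <- vLA / bsa
  iPVC <- vPVC / bsa
  iTVLC <- iLA + iPVC
  ratio <- ccl / mdblc
  new("MorphoMetrics", vLA = vLA, vPVC = vPVC, bsa = bsa,
      iLA = iLA, iPVC = iPVC, iTVLC = iTVLC, ccl = ccl, mdblc = mdblc,
      ratio = ratio,
      riskClass = classifyRisk(iTVLC, ratio, thresholds))
}

#' Quantify one labelled volume end to end
#'
#' Runs the full measurement chain on a labelled segmentation: centerline
#' tree, junction detection, confluence demarcation, LA surface
#' extraction, projection, 100-point DBLC sampling, voxel-count volumes
#' and metric assembly.
#'
#' @param vol A [LabelVolume-class].
#' @param bsa Body surface area, m^2.
#' @param thresholds Risk thresholds, see [classifyRisk()].
#' @param maxProjDist Projection sanity bound (mm), see
#'   [projectConfluence()].
#' @return A list with elements `metrics` ([MorphoMetrics-class]),
#'   `correspondence` ([CorrespondenceSet-class]), `segment`
#'   ([ConfluenceSegment-class]), `tree` ([CenterlineTree-class]) and
#'   `mesh` ([SurfaceMesh-class]).
#' @export
quantifyConfluence <- function(vol, bsa, thresholds = c(20.0, 7.7),
                               maxProjDist = 50) {
  tree <- extractCenterlineTree(vol)
  junctions <- findJunctions(tree, vol)
  seg <- demarcateConfluence(tree, junctions)
  mesh <- extractLASurface(vol)
  cs <- projectConfluence(seg, mesh, maxDist = maxProjDist)
  cs <- sampleDBLC(cs, seg)
  metrics <- computeMetrics(vLA = voxelVolume(vol, "LA"),
                            vPVC = voxelVolume(vol, "PVC"),
                            ccl = cs@ccl, mdblc = cs@mdblc, bsa = bsa,
                            thresholds = thresholds)
  list(metrics = metrics, correspondence = cs, segment = seg,
       tree = tree, mesh = mesh)
}
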