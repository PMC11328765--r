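# S4 classes for the morphometry chain.  All world coordinates are mm;
# volumes are reported in cm^3 (1 cm^3 = 1000 mm^3); voxel indices are
# 0-based in the world-coordinate contract
#   world(i, j, k) = origin + (i * sx, j * sy, k * sz).

.requiredRoles <- c("LA", "PVC", "LUPV", "RUPV", "LIPV", "RIPV", "VV")
.venousRoles <- c("PVC", "LUPV", "RUPV", "LIPV", "RIPV", "VV")

#' Default label schema
#'
#' Maps anatomical roles to integer labels: left atrium (LA), pulmonary
#' venous confluence (PVC), left upper/inferior and right upper/inferior
#' pulmonary veins (LUPV, LIPV, RUPV, RIPV) and the vertical vein (VV).
#' The default assigns 1..7 in that order; any set of distinct positive
#' integers covering all seven roles is accepted wherever a schema is
#' taken.
#'
#' @return Named integer vector mapping role to label.
#' @examples
#' defaultLabelSchema()
#' @export
defaultLabelSchema <- function() {
  setNames(1:7, .requiredRoles)
}

.validateSchema <- function(schema) {
  if (is.null(names(schema)) || !all(.requiredRoles %in% names(schema)))
    return(sprintf("schema must name all roles: %s",
                   paste(.requiredRoles, collapse = ", ")))
  schema <- schema[.requiredRoles]
  if (any(is.na(schema)) || any(schema <= 0) || any(schema != round(schema)))
    return("schema labels must be positive integers")
  if (anyDuplicated(schema))
    return("schema labels must be distinct")
  TRUE
}

#' LabelVolume: a labelled 3D segmentation
#'
#' Holds an integer label grid with voxel spacing (mm), the world position
#' of voxel (0,0,0), and the role-to-label schema.  The world frame is
#' axis-aligned by contract; oblique acquisitions must be resampled before
#' entry.
#'
#' @slot voxels 3D integer array of labels (0 = background).
#' @slot spacing Numeric length 3, mm per voxel along each axis, all > 0.
#' @slot origin Numeric length 3, world mm of voxel index (0,0,0).
#' @slot schema Named integer vector mapping the seven roles to labels.
#' @seealso [readLabelVolume()], [makePhantom()], [voxelVolume()]
#' @export
setClass("LabelVolume",
         representation(voxels = "array", spacing = "numeric",
                        origin = "numeric", schema = "integer"))

setValidity("LabelVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("voxels must be a 3D array")
  if (!is.integer(v))
    return("voxels must have integer storage")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  sv <- .validateSchema(object@schema)
  if (!isTRUE(sv)) return(sv)
  present <- unique(as.vector(v))
  bad <- setdiff(present, c(0L, unname(object@schema)))
  if (length(bad))
    return(sprintf("schema violation: unknown label(s) %s present in volume",
                   paste(sort(bad), collapse = ", ")))
  TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels 3D array of integer labels (0 = background).
#' @param spacing Voxel spacing in mm, length 3.
#' @param origin World mm of voxel (0,0,0); default `c(0,0,0)`.
#' @param schema Role-to-label map; default [defaultLabelSchema()].
#' @return A validated [LabelVolume-class] object.
#' @examples
#' v <- array(0L, c(4, 4, 4)); v[2, 2, 2] <- 1L
#' LabelVolume(v, spacing = c(1, 1, 1))
#' @export
LabelVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                        schema = defaultLabelSchema()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("format error: voxels must be a 3D array")
  if (is.double(voxels)) {
    if (any(voxels != round(voxels)))
      stop("format error: voxel data must be integer labels")
    storage.mode(voxels) <- "integer"
  }
  schema <- setNames(as.integer(schema), names(schema))[.requiredRoles]
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), schema = schema)
}

#' @describeIn LabelVolume-class voxel spacing (mm), length 3
#' @param object,vol A `LabelVolume`.
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @export
setMethod("voxelSpacing", "LabelVolume", function(object) object@spacing)

#' @describeIn LabelVolume-class world position (mm) of voxel (0,0,0)
#' @export
setGeneric("volumeOrigin", function(object) standardGeneric("volumeOrigin"))
#' @export
setMethod("volumeOrigin", "LabelVolume", function(object) object@origin)

#' @describeIn LabelVolume-class role-to-label schema
#' @export
setGeneric("labelSchema", function(object) standardGeneric("labelSchema"))
#' @export
setMethod("labelSchema", "LabelVolume", function(object) object@schema)

#' @describeIn LabelVolume-class the raw 3D integer label array
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @export
setMethod("voxelData", "LabelVolume", function(object) object@voxels)

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  counts <- labelCounts(object)
  cat(sprintf("LabelVolume %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat("  origin (mm):", paste(format(object@origin), collapse = ", "), "\n")
  cat("  voxels per role:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
})

#' Voxel counts per role
#'
#' @param vol A [LabelVolume-class].
#' @return Named integer vector of voxel counts per schema role.
#' @export
labelCounts <- function(vol) {
  stopifnot(is(vol, "LabelVolume"))
  tab <- tabulate(vol@voxels, nbins = max(vol@schema))
  setNames(tab[vol@schema], names(vol@schema))
}

# logical mask of one role
.roleMask <- function(vol, role) {
  role <- match.arg(role, .requiredRoles)
  vol@voxels == vol@schema[[role]]
}

#' Voxel index / world coordinate conversion
#'
#' Voxel indices are 0-based; `worldToVoxel()` rounds to the nearest voxel,
#' so the composition with `voxelToWorld()` is the identity on indices.
#'
#' @param vol A [LabelVolume-class].
#' @param idx `n x 3` matrix of 0-based voxel indices.
#' @param xyz `n x 3` matrix of world coordinates (mm).
#' @return `n x 3` matrix of world coordinates, or 0-based indices.
#' @export
voxelToWorld <- function(vol, idx) {
  idx <- .asPolyline(idx)
  sweep(sweep(idx, 2L, vol@spacing, "*"), 2L, vol@origin, "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(vol, xyz) {
  xyz <- .asPolyline(xyz)
  round(sweep(sweep(xyz, 2L, vol@origin, "-"), 2L, vol@spacing, "/"))
}

#' CenterlineTree: per-structure centerline polylines
#'
#' One ordered polyline (world mm) per labelled venous structure.  Vein
#' branches are ordered from their free end toward the confluence; the main
#' channel (PVC) keeps its build orientation.  Junction nodes are attached
#' by [findJunctions()].
#'
#' @slot branches Named list of `n x 3` matrices (world mm).
#' @slot junctions List of junction nodes (may be empty until
#'   [findJunctions()] is run); each node has elements `point`, `roles`,
#'   `station`.
#' @slot spacing Voxel spacing (mm) of the source volume, kept for
#'   tolerance bookkeeping.
#' @export
setClass("CenterlineTree",
         representation(branches = "list", junctions = "list",
                        spacing = "numeric"))

setValidity("CenterlineTree", function(object) {
  if (!length(object@branches)) return("tree has no branches")
  ok <- vapply(object@branches, function(b)
    is.matrix(b) && ncol(b) == 3L && nrow(b) >= 2L, logical(1))
  if (!all(ok)) return("each branch must be an n x 3 matrix with >= 2 points")
  TRUE
})

#' @describeIn CenterlineTree-class named list of branch polylines
#' @param object A `CenterlineTree`.
#' @export
setGeneric("branchPolylines", function(object)
  standardGeneric("branchPolylines"))
#' @export
setMethod("branchPolylines", "CenterlineTree", function(object)
  object@branches)

setMethod("show", "CenterlineTree", function(object) {
  cat("CenterlineTree with", length(object@branches), "branches\n")
  for (nm in names(object@branches)) {
    b <- object@branches[[nm]]
    cat(sprintf("  %-5s %4d points, arc length %.2f mm\n", nm, nrow(b),
                arcLength(b)))
  }
  if (length(object@junctions))
    cat("  junctions:",
        paste(vapply(object@junctions, function(j)
          paste(j$roles, collapse = "+"), character(1)), collapse = "; "),
        "\n")
})

#' ConfluenceSegment: the demarcated confluence centerline
#'
#' The sub-polyline of the main venous channel between the two junction
#' planes: the plane where the right upper and inferior pulmonary veins
#' join, and the plane where the vertical vein and the left upper
#' pulmonary vein join (mirrored for a right-sided vertical vein).
#'
#' @slot points Ordered polyline, world mm; endpoints lie on the junction
#'   planes.
#' @slot arcLen Arc length in mm.
#' @slot endRoles List with elements `first` and `last`: the member roles
#'   of the junction delimiting each end.
#' @export
setClass("ConfluenceSegment",
         representation(points = "matrix", arcLen = "numeric",
                        endRoles = "list"))

setValidity("ConfluenceSegment", function(object) {
  if (nrow(object@points) < 2L) return("segment needs >= 2 points")
  if (object@arcLen <= 0) return("segment arc length must be positive")
  if (abs(object@arcLen - arcLength(object@points)) >
      1e-6 * (1 + object@arcLen))
    return("recorded arc length does not match the polyline")
  TRUE
})

#' @describeIn ConfluenceSegment-class segment polyline (world mm)
#' @param object A `ConfluenceSegment`.
#' @export
setGeneric("segmentPoints", function(object) standardGeneric("segmentPoints"))
#' @export
setMethod("segmentPoints", "ConfluenceSegment", function(object)
  object@points)

setMethod("show", "ConfluenceSegment", function(object) {
  cat(sprintf("ConfluenceSegment: %d points, arc length %.2f mm\n",
              nrow(object@points), object@arcLen))
  cat("  ends:", paste(object@endRoles$first, collapse = "+"), "<->",
      paste(object@endRoles$last, collapse = "+"), "\n")
})

#' SurfaceMesh: triangulated isosurface
#'
#' Triangle mesh of a label isosurface (level 0.5 between the label and
#' everything else), vertices in world mm.
#'
#' @slot vertices `n x 3` matrix, world mm.
#' @slot faces `m x 3` integer matrix of 1-based vertex indices.
#' @export
setClass("SurfaceMesh",
         representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (nrow(object@faces) &&
      (max(object@faces) > nrow(object@vertices) || min(object@faces) < 1L))
    return("face indices out of range")
  TRUE
})

#' @describeIn SurfaceMesh-class vertex coordinates (world mm)
#' @param object A `SurfaceMesh`.
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @export
setMethod("meshVertices", "SurfaceMesh", function(object) object@vertices)

#' @describeIn SurfaceMesh-class triangle index matrix
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))
#' @export
setMethod("meshFaces", "SurfaceMesh", function(object) object@faces)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@faces)))
})

#' CorrespondenceSet: the corresponding confluence on the LA surface
#'
#' The ordered image of the confluence centerline under closest-point
#' projection onto the LA surface (the "corresponding confluence"), its
#' arc length (CCL), and - once [sampleDBLC()] has run - 100 samples
#' `p_i` at equal arc-length intervals, their projection partners `q_i`
#' on the confluence centerline, the per-point distances DBLC_i and their
#' mean (mDBLC).
#'
#' @slot curve Projected curve on the LA surface, ordered, world mm.
#' @slot samples `100 x 3` matrix of sample points `p_i` (empty until
#'   sampling).
#' @slot partners `100 x 3` matrix of projection partners `q_i`.
#' @slot dblc Numeric length 100, distances `|p_i - q_i|` in mm.
#' @slot ccl Arc length of the projected curve, mm.
#' @slot mdblc Mean of `dblc`, mm.
#' @export
setClass("CorrespondenceSet",
         representation(curve = "matrix", samples = "matrix",
                        partners = "matrix", dblc = "numeric",
                        ccl = "numeric", mdblc = "numeric"))

setValidity("CorrespondenceSet", function(object) {
  if (ncol(object@curve) != 3L) return("curve must be n x 3")
  if (object@ccl < 0) return("CCL must be non-negative")
  if (nrow(object@samples)) {
    if (nrow(object@samples) != 100L || nrow(object@partners) != 100L ||
        length(object@dblc) != 100L)
      return("a completed correspondence set has exactly 100 samples")
    if (any(object@dblc < 0)) return("DBLC distances must be >= 0")
    if (abs(object@mdblc - mean(object@dblc)) > 1e-9 * (1 + object@mdblc))
      return("mDBLC must equal the mean of the 100 DBLC values")
  }
  TRUE
})

#' @describeIn CorrespondenceSet-class per-point DBLC distances (mm)
#' @param object A `CorrespondenceSet`.
#' @export
setGeneric("dblcValues", function(object) standardGeneric("dblcValues"))
#' @export
setMethod("dblcValues", "CorrespondenceSet", function(object) object@dblc)

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet: CCL %.2f mm", object@ccl))
  if (nrow(object@samples))
    cat(sprintf(", mDBLC %.3f mm over %d samples", object@mdblc,
                nrow(object@samples)))
  cat("\n")
})

#' MorphoMetrics: the per-patient morphologic parameters
#'
#' Voxel-count volumes of the LA and the confluence, their
#' body-surface-area indexed forms, the indexed total volume of LA and
#' confluence (iTVLC = iLA + iPVC), CCL, mDBLC, the CCL/mDBLC ratio, and
#' the threshold-based risk class.
#'
#' @slot vLA,vPVC Volumes in cm^3.
#' @slot bsa Body surface area in m^2.
#' @slot iLA,iPVC,iTVLC Indexed volumes, cm^3/m^2.
#' @slot ccl,mdblc Lengths in mm.
#' @slot ratio CCL/mDBLC (dimensionless).
#' @slot riskClass One of `"low"`, `"medium"`, `"high"`.
#' @seealso [computeMetrics()], [classifyRisk()]
#' @export
setClass("MorphoMetrics",
         representation(vLA = "numeric", vPVC = "numeric", bsa = "numeric",
                        iLA = "numeric", iPVC = "numeric",
                        iTVLC = "numeric", ccl = "numeric",
                        mdblc = "numeric", ratio = "numeric",
                        riskClass = "character"))

setValidity("MorphoMetrics", function(object) {
  if (object@vLA < 0 || object@vPVC < 0) return("volumes must be >= 0")
  if (object@bsa <= 0) return("BSA must be > 0")
  if (object@iTVLC != object@iLA + object@iPVC)
    return("iTVLC must equal iLA + iPVC exactly")
  if (!object@riskClass %in% c("low", "medium", "high"))
    return("riskClass must be low/medium/high")
  TRUE
})

setMethod("show", "MorphoMetrics", function(object) {
  cat("MorphoMetrics\n")
  cat(sprintf("  V_LA  %8.3f cm^3   iLA   %8.3f cm^3/m^2\n",
              object@vLA, object@iLA))
  cat(sprintf("  V_PVC %8.3f cm^3   iPVC  %8.3f cm^3/m^2\n",
              object@vPVC, object@iPVC))
  cat(sprintf("  iTVLC %8.3f cm^3/m^2  (BSA %.3f m^2)\n",
              object@iTVLC, object@bsa))
  cat(sprintf("  CCL %.2f mm, mDBLC %.3f mm, CCL/mDBLC %.2f\n",
              object@ccl, object@mdblc, object@ratio))
  cat("  risk class:", object@riskClass, "\n")
})

#' Flatten MorphoMetrics to a one-row data frame
#'
#' @param metrics A [MorphoMetrics-class] object.
#' @return One-row `data.frame` with columns `v_la, v_pvc, bsa, ila_volume,
#'   ipvc_volume, itvlc, ccl, mdblc, ratio, risk_class`.
#' @export
metricsTable <- function(metrics) {
  stopifnot(is(metrics, "MorphoMetrics"))
  data.frame(v_la = metrics@vLA, v_pvc = metrics@vPVC, bsa = metrics@bsa,
             ila_volume = metrics@iLA, ipvc_volume = metrics@iPVC,
             itvlc = metrics@iTVLC, ccl = metrics@ccl,
             mdblc = metrics@mdblc, ratio = metrics@ratio,
             risk_class = metrics@riskClass,
             stringsAsFactors = FALSE)
}
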