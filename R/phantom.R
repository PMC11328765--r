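# Analytic voxel phantoms of the LA + confluence + vein anatomy, with
# closed-form ground truth, and morphology-linked synthetic survival
# cohorts.  Phantoms emulate the supracardiac layout: a confluence channel
# behind the LA, the right upper/inferior pulmonary veins joining at one
# end, the left veins at the other, and the vertical vein leaving the
# left-vein end (type Ia; type Ib mirrors left-right).

#' Phantom configuration
#'
#' Describes an analytic LA + confluence + vein phantom.  Three kinds are
#' supported:
#' \describe{
#'   \item{`slab`}{LA is a box with its anterior face at `x = 0`; the
#'     confluence is a straight tube of length `confLength` whose axis is
#'     kept at constant distance `gap` from the face.  The axis is tilted
#'     within the face-parallel plane (slope `tiltSlope`) so that tube
#'     cross-sections sweep through all lattice phases, which keeps the
#'     voxel-count volume free of lattice-locking bias; the tilt changes
#'     neither the gap nor the length.  Truth: CCL = `confLength`,
#'     DBLC = `gap`.}
#'   \item{`sphere_arc`}{LA is a sphere of radius `laRadius` centred at the
#'     origin; the confluence is a concentric circular arc of radius
#'     `laRadius + gap` in the equatorial plane subtending `arcAngle`
#'     radians.  Truth: CCL = `laRadius * arcAngle`, DBLC = `gap`.}
#'   \item{`ellipsoid_tree`}{LA is an ellipsoid with semi-axes `semiAxes`;
#'     the confluence arc lies in the equatorial plane at
#'     `max(semiAxes[1:2]) + gap`.  Volume truth is `4/3 pi a b c`; CCL
#'     and DBLC truths are only closed-form when the two equatorial
#'     semi-axes are equal.}
#' }
#' Pulmonary-vein stubs and the vertical vein are attached at the two ends
#' of the confluence; `vvSide = "left"` gives the type Ia layout
#' (RUPV+RIPV at one junction, LUPV+LIPV+VV at the other), `"right"`
#' mirrors the left/right role names (type Ib).
#'
#' @param kind One of `"slab"`, `"sphere_arc"`, `"ellipsoid_tree"`.
#' @param spacing Isotropic voxel spacing in mm (default 0.5).
#' @param gap Distance (mm) from the LA surface to the confluence
#'   centerline: the uniform DBLC truth.  Must exceed `tubeRadius`.
#' @param confLength Straight confluence length L (mm), slab only.
#' @param tiltSlope Slope of the slab confluence axis within the
#'   face-parallel plane (dimensionless; slab only).
#' @param laExtent Box extents (mm) of the slab LA, `c(depth, length,
#'   height)`; the face at `x = 0` spans `length x height`.
#' @param laRadius Sphere radius R (mm), sphere_arc only.
#' @param semiAxes Ellipsoid semi-axes (mm), ellipsoid_tree only.
#' @param arcAngle Arc angle theta (radians), arc kinds only.
#' @param tubeRadius Confluence tube radius (mm).
#' @param stubRadius,stubLength Radius and length (mm) of the vein stubs.
#' @param vvSide `"left"` (type Ia) or `"right"` (type Ib).
#' @param strict If `TRUE`, an under-resolved tube
#'   (`tubeRadius < 2 * spacing`) is an error instead of a warning.
#' @return An object of class `phantomConfig`.
#' @seealso [makePhantom()]
#' @export
phantomConfig <- function(kind = c("slab", "sphere_arc", "ellipsoid_tree"),
                          spacing = 0.5,
                          gap = if (kind == "slab") 3 else 2,
                          confLength = 30, tiltSlope = 0.15,
                          laExtent = c(12, 46, 26),
                          laRadius = 20, semiAxes = c(20, 20, 20),
                          arcAngle = 1,
                          tubeRadius = if (kind == "slab") 2.5 else 1.8,
                          stubRadius = 0.8 * tubeRadius, stubLength = 8,
                          vvSide = c("left", "right"), strict = FALSE) {
  kind <- match.arg(kind)
  vvSide <- match.arg(vvSide)
  if (spacing <= 0) stop("config error: spacing must be > 0")
  if (gap <= 0) stop("config error: gap must be > 0")
  if (tubeRadius <= 0 || stubRadius <= 0)
    stop("config error: tube radii must be > 0")
  if (kind == "slab" && confLength <= 0)
    stop("config error: confLength must be > 0")
  if (kind != "slab" && (arcAngle <= 0 || arcAngle > pi))
    stop("config error: arcAngle must be in (0, pi]")
  if (tubeRadius >= gap)
    stop("config error: confluence tube (radius ", tubeRadius,
         " mm) would intersect the LA label across a gap of ", gap, " mm")
  if (stubRadius >= gap)
    stop("config error: vein stubs (radius ", stubRadius,
         " mm) would intersect the LA label across a gap of ", gap, " mm")
  if (tubeRadius < 2 * spacing) {
    msg <- sprintf(
      "tube radius %.2f mm is under-resolved at %.2f mm spacing (< 2 voxels)",
      tubeRadius, spacing)
    if (strict) stop("config error: ", msg) else warning(msg)
  }
  structure(list(kind = kind, spacing = spacing, gap = gap,
                 confLength = confLength, tiltSlope = tiltSlope,
                 laExtent = laExtent, laRadius = laRadius,
                 semiAxes = semiAxes, arcAngle = arcAngle,
                 tubeRadius = tubeRadius, stubRadius = stubRadius,
                 stubLength = stubLength, vvSide = vvSide,
                 strict = strict),
            class = "phantomConfig")
}

# role layout at the two confluence ends for a given vertical-vein side
.phantomLayout <- function(vvSide) {
  if (vvSide == "left")
    list(pairEnd = c("RUPV", "RIPV"), vvEnd = c("LUPV", "LIPV", "VV"))
  else
    list(pairEnd = c("LUPV", "LIPV"), vvEnd = c("RUPV", "RIPV", "VV"))
}

# grid with controllable per-axis lattice phase: phase h/2 puts geometry
# planes at integer multiples of h exactly between voxel centers (used for
# the slab face and the slab tube axis), phase 0 puts a voxel-center plane
# at z = 0 (used for the arc plane, whose cross-section circles otherwise
# straddle the lattice rows unfavourably)
.phantomGrid <- function(lo, hi, h, margin, phase = rep(h / 2, 3)) {
  lo <- floor((lo - margin) / h) * h
  hi <- ceiling((hi + margin) / h) * h
  lapply(1:3, function(k) seq(lo[k] + phase[k], hi[k], by = h))
}

# distance predicate painters ----------------------------------------------

# subgrid index ranges covering a bounding box
.gridWindow <- function(axes, lo, hi) {
  lapply(1:3, function(k) which(axes[[k]] >= lo[k] & axes[[k]] <= hi[k]))
}

# paint label into voxels where predicate(P) holds (P = m x 3 of centers),
# restricted to a bounding box; returns the updated array and a count of
# voxels that collided with the LA label (for overlap checks)
.paintSolid <- function(vox, axes, lo, hi, predicate, label, laLabel) {
  w <- .gridWindow(axes, lo, hi)
  if (!all(lengths(w) > 0)) return(list(vox = vox, laHits = 0L))
  P <- as.matrix(expand.grid(x = axes[[1]][w[[1]]], y = axes[[2]][w[[2]]],
                             z = axes[[3]][w[[3]]], KEEP.OUT.ATTRS = FALSE))
  inside <- as.vector(predicate(P))
  sub <- vox[w[[1]], w[[2]], w[[3]]]
  subDim <- dim(sub)
  sub <- as.vector(sub)
  laHits <- sum(inside & sub == laLabel)
  sel <- inside & sub == 0L
  sub[sel] <- label
  vox[w[[1]], w[[2]], w[[3]]] <- array(sub, subDim)
  list(vox = vox, laHits = laHits)
}

.tubePredicate <- function(S, u, L, r) {
  force(S); force(u); force(L); force(r)
  function(P) {
    W <- sweep(P, 2L, S, "-")
    along <- W %*% u
    perp2 <- rowSums(W^2) - along^2
    perp2 <= r^2 & along >= 0 & along <= L
  }
}

.arcPredicate <- function(A, theta, r) {
  force(A); force(theta); force(r)
  function(P) {
    phi <- atan2(P[, 2], P[, 1])
    rad <- sqrt(P[, 1]^2 + P[, 2]^2)
    d2 <- (rad - A)^2 + P[, 3]^2
    d2 <= r^2 & phi >= 0 & phi <= theta
  }
}

#' Generate an analytic voxel phantom
#'
#' Rasterizes the configured geometry by voxel-center thresholding
#' (a voxel belongs to a solid when its center does) and returns the
#' labelled volume together with the closed-form ground truth: the LA and
#' confluence volumes, the true confluence centerline, CCL, the uniform
#' DBLC, and the world coordinates of the two junctions.  Truth values
#' come from the closed forms, never from the raster.
#'
#' @param config A [phantomConfig()].
#' @return A list with elements `volume` (a [LabelVolume-class]), `truth`
#'   (list: `laVolume`, `pvcVolume` in cm^3, `ccl`, `dblc` in mm, `ratio`,
#'   `centerline`, `junctions`), and `config`.
#' @examples
#' ph <- makePhantom(phantomConfig("slab", spacing = 1))
#' ph$truth$ccl / ph$truth$dblc   # 10
#' @export
makePhantom <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  h <- config$spacing
  schema <- defaultLabelSchema()
  layout <- .phantomLayout(config$vvSide)
  rT <- config$tubeRadius; rS <- config$stubRadius; sL <- config$stubLength

  if (config$kind == "slab") {
    d <- config$gap; L <- config$confLength; sigma <- config$tiltSlope
    u <- c(0, 1, sigma) / sqrt(1 + sigma^2)       # confluence axis
    S <- c(d, 0, 0); E <- S + L * u
    ext <- config$laExtent
    boxLo <- c(-ext[1], -ext[2] / 2 + L / 2 * u[2], -ext[3] / 2 + E[3] / 2)
    boxHi <- c(0, ext[2] / 2 + L / 2 * u[2], ext[3] / 2 + E[3] / 2)
    laPredicate <- function(P)
      P[, 1] >= boxLo[1] & P[, 1] <= boxHi[1] &
      P[, 2] >= boxLo[2] & P[, 2] <= boxHi[2] &
      P[, 3] >= boxLo[3] & P[, 3] <= boxHi[3]
    laLo <- boxLo; laHi <- boxHi
    laVolume <- prod(boxHi - boxLo) / 1000
    pvcVolume <- pi * rT^2 * L / 1000
    tubePred <- .tubePredicate(S, u, L, rT)
    tubeLo <- pmin(S, E) - rT; tubeHi <- pmax(S, E) + rT
    phi <- seq(0, 1, length.out = max(64L, ceiling(L / (h / 2))))
    centerline <- t(S + outer(u, phi * L))
    ccl <- L; dblc <- d
    outS <- -u; outE <- u
    radS <- c(1, 0, 0); radE <- c(1, 0, 0)
  } else {
    R <- if (config$kind == "sphere_arc") config$laRadius
         else max(config$semiAxes[1:2])
    ax <- if (config$kind == "sphere_arc") rep(config$laRadius, 3)
          else config$semiAxes
    g <- config$gap; theta <- config$arcAngle
    A <- R + g
    laPredicate <- function(P)
      (P[, 1] / ax[1])^2 + (P[, 2] / ax[2])^2 + (P[, 3] / ax[3])^2 <= 1
    laLo <- -ax; laHi <- ax
    laVolume <- 4 / 3 * pi * prod(ax) / 1000
    pvcVolume <- pi * rT^2 * A * theta / 1000
    tubePred <- .arcPredicate(A, theta, rT)
    tubeLo <- c(min(cos(seq(0, theta, length.out = 33))) * A - rT,
                min(0, sin(theta)) * A - rT, -rT)
    tubeLo[1] <- min(tubeLo[1], A * cos(theta) - rT)
    tubeHi <- c(A + rT, A * max(sin(seq(0, theta, length.out = 33))) + rT,
                rT)
    S <- c(A, 0, 0); E <- c(A * cos(theta), A * sin(theta), 0)
    phi <- seq(0, theta, length.out = max(64L, ceiling(A * theta / (h / 2))))
    centerline <- cbind(A * cos(phi), A * sin(phi), 0)
    eqAxes <- if (config$kind == "sphere_arc") TRUE
              else isTRUE(all.equal(ax[1], ax[2]))
    ccl <- if (eqAxes) R * theta else NA_real_
    dblc <- if (eqAxes) g else NA_real_
    outS <- c(0, -1, 0); outE <- c(-sin(theta), cos(theta), 0)
    radS <- c(1, 0, 0); radE <- c(cos(theta), sin(theta), 0)
  }

  # vein stub directions: the paired veins fan out of the pair end, the
  # vv-end veins fan out of the other end with the vertical vein ascending
  up <- c(0, 0, 1)
  stubs <- list()
  pair <- layout$pairEnd; vvend <- layout$vvEnd
  stubs[[pair[1]]] <- list(S = S, dir = 0.45 * radS + outS + 0.7 * up)
  stubs[[pair[2]]] <- list(S = S, dir = 0.45 * radS + outS - 0.7 * up)
  stubs[[vvend[1]]] <- list(S = E, dir = 0.45 * radE + outE + 0.7 * up)
  stubs[[vvend[2]]] <- list(S = E, dir = 0.45 * radE + outE - 0.7 * up)
  stubs[[vvend[3]]] <- list(S = E, dir = 0.5 * radE + 0.3 * outE + 1.6 * up)

  lo <- pmin(laLo, tubeLo)
  hi <- pmax(laHi, tubeHi)
  for (st in stubs) {
    dirn <- st$dir / sqrt(sum(st$dir^2))
    lo <- pmin(lo, st$S + sL * pmin(dirn, 0) - rS)
    hi <- pmax(hi, st$S + sL * pmax(dirn, 0) + rS)
  }
  phase <- if (config$kind == "slab") rep(h / 2, 3) else c(h / 2, h / 2, 0)
  axes <- .phantomGrid(lo, hi, h, margin = 2 * h, phase = phase)
  dims <- lengths(axes)
  vox <- array(0L, dim = dims)
  origin <- c(axes[[1]][1], axes[[2]][1], axes[[3]][1])

  # paint LA
  w <- .gridWindow(axes, laLo - h, laHi + h)
  P <- as.matrix(expand.grid(x = axes[[1]][w[[1]]], y = axes[[2]][w[[2]]],
                             z = axes[[3]][w[[3]]], KEEP.OUT.ATTRS = FALSE))
  sub <- array(0L, dim = lengths(w))
  sub[laPredicate(P)] <- schema[["LA"]]
  vox[w[[1]], w[[2]], w[[3]]] <- sub

  # paint confluence, then stubs; collisions with LA are config errors
  res <- .paintSolid(vox, axes, tubeLo - h, tubeHi + h, tubePred,
                     schema[["PVC"]], schema[["LA"]])
  if (res$laHits > 0)
    stop("config error: confluence tube intersects the LA label")
  vox <- res$vox
  for (role in names(stubs)) {
    st <- stubs[[role]]
    dirn <- st$dir / sqrt(sum(st$dir^2))
    sLo <- pmin(st$S, st$S + sL * dirn) - rS
    sHi <- pmax(st$S, st$S + sL * dirn) + rS
    res <- .paintSolid(vox, axes, sLo - h, sHi + h,
                       .tubePredicate(st$S, dirn, sL, rS),
                       schema[[role]], schema[["LA"]])
    if (res$laHits > 0)
      stop(sprintf("config error: %s stub intersects the LA label", role))
    vox <- res$vox
  }

  # where stubs meet (earlier labels win), a later stub can be left with a
  # few orphan voxels; keep each venous label's largest 6-connected
  # component and clear the strays
  for (role in .venousRoles) {
    lin <- which(vox == schema[[role]])
    if (length(lin) < 2L) next
    ed <- .voxelEdges(lin, dims, rep(h, 3), connectivity = 6L)
    g <- igraph::make_graph(rbind(ed$from, ed$to), n = length(lin),
                            directed = FALSE)
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      keep <- which.max(comp$csize)
      vox[lin[comp$membership != keep]] <- 0L
    }
  }

  volume <- LabelVolume(vox, spacing = rep(h, 3), origin = origin,
                        schema = schema)
  truth <- list(kind = config$kind,
                laVolume = laVolume, pvcVolume = pvcVolume,
                ccl = ccl, dblc = dblc, ratio = ccl / dblc,
                centerline = centerline,
                junctions = list(
                  list(point = S, roles = layout$pairEnd),
                  list(point = E, roles = layout$vvEnd)))
  list(volume = volume, truth = truth, config = config)
}

# ---------------------------------------------------------------------------

#' Generate a morphology-linked synthetic survival cohort
#'
#' Draws per-patient phantom geometries (sphere-arc kind) from documented
#' uniform ranges, computes the closed-form morphometric truth (iLA, iPVC,
#' iTVLC in cm^3/m^2 and the CCL/mDBLC ratio), and simulates a
#' right-censored time-to-PPVS outcome whose hazard is log-linear in the
#' morphometry:
#' \deqn{h_i = h_0 \exp(\beta_{iTVLC} \cdot iTVLC_i +
#'             \beta_{ratio} \cdot ratio_i)}
#' Event times are exponential; censoring is independent uniform on
#' `(0, c_max)` with `c_max` calibrated so the expected censored fraction
#' equals `censorRate`.  `prepvo` is drawn with probability decreasing in
#' iTVLC (mirroring the clinical association) but has no direct effect on
#' the hazard, so the generative coefficients are exactly
#' `effectItvlc`/`effectRatio`.
#'
#' Default geometry ranges: LA radius U(8.5, 12.5) mm, gap U(1.6, 2.5) mm,
#' arc angle U(0.9, 1.9) rad, BSA U(0.24, 0.34) m^2; these bracket an
#' iTVLC of roughly 8-35 cm^3/m^2 and a CCL/mDBLC ratio of roughly 3-15,
#' i.e. they straddle the clinical thresholds of 20 cm^3/m^2 and 7.7.
#'
#' @param n Number of patients (>= 2).
#' @param effectItvlc Log hazard ratio per cm^3/m^2 of iTVLC.
#' @param effectRatio Log hazard ratio per unit of CCL/mDBLC ratio.
#' @param censorRate Expected fraction censored, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param baselineHazard Baseline hazard `h_0` per month (default 0.6).
#' @param spacing Voxel spacing recorded in the per-patient phantom
#'   configurations (used when the cohort is rasterized by the pipeline).
#' @return List with `cohort` (a `data.frame`: `id, age_days, bsa_m2,
#'   prepvo, time_months, event` plus the truth columns `itvlc, ratio,
#'   ila_volume, ipvc_volume`) and `configs` (list of [phantomConfig()]
#'   objects, one per patient).
#' @export
makeSyntheticCohort <- function(n, effectItvlc = -0.15, effectRatio = 0,
                                censorRate = 0.3, seed = 1,
                                baselineHazard = 0.6, spacing = 0.5) {
  if (n < 2) stop("n must be >= 2")
  if (!is.finite(effectItvlc) || !is.finite(effectRatio))
    stop("effects must be finite")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must be in [0, 1)")
  .withSeed(seed, {
    R <- runif(n, 8.5, 12.5)
    g <- runif(n, 1.6, 2.5)
    theta <- runif(n, 0.9, 1.9)
    bsa <- runif(n, 0.24, 0.34)
    rTube <- 0.65 * g
    ila <- (4 / 3 * pi * R^3 / 1000) / bsa
    ipvc <- (pi * rTube^2 * (R + g) * theta / 1000) / bsa
    itvlc <- ila + ipvc
    ratio <- R * theta / g
    age <- pmin(3000, pmax(3, round(rlnorm(n, log(61), 0.8))))
    prepvo <- rbinom(n, 1L, stats::plogis(-0.66 - 0.12 * (itvlc - 20))) == 1L

    lambda <- baselineHazard * exp(effectItvlc * itvlc + effectRatio * ratio)
    tEvent <- rexp(n, rate = lambda)
    if (censorRate == 0) {
      cTime <- rep(Inf, n)
    } else {
      pcens <- function(cmax)
        mean((1 - exp(-lambda * cmax)) / (lambda * cmax)) - censorRate
      cmax <- uniroot(pcens, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
      cTime <- runif(n, 0, cmax)
    }
    event <- tEvent <= cTime
    time <- pmax(0.1, round(pmin(tEvent, cTime), 1))

    cohort <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      age_days = age, bsa_m2 = bsa, prepvo = prepvo,
      time_months = time, event = event,
      itvlc = itvlc, ratio = ratio,
      ila_volume = ila, ipvc_volume = ipvc,
      stringsAsFactors = FALSE)
    configs <- lapply(seq_len(n), function(i)
      suppressWarnings(phantomConfig(
        "sphere_arc", spacing = spacing, gap = g[i], laRadius = R[i],
        arcAngle = theta[i], tubeRadius = rTube[i],
        stubRadius = 0.8 * rTube[i], stubLength = 6)))
    list(cohort = cohort, configs = configs,
         params = list(effectItvlc = effectItvlc, effectRatio = effectRatio,
                       censorRate = censorRate, seed = seed,
                       baselineHazard = baselineHazard))
  })
}
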