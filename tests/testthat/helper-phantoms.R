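# Phantoms and their quantifications are expensive enough to share across
# test files; build them lazily and cache for the session.

.phantomCache <- new.env(parent = emptyenv())

cachedPhantom <- function(name) {
  if (!is.null(.phantomCache[[name]])) return(.phantomCache[[name]])
  ph <- switch(name,
    slab = makePhantom(phantomConfig("slab")),
    sphere = makePhantom(phantomConfig("sphere_arc")),
    slab2x = makePhantom(phantomConfig(
      "slab", gap = 6, confLength = 60, tubeRadius = 5, stubRadius = 4,
      stubLength = 16, laExtent = c(24, 92, 52))),
    stop("unknown cached phantom: ", name))
  .phantomCache[[name]] <- ph
  ph
}

cachedQuantification <- function(name, bsa = 0.26) {
  key <- paste0("q_", name)
  if (!is.null(.phantomCache[[key]])) return(.phantomCache[[key]])
  ph <- cachedPhantom(name)
  t0 <- proc.time()[["elapsed"]]
  q <- quantifyConfluence(ph$volume, bsa = bsa)
  q$elapsed <- proc.time()[["elapsed"]] - t0
  .phantomCache[[key]] <- q
  q
}

# a bare cylinder along +y as a LabelVolume with only the PVC label;
# the axis is deliberately off the lattice planes (quarter-voxel offset)
makeCylinderVolume <- function(radius = 4, length = 40, spacing = 0.5) {
  h <- spacing
  xs <- seq(-radius - 2 * h, radius + 2 * h, by = h) + h / 4
  ys <- seq(-2 * h, length + 2 * h, by = h) + h / 4
  zs <- xs
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  inside <- g$x^2 + g$z^2 <= radius^2 & g$y >= 0 & g$y <= length
  vox <- array(0L, dim = c(length(xs), length(ys), length(zs)))
  vox[inside] <- 2L   # PVC
  LabelVolume(vox, spacing = rep(h, 3),
              origin = c(xs[1], ys[1], zs[1]))
}

# an L-shaped tube (limb along +y joined to a limb along +x) with only
# the PVC label
makeLTubeVolume <- function(radius = 2, limb = 20, spacing = 0.5) {
  h <- spacing
  xs <- seq(-radius - 2 * h, limb + radius + 2 * h, by = h) + h / 4
  ys <- xs
  zs <- seq(-radius - 2 * h, radius + 2 * h, by = h) + h / 4
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  t1 <- pmin(pmax(g$y, 0), limb)                     # (0, t, 0)
  d1 <- sqrt(g$x^2 + (g$y - t1)^2 + g$z^2)
  t2 <- pmin(pmax(g$x, 0), limb)                     # (t, limb, 0)
  d2 <- sqrt((g$x - t2)^2 + (g$y - limb)^2 + g$z^2)
  inside <- pmin(d1, d2) <= radius
  vox <- array(0L, dim = c(length(xs), length(ys), length(zs)))
  vox[inside] <- 2L
  LabelVolume(vox, spacing = rep(h, 3),
              origin = c(xs[1], ys[1], zs[1]))
}

# a survival sample data.frame from a synthetic cohort
cohortSample <- function(sc, cols = c("itvlc", "ratio")) {
  d <- data.frame(time = sc$cohort$time_months,
                  event = as.integer(sc$cohort$event))
  for (cl in cols) d[[cl]] <- sc$cohort[[cl]]
  d
}
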