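# Polyline primitives shared by the centerline, projection and sampling
# stages.  Polylines are n x 3 matrices of world coordinates in mm.

.asPolyline <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points)) && length(points) == 3L) points <- matrix(points, 1L)
  if (!is.matrix(points) || ncol(points) != 3L || !is.numeric(points))
    stop("a polyline must be an n x 3 numeric matrix of world coordinates (mm)")
  storage.mode(points) <- "double"
  points
}

# cumulative arc length from the first point; length n
.cumArc <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  c(0, cumsum(sqrt(rowSums((P[-1L, , drop = FALSE] -
                            P[-n, , drop = FALSE])^2))))
}

#' Arc length of a polyline
#'
#' Sum of Euclidean distances between consecutive points.  This is the
#' length primitive behind both the corresponding confluence length (CCL)
#' and the demarcated confluence segment length; it is always at least the
#' straight-line end-to-end distance.
#'
#' @param points An `n x 3` numeric matrix of world coordinates in mm,
#'   `n >= 2`.
#' @return Arc length in mm.
#' @examples
#' arcLength(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
arcLength <- function(points) {
  P <- .asPolyline(points)
  if (nrow(P) < 2L)
    stop("arc length needs at least 2 points")
  s <- .cumArc(P)
  s[length(s)]
}

# Resample a polyline at stations spaced equally in arc length.  Both
# endpoints are always included; n is the number of output points.
.resamplePolyline <- function(P, n) {
  P <- .asPolyline(P)
  if (nrow(P) < 2L) stop("cannot resample a polyline with fewer than 2 points")
  s <- .cumArc(P)
  total <- s[length(s)]
  if (total <= 0) return(P[rep(1L, n), , drop = FALSE])
  # drop zero-length duplicate stations for approx()
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; P <- P[keep, , drop = FALSE]
  st <- seq(0, total, length.out = n)
  out <- vapply(1:3, function(k) approx(s, P[, k], xout = st)$y,
                numeric(n))
  matrix(out, ncol = 3L)
}

# Moving-average smoothing with fixed endpoints.  Interior points are
# replaced by the mean over a centred window; points too close to either
# end for a full window are left untouched.
.smoothPolyline <- function(P, window = 3L) {
  P <- .asPolyline(P)
  n <- nrow(P)
  window <- as.integer(window)
  if (window <= 1L || n < window + 2L) return(P)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  out <- P
  kernel <- rep(1 / window, window)
  for (k in 1:3) {
    sm <- stats::filter(P[, k], kernel, sides = 2)
    idx <- (1L + half):(n - half)
    out[idx, k] <- sm[idx]
  }
  out
}

# Closest points on a polyline (treated as a chain of segments) for a set
# of query points.  Returns the foot points, distances, and arc-length
# stations of the feet.
.closestOnPolyline <- function(P, Q) {
  P <- .asPolyline(P); Q <- .asPolyline(Q)
  n <- nrow(P)
  A <- P[-n, , drop = FALSE]
  D <- P[-1L, , drop = FALSE] - A
  len2 <- rowSums(D^2)
  len2[len2 == 0] <- 1e-300
  s0 <- .cumArc(P)[-n]
  m <- nrow(Q)
  feet <- matrix(0, m, 3L)
  dist <- numeric(m)
  station <- numeric(m)
  for (i in seq_len(m)) {
    q <- Q[i, ]
    w <- sweep(A, 2L, q, "-")
    t <- pmin(1, pmax(0, -(w[, 1] * D[, 1] + w[, 2] * D[, 2] +
                             w[, 3] * D[, 3]) / len2))
    px <- A + D * t
    d2 <- rowSums(sweep(px, 2L, q, "-")^2)
    j <- which.min(d2)
    feet[i, ] <- px[j, ]
    dist[i] <- sqrt(d2[j])
    station[i] <- s0[j] + t[j] * sqrt(len2[j])
  }
  list(points = feet, dist = dist, station = station)
}

# Unit tangents along a polyline by central differences (one-sided at the
# ends).
.polylineTangents <- function(P) {
  P <- .asPolyline(P)
  n <- nrow(P)
  Tg <- matrix(0, n, 3L)
  if (n >= 2L) {
    Tg[1L, ] <- P[2L, ] - P[1L, ]
    Tg[n, ] <- P[n, ] - P[n - 1L, ]
    if (n > 2L)
      Tg[2:(n - 1L), ] <- P[3:n, , drop = FALSE] - P[1:(n - 2L), , drop = FALSE]
  }
  nrm <- sqrt(rowSums(Tg^2))
  nrm[nrm == 0] <- 1
  Tg / nrm
}

# Point on a polyline at a given arc-length station (clamped to [0, L]).
.pointAtStation <- function(P, s) {
  P <- .asPolyline(P)
  cs <- .cumArc(P)
  s <- pmin(max(cs), pmax(0, s))
  vapply(1:3, function(k) approx(cs, P[, k], xout = s)$y, numeric(length(s)))
}

# run expression under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
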