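# Internal helpers: seeded RNG scoping, seed splitting, polygon primitives.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic seed splitting: one root seed spawns independent child seeds,
# so adding a component does not perturb the draws of the others. LCG-style
# mixing, folded into the positive 32-bit integer range.
split_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in seq_len(2L)) {
    s <- (s * 48271 + 11 * (as.double(index) + 1)) %% 2147483647
  }
  as.integer(s)
}

# Signed area of a polygon ring (x, y open ring, no repeated last vertex).
# Positive for counter-clockwise orientation in a standard (y-up) frame.
polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(x, y) abs(polygon_signed_area(x, y))

# Simple-polygon check: no two non-adjacent edges intersect.
polygon_is_simple <- function(x, y) {
  n <- length(x)
  if (n < 3) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (seg_int(c(x[i], y[i]), c(x2[i], y2[i]), c(x[j], y[j]), c(x2[j], y2[j])))
        return(FALSE)
    }
  }
  TRUE
}

# Boundary-inclusive point-in-polygon for many points against one ring.
points_in_polygon <- function(px, py, ring_x, ring_y) {
  sp::point.in.polygon(px, py, ring_x, ring_y) > 0
}

# Minimum distance from a single point to a polygon boundary (edges).
point_to_ring_distance <- function(px, py, ring_x, ring_y) {
  n <- length(ring_x)
  x2 <- c(ring_x[-1], ring_x[1]); y2 <- c(ring_y[-1], ring_y[1])
  dx <- x2 - ring_x; dy <- y2 - ring_y
  len2 <- dx^2 + dy^2
  t <- ((px - ring_x) * dx + (py - ring_y) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- ring_x + t * dx; qy <- ring_y + t * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
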