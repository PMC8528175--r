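#' Test whether two closed line segments intersect
#'
#' Uses the standard orientation (counter-clockwise) test, with collinear
#' overlap handled by bounding-box checks. Segments are treated as closed
#' sets, so sharing a single endpoint counts as an intersection; this is the
#' convention used when enforcing that connector lines of a dot pattern
#' neither cross nor touch.
#'
#' @param a1,a2 Numeric length-2 vectors, endpoints of the first segment.
#' @param b1,b2 Numeric length-2 vectors, endpoints of the second segment.
#' @return `TRUE` if the closed segments share at least one point.
#' @examples
#' segments_intersect(c(0, 0), c(1, 1), c(0, 1), c(1, 0)) # crossing diagonals
#' segments_intersect(c(0, 0), c(1, 0), c(0, 1), c(1, 1)) # parallel, disjoint
#' @export
segments_intersect <- function(a1, a2, b1, b2) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(b1), is.finite(b2))
  orient <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(p, q, r) {
    # r collinear with pq: does r lie within the bounding box?
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  d1 <- orient(a1, a2, b1)
  d2 <- orient(a1, a2, b2)
  d3 <- orient(b1, b2, a1)
  d4 <- orient(b1, b2, a2)
  if (d1 != d2 && d3 != d4) return(TRUE)
  if (d1 == 0 && on_seg(a1, a2, b1)) return(TRUE)
  if (d2 == 0 && on_seg(a1, a2, b2)) return(TRUE)
  if (d3 == 0 && on_seg(b1, b2, a1)) return(TRUE)
  if (d4 == 0 && on_seg(b1, b2, a2)) return(TRUE)
  FALSE
}

#' Distance from a point to a closed line segment
#'
#' Euclidean distance from `p` to the nearest point of the segment
#' `s1`--`s2` (endpoints included). Zero-length segments degrade to
#' point-to-point distance.
#'
#' @param p Numeric length-2 vector.
#' @param s1,s2 Numeric length-2 vectors, segment endpoints.
#' @return Non-negative scalar distance.
#' @examples
#' point_segment_distance(c(0, 0), c(1, 0), c(1, 1)) # 1
#' point_segment_distance(c(2, 2), c(0, 0), c(1, 0)) # sqrt(5)
#' @export
point_segment_distance <- function(p, s1, s2) {
  stopifnot(is.finite(p), is.finite(s1), is.finite(s2))
  d <- s2 - s1
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt(sum((p - s1)^2)))
  t <- max(0, min(1, sum((p - s1) * d) / len2))
  sqrt(sum((p - s1 - t * d)^2))
}

# Vectorised distance from many points (matrix n x 2) to one segment.
# Internal workhorse for rejection sampling and validation.
points_segment_distance <- function(pts, s1, s2) {
  d <- s2 - s1
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt((pts[, 1] - s1[1])^2 + (pts[, 2] - s1[2])^2))
  t <- ((pts[, 1] - s1[1]) * d[1] + (pts[, 2] - s1[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - s1[1] - t * d[1])^2 + (pts[, 2] - s1[2] - t * d[2])^2)
}
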