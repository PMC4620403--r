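# Angle and polygon helpers shared across modules.

#' Wrap an angle to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
deg_mod <- function(x) {
  ((x %% 360) + 360) %% 360
}

#' Screen-counterclockwise direction between two pixel coordinates
#'
#' Angles follow the displayed-image convention: columns increase to the
#' right, rows increase downward, and angles grow counterclockwise as seen
#' on screen (0 deg points toward increasing column). This is the one place
#' where the orientation convention is fixed; everything else inherits it.
#'
#' @param from length-2 numeric `(row, col)` origin.
#' @param to numeric `(row, col)` target, or an n x 2 matrix of targets.
#' @return direction(s) in degrees in `[0, 360)`.
#' @export
direction_deg <- function(from, to) {
  if (is.null(dim(to))) to <- matrix(to, ncol = 2)
  dr <- to[, 1] - from[1]
  dc <- to[, 2] - from[2]
  if (any(dr == 0 & dc == 0)) {
    stop("direction undefined: target coincides with origin")
  }
  deg_mod(atan2(-dr, dc) * 180 / pi)
}

# Close a polygon (repeat first vertex) if not already closed.
close_polygon <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 2L) return(p)
  if (!all(p[1L, ] == p[nrow(p), ])) p <- rbind(p, p[1L, ])
  p
}

# Drop a repeated closing vertex and consecutive duplicates.
open_polygon <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) >= 2L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(p))) == 0)
    p <- p[!dup, , drop = FALSE]
  }
  p
}

# Proper/improper intersection test for segments p1-p2 and p3-p4.
segments_intersect <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# TRUE when the polygon (open vertex list) has no self-intersections.
is_simple_polygon <- function(p) {
  p <- open_polygon(p)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (shared vertex), including the wrap pair
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- p[i, ]; b <- p[i %% n + 1L, ]
      c <- p[j, ]; d <- p[j %% n + 1L, ]
      if (segments_intersect(a, b, c, d)) return(FALSE)
    }
  }
  TRUE
}

# Points (n x 2, (row, col)) inside a polygon, via mgcv's ray caster.
points_in_polygon <- function(points, polygon) {
  poly <- close_polygon(polygon)
  mgcv::in.out(poly, as.matrix(points))
}
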