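# independent brute-force oracles used across the test files

# naive O(n^2) time-averaged MSD
naive_msd <- function(x, y, max_lag) {
  vapply(seq_len(max_lag), function(k) {
    acc <- 0
    n <- 0L
    for (i in seq_len(length(x) - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      n <- n + 1L
    }
    acc / n
  }, numeric(1))
}

# ray-casting point-in-polygon (boundary handled separately by caller)
naive_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[j, 1] + (py - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# do two segments intersect (including touching)?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# brute-force polygon disjointness: no edge crossings and no containment
polygons_disjoint <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1 else i + 1, ]
    for (j in seq_len(nb)) {
      p3 <- b[j, ]; p4 <- b[if (j == nb) 1 else j + 1, ]
      if (segments_intersect(p1, p2, p3, p4)) return(FALSE)
    }
  }
  if (naive_point_in_polygon(a[1, 1], a[1, 2], b)) return(FALSE)
  if (naive_point_in_polygon(b[1, 1], b[1, 2], a)) return(FALSE)
  TRUE
}

# minimal trajectory data.frame from coordinates
make_traj <- function(x, y, dt = 0.05, id = 1L, intensity = 1000) {
  data.frame(trajectory_id = id, frame = seq_along(x),
             t_s = (seq_along(x) - 1) * dt, x_um = x, y_um = y,
             intensity = intensity, channel = "test",
             stringsAsFactors = FALSE)
}

# straight dendrite along the x axis
straight_dendrite <- function(length_um = 90, uncaging_fraction = 0.5,
                              halfwidth_um = 1) {
  simulate_dendrite(length_um, halfwidth_um = halfwidth_um, n_spines = 0,
                    uncaging_fraction = uncaging_fraction, curvature = 0)
}
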