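#' Simulate a dendrite geometry model
#'
#' Builds a dendritic-shaft geometry: a centerline polyline with cumulative
#' arc-length coordinates, a constant shaft half-width, optional spine
#' polygons attached to the shaft boundary, and the arc-length position of a
#' glutamate-uncaging (stimulation) site. All coordinates are in micrometres.
#'
#' The centerline is a planar curve of exact total arc length `length_um`,
#' generated as a discrete curve whose heading performs a Gaussian random
#' walk with standard deviation `curvature * step_um` per step; `curvature
#' = 0` gives a straight line along the x-axis. Spines are small
#' quadrilateral protrusions placed in disjoint arc-length slots on
#' alternating random sides of the shaft, so any number of requested spines
#' yields pairwise-disjoint simple polygons.
#'
#' @param length_um Total dendrite length L (um, > 0).
#' @param halfwidth_um Shaft half-width (um, > 0).
#' @param n_spines Number of spine polygons to attach (>= 0).
#' @param uncaging_fraction Position of the uncaging site as a fraction of L
#'   in `[0, 1]`; the site's arc-length coordinate is `uncaging_fraction * L`.
#' @param curvature Heading-noise scale (1/um); 0 gives a straight shaft.
#' @param spine_length_um Protrusion length of each spine (um).
#' @param spine_width_um Base width of each spine (um).
#' @param step_um Centerline discretisation step (um).
#' @param seed Optional integer seed; the geometry is reproducible given it.
#'
#' @return An object of class `dendrite_model`: a list with elements
#'   `centerline` (n x 2 matrix, um), `s` (cumulative arc length per vertex,
#'   um), `L` (total length, um), `halfwidth_um`, `spines` (list of
#'   `list(label, polygon)` with closed polygon matrices), and `uncaging_s`
#'   (arc-length coordinate of the stimulation site, um).
#' @export
#' @examples
#' d <- simulate_dendrite(90, n_spines = 0, uncaging_fraction = 0.5)
#' d$L
#' d$uncaging_s
simulate_dendrite <- function(length_um, halfwidth_um = 1, n_spines = 0,
                              uncaging_fraction = 0.5, curvature = 0,
                              spine_length_um = 1, spine_width_um = 0.6,
                              step_um = 1, seed = NULL) {
  if (!is.numeric(length_um) || length_um <= 0)
    .stopf("'length_um' must be > 0")
  if (halfwidth_um <= 0) .stopf("'halfwidth_um' must be > 0")
  if (uncaging_fraction < 0 || uncaging_fraction > 1)
    .stopf("'uncaging_fraction' must be in [0, 1]")
  if (n_spines < 0) .stopf("'n_spines' must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  n_seg <- max(2L, as.integer(ceiling(length_um / step_um)))
  ds <- length_um / n_seg
  dtheta <- if (curvature > 0) rnorm(n_seg - 1, 0, curvature * ds) else
    rep(0, n_seg - 1)
  theta <- cumsum(c(0, dtheta))
  centerline <- rbind(c(0, 0),
                      cbind(cumsum(ds * cos(theta)), cumsum(ds * sin(theta))))
  colnames(centerline) <- c("x", "y")
  s <- c(0, cumsum(sqrt(rowSums(diff(centerline)^2))))
  L <- s[length(s)]

  spines <- list()
  if (n_spines > 0) {
    # one spine per arc-length slot keeps polygons pairwise disjoint
    margin <- spine_width_um
    usable <- L - 2 * margin
    if (usable <= 0 || usable / n_spines < 2 * spine_width_um)
      .stopf("dendrite too short for %d disjoint spines", n_spines)
    slot <- usable / n_spines
    for (i in seq_len(n_spines)) {
      lo <- margin + (i - 1) * slot + spine_width_um
      hi <- margin + i * slot - spine_width_um
      s0 <- runif(1, lo, max(lo, hi))
      side <- sample(c(-1, 1), 1)
      fr <- .frame_at_s(centerline, s, s0)
      base <- fr$point + side * halfwidth_um * fr$normal
      tipc <- fr$point + side * (halfwidth_um + spine_length_um) * fr$normal
      w2 <- spine_width_um / 2
      poly <- rbind(base - w2 * fr$tangent,
                    base + w2 * fr$tangent,
                    tipc + 0.35 * spine_width_um * fr$tangent,
                    tipc - 0.35 * spine_width_um * fr$tangent)
      colnames(poly) <- c("x", "y")
      spines[[i]] <- list(label = sprintf("spine_%02d", i), s = s0,
                          polygon = poly)
    }
  }

  structure(list(centerline = centerline, s = s, L = L,
                 halfwidth_um = halfwidth_um, spines = spines,
                 uncaging_s = uncaging_fraction * L),
            class = "dendrite_model")
}

#' @export
print.dendrite_model <- function(x, ...) {
  cat(sprintf(
    "dendrite_model: L = %.2f um, halfwidth = %.2f um, %d spines, uncaging at s = %.2f um\n",
    x$L, x$halfwidth_um, length(x$spines), x$uncaging_s))
  invisible(x)
}

# interpolated point, tangent and left normal at arc-length s0
.frame_at_s <- function(centerline, s, s0) {
  s0 <- .clamp(s0, 0, s[length(s)])
  j <- findInterval(s0, s, rightmost.closed = TRUE)
  j <- .clamp(j, 1L, nrow(centerline) - 1L)
  a <- centerline[j, ]
  b <- centerline[j + 1L, ]
  seg <- s[j + 1L] - s[j]
  t <- if (seg > 0) (s0 - s[j]) / seg else 0
  tangent <- (b - a) / sqrt(sum((b - a)^2))
  list(point = a + t * (b - a), tangent = tangent,
       normal = c(-tangent[2], tangent[1]), segment = j)
}

# fast single-point projection with a segment hint: search a window of
# segments around the hint and widen to a full scan only if the optimum
# sits on the window edge (used by the per-step simulation loop)
.project_point <- function(cl, sv, p, hint = 1L, halo = 6L) {
  n_seg <- nrow(cl) - 1L
  lo <- max(1L, hint - halo)
  hi <- min(n_seg, hint + halo)
  repeat {
    idx <- lo:hi
    ax <- cl[idx, 1]; ay <- cl[idx, 2]
    bx <- cl[idx + 1L, 1]; by <- cl[idx + 1L, 2]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    t <- .clamp(((p[1] - ax) * abx + (p[2] - ay) * aby) / len2, 0, 1)
    dx <- p[1] - ax - t * abx; dy <- p[2] - ay - t * aby
    d2 <- dx^2 + dy^2
    k <- which.min(d2)
    at_edge <- (k == 1L && lo > 1L) || (k == length(idx) && hi < n_seg)
    if (!at_edge || (lo == 1L && hi == n_seg)) {
      j <- idx[k]
      cross <- abx[k] * (p[2] - ay[k]) - aby[k] * (p[1] - ax[k])
      return(list(s = sv[j] + t[k] * (sv[j + 1L] - sv[j]),
                  d = sqrt(d2[k]),
                  d_signed = sign(cross) * sqrt(d2[k]), seg = j))
    }
    lo <- 1L; hi <- n_seg
  }
}

#' Project points onto the dendrite centerline
#'
#' Orthogonal projection of 2D points onto the centerline polyline. For each
#' point the closest point over all segments is found; the result is the
#' arc-length coordinate `s` of that closest point, the unsigned Euclidean
#' distance `d` to it, and the signed lateral offset `d_signed` (positive on
#' the left of the travel direction). Ties between segments are broken in
#' favour of the smaller `s`.
#'
#' @param points Numeric n x 2 matrix (or length-2 vector) of positions (um).
#' @param dendrite A [simulate_dendrite()] model.
#' @return A data.frame with columns `s`, `d`, `d_signed` (all um).
#' @export
project_to_path <- function(points, dendrite) {
  stopifnot(inherits(dendrite, "dendrite_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  cl <- dendrite$centerline
  sv <- dendrite$s
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  best_sign <- numeric(n)
  for (j in seq_len(nrow(cl) - 1L)) {
    a <- cl[j, ]; b <- cl[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    px <- points[, 1] - a[1]; py <- points[, 2] - a[2]
    t <- .clamp((px * ab[1] + py * ab[2]) / len2, 0, 1)
    dx <- px - t * ab[1]; dy <- py - t * ab[2]
    d2 <- dx * dx + dy * dy
    s_here <- sv[j] + t * (sv[j + 1L] - sv[j])
    # strict improvement, or equal distance with smaller s
    upd <- d2 < best_d2 - 1e-15 |
      (abs(d2 - best_d2) <= 1e-15 & s_here < best_s)
    if (any(upd)) {
      cross <- ab[1] * py - ab[2] * px  # >0 left of segment direction
      best_d2[upd] <- d2[upd]
      best_s[upd] <- s_here[upd]
      best_sign[upd] <- sign(cross[upd])
    }
  }
  d <- sqrt(best_d2)
  data.frame(s = best_s, d = d, d_signed = best_sign * d)
}

#' Assign an arc-length position to a proximity zone
#'
#' The dendrite is divided into three equal-length zones by proximity to the
#' uncaging site: with `u` the uncaging coordinate and `delta = |s - u|`,
#' zone 1 is `delta <= L/6`, zone 2 is `L/6 < delta <= L/3` and zone 3 the
#' remainder. For a 90 um dendrite, zone 1 is the 30 um of shaft flanking
#' the uncaging site, zone 2 the two adjacent 15 um stretches, and zone 3
#' the rest.
#'
#' @param s Arc-length coordinate(s), um, in `[0, L]`.
#' @param dendrite A [simulate_dendrite()] model.
#' @return Integer vector of zones in `{1, 2, 3}`.
#' @export
assign_zone <- function(s, dendrite) {
  stopifnot(inherits(dendrite, "dendrite_model"))
  if (any(s < -1e-9 | s > dendrite$L + 1e-9))
    .stopf("'s' outside [0, L]")
  delta <- abs(s - dendrite$uncaging_s)
  ifelse(delta <= dendrite$L / 6, 1L,
         ifelse(delta <= dendrite$L / 3, 2L, 3L))
}

#' Assign an arc-length position to the stimulated (IN) or distal (OUT) region
#'
#' The IN region is the stretch of shaft flanking the uncaging site where
#' stimulation-induced actin polymerisation is expected: `|s - uncaging_s|
#' <= region_halfwidth_um` (boundary inclusive). The default half-width of
#' 15 um gives the 30 um total region used throughout the analyses.
#'
#' @param s Arc-length coordinate(s), um.
#' @param dendrite A [simulate_dendrite()] model.
#' @param region_halfwidth_um Region half-width (um, default 15).
#' @return Character vector `"IN"`/`"OUT"`.
#' @export
assign_region <- function(s, dendrite, region_halfwidth_um = 15) {
  stopifnot(inherits(dendrite, "dendrite_model"))
  ifelse(abs(s - dendrite$uncaging_s) <= region_halfwidth_um, "IN", "OUT")
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' @param points n x 2 matrix of points.
#' @param polygon m x 2 matrix of polygon vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(points, polygon) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  poly <- as.matrix(polygon)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, points)
  # include points on (or numerically at) the boundary
  on_edge <- rep(FALSE, nrow(points))
  for (j in seq_len(nrow(bnd) - 1L)) {
    a <- bnd[j, ]; b <- bnd[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- .clamp(((points[, 1] - a[1]) * ab[1] +
                 (points[, 2] - a[2]) * ab[2]) / len2, 0, 1)
    d2 <- (points[, 1] - a[1] - t * ab[1])^2 +
          (points[, 2] - a[2] - t * ab[2])^2
    on_edge <- on_edge | d2 <= 1e-18
  }
  inside | on_edge
}

#' Write / read a dendrite model as JSON
#'
#' Serialises the geometry with explicit units in the key names.
#'
#' @param dendrite A `dendrite_model`.
#' @param path Output file path.
#' @return `write_dendrite_json` returns `path` invisibly;
#'   `read_dendrite_json` returns a `dendrite_model`.
#' @export
write_dendrite_json <- function(dendrite, path) {
  stopifnot(inherits(dendrite, "dendrite_model"))
  obj <- list(
    centerline_um = unname(dendrite$centerline),
    s_um = dendrite$s,
    length_um = dendrite$L,
    shaft_halfwidth_um = dendrite$halfwidth_um,
    uncaging_s_um = dendrite$uncaging_s,
    spines = lapply(dendrite$spines, function(sp)
      list(label = sp$label, s_um = sp$s, polygon_um = unname(sp$polygon)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dendrite_json
#' @export
read_dendrite_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- as.matrix(obj$centerline_um)
  colnames(cl) <- c("x", "y")
  spines <- list()
  if (length(obj$spines)) {
    sp_list <- obj$spines
    if (is.data.frame(sp_list)) {
      sp_list <- lapply(seq_len(nrow(sp_list)), function(i) as.list(sp_list[i, ]))
    }
    spines <- lapply(sp_list, function(sp) {
      poly <- as.matrix(if (is.list(sp$polygon_um)) sp$polygon_um[[1]] else sp$polygon_um)
      colnames(poly) <- c("x", "y")
      list(label = sp$label, s = sp$s_um, polygon = poly)
    })
  }
  structure(list(centerline = cl, s = as.numeric(obj$s_um),
                 L = obj$length_um, halfwidth_um = obj$shaft_halfwidth_um,
                 spines = spines, uncaging_s = obj$uncaging_s_um),
            class = "dendrite_model")
}
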