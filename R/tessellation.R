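#' Generate a confluent-monolayer cell tessellation
#'
#' Tiles the field with a Voronoi tessellation of random seed points,
#' optionally Lloyd-relaxed so cells become rounder and more uniform, as
#' confluent endothelial monolayers are. The Delaunay triangulation is
#' enumerated exactly (all seed triples with an empty circumcircle);
#' Voronoi vertices — the circumcentres of Delaunay triangles — are the
#' ground-truth tricellular junctions. Vertices closer than `merge_radius`
#' (degenerate meetings of four or more cells) are merged into a single
#' junction whose degree counts all distinct incident cells.
#'
#' @param spec A [field_spec()].
#' @param relaxation_steps Number of Lloyd (centroid) relaxation steps.
#' @param merge_radius Vertices closer than this many px are one junction.
#' @return An object of class `cell_tessellation`: list with `seeds`
#'   (n x 2 matrix), `vertices` (a [junction_set()] with `degree`),
#'   `edges` (m x 4 matrix `x1,y1,x2,y2`, clipped to the field) and `field`.
#'   Coordinates are 0-based pixel units, x = column, y = row.
#' @export
generate_tessellation <- function(spec, relaxation_steps = 2,
                                  merge_radius = 2) {
  stopifnot(inherits(spec, "field_spec"))
  H <- spec$height_px; W <- spec$width_px; n <- spec$n_cells
  if (H * W / n < 16)
    stop("n_cells too large for field: mean cell diameter below 4 px")
  set.seed(spec$rng_seed)
  seeds <- cbind(x = runif(n, 0, W - 1), y = runif(n, 0, H - 1))
  for (step in seq_len(relaxation_steps)) {
    ns <- cpp_nearest_seed(H, W, seeds)
    lab <- as.vector(ns$labels)
    xs <- rep(seq_len(W) - 1, each = H)
    ys <- rep(seq_len(H) - 1, times = W)
    cx <- tapply(xs, lab, mean)
    cy <- tapply(ys, lab, mean)
    idx <- as.integer(names(cx))
    seeds[idx, 1] <- cx
    seeds[idx, 2] <- cy
  }
  .build_tessellation(seeds, spec, merge_radius)
}

#' Tessellation from explicit seed points
#'
#' Builds the Voronoi tessellation of user-supplied cell seed points
#' (no relaxation), with the same vertex-merging rule as
#' [generate_tessellation()]. Mainly useful for controlled geometries.
#'
#' @param seeds n x 2 matrix of (x, y) seed points, 0-based pixel units.
#' @param spec A [field_spec()] (its `n_cells` and `rng_seed` are ignored).
#' @param merge_radius Vertices closer than this many px are one junction.
#' @return A `cell_tessellation`.
#' @export
tessellation_from_points <- function(seeds, spec, merge_radius = 2) {
  seeds <- as.matrix(seeds)
  stopifnot(ncol(seeds) == 2, nrow(seeds) >= 3)
  colnames(seeds) <- c("x", "y")
  .build_tessellation(seeds, spec, merge_radius)
}

.build_tessellation <- function(seeds, spec, merge_radius) {
  H <- spec$height_px; W <- spec$width_px
  dl <- cpp_delaunay(seeds)
  tri <- dl$triangles
  cc <- dl$circumcentres
  verts <- .merge_vertices(cc, tri, merge_radius)
  inside <- verts$x >= 0 & verts$x <= W - 1 & verts$y >= 0 & verts$y <= H - 1
  verts <- verts[inside, , drop = FALSE]
  rownames(verts) <- NULL
  edges <- .voronoi_edges(seeds, tri, cc, W, H)
  structure(list(seeds = seeds,
                 vertices = junction_set(verts$x, verts$y,
                                         degree = verts$degree),
                 edges = edges, triangles = tri, field = spec),
            class = "cell_tessellation")
}

# Single-linkage merge of circumcentres within `radius`; degree = number of
# distinct seed indices over the merged triangles.
.merge_vertices <- function(cc, tri, radius) {
  m <- nrow(cc)
  if (m == 0)
    return(data.frame(x = numeric(), y = numeric(), degree = integer()))
  grp <- if (m == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(cc), method = "single"),
                  h = radius)
  out <- lapply(split(seq_len(m), grp), function(ix) {
    data.frame(x = mean(cc[ix, 1]), y = mean(cc[ix, 2]),
               degree = length(unique(as.vector(tri[ix, , drop = FALSE]))))
  })
  do.call(rbind, out)
}

# Voronoi edges from Delaunay adjacency: interior Delaunay edges give the
# segment between the two adjacent circumcentres; hull edges give a ray
# from the circumcentre away from the opposite seed, clipped to the field.
.voronoi_edges <- function(seeds, tri, cc, W, H) {
  if (nrow(tri) == 0) return(matrix(numeric(), 0, 4))
  ek <- function(i, j) paste(pmin(i, j), pmax(i, j))
  all_e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  all_t <- rep(seq_len(nrow(tri)), 3)
  keys <- ek(all_e[, 1], all_e[, 2])
  segs <- list()
  for (k in unique(keys)) {
    ts <- all_t[keys == k]
    ij <- as.integer(strsplit(k, " ")[[1]])
    if (length(ts) >= 2) {
      s <- c(cc[ts[1], ], cc[ts[2], ])
    } else {
      # hull edge: ray from the circumcentre through the edge midpoint,
      # pointing away from the triangle's third seed
      t1 <- ts[1]
      third <- setdiff(tri[t1, ], ij)
      mid <- (seeds[ij[1], ] + seeds[ij[2], ]) / 2
      dir <- mid - seeds[third[1], ]
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) next
      dir <- dir / nd
      far <- cc[t1, ] + dir * (W + H)
      s <- c(cc[t1, ], far)
    }
    s <- .clip_segment(s, W, H)
    if (!is.null(s)) segs[[length(segs) + 1]] <- s
  }
  if (length(segs) == 0) return(matrix(numeric(), 0, 4))
  out <- do.call(rbind, segs)
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

# Liang-Barsky clipping of segment c(x1,y1,x2,y2) to [0,W-1] x [0,H-1].
.clip_segment <- function(s, W, H) {
  x1 <- s[1]; y1 <- s[2]; x2 <- s[3]; y2 <- s[4]
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - 0, (W - 1) - x1, y1 - 0, (H - 1) - y1)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 > t1) return(NULL)
  out <- c(x1 + t0 * dx, y1 + t0 * dy, x1 + t1 * dx, y1 + t1 * dy)
  if (sqrt((out[3] - out[1])^2 + (out[4] - out[2])^2) < 1e-9) return(NULL)
  out
}

#' @export
print.cell_tessellation <- function(x, ...) {
  cat(sprintf(
    "<cell_tessellation> %d cells, %d tricellular junctions, %d edges (%d x %d px)\n",
    nrow(x$seeds), nrow(x$vertices), nrow(x$edges),
    x$field$width_px, x$field$height_px))
  invisible(x)
}
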