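#' Deterministic geometric tricellular-junction detector
#'
#' Model-free detector used as an oracle against the trained segmenter and
#' as the fast path for clean images: threshold the border channel,
#' thin the border network to a 1-px skeleton (Zhang-Suen), report skeleton
#' pixels where at least three branches meet (crossing number >= 3), and
#' merge detections within `merge_radius` px into single centroids.
#'
#' @param border_image Numeric matrix, border ridges brighter than
#'   cell interiors.
#' @param threshold Binarisation threshold; `NULL` picks Otsu's threshold
#'   on the intensity histogram (256 bins).
#' @param merge_radius Branch points within this distance are one junction.
#' @details The image is first brought into a canonical orientation (the
#'   lexicographically smallest of its four 90-degree rotations) and
#'   detections are mapped back, so the detector commutes exactly with
#'   90-degree image rotations even though morphological thinning on its
#'   own does not.
#' @return A [junction_set()]; empty for a blank image.
#' @export
geometric_detector <- function(border_image, threshold = NULL,
                               merge_radius = 3) {
  can <- .canonical_rotation(border_image)
  det <- .detect_branch_junctions(can$img, threshold, merge_radius)
  .unrotate_junctions(det, can$k, dim(can$img))
}

# lexicographically smallest of the four 90-degree rotations
.canonical_rotation <- function(img) {
  cand <- list(img)
  for (k in 1:3) cand[[k + 1]] <- .rot90(cand[[k]])
  best <- 1
  for (k in 2:4) {
    a <- as.vector(cand[[k]]); b <- as.vector(cand[[best]])
    i <- which(a != b)[1]
    if (!is.na(i) && a[i] < b[i]) best <- k
  }
  list(img = cand[[best]], k = best - 1L)
}

# invert k applications of .rot90 ((x, y) -> (H-1-y, x)) on point sets
.unrotate_junctions <- function(jn, k, dims) {
  h <- dims[1]; w <- dims[2]
  x <- jn$x; y <- jn$y
  for (i in seq_len(k)) {
    tmp <- y
    y <- w - 1 - x
    x <- tmp
    t2 <- h; h <- w; w <- t2
  }
  junction_set(x, y)
}

.detect_branch_junctions <- function(border_image, threshold, merge_radius) {
  rng <- range(border_image)
  if (diff(rng) < 1e-6) return(junction_set())
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(border_image), range = rng)
  fg <- border_image > threshold
  if (!any(fg)) return(junction_set())
  sk <- cpp_thin(fg)
  bp <- .branch_points(sk)
  if (nrow(bp) == 0) return(junction_set())
  grp <- if (nrow(bp) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(bp), method = "single"),
                  h = merge_radius)
  cx <- as.numeric(tapply(bp[, 1], grp, mean))
  cy <- as.numeric(tapply(bp[, 2], grp, mean))
  keep <- vapply(seq_along(cx), function(i)
    .n_skeleton_arcs(sk, cx[i], cy[i]) >= 3, logical(1))
  junction_set(cx[keep], cy[keep])
}

# number of distinct skeleton branches around (cx, cy): connected arcs of
# skeleton pixels in the annulus 4-6 px from the candidate. A true
# junction has >= 3 emanating borders; thinning zigzag artifacts on a
# single border have only 2.
.n_skeleton_arcs <- function(sk, cx, cy, r_in = 4, r_out = 6) {
  H <- nrow(sk); W <- ncol(sk)
  rs <- max(0, floor(cy - r_out)):min(H - 1, ceiling(cy + r_out))
  cs <- max(0, floor(cx - r_out)):min(W - 1, ceiling(cx + r_out))
  sub <- sk[rs + 1, cs + 1, drop = FALSE]
  d <- sqrt(outer((rs - cy)^2, (cs - cx)^2, "+"))
  ann <- which(sub & d >= r_in & d <= r_out, arr.ind = TRUE)
  if (nrow(ann) == 0) return(0L)
  if (nrow(ann) == 1) return(1L)
  grp <- stats::cutree(stats::hclust(stats::dist(ann), method = "single"),
                       h = 1.6)
  length(unique(grp))
}

# skeleton pixels whose 8-neighbour ring has >= 3 background-to-foreground
# transitions (crossing number), i.e. >= 3 incident branches
.branch_points <- function(sk) {
  H <- nrow(sk); W <- ncol(sk)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- sk
  # ring neighbours clockwise from north
  off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  idx <- which(pad, arr.ind = TRUE)
  ring <- sapply(off, function(o) pad[cbind(idx[, 1] + o[1], idx[, 2] + o[2])])
  if (is.null(dim(ring))) ring <- matrix(ring, nrow = 1)
  nxt <- ring[, c(2:8, 1), drop = FALSE]
  crossings <- rowSums(!ring & nxt)
  sel <- crossings >= 3
  # back to 0-based x (col), y (row)
  cbind(x = idx[sel, 2] - 2, y = idx[sel, 1] - 2)
}

#' Greedy matching of detected junctions against ground truth
#'
#' Greedy nearest-pair matching within `radius` px: candidate pairs are
#' sorted by distance and accepted while both members are unmatched, so
#' each ground-truth junction is matched at most once. Returns precision,
#' recall and F1.
#'
#' @param detected,truth [junction_set()]s (or data frames with `x`, `y`).
#' @param radius Matching radius in px.
#' @return List: `n_matched`, `precision`, `recall`, `f1`, `pairs`
#'   (matrix of detected/truth index pairs).
#' @export
match_junctions <- function(detected, truth, radius = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(n_matched = 0L,
                precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                f1 = 0, pairs = matrix(integer(), 0, 2)))
  d <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  cand <- which(d <= radius^2, arr.ind = TRUE)
  ord <- order(d[cand])
  used_d <- logical(nd); used_t <- logical(nt)
  pairs <- matrix(integer(), 0, 2)
  for (i in ord) {
    di <- cand[i, 1]; ti <- cand[i, 2]
    if (used_d[di] || used_t[ti]) next
    used_d[di] <- TRUE; used_t[ti] <- TRUE
    pairs <- rbind(pairs, c(di, ti))
  }
  m <- nrow(pairs)
  precision <- m / nd; recall <- m / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(n_matched = m, precision = precision, recall = recall, f1 = f1,
       pairs = pairs)
}

#' Binarise a probability map and split merged junctions by watershed
#'
#' Thresholds the per-pixel junction probability map, splits contiguous
#' foreground blobs that contain two junctions by the watershed transform
#' on the negated distance transform of the foreground, takes each
#' region's centroid, and emits the uniform-size binary map (a disk of
#' `junction_radius_px` at every centroid) used for downstream display and
#' association.
#'
#' @param prob_map Numeric matrix in \[0, 1\].
#' @param prob_threshold Foreground threshold in (0, 1).
#' @param junction_radius_px Radius of the uniform output disks.
#' @param merge_radius Centroids closer than this are merged.
#' @param tolerance Watershed depth tolerance (in distance-map units)
#'   below which adjacent catchment basins are fused.
#' @return List: `junctions` (a [junction_set()]) and `binary_map`.
#' @export
binarize_and_split <- function(prob_map, prob_threshold = 0.5,
                               junction_radius_px = 3, merge_radius = 3,
                               tolerance = 0.5) {
  stopifnot(prob_threshold > 0, prob_threshold < 1)
  fg <- prob_map > prob_threshold
  H <- nrow(prob_map); W <- ncol(prob_map)
  if (!any(fg))
    return(list(junctions = junction_set(), binary_map = matrix(0L, H, W)))
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
  labs <- sort(unique(as.vector(ws[ws > 0])))
  cx <- tapply(rep(seq_len(W) - 1, each = H)[ws > 0], ws[ws > 0], mean)
  cy <- tapply(rep(seq_len(H) - 1, times = W)[ws > 0], ws[ws > 0], mean)
  pts <- cbind(as.numeric(cx), as.numeric(cy))
  grp <- if (nrow(pts) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                  h = merge_radius)
  jx <- tapply(pts[, 1], grp, mean)
  jy <- tapply(pts[, 2], grp, mean)
  jn <- junction_set(as.numeric(jx), as.numeric(jy))
  bmap <- .disk_mask(jn, junction_radius_px, H, W)
  list(junctions = jn, binary_map = bmap)
}
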