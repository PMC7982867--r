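#' Detect fiducial spheres in a CT volume
#'
#' The tracked reference body carries bright spheres that are segmented by
#' thresholding, grouped into 26-connected components, filtered by a
#' minimum size, and localised by intensity-weighted centroids (sub-voxel
#' accuracy even at 2 mm resolution). Centres are returned in a canonical
#' lexicographic order on (x, y, z) so that tracked positions supplied in
#' the same order correspond pairwise.
#'
#' @param ct a [volume3d()] CT volume.
#' @param threshold intensity threshold; must sit above bone and soft
#'   tissue but below the sphere intensity.
#' @param expected_n number of spheres expected (4 in the study frame).
#' @param min_voxels minimum component size; the default rejects anything
#'   smaller than a sphere of half the given radius.
#' @param radius_mm nominal sphere radius used for the size filter.
#' @return A `fiducial_detection`: `centers_ct` (n x 3 mm, lexicographic),
#'   `voxel_counts`, `threshold_used`.
#' @export
detect_fiducials <- function(ct, threshold, expected_n = 4L,
                             radius_mm = 5.5, min_voxels = NULL) {
  mask <- ct$data > threshold
  if (is.null(min_voxels)) {
    min_voxels <- max(1, floor((4 / 3) * pi * (radius_mm / 2)^3 / prod(ct$spacing)))
  }
  lab <- connected_components_26(mask)
  ncomp <- max(lab)
  if (ncomp == 0) stop("detect_fiducials: 0 components found above threshold")
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- which(sizes >= min_voxels)
  if (length(keep) != expected_n) {
    stop(sprintf("detect_fiducials: expected %d fiducials, found %d components",
                 expected_n, length(keep)))
  }
  centers <- matrix(NA_real_, length(keep), 3)
  counts <- integer(length(keep))
  d <- dim(ct$data)
  for (m in seq_along(keep)) {
    idx <- which(lab == keep[m])
    counts[m] <- length(idx)
    ai <- arrayInd(idx, d)
    w <- ct$data[idx]
    w <- w / sum(w)
    centers[m, ] <- colSums(index_to_world(ct, ai) * w)
  }
  ord <- canonical_fiducial_order(centers)
  structure(list(centers_ct = point_set(centers[ord, , drop = FALSE], frame = "CT"),
                 voxel_counts = counts[ord],
                 threshold_used = threshold),
            class = "fiducial_detection")
}

#' Canonical fiducial ordering
#'
#' Lexicographic on (x, y, z) with coordinates rounded to 1 mm, so that
#' sub-voxel localisation noise cannot flip the order of spheres whose
#' nominal coordinates coincide on an axis (sphere separations are tens of
#' mm). Tracked positions must be supplied in the same canonical order.
#'
#' @param centers n x 3 matrix.
#' @return integer permutation.
#' @export
canonical_fiducial_order <- function(centers) {
  r <- round(centers)
  order(r[, 1], r[, 2], r[, 3])
}

#' Ground-truth alignment from paired fiducial positions
#'
#' Pairs the CT-detected sphere centres with their tracked positions (same
#' canonical order) and fits the rigid reference-to-CT transform by
#' least-squares landmark registration; this transform is the ground truth
#' against which ultrasound-based alignments are scored.
#'
#' @param detection a `fiducial_detection` (or an n x 3 matrix of CT
#'   centres).
#' @param tracked_centers n x 3 matrix of the same spheres in the reference
#'   (tracker) space, in the same order.
#' @return A `ground_truth_alignment`: `transform` (reference -> CT) and
#'   `fre_mm`.
#' @export
ground_truth_transform <- function(detection, tracked_centers) {
  centers_ct <- if (inherits(detection, "fiducial_detection")) {
    detection$centers_ct
  } else {
    point_set(detection)
  }
  tracked_centers <- point_set(tracked_centers)
  if (nrow(tracked_centers) != nrow(centers_ct)) {
    stop("ground_truth_transform: tracked and CT centre counts differ")
  }
  fit <- fit_rigid_landmarks(tracked_centers, centers_ct)
  structure(list(transform = fit$transform, fre_mm = fit$fre_mm),
            class = "ground_truth_alignment")
}

#' Read tracked fiducial positions from CSV
#'
#' Expects columns `name,x,y,z` (mm, reference space); rows are sorted by
#' name to give a stable order.
#'
#' @param path CSV path.
#' @export
read_tracked_fiducials_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("name", "x", "y", "z") %in% names(df)))
  df <- df[order(df$name), ]
  m <- as.matrix(df[, c("x", "y", "z")])
  dimnames(m) <- NULL
  point_set(m, frame = "reference")
}
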