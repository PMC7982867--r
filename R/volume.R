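#' 3D volumes with physical geometry
#'
#' Minimal container for scalar or label volumes: a 3D array plus isotropic
#' (or per-axis) voxel spacing and the world coordinate of the centre of the
#' first voxel. Array axes map to LPS world axes (i -> x left, j -> y
#' posterior, k -> z superior); voxel `[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric or integer array.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param origin world position (mm) of the centre of voxel `[1, 1, 1]`.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("volume3d: spacing must be positive")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = "/"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @rdname volume3d
#' @export
vol_dim <- function(vol) dim(vol$data)

#' World <-> continuous voxel index conversion
#'
#' `world_to_index` returns 1-based continuous indices (1 = centre of the
#' first voxel); `index_to_world` is its inverse.
#'
#' @param vol a [volume3d()].
#' @param pts n x 3 matrix of world points (mm) or of continuous indices.
#' @export
world_to_index <- function(vol, pts) {
  pts <- point_set(pts)
  sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, "/") + 1
}

#' @rdname world_to_index
#' @export
index_to_world <- function(vol, pts) {
  pts <- point_set(pts)
  sweep(sweep(pts - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Nearest-voxel lookup of volume values at world points
#'
#' Points outside the volume return `outside`.
#'
#' @param vol a [volume3d()].
#' @param pts n x 3 world points (mm).
#' @param outside value returned for out-of-volume points.
#' @export
vol_value_at <- function(vol, pts, outside = 0) {
  idx <- round(world_to_index(vol, pts))
  d <- dim(vol$data)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(idx))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- vol$data[lin]
  }
  out
}

#' Trilinear interpolation at world points
#'
#' @inheritParams vol_value_at
#' @param rule for points outside the grid: `"error"` or `"constant"`
#'   (returns `outside`).
#' @export
vol_interp <- function(vol, pts, rule = c("error", "constant"), outside = 0) {
  rule <- match.arg(rule)
  idx <- world_to_index(vol, pts)
  d <- dim(vol$data)
  eps <- 1e-9
  inside <- idx[, 1] >= 1 - eps & idx[, 1] <= d[1] + eps &
            idx[, 2] >= 1 - eps & idx[, 2] <= d[2] + eps &
            idx[, 3] >= 1 - eps & idx[, 3] <= d[3] + eps
  if (rule == "error" && !all(inside)) {
    stop("vol_interp: sample point outside volume extent")
  }
  out <- rep(outside, nrow(idx))
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 1), d[1])
  p[, 2] <- pmin(pmax(p[, 2], 1), d[2])
  p[, 3] <- pmin(pmax(p[, 3], 1), d[3])
  i0 <- pmin(floor(p[, 1]), d[1] - 1); i0 <- pmax(i0, 1)
  j0 <- pmin(floor(p[, 2]), d[2] - 1); j0 <- pmax(j0, 1)
  k0 <- pmin(floor(p[, 3]), d[3] - 1); k0 <- pmax(k0, 1)
  if (d[1] == 1) i0 <- rep(1, nrow(p))
  if (d[2] == 1) j0 <- rep(1, nrow(p))
  if (d[3] == 1) k0 <- rep(1, nrow(p))
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  at <- function(i, j, k) vol$data[(k - 1) * d[1] * d[2] + (j - 1) * d[1] + i]
  v <- at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
       at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
       at(i1, j1, k0) * fx       * fy       * (1 - fz) +
       at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
       at(i1, j0, k1) * fx       * (1 - fy) * fz +
       at(i0, j1, k1) * (1 - fx) * fy       * fz +
       at(i1, j1, k1) * fx       * fy       * fz
  out[inside] <- v
  out
}

#' Resample a volume onto an isotropic grid
#'
#' Covers the same physical extent with linear (scalar volumes) or
#' nearest-neighbour (labelmaps) interpolation.
#'
#' @param vol a [volume3d()].
#' @param spacing_mm target isotropic spacing; must be positive.
#' @param method `"linear"` or `"nearest"`.
#' @export
vol_resample <- function(vol, spacing_mm, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0) {
    stop("vol_resample: spacing must be a positive scalar")
  }
  if (all(abs(vol$spacing - spacing_mm) < 1e-12)) return(vol)
  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(2L, as.integer(floor(extent / spacing_mm)) + 1L)
  xs <- vol$origin[1] + (seq_len(nd[1]) - 1) * spacing_mm
  ys <- vol$origin[2] + (seq_len(nd[2]) - 1) * spacing_mm
  zs <- vol$origin[3] + (seq_len(nd[3]) - 1) * spacing_mm
  pts <- cbind(rep(xs, times = nd[2] * nd[3]),
               rep(rep(ys, each = nd[1]), times = nd[3]),
               rep(zs, each = nd[1] * nd[2]))
  vals <- if (method == "linear") {
    vol_interp(vol, pts, rule = "constant", outside = 0)
  } else {
    vol_value_at(vol, pts, outside = 0)
  }
  out <- array(vals, dim = nd)
  if (method == "nearest") storage.mode(out) <- storage.mode(vol$data)
  volume3d(out, spacing = spacing_mm, origin = vol$origin)
}

#' 26-connected components of a logical mask
#'
#' Breadth-first labelling of a 3D logical array with 26-connectivity.
#' Returns an integer array of the same shape (0 = background, components
#' numbered from 1 in discovery order).
#'
#' @param mask 3D logical array.
#' @export
connected_components_26 <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  nxy <- d[1] * d[2]
  # 26-neighbour linear-index offsets, with explicit boundary guards below
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  in_mask <- array(FALSE, dim = d); in_mask[fg] <- TRUE
  comp <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    comp <- comp + 1L
    queue <- seed
    lab[seed] <- comp
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      k <- (cur - 1L) %/% nxy + 1L
      j <- ((cur - 1L) %% nxy) %/% d[1] + 1L
      i <- (cur - 1L) %% d[1] + 1L
      for (r in seq_len(nrow(off))) {
        ii <- i + off$di[r]; jj <- j + off$dj[r]; kk <- k + off$dk[r]
        ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
        if (!any(ok)) next
        lin <- (kk[ok] - 1L) * nxy + (jj[ok] - 1L) * d[1] + ii[ok]
        lin <- lin[in_mask[lin] & lab[lin] == 0L]
        if (length(lin) > 0) {
          lin <- unique(lin)
          lab[lin] <- comp
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

#' Write a volume to NIfTI (requires the RNifti package)
#'
#' Convenience exporter for external inspection; geometry metadata (spacing,
#' origin) is written into the NIfTI header with an LPS-consistent affine.
#'
#' @param vol a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_volume_nifti: the RNifti package is required")
  }
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
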