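#' Extract bone-surface points from one ultrasound frame
#'
#' Per image column, the deepest local intensity maximum above
#' `echo_threshold` is taken as the candidate bone echo; it is kept only if
#' the mean intensity deeper than it stays below `shadow_ratio` times the
#' peak (shadow confirmation). The peak position is refined to sub-pixel
#' accuracy by a parabolic fit through the peak and its neighbours.
#'
#' @param frame a `tracked_frame`.
#' @param echo_threshold peak acceptance threshold in (0, 1).
#' @param shadow_ratio shadow confirmation ratio in (0, 1).
#' @param pixel_spacing_mm pixel size; taken from the frame's config when
#'   attached, otherwise required.
#' @return data.frame with `column`, `row` (sub-pixel), `u_mm`, `v_mm`
#'   (image-plane mm) and `intensity`; zero rows when nothing qualifies.
#' @export
extract_bone_points_frame <- function(frame, echo_threshold = 0.45,
                                      shadow_ratio = 0.5,
                                      pixel_spacing_mm = NULL) {
  if (echo_threshold <= 0 || echo_threshold >= 1 ||
      shadow_ratio <= 0 || shadow_ratio >= 1) {
    stop("extract_bone_points_frame: thresholds must lie in (0, 1)")
  }
  img <- frame$image
  nr <- nrow(img); nc <- ncol(img)
  ps <- pixel_spacing_mm
  if (is.null(ps)) stop("extract_bone_points_frame: pixel_spacing_mm is required")
  out <- vector("list", nc)
  for (cc in seq_len(nc)) {
    v <- img[, cc]
    is_peak <- v > echo_threshold
    if (nr >= 3) {
      interior <- 2:(nr - 1)
      is_peak[interior] <- is_peak[interior] & v[interior] >= v[interior - 1] &
        v[interior] >= v[interior + 1]
      is_peak[1] <- is_peak[1] & v[1] >= v[2]
      is_peak[nr] <- is_peak[nr] & v[nr] >= v[nr - 1]
    }
    peaks <- which(is_peak)
    if (length(peaks) == 0) next
    r0 <- peaks[length(peaks)]                   # deepest-side echo
    below <- v[seq_len(nr) > r0 + 2]
    # a peak at the image bottom cannot be shadow-confirmed; reject it
    if (length(below) < 3) next
    if (mean(below) >= shadow_ratio * v[r0]) next
    r_sub <- r0
    if (r0 > 1 && r0 < nr) {
      den <- v[r0 - 1] - 2 * v[r0] + v[r0 + 1]
      if (den < 0) r_sub <- r0 + 0.5 * (v[r0 - 1] - v[r0 + 1]) / den
    }
    out[[cc]] <- data.frame(column = cc, row = r_sub,
                            u_mm = (cc - (nc + 1) / 2) * ps,
                            v_mm = (r_sub - 1) * ps,
                            intensity = v[r0])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(column = integer(0), row = numeric(0), u_mm = numeric(0),
                      v_mm = numeric(0), intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Build a reference-space bone point cloud from a sweep
#'
#' Extracts bone-surface points from every frame and maps them to the
#' reference space through the frame poses, keeping per-point provenance
#' (frame and column index, echo intensity).
#'
#' @param sweep a `tracked_sweep`.
#' @inheritParams extract_bone_points_frame
#' @return a `bone_cloud`: `points` (n x 3 reference mm), `frame_index`,
#'   `column_index`, `intensity`, `flagged_empty`.
#' @export
sweep_to_cloud <- function(sweep, echo_threshold = 0.45, shadow_ratio = 0.5) {
  if (length(sweep$frames) == 0) stop("sweep_to_cloud: empty sweep")
  ps <- sweep$config$pixel_spacing_mm
  pts <- list(); fi <- list(); ci <- list(); ii <- list()
  for (f in seq_along(sweep$frames)) {
    frame <- sweep$frames[[f]]
    bp <- extract_bone_points_frame(frame, echo_threshold, shadow_ratio,
                                    pixel_spacing_mm = ps)
    if (nrow(bp) == 0) next
    pts[[length(pts) + 1]] <- apply_transform(frame$pose, cbind(bp$u_mm, bp$v_mm, 0))
    fi[[length(fi) + 1]] <- rep(f, nrow(bp))
    ci[[length(ci) + 1]] <- bp$column
    ii[[length(ii) + 1]] <- bp$intensity
  }
  if (length(pts) == 0) {
    return(structure(list(points = point_set(matrix(numeric(0), 0, 3), frame = "reference"),
                          frame_index = integer(0), column_index = integer(0),
                          intensity = numeric(0), flagged_empty = TRUE),
                     class = "bone_cloud"))
  }
  structure(list(points = point_set(do.call(rbind, pts), frame = "reference"),
                 frame_index = unlist(fi), column_index = unlist(ci),
                 intensity = unlist(ii), flagged_empty = FALSE),
            class = "bone_cloud")
}

#' Extract the posterior CT vertebral surface
#'
#' For each posterior-to-anterior voxel column of the labelmap, the first
#' voxel carrying one of the requested level's labels is emitted as a
#' surface point (voxel centre, mm). With `include_neighbors` the adjacent
#' levels contribute their own first-hit voxels too, which lets a
#' registration lock onto the wrong level the way a real system can.
#'
#' @param labelmap a [volume3d()] labelmap (codes `level * 10 + region`).
#' @param level vertebral level index.
#' @param include_neighbors include levels `level +/- 1`.
#' @param stride keep every `stride`-th surface point (deterministic
#'   thinning for speed).
#' @return a `ct_surface`: `points` (n x 3 CT mm), `label`, `level_of`.
#' @export
extract_ct_surface <- function(labelmap, level, include_neighbors = FALSE,
                               stride = 1L) {
  codes_lv <- function(lv) lv * 10L + unname(REGIONS)
  levels_wanted <- level
  if (include_neighbors) {
    levels_wanted <- c(level - 1L, level, level + 1L)
  }
  lab <- labelmap$data
  present <- unique(label_level(lab[lab > 0L]))
  if (!level %in% present) stop("extract_ct_surface: level absent from labelmap")
  levels_wanted <- intersect(levels_wanted, present)
  d <- dim(lab)
  mask <- array(lab %in% unlist(lapply(levels_wanted, codes_lv)), dim = d)
  # first labelled voxel scanning posterior (large y/j) to anterior, per (i,k)
  m <- matrix(aperm(mask, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  any_hit <- rowSums(m) > 0
  jstar <- max.col(m * rep(seq_len(d[2]), each = nrow(m)), ties.method = "first")
  rows <- which(any_hit)
  i <- (rows - 1L) %% d[1] + 1L
  k <- (rows - 1L) %/% d[1] + 1L
  if (stride > 1L) {
    # dithered thinning: a raster-order stride would alias along x and bias
    # the thinned surface's centroid
    keep <- ((i + 3L * k) %% stride) == 0L
    rows <- rows[keep]; i <- i[keep]; k <- k[keep]
  }
  j <- jstar[rows]
  pts <- index_to_world(labelmap, cbind(i, j, k))
  lin <- (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
  lbl <- lab[lin]
  structure(list(points = point_set(pts, frame = "CT"),
                 label = lbl, level_of = label_level(lbl)),
            class = "ct_surface")
}

#' Initialization of the US-to-CT alignment from the sweep convention
#'
#' The acquisition protocol is a linear caudo-cranial scan with the beam
#' pointing antero-posteriorly; this prior fixes the initial orientation:
#' the sweep travel direction is aligned with the CT +z axis and the mean
#' image depth axis with the CT -y axis. The translation matches the bone
#' cloud to the level's posterior CT surface: centroids laterally and
#' axially, and the posterior extreme (spinous crest) along the beam, since
#' the probe footprint sees only the medial part of the surface and a plain
#' centroid match would bias the depth. When the cloud is empty the
#' mid-sweep half-depth point is mapped to the level's labelled-voxel
#' centroid instead.
#'
#' @param sweep a `tracked_sweep` with at least 2 frames.
#' @param phantom a `spine_phantom` (for the level geometry).
#' @param level level to initialise against.
#' @param cloud optional precomputed [sweep_to_cloud()] result.
#' @param surface optional precomputed [extract_ct_surface()] result.
#' @return initial reference-to-CT `rigid_transform`.
#' @export
initialize_from_sweep <- function(sweep, phantom, level, cloud = NULL,
                                  surface = NULL) {
  if (length(sweep$frames) < 2) {
    stop("initialize_from_sweep: at least 2 frames are required")
  }
  origins <- t(vapply(sweep$frames, function(f) unclass(f$pose)[1:3, 4], numeric(3)))
  d <- origins[nrow(origins), ] - origins[1, ]
  nd <- sqrt(sum(d^2))
  if (nd < 1e-6) stop("initialize_from_sweep: degenerate (zero-length) sweep travel")
  dhat <- d / nd
  depth_axes <- vapply(sweep$frames, function(f) unclass(f$pose)[1:3, 2], numeric(3))
  a <- rowMeans(depth_axes)
  a <- a - sum(a * dhat) * dhat
  na <- sqrt(sum(a^2))
  if (na < 1e-9) stop("initialize_from_sweep: beam direction parallel to travel")
  ahat <- a / na
  bx <- c(ahat[2] * dhat[3] - ahat[3] * dhat[2],
          ahat[3] * dhat[1] - ahat[1] * dhat[3],
          ahat[1] * dhat[2] - ahat[2] * dhat[1])
  M_ref <- cbind(bx, ahat, dhat)
  M_ct <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  R0 <- M_ct %*% t(M_ref)
  if (is.null(cloud)) cloud <- sweep_to_cloud(sweep)
  m <- diag(4)
  m[1:3, 1:3] <- R0
  if (!cloud$flagged_empty) {
    if (is.null(surface)) {
      surface <- extract_ct_surface(phantom$labelmap, level, stride = 4L)
    }
    S <- surface$points
    C <- cloud$points %*% t(R0)
    # lateral / axial: match medians (robust to points grazing a neighbour
    # level); depth: match the posterior extreme (the spinous crest), which
    # both point sets see at the same place
    match_tr <- function(C, S) {
      c(stats::median(S[, 1]) - stats::median(C[, 1]),
        stats::quantile(S[, 2], 0.99, names = FALSE) -
          stats::quantile(C[, 2], 0.99, names = FALSE),
        stats::median(S[, 3]) - stats::median(C[, 3]))
    }
    tr <- match_tr(C, S)
    # second pass: window both sets to the level's axial extent so sweep
    # overshoot beyond the level cannot bias the match
    z_mid <- stats::median(S[, 3])
    z_win <- 1.2 * stats::quantile(abs(S[, 3] - z_mid), 0.95, names = FALSE)
    C2 <- sweep(C, 2, -tr)
    C2 <- C2[abs(C2[, 3] - z_mid) <= z_win, , drop = FALSE]
    S2 <- S[abs(S[, 3] - z_mid) <= z_win, , drop = FALSE]
    if (nrow(C2) >= 10) tr <- tr + match_tr(C2, S2)
    m[1:3, 4] <- tr
  } else {
    half_depth <- sweep$config$depth_cm * 10 / 2
    mid <- colMeans(t(vapply(sweep$frames, function(f) {
      as.numeric(apply_transform(f$pose, c(0, half_depth, 0)))
    }, numeric(3))))
    m[1:3, 4] <- phantom$level_centroids[level, ] - as.numeric(R0 %*% mid)
  }
  rigid_transform(m, tol = 1e-7)
}

# exact nearest neighbours of query rows among ref rows; kd-tree when RANN
# is available, chunked brute force otherwise (ties -> lowest index)
nn_match <- function(query, ref) {
  if (requireNamespace("RANN", quietly = TRUE)) {
    res <- RANN::nn2(ref, query, k = 1)
    return(list(idx = as.integer(res$nn.idx[, 1]), dist = as.numeric(res$nn.dists[, 1])))
  }
  n <- nrow(query)
  idx <- integer(n); dst <- numeric(n)
  r2 <- rowSums(ref^2)
  chunk <- max(1L, as.integer(2e6 / nrow(ref)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), r2, "+") - 2 * q %*% t(ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(e - s + 1L), j)]))
  }
  list(idx = idx, dist = dst)
}

#' Trimmed iterative-closest-point rigid registration
#'
#' Aligns a reference-space bone point cloud to a CT posterior surface:
#' nearest-neighbour correspondences, a trimming step keeping the closest
#' fraction of pairs, and a closed-form rigid update per iteration.
#' Iterations are accepted only while the trimmed RMS does not increase, so
#' the reported RMS trace is non-increasing. This point-based scheme is a
#' documented stand-in for the production intensity-based registration of
#' the clinical system; all downstream metrics are registration-agnostic.
#'
#' @param cloud a `bone_cloud` or n x 3 matrix (reference mm).
#' @param surface a `ct_surface` or m x 3 matrix (CT mm).
#' @param init initial reference-to-CT `rigid_transform`.
#' @param max_iter iteration cap (per start).
#' @param tol_mm stop when the trimmed RMS changes by less than this.
#' @param trim fraction of closest pairs kept per iteration.
#' @param max_cloud_points deterministic subsample cap on the cloud.
#' @param restart_offset_mm magnitude of the deterministic translation
#'   offsets used for multi-start (0 disables restarts). Point-to-point ICP
#'   on sampled surfaces can settle in a shallow basin about one sample
#'   spacing away from the best alignment by sliding tangentially;
#'   restarting from four lateral/axial offsets (depth is strongly
#'   constrained by the surface heightfield) and keeping the lowest-RMS
#'   result removes that failure mode.
#' @return a `registration_result`: `transform` (reference -> CT),
#'   `iterations`, `final_rms_mm`, `converged`, `rms_trace` (all from the
#'   best start).
#' @export
icp_register <- function(cloud, surface, init = rt_identity(), max_iter = 40L,
                         tol_mm = 1e-3, trim = 0.8, max_cloud_points = 600L,
                         restart_offset_mm = 1.5) {
  pts <- if (inherits(cloud, "bone_cloud")) cloud$points else point_set(cloud)
  surf <- if (inherits(surface, "ct_surface")) surface$points else point_set(surface)
  if (nrow(pts) == 0 || nrow(surf) == 0) {
    stop("icp_register: empty cloud or surface")
  }
  if (nrow(pts) > max_cloud_points) {
    pts <- pts[round(seq(1, nrow(pts), length.out = max_cloud_points)), , drop = FALSE]
  }
  offsets <- rbind(c(0, 0, 0))
  if (restart_offset_mm > 0) {
    offsets <- rbind(offsets, restart_offset_mm * rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1)))
  }
  best <- NULL
  for (o in seq_len(nrow(offsets))) {
    start <- compose(rt_translation(offsets[o, ]), as_rigid(init))
    run <- icp_single_start(pts, surf, start, max_iter, tol_mm, trim)
    if (is.null(best) ||
        (is.finite(run$final_rms_mm) &&
         (!is.finite(best$final_rms_mm) || run$final_rms_mm < best$final_rms_mm))) {
      best <- run
    }
    if (is.finite(best$final_rms_mm) && best$final_rms_mm < tol_mm) break
  }
  best
}

icp_single_start <- function(pts, surf, init, max_iter, tol_mm, trim) {
  Tcur <- as_rigid(init)
  prev_rms <- Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  n_keep <- max(3L, floor(trim * nrow(pts)))
  while (it < max_iter) {
    it <- it + 1L
    moved <- apply_transform(Tcur, pts)
    nn <- nn_match(moved, surf)
    keep <- order(nn$dist)[seq_len(n_keep)]
    fit <- fit_rigid_landmarks(pts[keep, , drop = FALSE],
                               surf[nn$idx[keep], , drop = FALSE])
    new_res <- apply_transform(fit$transform, pts[keep, , drop = FALSE]) -
      surf[nn$idx[keep], , drop = FALSE]
    rms <- sqrt(mean(rowSums(new_res^2)))
    if (rms > prev_rms + 1e-12) {
      it <- it - 1L
      break
    }
    Tcur <- fit$transform
    trace <- c(trace, rms)
    if (is.finite(prev_rms) && abs(prev_rms - rms) < tol_mm) {
      converged <- TRUE
      prev_rms <- rms
      break
    }
    prev_rms <- rms
  }
  structure(list(transform = Tcur, iterations = it,
                 final_rms_mm = if (length(trace)) trace[length(trace)] else NA_real_,
                 converged = converged, rms_trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d iterations, RMS %.4g mm, converged: %s\n",
              x$iterations, x$final_rms_mm, x$converged))
  invisible(x)
}

#' Write a registration run record (transform + structured text)
#'
#' @param result a `registration_result`.
#' @param dir output directory.
#' @param name base name for the two files.
#' @export
write_registration_record <- function(result, dir, name = "registration") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transform(result$transform, file.path(dir, paste0(name, "_transform.txt")))
  writeLines(c(sprintf("iterations: %d", result$iterations),
               sprintf("converged: %s", result$converged),
               sprintf("final_rms_mm: %.6f", result$final_rms_mm),
               paste("rms_trace:", paste(sprintf("%.6f", result$rms_trace), collapse = " "))),
             file.path(dir, paste0(name, "_run.txt")))
  invisible(dir)
}
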