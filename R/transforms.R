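#' Rigid 4x4 homogeneous transforms
#'
#' A `rigid_transform` is a 4x4 homogeneous matrix whose rotation block is
#' orthonormal with determinant +1 and whose last row is exactly
#' `(0, 0, 0, 1)`. Translations are in millimetres. All anatomical
#' coordinates in this package follow the right-handed LPS convention
#' (+x left, +y posterior, +z superior).
#'
#' @param m 4x4 numeric matrix.
#' @param tol orthonormality tolerance for validation.
#' @return An object of class `rigid_transform` (a validated 4x4 matrix).
#' @export
rigid_transform <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L)) || !is.numeric(m)) {
    stop("rigid_transform: 'm' must be a 4x4 numeric matrix")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("rigid_transform: matrix entries must be finite")
  }
  if (any(m[4, ] != c(0, 0, 0, 1))) {
    stop("rigid_transform: last row must be exactly (0, 0, 0, 1)")
  }
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("rigid_transform: rotation block is not orthonormal within tolerance")
  }
  if (abs(det(R) - 1) > tol) {
    stop("rigid_transform: rotation block must have determinant +1 (no reflection)")
  }
  m <- unname(m)
  class(m) <- c("rigid_transform", "matrix")
  m
}

#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(m, tol = 1e-9) {
  out <- tryCatch(rigid_transform(unclass(m), tol = tol), error = function(e) NULL)
  !is.null(out)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform(diag(4))

#' Pure translation
#' @param t length-3 translation vector (mm).
#' @export
rt_translation <- function(t) {
  stopifnot(length(t) == 3, all(is.finite(t)))
  m <- diag(4)
  m[1:3, 4] <- t
  rigid_transform(m)
}

#' Rotation about an axis through a pivot point
#'
#' Builds the rigid transform rotating by `angle_deg` degrees about the line
#' through `pivot` with direction `axis` (Rodrigues formula).
#'
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param axis length-3 direction vector; must have non-zero norm.
#' @param pivot length-3 point on the rotation axis (default origin).
#' @export
rt_rotation <- function(angle_deg, axis, pivot = c(0, 0, 0)) {
  stopifnot(length(axis) == 3, length(pivot) == 3)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rt_rotation: axis must have non-zero norm")
  k <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- as.numeric(pivot - R %*% pivot)
  rigid_transform(m, tol = 1e-8)
}

#' Compose two rigid transforms
#'
#' Returns the transform mapping `x` to `a(b(x))`.
#'
#' @param a,b `rigid_transform` objects (validated if plain matrices).
#' @export
compose <- function(a, b) {
  a <- as_rigid(a); b <- as_rigid(b)
  m <- unclass(a) %*% unclass(b)
  m[4, ] <- c(0, 0, 0, 1)
  rigid_transform(m, tol = 1e-7)
}

#' Invert a rigid transform
#'
#' Closed form: the inverse rotation is the transpose and the inverse
#' translation is the negated, rotated translation.
#'
#' @param t a `rigid_transform`.
#' @export
invert <- function(t) {
  t <- as_rigid(t)
  R <- t[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t[1:3, 4]
  rigid_transform(m, tol = 1e-7)
}

as_rigid <- function(t) {
  if (inherits(t, "rigid_transform")) return(t)
  rigid_transform(t)
}

#' Ordered 3D point sets
#'
#' Points are stored as an n x 3 numeric matrix (mm); the optional `frame`
#' attribute tags the coordinate space (`"CT"`, `"reference"` or `"image"`).
#' Order is semantically meaningful: registration routines pair points by
#' position in the set.
#'
#' @param points n x 3 numeric matrix or length-3 vector.
#' @param frame optional coordinate-space tag.
#' @export
point_set <- function(points, frame = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("point_set: points must have 3 columns")
  if (anyNA(points) || any(!is.finite(points))) stop("point_set: coordinates must be finite")
  storage.mode(points) <- "double"
  if (!is.null(frame)) attr(points, "frame") <- frame
  points
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param p n x 3 point matrix (optionally a tagged [point_set()]).
#' @param expected_frame if given and `p` carries a `frame` attribute, the
#'   two must agree or an error is raised.
#' @param new_frame optional frame tag for the result.
#' @return transformed n x 3 point matrix.
#' @export
apply_transform <- function(t, p, expected_frame = NULL, new_frame = NULL) {
  t <- as_rigid(t)
  p <- point_set(p, frame = attr(p, "frame"))
  if (!is.null(expected_frame) && !is.null(attr(p, "frame")) &&
      !identical(attr(p, "frame"), expected_frame)) {
    stop(sprintf("apply_transform: point set is in frame '%s', expected '%s'",
                 attr(p, "frame"), expected_frame))
  }
  out <- p %*% t(t[1:3, 1:3])
  out <- sweep(out, 2, t[1:3, 4], "+")
  attr(out, "frame") <- new_frame
  out
}

#' Least-squares rigid landmark registration (Horn/Kabsch)
#'
#' Finds the rigid transform that maps `moving` onto `fixed` in the
#' least-squares sense, via SVD of the cross-covariance with determinant
#' correction (a reflection solution is corrected by flipping the sign of
#' the smallest singular vector). Also returns the fiducial registration
#' error (FRE) as the root-mean-square residual in mm.
#'
#' @param moving,fixed paired n x 3 point matrices, n >= 3, not collinear.
#' @return list with `transform` (a `rigid_transform`) and `fre_mm`.
#' @export
fit_rigid_landmarks <- function(moving, fixed) {
  moving <- point_set(moving); fixed <- point_set(fixed)
  if (nrow(moving) != nrow(fixed)) {
    stop("fit_rigid_landmarks: point sets must have equal cardinality")
  }
  n <- nrow(moving)
  if (n < 3) stop("fit_rigid_landmarks: at least 3 paired points are required")
  mc <- colMeans(moving); fc <- colMeans(fixed)
  Pm <- sweep(moving, 2, mc); Pf <- sweep(fixed, 2, fc)
  # collinear configurations leave the rotation about the line unconstrained
  sv_m <- svd(Pm, nu = 0, nv = 0)$d
  scale_m <- max(sv_m[1], 1e-12)
  if (sv_m[2] / scale_m < 1e-8) {
    stop("fit_rigid_landmarks: degenerate configuration (points are collinear)")
  }
  H <- crossprod(Pm, Pf)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- fc - as.numeric(R %*% mc)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- tr
  tf <- rigid_transform(m, tol = 1e-7)
  res <- apply_transform(tf, moving) - fixed
  list(transform = tf, fre_mm = sqrt(mean(rowSums(res^2))))
}

#' Perturb a rigid transform by a rotation about a pivot plus a translation
#'
#' Composes `translation ∘ rotation(angle, axis, pivot) ∘ t`; used to inject
#' controlled misalignments when studying error propagation.
#'
#' @param t base `rigid_transform`.
#' @param angle_deg rotation angle (degrees).
#' @param axis length-3 rotation axis (non-zero norm).
#' @param translation_mm length-3 translation (mm).
#' @param pivot length-3 pivot point of the rotation (mm).
#' @export
perturb_transform <- function(t, angle_deg = 0, axis = c(0, 0, 1),
                              translation_mm = c(0, 0, 0), pivot = c(0, 0, 0)) {
  t <- as_rigid(t)
  if (sqrt(sum(axis^2)) < 1e-12) stop("perturb_transform: axis must have non-zero norm")
  pert <- compose(rt_translation(translation_mm), rt_rotation(angle_deg, axis, pivot))
  compose(pert, t)
}

#' Read / write transforms as plain-text 4x4 matrices
#'
#' One row per line, numbers separated by whitespace, row-major. The reader
#' validates rigidity before returning.
#'
#' @param t a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(t, path) {
  t <- as_rigid(t)
  writeLines(apply(unclass(t), 1, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")
  }), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4) stop("read_transform: expected 4 matrix rows")
  m <- t(vapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                numeric(4), USE.NAMES = FALSE))
  rigid_transform(m, tol = 1e-6)
}
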