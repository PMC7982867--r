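#' Evaluation thresholds
#'
#' An alignment is a success when its TRE is strictly below
#' `success_threshold_mm` (the 2 mm clinical navigation threshold) and a
#' level mismatch when the TRE reaches `mismatch_threshold_mm` (10 mm);
#' everything in between is a plain failure.
#'
#' @param success_threshold_mm success boundary (strict `<`).
#' @param mismatch_threshold_mm level-mismatch boundary (`>=`).
#' @export
eval_config <- function(success_threshold_mm = 2.0, mismatch_threshold_mm = 10.0) {
  if (!(success_threshold_mm > 0 && success_threshold_mm < mismatch_threshold_mm)) {
    stop("eval_config: need 0 < success threshold < mismatch threshold")
  }
  structure(list(success_threshold_mm = success_threshold_mm,
                 mismatch_threshold_mm = mismatch_threshold_mm),
            class = "eval_config")
}

#' Target registration error between two alignments
#'
#' Root-mean-square over the landmarks of the Euclidean distance between
#' their images under the evaluated and the ground-truth transform (the
#' study convention uses 7 anatomical landmarks per vertebra).
#'
#' @param t_est,t_gt evaluated and ground-truth `rigid_transform`s
#'   (reference -> CT).
#' @param landmarks n x 3 landmark matrix, in the transforms' source space.
#' @return TRE in mm.
#' @export
compute_tre <- function(t_est, t_gt, landmarks) {
  landmarks <- point_set(landmarks)
  if (nrow(landmarks) == 0) stop("compute_tre: empty landmark set")
  d <- apply_transform(t_est, landmarks) - apply_transform(t_gt, landmarks)
  sqrt(mean(rowSums(d^2)))
}

#' Classify an alignment outcome from its TRE
#'
#' `success` iff `tre < success_threshold` (strict), `level_mismatch` iff
#' `tre >= mismatch_threshold`, otherwise `failure`. Vectorised.
#'
#' @param tre_mm non-negative TRE value(s) in mm.
#' @param config an [eval_config()].
#' @export
classify_alignment <- function(tre_mm, config = eval_config()) {
  if (any(!is.finite(tre_mm)) || any(tre_mm < 0)) {
    stop("classify_alignment: TRE must be finite and non-negative")
  }
  out <- ifelse(tre_mm < config$success_threshold_mm, "success",
                ifelse(tre_mm >= config$mismatch_threshold_mm, "level_mismatch",
                       "failure"))
  factor(out, levels = c("success", "failure", "level_mismatch"))
}

#' Success / failure / mismatch rates and TRE summaries per stratum
#'
#' Percentages are on the 0-100 scale and unrounded (round only for
#' presentation); the median and IQR use the linear-interpolation quantile
#' definition (R type 7).
#'
#' @param results data.frame with at least `tre_mm` and `classification`.
#' @param by character vector of stratification columns (empty = pooled).
#' @return data.frame with `n`, `median_tre_mm`, `iqr_tre_mm`,
#'   `pct_success`, `pct_failure`, `pct_mismatch` per stratum.
#' @export
summarize_rates <- function(results, by = character()) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("summarize_rates: empty results")
  }
  stopifnot(all(c("tre_mm", "classification") %in% names(results)))
  grouped <- if (length(by)) dplyr::group_by(results, dplyr::across(dplyr::all_of(by)))
             else results
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    median_tre_mm = stats::median(.data$tre_mm),
    iqr_tre_mm = stats::IQR(.data$tre_mm),
    pct_success = 100 * mean(.data$classification == "success"),
    pct_failure = 100 * mean(.data$classification == "failure"),
    pct_mismatch = 100 * mean(.data$classification == "level_mismatch"),
    .groups = "drop")
  as.data.frame(out)
}

#' Median-TRE propagation matrix across vertebral levels
#'
#' Cell (i, j) is the median, over acquisitions performed at level i, of
#' the TRE measured at level j; the diagonal holds each level's own
#' accuracy and the off-diagonal cells show how errors propagate.
#'
#' @param results_long data.frame with `acq_level`, `measured_level`,
#'   `tre_mm` (one row per acquisition x measured level).
#' @param levels level indices spanning the matrix (default: all levels
#'   appearing as acquisition or measurement level).
#' @return square numeric matrix over `levels`.
#' @export
propagation_matrix <- function(results_long, levels = NULL) {
  stopifnot(all(c("acq_level", "measured_level", "tre_mm") %in% names(results_long)))
  if (is.null(levels)) {
    levels <- sort(unique(c(results_long$acq_level, results_long$measured_level)))
  }
  n <- length(levels)
  m <- matrix(NA_real_, n, n, dimnames = list(paste0("acq_L", levels),
                                              paste0("meas_L", levels)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- results_long$tre_mm[results_long$acq_level == levels[i] &
                             results_long$measured_level == levels[j]]
    if (length(v) == 0) stop("propagation_matrix: missing level pair coverage")
    m[i, j] <- stats::median(v)
  }
  m
}

#' Pairwise inter-level distances from successive spinous-process gaps
#'
#' `distance(i, j)` is the sum of the gaps between levels i and j; the
#' result is symmetric with a zero diagonal. Gaps are given between
#' successive levels, caudal pair first by default (the convention of the
#' phantom config), and are re-ordered internally so rows/columns follow
#' level indices 1..n (L1 most cranial).
#'
#' @param gaps_mm positive gap vector (length n - 1).
#' @param caudal_first whether `gaps_mm[1]` is the most caudal pair.
#' @return n x n distance matrix (mm).
#' @export
cumulative_level_distances <- function(gaps_mm, caudal_first = TRUE) {
  if (any(gaps_mm <= 0)) stop("cumulative_level_distances: gaps must be positive")
  g <- if (caudal_first) rev(gaps_mm) else gaps_mm
  pos <- c(0, cumsum(g))
  n <- length(pos)
  m <- abs(outer(pos, pos, "-"))
  dimnames(m) <- list(paste0("L", 1:n), paste0("L", 1:n))
  m
}

#' Linear regression of TRE on inter-level distance
#'
#' Ordinary least squares of the propagation-matrix cells on the distance
#' between the acquisition and the measured level.
#'
#' @param matrix propagation matrix ([propagation_matrix()]).
#' @param distances matching pairwise distance matrix
#'   ([cumulative_level_distances()]).
#' @return a `distance_fit`: `slope` (mm TRE per mm), `intercept` (mm),
#'   `residual_rms_mm`, `n`.
#' @export
fit_tre_vs_distance <- function(matrix, distances) {
  if (!all(dim(matrix) == dim(distances))) {
    stop("fit_tre_vs_distance: matrix and distances must cover the same levels")
  }
  x <- as.numeric(distances)
  y <- as.numeric(matrix)
  if (stats::sd(x) == 0) stop("fit_tre_vs_distance: degenerate (all distances identical)")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 residual_rms_mm = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(y)),
            class = "distance_fit")
}

#' Intensity profile along a line segment
#'
#' Trilinear interpolation of a volume at `n_samples` equally spaced
#' positions between two world points.
#'
#' @param volume a [volume3d()].
#' @param p0,p1 segment endpoints (mm); must be distinct and inside the
#'   volume extent.
#' @param n_samples number of samples (>= 2).
#' @return an `intensity_profile`: `position_mm` (strictly increasing, 0 at
#'   `p0`) and `intensity`.
#' @export
intensity_profile <- function(volume, p0, p1, n_samples = 100L) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (n_samples < 2) stop("intensity_profile: need at least 2 samples")
  L <- sqrt(sum((p1 - p0)^2))
  if (L < 1e-12) stop("intensity_profile: p0 and p1 must be distinct")
  s <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + s * (p1[1] - p0[1]),
               p0[2] + s * (p1[2] - p0[2]),
               p0[3] + s * (p1[3] - p0[3]))
  vals <- vol_interp(volume, pts, rule = "error")
  structure(list(position_mm = s * L, intensity = vals),
            class = "intensity_profile")
}

#' Median and interquartile range over an ensemble of profiles
#'
#' All profiles must share the same sampling grid. Quantiles use the
#' linear-interpolation definition (R type 7).
#'
#' @param profiles list of `intensity_profile`s.
#' @return an `intensity_profile` with `median` and `iqr` components.
#' @export
profile_ensemble_stats <- function(profiles) {
  if (length(profiles) < 1) stop("profile_ensemble_stats: need at least one profile")
  pos <- profiles[[1]]$position_mm
  for (p in profiles) {
    if (length(p$position_mm) != length(pos) ||
        max(abs(p$position_mm - pos)) > 1e-9) {
      stop("profile_ensemble_stats: mismatched sampling grids")
    }
  }
  vals <- do.call(rbind, lapply(profiles, `[[`, "intensity"))
  med <- apply(vals, 2, stats::median)
  q1 <- apply(vals, 2, stats::quantile, probs = 0.25, names = FALSE)
  q3 <- apply(vals, 2, stats::quantile, probs = 0.75, names = FALSE)
  structure(list(position_mm = pos, median = med, iqr = q3 - q1),
            class = "intensity_profile")
}
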