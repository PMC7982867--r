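#' First-hit ultrasound coverage of the labelled vertebral anatomy
#'
#' For every frame and image column of a sweep, a ray is marched in CT
#' space (through the ground-truth transform composed with the frame pose)
#' along the column's depth direction; assuming no ultrasound penetration
#' beyond bone, only the FIRST labelled voxel encountered counts. Hits are
#' accumulated as a set of unique voxels and binned: the acquisition
#' level's own voxels by region (SP, L, AP, TP, VB), and voxels of the
#' adjacent inferior/superior levels pooled into `Inf` / `Sup`. Voxels of
#' levels further away terminate the ray but are not counted.
#'
#' @param sweep a `tracked_sweep`.
#' @param labelmap a [volume3d()] labelmap (codes `level * 10 + region`).
#' @param t_gt ground-truth reference-to-CT `rigid_transform`.
#' @param level acquisition level index.
#' @param step_mm marching step; must not exceed half the minimum voxel
#'   spacing. The default, a tenth of the voxel spacing, is fine enough to
#'   resolve grazing ray-voxel intersections, so the marched first-hit set
#'   matches the fine-step definition of the model.
#' @return a `coverage_histogram`: named integer `counts` over
#'   `SP, L, AP, TP, VB, Inf, Sup`, plus `level` and `n_rays`.
#' @export
compute_coverage <- function(sweep, labelmap, t_gt, level,
                             step_mm = min(labelmap$spacing) / 10) {
  if (step_mm > min(labelmap$spacing) / 2 + 1e-12) {
    stop("compute_coverage: step must not exceed half the voxel spacing")
  }
  counts <- stats::setNames(integer(length(COVERAGE_BINS)), COVERAGE_BINS)
  if (length(sweep$frames) == 0) {
    return(structure(list(counts = counts, level = level, n_rays = 0L),
                     class = "coverage_histogram"))
  }
  cfg <- sweep$config
  nc <- cfg$n_cols; ps <- cfg$pixel_spacing_mm
  u <- (seq_len(nc) - (nc + 1) / 2) * ps
  origins <- list(); dirs <- list()
  for (f in sweep$frames) {
    img_to_ct <- compose(t_gt, f$pose)
    o <- apply_transform(img_to_ct, cbind(u, 0, 0))
    dirvec <- unclass(img_to_ct)[1:3, 2]
    origins[[length(origins) + 1]] <- o
    dirs[[length(dirs) + 1]] <- matrix(dirvec, nc, 3, byrow = TRUE)
  }
  O <- do.call(rbind, origins)
  D <- do.call(rbind, dirs)
  max_depth <- cfg$depth_cm * 10
  n_steps <- ceiling(max_depth / step_mm)
  active <- rep(TRUE, nrow(O))
  hit_voxel <- integer(0)
  dd <- vol_dim(labelmap)
  for (s in 0:n_steps) {
    if (!any(active)) break
    p <- O[active, , drop = FALSE] + s * step_mm * D[active, , drop = FALSE]
    idx <- round(world_to_index(labelmap, p))
    inside <- idx[, 1] >= 1 & idx[, 1] <= dd[1] &
              idx[, 2] >= 1 & idx[, 2] <= dd[2] &
              idx[, 3] >= 1 & idx[, 3] <= dd[3]
    lin <- rep(0L, nrow(idx))
    if (any(inside)) {
      lin[inside] <- (idx[inside, 3] - 1L) * dd[1] * dd[2] +
        (idx[inside, 2] - 1L) * dd[1] + idx[inside, 1]
    }
    lab <- rep(0L, nrow(idx))
    lab[inside] <- labelmap$data[lin[inside]]
    hit <- lab > 0L
    if (any(hit)) {
      hit_voxel <- c(hit_voxel, lin[hit])
      w <- which(active)
      active[w[hit]] <- FALSE
    }
  }
  if (length(hit_voxel) > 0) {
    vox <- unique(hit_voxel)
    code <- labelmap$data[vox]
    lv <- label_level(code)
    reg <- label_region(code)
    own <- lv == level
    for (b in seq_along(REGIONS)) {
      counts[names(REGIONS)[b]] <- sum(own & reg == REGIONS[[b]])
    }
    counts["Inf"] <- sum(lv == level + 1L)
    counts["Sup"] <- sum(lv == level - 1L)
  }
  structure(list(counts = counts, level = as.integer(level), n_rays = nrow(O)),
            class = "coverage_histogram")
}

#' Fixed-effect design for the coverage-accuracy model
#'
#' Builds the design linking own-level TRE to the coverage of the five
#' anatomical labels and all their pairwise interactions (5 + choose(5,2)
#' = 15 fixed-effect columns), with grouping columns for the random
#' intercepts (level, level x frequency, level x depth). Level-mismatch
#' acquisitions are removed first, mirroring the outlier handling of the
#' accuracy analysis.
#'
#' @param histograms data.frame with one row per acquisition and columns
#'   `SP, L, AP, TP, VB` (own-level coverage counts).
#' @param results data.frame aligned row-wise with `histograms`, holding
#'   `tre_mm`, `classification`, `level`, `depth_cm`, `frequency_mhz`.
#' @return design data.frame with `tre_mm`, 15 fixed-effect columns, and
#'   factors `level`, `level_frequency`, `level_depth`.
#' @export
build_accuracy_design <- function(histograms, results) {
  stopifnot(nrow(histograms) == nrow(results))
  keep <- results$classification != "level_mismatch"
  if (!any(keep)) stop("build_accuracy_design: no acquisitions left after outlier removal")
  h <- histograms[keep, , drop = FALSE]
  r <- results[keep, , drop = FALSE]
  labels <- names(REGIONS)
  design <- data.frame(tre_mm = r$tre_mm)
  for (l in labels) design[[l]] <- h[[l]]
  pairs <- utils::combn(labels, 2)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    design[[paste(a, b, sep = "_")]] <- h[[a]] * h[[b]]
  }
  design$level <- factor(r$level)
  design$level_frequency <- factor(paste(r$level, r$frequency_mhz, sep = ":"))
  design$level_depth <- factor(paste(r$level, r$depth_cm, sep = ":"))
  design
}

#' Binary level-misalignment response and coverage-sum covariate
#'
#' The response is 1 when the acquisition's own-level TRE reaches the
#' mismatch threshold (10 mm); the covariate is the total own-level
#' coverage (SP + L + AP + TP + VB, excluding the adjacent-level bins).
#'
#' @param results data.frame with `tre_mm` (own level) and grouping
#'   columns `level`, `depth_cm`, `frequency_mhz`.
#' @param histograms aligned data.frame with the five own-level bins.
#' @param mismatch_threshold_mm threshold defining the positive response.
#' @return list with `response` (0/1), `covariate`, `groups` (data.frame).
#' @export
build_misalignment_response <- function(results, histograms,
                                        mismatch_threshold_mm = 10) {
  stopifnot(nrow(histograms) == nrow(results))
  response <- as.integer(results$tre_mm >= mismatch_threshold_mm)
  covariate <- rowSums(histograms[, names(REGIONS), drop = FALSE])
  groups <- data.frame(
    level = factor(results$level),
    level_frequency = factor(paste(results$level, results$frequency_mhz, sep = ":")),
    level_depth = factor(paste(results$level, results$depth_cm, sep = ":")))
  list(response = response, covariate = as.numeric(covariate), groups = groups)
}

fit_terms <- function() {
  labels <- names(REGIONS)
  pairs <- utils::combn(labels, 2)
  c(labels, paste(pairs[1, ], pairs[2, ], sep = "_"))
}

#' Linear mixed-effect model of TRE on label coverage
#'
#' Fits `tre_mm ~ 15 coverage terms + (1 | level) + (1 | level:frequency)
#' + (1 | level:depth)` with lmerTest (Satterthwaite p-values). A constant
#' response returns zero slopes with a degenerate flag; convergence
#' problems and singular fits are flagged, not raised.
#'
#' @param design output of [build_accuracy_design()].
#' @return a `coverage_model_fit`: `coefficients` (term, estimate, se,
#'   p_value), `converged`, `singular`, `messages`.
#' @export
fit_accuracy_model <- function(design) {
  terms <- fit_terms()
  stopifnot(all(c("tre_mm", terms) %in% names(design)))
  if (stats::sd(design$tre_mm) == 0) {
    co <- data.frame(term = c("(Intercept)", terms),
                     estimate = c(design$tre_mm[1], rep(0, length(terms))),
                     se = NA_real_, p_value = NA_real_)
    return(structure(list(coefficients = co, converged = TRUE, singular = TRUE,
                          messages = "zero-variance response"),
                     class = "coverage_model_fit"))
  }
  fml <- stats::as.formula(paste("tre_mm ~", paste(terms, collapse = " + "),
                                 "+ (1 | level) + (1 | level_frequency) + (1 | level_depth)"))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = design,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], p_value = sm[, "Pr(>|t|)"],
                   row.names = NULL)
  structure(list(coefficients = co,
                 converged = !any(grepl("failed to converge", msgs)),
                 singular = lme4::isSingular(fit),
                 messages = msgs, fit = fit),
            class = "coverage_model_fit")
}

#' Binomial mixed-effect model of level misalignment on total coverage
#'
#' Fits a logistic model of the binary mismatch response on the own-level
#' coverage sum, with random intercepts for level and the level x
#' frequency / level x depth sub-groups (`groups = NULL` drops the random
#' effects and fits a plain logistic regression). Complete separation is
#' flagged via `converged = FALSE`.
#'
#' @param response 0/1 vector.
#' @param covariate numeric vector (own-level coverage sum).
#' @param groups data.frame with `level`, `level_frequency`, `level_depth`
#'   factors, or `NULL`.
#' @return a `coverage_model_fit` with the covariate row in
#'   `coefficients`, plus `separated`.
#' @export
fit_mismatch_model <- function(response, covariate, groups = NULL) {
  if (length(unique(response)) < 2) {
    stop("fit_mismatch_model: need at least one positive and one negative case")
  }
  msgs <- character(0)
  df <- data.frame(y = response, coverage_sum = covariate)
  if (is.null(groups)) {
    fit <- withCallingHandlers(
      stats::glm(y ~ coverage_sum, family = stats::binomial(), data = df),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    singular <- FALSE
  } else {
    df <- cbind(df, groups)
    fit <- withCallingHandlers(
      lme4::glmer(y ~ coverage_sum + (1 | level) + (1 | level_frequency) +
                    (1 | level_depth),
                  family = stats::binomial(), data = df,
                  control = lme4::glmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      })
    sm <- withCallingHandlers(
      summary(fit)$coefficients,
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    singular <- lme4::isSingular(fit)
  }
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   p_value = sm[, 4], row.names = NULL)
  # under complete separation the MLE diverges and fitted probabilities pin
  # to the observed 0/1 labels
  p_hat <- stats::fitted(fit)
  separated <- any(grepl("fitted probabilities numerically 0 or 1", msgs)) ||
    mean(abs(df$y - p_hat)) < 1e-3
  structure(list(coefficients = co,
                 converged = !separated && !any(grepl("failed to converge", msgs)),
                 singular = singular, separated = separated,
                 messages = msgs, fit = fit),
            class = "coverage_model_fit")
}

#' @export
print.coverage_model_fit <- function(x, ...) {
  cat("<coverage_model_fit> converged:", x$converged, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
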