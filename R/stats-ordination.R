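## Spearman correlations of raw variables with ordination axes, with a
## display flag at the conventional |r| threshold
spearman_vectors <- function(vars, axes, threshold) {
  vars <- as.matrix(vars)
  if (is.null(colnames(vars)))
    colnames(vars) <- paste0("V", seq_len(ncol(vars)))
  r <- cor(vars, axes, method = "spearman")
  data.frame(variable = colnames(vars), r,
             display = apply(abs(r) > threshold, 1, any),
             row.names = NULL)
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Constrained ordination in which between-group variability is scaled by
#' within-group dispersion: the distance matrix is decomposed into principal
#' coordinates, the first `m` axes are retained, and canonical discriminant
#' axes maximising group separation are fit on them (linear discriminant
#' analysis in PCO space, the Anderson & Willis construction). When
#' `m = "auto"` the number of retained axes is chosen to maximise
#' leave-one-out allocation success, ties broken toward smaller `m`.
#'
#' @param d distances (`dist` or square symmetric matrix).
#' @param groups group label per row.
#' @param m_axes number of PCO axes to retain, or `"auto"`.
#' @param vars optional numeric matrix of the original variables (same rows
#'   as `d`) for Spearman correlation vector overlays.
#' @param vector_threshold display threshold on `|r|` for the vector overlay
#'   (default 0.20).
#' @return Object of class `"reef_cap"`: `points` (canonical scores),
#'   `m`, `loo_success` (overall leave-one-out allocation success,
#'   fraction), `loo_by_group`, `canonical_correlations`, `vectors`
#'   (Spearman correlations of variables with the canonical axes, rows with
#'   `|r|` above the threshold flagged), `groups`.
#' @references Anderson, M. J. & Willis, T. J. (2003) Canonical analysis of
#'   principal coordinates. Ecology 84, 511-525.
#' @export
reef_cap <- function(d, groups, m_axes = "auto", vars = NULL,
                     vector_threshold = 0.20) {
  dm <- as_distmat(d)
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  pc <- pco_coords(dm)
  Yr <- pc$Yr
  n <- nrow(dm)
  max_m <- min(ncol(Yr), n - nlevels(groups) - 1)
  if (max_m < 1) stop("too few observations for any PCO axis")

  loo_success_m <- function(m) {
    fit <- suppressWarnings(MASS::lda(Yr[, seq_len(m), drop = FALSE],
                                      grouping = groups, CV = TRUE))
    mean(fit$class == groups)
  }

  if (identical(m_axes, "auto")) {
    succ <- vapply(seq_len(max_m), loo_success_m, numeric(1))
    m <- which.max(succ)          # which.max takes the first (smallest) max
    loo <- succ[m]
  } else {
    m <- as.integer(m_axes)
    if (m < 1 || m > max_m)
      stop("m_axes must be between 1 and ", max_m)
    loo <- loo_success_m(m)
  }

  Q <- Yr[, seq_len(m), drop = FALSE]
  fit <- suppressWarnings(MASS::lda(Q, grouping = groups))
  pred <- stats::predict(fit, Q)
  cv <- suppressWarnings(MASS::lda(Q, grouping = groups, CV = TRUE))
  by_group <- tapply(cv$class == groups, groups, mean)
  cc <- stats::cancor(Q, model.matrix(~ groups - 1))$cor
  cc <- cc[seq_len(min(length(cc), nlevels(groups) - 1))]

  vectors <- NULL
  if (!is.null(vars)) vectors <- spearman_vectors(vars, pred$x,
                                                 vector_threshold)

  structure(list(points = pred$x, m = m, loo_success = loo,
                 loo_by_group = by_group,
                 canonical_correlations = cc, vectors = vectors,
                 groups = groups, method = "CAP"),
            class = "reef_cap")
}

#' @export
print.reef_cap <- function(x, digits = 4, ...) {
  cat(sprintf("CAP ordination: m = %d PCO axes, leave-one-out allocation success %.1f%%\n",
              x$m, 100 * x$loo_success))
  cat("Canonical correlations:",
      paste(signif(x$canonical_correlations, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.reef_cap <- function(x, ...) {
  pts <- x$points
  if (ncol(pts) == 1) pts <- cbind(pts, 0)
  plot(pts[, 1], pts[, 2], col = as.integer(x$groups),
       pch = as.integer(x$groups) %% 25,
       xlab = "CAP1", ylab = "CAP2", ...)
  invisible(x)
}

#' Non-metric multidimensional scaling (nMDS)
#'
#' Unconstrained rank-based ordination preserving inter-point distances
#' (hence raw dispersion patterns). Kruskal stress-1 is minimised by
#' monotone regression over `n_restarts` random restarts (via
#' `vegan::metaMDS` with `monoMDS`); the best configuration and its stress
#' (on the 0-1 scale) are returned.
#'
#' @param d distances (`dist` or square symmetric matrix).
#' @param k number of ordination dimensions (default 2; must satisfy
#'   `k < n - 1`).
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed for reproducibility.
#' @param vars optional matrix of original variables for Spearman vectors.
#' @param vector_threshold display threshold on `|r|` (default 0.20).
#' @return Object of class `"reef_nmds"`: `points`, `stress`, `k`,
#'   `vectors`, `method`.
#' @export
reef_nmds <- function(d, k = 2, n_restarts = 20, seed = NULL, vars = NULL,
                      vector_threshold = 0.20) {
  dm <- as_distmat(d)
  n <- nrow(dm)
  if (k < 1) stop("k must be >= 1")
  if (k >= n - 1) stop("k must be < n - 1")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(dm), k = k, try = n_restarts,
                        trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE,
                        expand = FALSE)
  vectors <- NULL
  if (!is.null(vars)) vectors <- spearman_vectors(vars, fit$points,
                                                 vector_threshold)
  structure(list(points = fit$points, stress = fit$stress, k = k,
                 vectors = vectors, method = "nMDS"),
            class = "reef_nmds")
}

#' @export
print.reef_nmds <- function(x, digits = 4, ...) {
  cat(sprintf("nMDS ordination: k = %d, stress = %s\n", x$k,
              signif(x$stress, digits)))
  invisible(x)
}

#' @export
plot.reef_nmds <- function(x, groups = NULL, ...) {
  pts <- x$points
  if (ncol(pts) == 1) pts <- cbind(pts, 0)
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(pts[, 1], pts[, 2], col = col, pch = 1,
       xlab = "nMDS1", ylab = "nMDS2",
       sub = sprintf("stress = %.2f", x$stress), ...)
  invisible(x)
}

#' Multivariate effect size: mean between-group Euclidean distance
#'
#' The effect size of a stressor (singly or in combination) is the average
#' Euclidean distance between the reef states of two scenario groups,
#' typically an impacted group versus the no-impact reference.
#'
#' @param d distances (`dist` or square symmetric matrix).
#' @param groups group label per row.
#' @param group_a,group_b the two group labels to compare (non-empty).
#' @return Arithmetic mean of all between-group pairwise distances.
#' @export
effect_size <- function(d, groups, group_a, group_b) {
  dm <- as_distmat(d)
  groups <- as.character(groups)
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (!length(ia)) stop("empty group: ", group_a)
  if (!length(ib)) stop("empty group: ", group_b)
  mean(dm[ia, ib, drop = FALSE])
}

#' Classify a two-stressor interaction
#'
#' Compares the combined effect of two stressors with the sum of their
#' individual effects: antagonistic if the combined effect falls short of
#' the sum by more than `tolerance`, synergistic if it exceeds the sum by
#' more than `tolerance`, additive otherwise. (Antagonism through a
#' dominant-stressor mechanism arises when one stressor degrades the system
#' so far that the other can add little.)
#'
#' @param effect_a,effect_b individual effect sizes (>= 0).
#' @param effect_ab combined effect size (>= 0).
#' @param tolerance non-negative additivity band half-width.
#' @return `"antagonistic"`, `"additive"` or `"synergistic"`.
#' @examples
#' classify_interaction(3, 4, 5, 0.1)  # antagonistic
#' @export
classify_interaction <- function(effect_a, effect_b, effect_ab,
                                 tolerance = 0) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (any(c(effect_a, effect_b, effect_ab) < 0))
    stop("effects must be >= 0")
  s <- effect_a + effect_b
  if (effect_ab < s - tolerance) "antagonistic"
  else if (effect_ab > s + tolerance) "synergistic"
  else "additive"
}
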