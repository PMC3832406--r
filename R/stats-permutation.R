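#' Normalise a community matrix
#'
#' Centres and scales every state-variable column to mean 0, standard
#' deviation 1 (denominator `n - 1`), so that benthic covers (%) and
#' consumer biomasses (g m-2) contribute comparably to Euclidean distances.
#'
#' @param cm a [snapshot_matrix()] community matrix, or a plain numeric
#'   matrix/data frame of variables.
#' @return The same object with variable columns normalised (attribute
#'   `normalised = TRUE` for community matrices).
#' @export
normalise_community <- function(cm) {
  if (inherits(cm, "community_matrix")) {
    vars <- attr(cm, "variables")
    m <- as.matrix(cm[, vars, drop = FALSE])
  } else {
    m <- as.matrix(cm)
    vars <- colnames(m)
  }
  if (nrow(m) < 2) stop("need at least 2 rows to normalise")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    stop("constant column(s): ", paste(bad, collapse = ", "),
         "; drop the variable (e.g. urchins at sites where they are absent)")
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (inherits(cm, "community_matrix")) {
    cm[, vars] <- z
    attr(cm, "normalised") <- TRUE
    cm
  } else z
}

#' Euclidean distances between community snapshots
#'
#' Normalises (unless already normalised) and returns the Euclidean distance
#' matrix on which all the permutational analyses operate.
#'
#' @param cm a [snapshot_matrix()] community matrix.
#' @param normalise normalise first (default `TRUE`; skipped if the matrix
#'   is already flagged normalised).
#' @return A `dist` object with attribute `groups` (data frame of the
#'   scenario factor columns).
#' @export
community_dist <- function(cm, normalise = TRUE) {
  stopifnot(inherits(cm, "community_matrix"))
  if (normalise && !isTRUE(attr(cm, "normalised")))
    cm <- normalise_community(cm)
  d <- dist(community_vars(cm))
  attr(d, "groups") <- data.frame(
    scenario = cm$scenario, fishing = cm$fishing,
    bleaching = cm$bleaching, water = cm$water, stringsAsFactors = FALSE)
  d
}

## --- internal: distance -> principal-coordinate machinery -----------------

as_distmat <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("distances must be non-negative")
  m
}

## Gower-centred inner-product matrix and real/imaginary PCO coordinates.
## Negative eigenvalues (impossible for Euclidean input) are retained as
## imaginary axes whose squared contributions are subtracted.
pco_coords <- function(dm, tol = 1e-9) {
  n <- nrow(dm)
  A <- -0.5 * dm^2
  rm <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
  e <- eigen(G, symmetric = TRUE)
  scale_tol <- tol * max(abs(e$values), 1)
  pos <- e$values > scale_tol
  neg <- e$values < -scale_tol
  Yr <- if (any(pos))
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                            sum(pos)) else
    matrix(0, n, 0)
  Yi <- if (any(neg))
    e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]),
                                            sum(neg)) else
    matrix(0, n, 0)
  list(G = G, Yr = Yr, Yi = Yi, eig = e$values, total_ss = sum(diag(G)))
}

## Orthogonal projector blocks of the full crossed fixed-factor model
## (balanced designs; sum-to-zero contrasts make the blocks orthogonal).
design_projectors <- function(factors) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  factors[] <- lapply(factors, function(f) factor(as.character(f)))
  n <- nrow(factors)
  cells <- interaction(factors, drop = FALSE)
  counts <- table(cells)
  if (length(unique(counts)) != 1)
    stop("unbalanced design: unequal replicates per cell")
  if (counts[1] < 1) stop("empty design cell")
  fml <- stats::as.formula(paste("~", paste(names(factors), collapse = "*")))
  contr <- lapply(factors, function(f) "contr.sum")
  names(contr) <- names(factors)
  X <- model.matrix(fml, data = factors, contrasts.arg = contr)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(fml), "term.labels")
  H <- lapply(seq_along(labs), function(t) {
    Xt <- X[, asg == t, drop = FALSE]
    Xt %*% solve(crossprod(Xt)) %*% t(Xt)
  })
  names(H) <- labs
  df <- vapply(seq_along(labs), function(t) sum(asg == t), integer(1))
  names(df) <- labs
  list(H = H, df = df, terms = labs, n = n)
}

ss_under <- function(H, Yr, Yi) {
  s <- sum((H %*% Yr)^2)
  if (ncol(Yi)) s <- s - sum((H %*% Yi)^2)
  s
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squared inter-point distances over the terms of a
#' fully crossed fixed-factor design (all main effects and interactions)
#' following Anderson's geometric approach: total SS is the sum of squared
#' distances divided by n, term SS are computed by projecting
#' principal-coordinate representations of the points onto the design
#' subspaces, and each term's pseudo-F is tested by permutation of
#' residuals under the reduced model excluding that term (Freedman-Lane):
#' the residuals of the reduced fit are permuted, added back to the reduced
#' fit, and the full model is re-fit to the permuted data. p-values use the
#' `(b + 1) / (m + 1)` convention, so `p >= 1/(nperm + 1)`.
#'
#' The design must be balanced (equal replicates per cell), which makes the
#' term subspaces orthogonal so that term SS plus residual SS equals total
#' SS exactly. If all points coincide (total SS = 0) the test is reported
#' as degenerate and no p-values are emitted.
#'
#' @param d distances: a `dist` object or square symmetric matrix
#'   (Euclidean distances of normalised data in the standard pipeline, see
#'   [community_dist()]).
#' @param factors data frame of crossed fixed factors (one column per
#'   factor), rows matching `d`.
#' @param nperm number of permutations (default 4999).
#' @param seed integer seed making the permutations reproducible.
#' @return An object of class `"reef_permanova"`: list with `aov_table`
#'   (term, Df, SumOfSqs, MeanSqs, pseudoF, `p_perm`), `total_ss`,
#'   `residual_ss`, `nperm`, `scheme`, `degenerate`.
#' @references Anderson, M. J. (2001) A new method for non-parametric
#'   multivariate analysis of variance. Austral Ecology 26, 32-46.
#' @export
reef_permanova <- function(d, factors, nperm = 4999, seed = NULL) {
  if (nperm < 1) stop("nperm must be >= 1")
  dm <- as_distmat(d)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != nrow(dm))
    stop("factors rows must match the distance matrix")
  pc <- pco_coords(dm)
  dp <- design_projectors(factors)
  n <- dp$n
  Yr <- pc$Yr; Yi <- pc$Yi

  degenerate <- pc$total_ss <= 1e-12 * n
  ss <- vapply(dp$H, ss_under, numeric(1), Yr = Yr, Yi = Yi)
  df <- dp$df
  ss_res <- pc$total_ss - sum(ss)
  df_res <- n - 1 - sum(df)
  if (df_res < 1) stop("no residual degrees of freedom")
  ms <- ss / df
  ms_res <- ss_res / df_res
  Fv <- ms / ms_res

  pvals <- rep(NA_real_, length(ss))
  if (!degenerate) {
    if (!is.null(seed)) set.seed(seed)
    H_all <- Reduce(`+`, dp$H)
    J <- matrix(1 / n, n, n)
    R_full <- diag(n) - J - H_all
    for (t in seq_along(dp$H)) {
      P_red <- if (length(dp$H) > 1)
        J + Reduce(`+`, dp$H[-t]) else J
      FitR <- P_red %*% Yr
      ResR <- Yr - FitR
      FitI <- if (ncol(Yi)) P_red %*% Yi else Yi
      ResI <- if (ncol(Yi)) Yi - FitI else Yi
      Ht <- dp$H[[t]]
      exceed <- 0L
      for (b in seq_len(nperm)) {
        pi_ <- sample.int(n)
        Ys <- FitR + ResR[pi_, , drop = FALSE]
        ss_t <- sum((Ht %*% Ys)^2)
        ss_r <- sum((R_full %*% Ys)^2)
        if (ncol(Yi)) {
          Ysi <- FitI + ResI[pi_, , drop = FALSE]
          ss_t <- ss_t - sum((Ht %*% Ysi)^2)
          ss_r <- ss_r - sum((R_full %*% Ysi)^2)
        }
        Fb <- (ss_t / df[t]) / (ss_r / df_res)
        if (Fb >= Fv[t] - 1e-12) exceed <- exceed + 1L
      }
      pvals[t] <- (exceed + 1) / (nperm + 1)
    }
  }

  tab <- data.frame(term = dp$terms, Df = as.integer(df), SumOfSqs = ss,
                    MeanSqs = ms, pseudoF = Fv, p_perm = pvals,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(aov_table = tab, total_ss = pc$total_ss,
                 residual_ss = ss_res, residual_df = df_res, nperm = nperm,
                 scheme = "permutation of residuals under a reduced model",
                 degenerate = degenerate),
            class = "reef_permanova")
}

#' @export
print.reef_permanova <- function(x, digits = 4, ...) {
  cat("PERMANOVA (", x$scheme, ", ", x$nperm, " permutations)\n", sep = "")
  if (x$degenerate)
    cat("  degenerate input: all points coincide (total SS = 0); no tests\n")
  tab <- x$aov_table
  tab$SumOfSqs <- signif(tab$SumOfSqs, digits)
  tab$MeanSqs <- signif(tab$MeanSqs, digits)
  tab$pseudoF <- signif(tab$pseudoF, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: Df %d, SS %s;  Total SS %s\n", x$residual_df,
              signif(x$residual_ss, digits), signif(x$total_ss, digits)))
  invisible(x)
}

#' Pairwise PERMANOVA comparisons
#'
#' One one-factor PERMANOVA per unordered pair of groups, reporting both the
#' pseudo-F and the pseudo-t (`t = sqrt(F)`). Following the standard
#' practice for these a-posteriori comparisons, no adjustment of the
#' significance level is made for multiple testing. With k groups there are
#' `k (k - 1) / 2` comparisons (153 for the 18-scenario grid).
#'
#' @param d distances (`dist` or square matrix).
#' @param groups group label per row of `d`.
#' @param nperm permutations per comparison (default 999).
#' @param seed integer seed.
#' @return Data frame with columns `group1`, `group2`, `t`, `pseudoF`,
#'   `p_perm`; pairs with a group of fewer than 2 members are skipped with
#'   a warning.
#' @export
pairwise_permanova <- function(d, groups, nperm = 999, seed = NULL) {
  dm <- as_distmat(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm))
    stop("groups length must match the distance matrix")
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (i in seq_len(length(lev) - 1)) {
    for (j in seq(i + 1, length(lev))) {
      idx <- groups %in% c(lev[i], lev[j])
      g <- groups[idx]
      if (min(table(g)) < 2) {
        warning("skipping pair ", lev[i], " vs ", lev[j],
                ": group with < 2 members")
        next
      }
      fit <- reef_permanova(dm[idx, idx], data.frame(group = g),
                            nperm = nperm, seed = NULL)
      out[[length(out) + 1]] <- data.frame(
        group1 = lev[i], group2 = lev[j],
        t = sqrt(fit$aov_table$pseudoF[1]),
        pseudoF = fit$aov_table$pseudoF[1],
        p_perm = fit$aov_table$p_perm[1], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Permutational analysis of multivariate dispersions (PERMDISP)
#'
#' Tests homogeneity of multivariate dispersions among groups: each point's
#' distance to its group centroid is computed in principal-coordinate space
#' (with negative-eigenvalue axes, absent for Euclidean input, entering as
#' subtracted squared components), a classical one-way F statistic is formed
#' on those distances, and significance is assessed by permuting the
#' least-squares residuals of the distances across groups.
#'
#' @param d distances (`dist` or square matrix).
#' @param groups group label per row (>= 2 groups, each with >= 2 members).
#' @param nperm number of permutations (default 999).
#' @param seed integer seed.
#' @return An object of class `"reef_permdisp"`: list with
#'   `group_means` (mean distance-to-centroid per group), `distances`,
#'   `F`, `df`, `p_perm`, `nperm`.
#' @references Anderson, M. J. (2006) Distance-based tests for homogeneity
#'   of multivariate dispersions. Biometrics 62, 245-253.
#' @export
reef_permdisp <- function(d, groups, nperm = 999, seed = NULL) {
  dm <- as_distmat(d)
  groups <- factor(as.character(groups))
  if (length(groups) != nrow(dm))
    stop("groups length must match the distance matrix")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  pc <- pco_coords(dm)
  n <- nrow(dm)
  z <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cr <- colMeans(pc$Yr[idx, , drop = FALSE])
    d2 <- rowSums((pc$Yr[idx, , drop = FALSE] -
                     matrix(cr, length(idx), length(cr), byrow = TRUE))^2)
    if (ncol(pc$Yi)) {
      ci <- colMeans(pc$Yi[idx, , drop = FALSE])
      d2 <- d2 - rowSums((pc$Yi[idx, , drop = FALSE] -
                            matrix(ci, length(idx), length(ci),
                                   byrow = TRUE))^2)
    }
    z[idx] <- sqrt(pmax(d2, 0))
  }

  k <- nlevels(groups)
  disp_F <- function(zv) {
    gm <- tapply(zv, groups, mean)
    ssb <- sum(table(groups) * (gm - mean(zv))^2)
    ssw <- sum((zv - gm[groups])^2)
    if (ssw <= 0) return(if (ssb <= 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  Fobs <- disp_F(z)

  if (!is.null(seed)) set.seed(seed)
  gm <- tapply(z, groups, mean)
  e <- z - gm[groups]
  exceed <- 0L
  for (b in seq_len(nperm)) {
    Fb <- disp_F(e[sample.int(n)])
    if (Fb >= Fobs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(group_means = tapply(z, groups, mean), distances = z,
                 groups = groups, F = Fobs,
                 df = c(k - 1, n - k),
                 p_perm = (exceed + 1) / (nperm + 1), nperm = nperm),
            class = "reef_permdisp")
}

#' @export
print.reef_permdisp <- function(x, digits = 4, ...) {
  cat(sprintf("PERMDISP: F = %s on %d and %d df, p(perm) = %s (%d permutations)\n",
              signif(x$F, digits), x$df[1], x$df[2],
              signif(x$p_perm, digits), x$nperm))
  cat("Mean distance to centroid:\n")
  print(signif(x$group_means, digits))
  invisible(x)
}
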