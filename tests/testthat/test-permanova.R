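test_that("normalisation gives unit-variance, zero-mean columns", {
  expect_equal(as.vector(normalise_community(matrix(c(1, 2, 3)))),
               c(-1, 0, 1))
  set.seed(2)
  m <- matrix(rnorm(360 * 7, mean = 5, sd = 3), 360, 7,
              dimnames = list(NULL, paste0("v", 1:7)))
  z <- normalise_community(m)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  # idempotence
  expect_equal(normalise_community(z), z, tolerance = 1e-12)
  m[, 3] <- 7
  expect_error(normalise_community(m), "constant column")
})

test_that("pseudo-F equals the classical one-way ANOVA F on univariate data", {
  set.seed(4)
  for (i in 1:5) {
    g <- factor(rep(letters[1:3], each = 6))
    y <- rnorm(18) + as.integer(g) * runif(1, 0, 2)
    fit <- reef_permanova(dist(y), data.frame(g = g), nperm = 19)
    Fc <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(fit$aov_table$pseudoF[1], Fc, tolerance = 1e-9)
  }
})

test_that("crossed-design partitioning matches aov and sums to total SS", {
  set.seed(8)
  fac <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                     rep = 1:4)[, 1:2]
  y <- rnorm(24) + 2 * (fac$A == "a1") + (fac$B == "b2")
  fit <- reef_permanova(dist(y), fac, nperm = 19)
  av <- summary(aov(y ~ A * B, data = cbind(fac, y = y)))[[1]]
  expect_equal(fit$aov_table$SumOfSqs, av$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(fit$aov_table$pseudoF, av$`F value`[1:3], tolerance = 1e-9)
  expect_equal(fit$aov_table$Df, av$Df[1:3])
  # term SS + residual = total, within 1e-9
  expect_lt(abs(sum(fit$aov_table$SumOfSqs) + fit$residual_ss -
                  fit$total_ss), 1e-9)
})

test_that("pseudo-F agrees with vegan::adonis2 on multivariate data", {
  set.seed(10)
  g <- factor(rep(c("u", "v", "w"), each = 7))
  x <- matrix(rnorm(21 * 4), 21, 4)
  x[g == "v", 1] <- x[g == "v", 1] + 1.5
  fit <- reef_permanova(dist(x), data.frame(g = g), nperm = 19)
  ref <- vegan::adonis2(dist(x) ~ g, data = data.frame(g = g),
                        permutations = 19, by = "terms")
  expect_equal(fit$aov_table$pseudoF[1], ref$F[1], tolerance = 1e-9)
  expect_equal(fit$aov_table$SumOfSqs[1], ref$SumOfSqs[1],
               tolerance = 1e-9)
  expect_equal(fit$total_ss, ref["Total", "SumOfSqs"], tolerance = 1e-9)
})

test_that("sampled permutation p matches full enumeration on n = 6", {
  set.seed(5)
  y <- c(0.3, 1.1, 0.8, 2.4, 3.0, 2.1)
  g <- factor(rep(c("p", "q"), each = 3))
  dm <- as.matrix(dist(y))
  Fstat <- function(idx) {
    gg <- factor(rep(c("p", "q"), each = 3)[idx])
    reef_permanova(dm, data.frame(g = gg), nperm = 1)$aov_table$pseudoF[1]
  }
  ## enumeration oracle: all 20 relabellings (choose(6,3)); F computed per
  ## relabelling of group membership
  Fobs <- Fstat(1:6)
  combs <- combn(6, 3)
  Fall <- apply(combs, 2, function(ix) {
    gg <- rep("q", 6); gg[ix] <- "p"
    reef_permanova(dm, data.frame(g = factor(gg)),
                   nperm = 1)$aov_table$pseudoF[1]
  })
  p_exact <- mean(Fall >= Fobs - 1e-12)
  fit <- reef_permanova(dm, data.frame(g = g), nperm = 999, seed = 1)
  p_sampled <- fit$aov_table$p_perm[1]
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_sampled - p_exact), 3 * mc_se + 2 / 1000)
})

test_that("degenerate input (all rows identical) yields no tests", {
  x <- matrix(1, 12, 3)
  fit <- reef_permanova(dist(x),
                        data.frame(g = factor(rep(c("a", "b"), each = 6))),
                        nperm = 19)
  expect_true(fit$degenerate)
  expect_equal(fit$total_ss, 0, tolerance = 1e-12)
  expect_true(all(is.na(fit$aov_table$p_perm)))
})

test_that("pseudo-F is invariant under rigid rotation and translation", {
  set.seed(12)
  x <- matrix(rnorm(30 * 3), 30, 3)
  g <- data.frame(g = factor(rep(c("a", "b", "c"), each = 10)))
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  x2 <- x %*% qr_ + matrix(5, 30, 3)
  f1 <- reef_permanova(dist(x), g, nperm = 1)$aov_table$pseudoF
  f2 <- reef_permanova(dist(x2), g, nperm = 1)$aov_table$pseudoF
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("permutation p-values are reproducible and within bounds", {
  set.seed(14)
  x <- matrix(rnorm(24 * 2), 24, 2)
  fac <- data.frame(a = rep(c("x", "y"), each = 12),
                    b = rep(rep(c("u", "v", "w"), each = 4), 2))
  f1 <- reef_permanova(dist(x), fac, nperm = 99, seed = 7)
  f2 <- reef_permanova(dist(x), fac, nperm = 99, seed = 7)
  expect_identical(f1$aov_table$p_perm, f2$aov_table$p_perm)
  expect_true(all(f1$aov_table$p_perm >= 1 / 100))
  expect_true(all(f1$aov_table$p_perm <= 1))
})

test_that("unbalanced designs are rejected", {
  y <- rnorm(10)
  g <- data.frame(g = factor(c(rep("a", 4), rep("b", 6))))
  expect_error(reef_permanova(dist(y), g, nperm = 9), "unbalanced")
})

test_that("pairwise comparisons count k(k-1)/2 and skip tiny groups", {
  set.seed(16)
  for (k in c(3, 6, 10)) {
    x <- matrix(rnorm(3 * k * 2), 3 * k, 2)
    g <- rep(paste0("g", seq_len(k)), each = 3)
    pw <- pairwise_permanova(dist(x), g, nperm = 9)
    expect_equal(nrow(pw), k * (k - 1) / 2)
    expect_equal(pw$t, sqrt(pw$pseudoF), tolerance = 1e-12)
  }
  x <- matrix(rnorm(10), 5, 2)
  g <- c("a", "a", "b", "b", "c")
  w <- testthat::capture_warnings(pw <- pairwise_permanova(dist(x), g,
                                                           nperm = 9))
  expect_match(w, "< 2 members", all = TRUE)
  expect_length(w, 2)
  expect_equal(nrow(pw), 1)
})

test_that("18 scenario groups give 153 pairwise comparisons", {
  set.seed(18)
  x <- matrix(rnorm(36 * 2), 36, 2)
  g <- rep(paste0("s", 1:18), each = 2)
  pw <- pairwise_permanova(dist(x), g, nperm = 1)
  expect_equal(nrow(pw), 153)
})

test_that("PERMANOVA type-I error stays at the nominal level", {
  ## no true effects: all cells drawn from one multivariate normal
  set.seed(20)
  n_data <- 500
  alpha <- 0.05
  rej <- logical(n_data)
  g <- data.frame(g = factor(rep(c("a", "b", "c"), each = 6)))
  for (i in seq_len(n_data)) {
    x <- matrix(rnorm(18 * 3), 18, 3)
    p <- reef_permanova(dist(x), g, nperm = 199)$aov_table$p_perm[1]
    rej[i] <- p <= alpha
  }
  mc_se <- sqrt(alpha * (1 - alpha) / n_data)
  expect_lte(mean(rej), alpha + 2 * mc_se)
})

test_that("PERMDISP agrees with vegan::betadisper and is translation-invariant", {
  set.seed(22)
  x <- matrix(rnorm(40 * 3), 40, 3)
  g <- factor(rep(c("a", "b"), each = 20))
  fit <- reef_permdisp(dist(x), g, nperm = 99, seed = 1)
  ref <- vegan::betadisper(dist(x), g, type = "centroid")
  expect_equal(unname(fit$group_means),
               unname(tapply(ref$distances, g, mean)), tolerance = 1e-9)
  refF <- summary(aov(ref$distances ~ g))[[1]]$`F value`[1]
  expect_equal(fit$F, refF, tolerance = 1e-9)
  ## rigid translation of one group leaves dispersions identical: F ~ 0
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    a <- matrix(rnorm(12 * 2), 12, 2)
    b <- a + 10                       # same shape, shifted
    d <- dist(rbind(a, b))
    f <- reef_permdisp(d, rep(c("a", "b"), each = 12), nperm = 49,
                       seed = s)
    expect_lt(f$F, 1e-9)
    f$p_perm
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.95)
})

test_that("PERMDISP detects a 3-fold spread difference", {
  hits <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    a <- rnorm(20, sd = 1)
    b <- rnorm(20, sd = 3)
    f <- reef_permdisp(dist(c(a, b)), rep(c("a", "b"), each = 20),
                       nperm = 99, seed = s)
    f$p_perm <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("PERMDISP centroid distances vanish for coincident points", {
  x <- rbind(matrix(1, 5, 2), matrix(3, 5, 2))
  g <- rep(c("a", "b"), each = 5)
  f <- reef_permdisp(dist(x), g, nperm = 19)
  expect_lt(max(f$distances), 1e-9)
  expect_error(reef_permdisp(dist(x), rep("a", 10), nperm = 9),
               "2 groups")
})
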