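# Shannon, Bray-Curtis, PCoA, PERMANOVA, dispersion and variability.

test_that("Shannon index closed forms and invariances", {
  expect_equal(shannonIndex(rep(1, 8)), log(8))
  expect_equal(shannonIndex(c(0, 7, 0)), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(shannonIndex(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(shannonIndex(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  # permutation invariance and uniform maximality
  set.seed(31)
  x <- rpois(20, 30) + 1
  expect_equal(shannonIndex(x), shannonIndex(sample(x)))
  expect_lte(shannonIndex(x), log(length(x)))
  expect_error(shannonIndex(c(0, 0)), "zero")
})

test_that("Bray-Curtis matches the formula and its metric-like bounds", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  expect_equal(as.numeric(brayCurtis(m)), 0.5)
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.numeric(brayCurtis(m2)), 0)
  m3 <- rbind(a = c(5, 5, 0, 0), b = c(0, 0, 3, 3))
  expect_equal(as.numeric(brayCurtis(m3)), 1)
  set.seed(32)
  r <- matrix(runif(40), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(brayCurtis(r))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  bad <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_error(brayCurtis(bad), "all-zero")
})

test_that("PCoA reproduces planted Euclidean geometry", {
  # two samples at distance d -> one axis at +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoaOrdination(d2)
  expect_equal(sort(unname(ord2$coordinates[, 1])), c(-1.5, 1.5))

  # planted 2-D points: recovered coordinates are an isometry
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 5, 6), 4, 2, byrow = TRUE,
                dimnames = list(paste0("p", 1:4), NULL))
  d <- dist(pts)
  ord <- pcoaOrdination(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(rec, as.matrix(d), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_gte(sum(ord$eigenvalues[ord$eigenvalues > 0]),
             max(ord$eigenvalues))
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA pseudo-F and R2 match vegan's adonis2", {
  set.seed(33)
  x <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(paste0("s", 1:12), NULL))
  g <- rep(c("a", "b", "c"), each = 4)
  d <- dist(x)
  mine <- permanova(d, g, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ad$R2[1], tolerance = 1e-10)
})

test_that("exhaustive PERMANOVA equals brute-force enumeration", {
  set.seed(34)
  for (rep in 1:5) {
    x <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
    d <- as.matrix(dist(x))
    g <- rep(c("a", "b"), each = 3)
    mine <- permanova(d, g, exhaustive = TRUE)
    expect_equal(mine$n_permutations, 20)
    expect_equal(mine$p_value, oracle_permanova_p(d, g), tolerance = 1e-12)
    expect_equal(mine$pseudo_F, oracle_pseudo_f(d, g), tolerance = 1e-10)
  }
})

test_that("PERMANOVA p-value respects the permutation floor and errors", {
  set.seed(35)
  x <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("s", 1:8), NULL))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 4)
  p <- permanova(d, g, n_permutations = 49, seed = 2)$p_value
  expect_gte(p, 1 / 50)
  expect_error(permanova(d, rep("a", 8)), "two groups")
})

test_that("pairwise PERMANOVA returns all pairs with BH adjustment", {
  set.seed(36)
  centers <- c(a = 0, b = 0, c = 6)   # only c is separated
  x <- do.call(rbind, lapply(names(centers), function(g)
    matrix(rnorm(5 * 3, mean = centers[[g]], sd = 0.5), 5, 3)))
  rownames(x) <- paste0("s", 1:15)
  g <- rep(names(centers), each = 5)
  res <- pairwisePermanova(dist(x), g, n_permutations = 999, seed = 3)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  sep <- res$group2 == "c" | res$group1 == "c"
  expect_true(all(res$p_adjusted[sep] < 0.05))
  expect_gt(res$p_value[!sep], 0.05)
})

test_that("dispersion homogeneity: congruent groups give F ~ 0", {
  set.seed(37)
  a <- matrix(rnorm(12 * 3), 12, 3)
  b <- a + 10                       # rigid shift: identical dispersion
  x <- rbind(a, b)
  rownames(x) <- paste0("s", 1:24)
  g <- rep(c("A", "B"), each = 12)
  dh <- dispersionHomogeneity(dist(x), g)
  expect_lt(dh$F, 1e-10)
  expect_gt(dh$p_value, 0.99)
  expect_true(all(dh$distances >= 0))
})

test_that("dispersion homogeneity detects a spread-ratio-5 contrast", {
  set.seed(38)
  hits <- 0
  for (i in 1:20) {
    tight <- matrix(rnorm(10 * 3, sd = 1), 10, 3)
    spread <- matrix(rnorm(10 * 3, sd = 5), 10, 3)
    x <- rbind(tight, spread)
    rownames(x) <- paste0("s", 1:20)
    dh <- dispersionHomogeneity(dist(x), rep(c("t", "s"), each = 10))
    hits <- hits + (dh$p_value < 0.05)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("group variability summarizes within-group dissimilarity", {
  m <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  m[3, 4] <- m[4, 3] <- 0.8
  g <- rep(c("same", "diff"), each = 2)
  gv <- groupVariability(m, g)
  expect_equal(unname(gv$variability["same"]), 0)
  # invariant to sample order
  ix <- c(3, 1, 4, 2)
  gv2 <- groupVariability(m[ix, ix], g[ix])
  expect_equal(gv$variability, gv2$variability[names(gv$variability)])
  expect_error(groupVariability(m, c("a", "b", "b", "b")), "fewer than 2")
})

test_that("planted low/high dispersion classes are recovered with ANOVA", {
  set.seed(39)
  ok <- 0
  for (i in 1:10) {
    mk <- function(sd, n) matrix(rnorm(n * 3, sd = sd), n, 3)
    x <- rbind(mk(1, 6), mk(1, 6), mk(5, 6), mk(5, 6))
    rownames(x) <- paste0("s", 1:24)
    g <- rep(c("d1", "d2", "s1", "s2"), each = 6)
    cls <- c(d1 = "deep", d2 = "deep", s1 = "shallow", s2 = "shallow")
    gv <- groupVariability(dist(x), g, classes = cls)
    ok <- ok + (gv$class_means["deep"] < gv$class_means["shallow"] &&
                  gv$p_value < 0.05)
  }
  expect_gte(ok / 10, 0.9)
})
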