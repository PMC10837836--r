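# Alpha/beta diversity, ordination and distance-based group tests.
# Matrices follow the vegan convention here: samples in rows.

#' Shannon diversity index (natural log)
#'
#' \code{H = -sum p_i ln p_i} over nonzero proportions, computed on
#' (typically rarefied) counts. For a matrix, one value per row (sample).
#'
#' @param x non-negative count/abundance vector, a sample-by-feature
#'   matrix, or an \linkS4class{AsvExperiment}.
#' @return numeric value(s) in nats.
#' @examples
#' shannonIndex(rep(1, 8))   # log(8)
#' @export
shannonIndex <- function(x) {
  if (is(x, "AsvExperiment")) x <- t(asvCounts(x))
  if (is.matrix(x)) {
    if (any(rowSums(x) <= 0)) stop("sample(s) with zero total counts")
    return(vegan::diversity(x, index = "shannon"))
  }
  if (any(x < 0)) stop("negative counts")
  if (sum(x) <= 0) stop("all-zero vector")
  vegan::diversity(x, index = "shannon")
}

#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(i,j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)} on sample rows.
#' For the beta-diversity workflow the input is the log2-transformed
#' relative abundance matrix (\code{\link{log2Abundance}} applied to
#' \code{\link{relativeAbundance}} of the rarefied table).
#'
#' @param x sample-by-feature non-negative matrix.
#' @return \code{dist} object with entries in [0, 1].
#' @export
brayCurtis <- function(x) {
  if (any(x < 0)) stop("Bray-Curtis requires non-negative entries")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2L)
    stop("undefined for pairs of all-zero samples: ",
         paste(rownames(x)[zero], collapse = ", "))
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering of \code{-d^2/2} and eigendecomposition
#' (\code{stats::cmdscale}). Coordinates are returned for positive
#' eigenvalues only; negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but their axes are
#' excluded, with no Lingoes/Cailliez correction applied.
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix.
#' @return list of class \code{pcoa_ordination}: \code{coordinates}
#'   (samples x positive axes, scaled by sqrt eigenvalue),
#'   \code{eigenvalues} (all, decreasing), \code{prop_explained}
#'   (positive eigenvalues over their sum).
#' @export
pcoaOrdination <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-12))
      stop("distance matrix must be symmetric with zero diagonal")
    d <- as.dist(d)
  }
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) stop("need at least two samples")
  # k = n-1 requested; rank deficiency is expected and read off the
  # eigenvalues, so cmdscale's warning about it is silenced
  fit <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-9 & eig > 0)
  coords <- fit$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 prop_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates),
      "positive axes\n")
  cat("  first axes explain:",
      paste0(round(100 * head(x$prop_explained, 3), 1), "%", collapse = ", "),
      "\n")
  neg <- sum(x$eigenvalues < 0)
  if (neg) cat("  ", neg, "negative eigenvalues (axes excluded), min",
               signif(min(x$eigenvalues), 3), "\n")
  invisible(x)
}

.asDistMatrix <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  m
}

# sums of squares for one labelling; D2 = squared distance matrix
.permanovaSS <- function(D2, groups) {
  N <- nrow(D2)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within)
}

.pseudoF <- function(ss, N, a)
  ((ss["total"] - ss["within"]) / (a - 1)) / (ss["within"] / (N - a))

# all distinct assignments of a label multiset to positions
.distinctAssignments <- function(groups, limit = 1e5) {
  lev <- levels(groups)
  counts <- table(groups)
  total <- factorial(length(groups)) / prod(factorial(counts))
  if (total > limit)
    stop("too many distinct assignments to enumerate (", format(total), ")")
  rec <- function(free, remaining) {
    if (!length(free)) return(list(integer(0)))
    out <- list()
    for (k in seq_along(lev)) {
      if (remaining[k] == 0L) next
      rem2 <- remaining
      rem2[k] <- rem2[k] - 1L
      for (tail in rec(free[-1], rem2))
        out[[length(out) + 1L]] <- c(k, tail)
    }
    out
  }
  asg <- rec(seq_along(groups), as.integer(counts))
  lapply(asg, function(a) factor(lev[a], levels = lev))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance:
#' \code{SS_total = sum_{i<j} d_ij^2 / N}, \code{SS_within} summed per
#' group, pseudo-F \code{= (SS_between/(a-1)) / (SS_within/(N-a))},
#' \code{R^2 = SS_between/SS_total}. The p-value is obtained either by
#' sampling label permutations, with the +1 correction
#' \code{p = (1 + #[F* >= F]) / (1 + n_permutations)}, or -- when
#' \code{exhaustive = TRUE} -- by complete enumeration of all distinct
#' assignments of the observed labels (the identity assignment included
#' in the reference set, so \code{p >= 1/N_distinct}).
#'
#' @param d \code{dist} or symmetric distance matrix.
#' @param groups factor (or coercible) of group labels, >= 2 groups.
#' @param n_permutations number of sampled permutations (ignored when
#'   exhaustive).
#' @param seed optional RNG seed for the sampled permutations.
#' @param exhaustive enumerate all distinct labelings instead of
#'   sampling.
#' @return data.frame of class \code{permanova_result} with columns
#'   \code{term}, \code{pseudo_F}, \code{R2}, \code{p_value},
#'   \code{n_permutations}.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  m <- .asDistMatrix(d)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(m)) stop("one group label per sample required")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("empty group level")
  D2 <- m^2
  N <- nrow(m)
  a <- nlevels(groups)
  ss <- .permanovaSS(D2, groups)
  f_obs <- .pseudoF(ss, N, a)
  r2 <- unname((ss["total"] - ss["within"]) / ss["total"])

  if (exhaustive) {
    perms <- .distinctAssignments(groups)
    f_perm <- vapply(perms, function(g)
      .pseudoF(.permanovaSS(D2, g), N, a), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    nperm <- length(perms)
  } else {
    f_perm <- withSeed(seed, vapply(seq_len(n_permutations), function(i) {
      g <- groups[sample.int(N)]
      .pseudoF(.permanovaSS(D2, g), N, a)
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    nperm <- n_permutations
  }
  structure(data.frame(term = "groups", pseudo_F = unname(f_obs), R2 = r2,
                       p_value = p, n_permutations = nperm,
                       stringsAsFactors = FALSE),
            class = c("permanova_result", "data.frame"))
}

#' Pairwise PERMANOVA
#'
#' \code{\link{permanova}} applied to every pair of group levels, with
#' Benjamini-Hochberg adjustment across the pairs reported alongside the
#' raw p-values.
#'
#' @inheritParams permanova
#' @return data.frame with one row per pair: \code{group1}, \code{group2},
#'   \code{pseudo_F}, \code{R2}, \code{p_value}, \code{p_adjusted}.
#' @export
pairwisePermanova <- function(d, groups, n_permutations = 999, seed = NULL,
                              exhaustive = FALSE) {
  m <- .asDistMatrix(d)
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least two groups")
  pairs <- combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    r <- permanova(m[sel, sel], droplevels(groups[sel]),
                   n_permutations = n_permutations,
                   seed = if (is.null(seed)) NULL else seed + k,
                   exhaustive = exhaustive)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               pseudo_F = r$pseudo_F, R2 = r$R2, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Homogeneity of multivariate dispersions
#'
#' Samples are embedded by PCoA (positive-eigenvalue axes only); each
#' group's centroid is computed in that space and every sample's
#' Euclidean distance to its own group centroid is returned, together
#' with a one-way ANOVA F-test on those distances. Groups with a single
#' sample are excluded with a warning. This is a real-axes variant of
#' the classical multivariate dispersion test; the imaginary-part
#' handling of negative eigenvalues is deliberately omitted.
#'
#' @param d \code{dist} or symmetric distance matrix.
#' @param groups factor of group labels (>= 2 groups with >= 2 samples).
#' @return list with \code{distances} (named, per sample), \code{groups},
#'   \code{F}, \code{p_value}, \code{anova} (the aov table).
#' @export
dispersionHomogeneity <- function(d, groups) {
  m <- .asDistMatrix(d)
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("group(s) of size 1 excluded: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes >= 2]
    m <- m[keep, keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least two groups of size >= 2")
  ord <- pcoaOrdination(m)
  co <- ord$coordinates
  dists <- numeric(nrow(co))
  names(dists) <- rownames(co)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(co[idx, , drop = FALSE])
    dists[idx] <- sqrt(colSums((t(co[idx, , drop = FALSE]) - cen)^2))
  }
  fit <- aov(dists ~ groups)
  tab <- anova(fit)
  list(distances = dists, groups = groups,
       F = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1], anova = tab)
}

#' Within-group community variability
#'
#' Per-group mean of the off-diagonal (pairwise) dissimilarities -- a
#' simple variability summary for contrasting, e.g., deep-sea against
#' shallow-water host groups. When \code{classes} maps each group level
#' to a class (e.g. habitat depth), a one-way ANOVA comparing the
#' within-group pairwise dissimilarities between classes is run.
#'
#' @param d \code{dist} or symmetric distance matrix.
#' @param groups factor of group labels; every group needs >= 2 samples.
#' @param classes optional named character vector mapping group levels to
#'   classes.
#' @return list with \code{variability} (named per group), and, when
#'   \code{classes} is given, \code{class_means}, \code{F},
#'   \code{p_value}.
#' @export
groupVariability <- function(d, groups, classes = NULL) {
  m <- .asDistMatrix(d)
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  if (any(sizes < 2)) stop("group(s) with fewer than 2 samples: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  per_pair <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    sub <- m[idx, idx]
    sub[upper.tri(sub)]
  })
  names(per_pair) <- levels(groups)
  variability <- vapply(per_pair, mean, numeric(1))
  out <- list(variability = variability)
  if (!is.null(classes)) {
    if (!all(levels(groups) %in% names(classes)))
      stop("classes must cover all group levels")
    dd <- data.frame(
      dissim = unlist(per_pair, use.names = FALSE),
      class = factor(rep(classes[levels(groups)], lengths(per_pair))))
    if (nlevels(dd$class) < 2) stop("need at least two classes")
    tab <- anova(aov(dissim ~ class, data = dd))
    out$class_means <- tapply(dd$dissim, dd$class, mean)
    out$F <- tab[["F value"]][1]
    out$p_value <- tab[["Pr(>F)"]][1]
  }
  out
}
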