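# Shared/specific feature sets across groups and filtered differential
# testing.

#' Shared and specific features across groups
#'
#' A feature is "present" in a group when its value passes the threshold
#' (strictly greater by default, matching presence rules of the form
#' ">0.01% relative abundance" / ">1 TMM") in at least one sample of the
#' group. Computes the per-feature membership pattern (the exclusive
#' patterns partition the present-feature universe), the inclusive
#' intersection size of every non-empty group combination (upset-style),
#' and per group pair the shared-feature percentage and the share of
#' total abundance those features carry.
#'
#' @param values feature-by-sample matrix on the scale the threshold
#'   refers to (relative abundance for ASVs, TMM-normalized abundance for
#'   transcripts).
#' @param groups factor over samples (>= 2 non-empty groups).
#' @param threshold presence threshold (default 0).
#' @param strict use strictly-greater comparison (default TRUE).
#' @return list of class \code{shared_features}: \code{membership}
#'   (logical feature x group matrix over the present universe),
#'   \code{exclusive_sets} (named sizes by membership pattern),
#'   \code{inclusive_sets} (named sizes for all 2^k - 1 combinations),
#'   \code{pairwise} (data.frame with \code{shared_n},
#'   \code{pct_shared}, \code{pct_abundance}).
#' @export
sharedFeatures <- function(values, groups, threshold = 0, strict = TRUE) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(values))
    stop("one group label per sample column required")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("empty group")
  cmp <- if (strict) `>` else `>=`
  membership <- vapply(levels(groups), function(g) {
    rowSums(cmp(values[, groups == g, drop = FALSE], threshold)) >= 1L
  }, logical(nrow(values)))
  membership <- matrix(membership, nrow = nrow(values),
                       dimnames = list(rownames(values), levels(groups)))
  universe <- rowSums(membership) >= 1L
  membership <- membership[universe, , drop = FALSE]
  lev <- colnames(membership)

  pattern <- apply(membership, 1, function(z) paste(lev[z], collapse = "&"))
  tab <- table(pattern)
  exclusive_sets <- setNames(as.integer(tab), names(tab))

  combos <- unlist(lapply(seq_along(lev), function(k)
    combn(lev, k, simplify = FALSE)), recursive = FALSE)
  inclusive_sets <- vapply(combos, function(cb)
    sum(rowSums(membership[, cb, drop = FALSE]) == length(cb)), integer(1))
  names(inclusive_sets) <- vapply(combos, paste, "", collapse = "&")

  pairs <- combn(lev, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    in1 <- membership[, g1]; in2 <- membership[, g2]
    shared <- in1 & in2
    uni <- in1 | in2
    sel <- groups %in% c(g1, g2)
    tot <- sum(values[, sel, drop = FALSE])
    ab <- if (tot > 0)
      100 * sum(values[rownames(membership)[shared], sel, drop = FALSE]) / tot
      else NA_real_
    data.frame(group1 = g1, group2 = g2, shared_n = sum(shared),
               pct_shared = 100 * sum(shared) / max(1L, sum(uni)),
               pct_abundance = ab, stringsAsFactors = FALSE)
  })
  structure(list(membership = membership,
                 exclusive_sets = exclusive_sets,
                 inclusive_sets = inclusive_sets,
                 pairwise = do.call(rbind, pw)),
            class = "shared_features")
}

#' @export
print.shared_features <- function(x, ...) {
  cat("Shared-feature analysis over", ncol(x$membership), "groups;",
      nrow(x$membership), "present features\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Differential features between two groups
#'
#' Filters features by the kind-specific abundance rule (ASVs: relative
#' abundance above \code{ra_threshold}; transcripts: TMM-normalized CPM
#' above \code{cpm_threshold}; either in at least \code{min_samples}
#' samples), then tests each surviving feature with a permutation test
#' on TMM-normalized log2-CPM: the statistic is the group-mean
#' difference moderated by the pooled standard error plus a floor
#' \code{s0} (the median pooled SE across features, guarding
#' low-variance features). The null distribution pools the moderated
#' statistics of all features over every distinct unordered relabelling
#' of the samples (exhaustive when there are at most
#' \code{n_permutations} splits, sampled otherwise); pooling borrows
#' strength across features so that small designs (e.g. 3 vs 3, with
#' only 10 distinct splits) retain p-value resolution. P-values are BH
#' adjusted and a feature passes when \code{p_adjusted < alpha} and
#' \code{|log2FC| >= log2(fc_threshold)}.
#'
#' @param counts feature-by-sample count matrix.
#' @param groups two-level factor over samples, >= 2 samples per level.
#' @param kind \code{"transcript"} or \code{"asv"} (selects the filter).
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param fc_threshold fold-change gate (default 2, i.e. |log2FC| >= 1).
#' @param ra_threshold ASV relative-abundance filter (default 1e-5,
#'   i.e. 0.001\%).
#' @param cpm_threshold transcript CPM filter (default 10).
#' @param min_samples samples that must pass the filter (default 2).
#' @param n_permutations maximum permutations (default 10000).
#' @param seed optional RNG seed (used only when sampling permutations).
#' @return data.frame of class \code{differential_result}: one row per
#'   tested feature with \code{feature}, \code{log2fc}, \code{p_value},
#'   \code{p_adjusted}, \code{direction} (up = higher in the second
#'   level), \code{pass}. Attributes record the numbers of filtered
#'   features and permutations used.
#' @export
differentialFeatures <- function(counts, groups,
                                 kind = c("transcript", "asv"),
                                 alpha = 0.01, fc_threshold = 2,
                                 ra_threshold = 1e-5, cpm_threshold = 10,
                                 min_samples = 2, n_permutations = 10000,
                                 seed = NULL) {
  kind <- match.arg(kind)
  .assertCountMatrix(counts, "counts")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")

  # kind-specific abundance filter
  if (kind == "asv") {
    ra <- sweep(counts, 2, colSums(counts), "/")
    keep <- rowSums(ra > ra_threshold) >= min_samples
  } else {
    f0 <- tmmFactors(counts)
    keep <- rowSums(cpmMatrix(counts, f0) > cpm_threshold) >= min_samples
  }
  if (sum(keep) < 2) stop("fewer than two features pass the filter")
  x <- counts[keep, , drop = FALSE]

  f <- tmmFactors(x)
  lib <- colSums(x) * f$factors[colnames(x)]
  logcpm <- edgeR::cpm(x, lib.size = lib, log = TRUE, prior.count = 2)

  n <- ncol(x)
  idx2 <- which(groups == levels(groups)[2])
  n2 <- length(idx2)
  splits <- combn(n, n2, simplify = FALSE)
  if (table(groups)[1] == n2)   # balanced: complements give the same |T|
    splits <- splits[vapply(splits, function(s) 1L %in% s, TRUE)]
  is_identity <- vapply(splits, function(s)
    setequal(s, idx2) || setequal(s, setdiff(seq_len(n), idx2)), TRUE)
  null_splits <- splits[!is_identity]
  if (length(null_splits) < 1)
    stop("fewer than two distinct permutations available")
  if (length(null_splits) > n_permutations) {
    null_splits <- withSeed(seed, sample(null_splits, n_permutations))
  }

  stat_for <- function(sel2) {
    g2 <- logcpm[, sel2, drop = FALSE]
    g1 <- logcpm[, -sel2, drop = FALSE]
    diff <- rowMeans(g2) - rowMeans(g1)
    v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
    k1 <- ncol(g1); k2 <- ncol(g2)
    s <- sqrt(((k1 - 1) * v1 + (k2 - 1) * v2) / (k1 + k2 - 2)) *
      sqrt(1 / k1 + 1 / k2)
    list(diff = diff, s = s)
  }
  obs <- stat_for(idx2)
  s0 <- median(obs$s)
  if (s0 == 0) s0 <- 1e-8
  t_obs <- abs(obs$diff) / (obs$s + s0)
  t_null <- unlist(lapply(null_splits, function(sp) {
    st <- stat_for(sp)
    abs(st$diff) / (st$s + s0)
  }))

  # p_i = (1 + #[|T*| >= |T_i|]) / (1 + N_null), via sorted null
  srt <- sort(t_null)
  ge <- length(srt) - findInterval(t_obs - 1e-12, srt)
  p <- (1 + ge) / (1 + length(srt))
  padj <- p.adjust(p, method = "BH")
  log2fc <- obs$diff
  pass <- padj < alpha & abs(log2fc) >= log2(fc_threshold)

  out <- data.frame(feature = rownames(x), log2fc = unname(log2fc),
                    p_value = unname(p), p_adjusted = unname(padj),
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    pass = unname(pass), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(keep)
  attr(out, "n_total") <- nrow(counts)
  attr(out, "n_permutations") <- length(null_splits)
  attr(out, "reference_level") <- levels(groups)[1]
  class(out) <- c("differential_result", "data.frame")
  out
}
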