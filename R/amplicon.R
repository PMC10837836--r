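# Compositional preprocessing of ASV tables.

#' Rarefy an ASV table to a fixed depth
#'
#' Each sample with total count >= \code{depth} is subsampled once,
#' without replacement, to exactly \code{depth} reads
#' (\code{vegan::rrarefy}); samples below the depth are dropped with a
#' warning naming them. One recorded draw (rather than an average over
#' draws) keeps downstream integer analyses exact and reproducible.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param depth target depth (positive integer).
#' @param seed RNG seed for the draw (optional; caller RNG restored).
#' @return rarefied \linkS4class{AsvExperiment}; every retained sample
#'   sums exactly to \code{depth}.
#' @export
rarefyCounts <- function(x, depth, seed = NULL) {
  stopifnot(is(x, "AsvExperiment"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- colSums(asvCounts(x))
  low <- totals < depth
  if (all(low)) stop("no sample reaches depth ", depth)
  if (any(low))
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(names(totals)[low], collapse = ", "))
  x <- x[, !low]
  cts <- asvCounts(x)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic
  # for "not count data"); integer ASV counts trip it spuriously
  rar <- withSeed(seed, withCallingHandlers(
    vegan::rrarefy(t(cts), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  out <- t(rar)
  dimnames(out) <- dimnames(cts)
  SummarizedExperiment::assay(x, "counts") <- out
  x
}

#' Relative abundances of an ASV table
#'
#' @param x an \linkS4class{AsvExperiment} or a feature-by-sample count
#'   matrix.
#' @return sample-by-feature matrix of proportions; each row sums to 1.
#'   Samples with zero total raise an error naming them.
#' @export
relativeAbundance <- function(x) {
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else x
  tot <- colSums(cts)
  if (any(tot <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(cts)[tot <= 0], collapse = ", "))
  t(sweep(cts, 2, tot, "/"))
}

#' Collapse ASV counts at a taxonomic rank
#'
#' Sums counts over ASVs sharing the same lineage down to \code{rank}.
#' ASVs unclassified at that rank (NA or empty, as happens below the
#' classifier's confidence cutoff) are pooled per parent lineage into an
#' \code{"unclassified_<parent>"} feature rather than discarded, so per
#' sample totals are conserved exactly.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return an \linkS4class{AsvExperiment} whose features are collapsed
#'   lineages.
#' @export
collapseTaxonomy <- function(x, rank) {
  stopifnot(is(x, "AsvExperiment"))
  if (!rank %in% .TAX_RANKS) stop("unknown rank: ", rank)
  lev <- match(rank, .TAX_RANKS)
  tax <- taxonomy(x)
  lin <- apply(tax[, seq_len(lev), drop = FALSE], 1, function(p) {
    p[is.na(p) | p == ""] <- NA
    if (is.na(p[lev])) {
      parent <- p[!is.na(p)]
      paste0("unclassified_",
             if (length(parent)) parent[length(parent)] else "root")
    } else paste(p, collapse = ";")
  })
  cts <- rowsum(asvCounts(x), lin)
  # carry forward the rank columns that define each collapsed feature
  first <- tax[!duplicated(lin), , drop = FALSE]
  rownames(first) <- lin[!duplicated(lin)]
  first <- first[rownames(cts), , drop = FALSE]
  if (lev < length(.TAX_RANKS))
    first[, (lev + 1L):length(.TAX_RANKS)] <- NA_character_
  unc <- startsWith(rownames(cts), "unclassified_")
  first[unc, lev] <- rownames(cts)[unc]
  AsvExperiment(cts, first, sampleData(x))
}

#' Filter features by minimum relative abundance in any sample
#'
#' Keeps features whose relative abundance reaches at least
#' \code{threshold} (inclusive) in one or more samples; the complement
#' of the low-abundance tail that inflates feature counts without
#' carrying community signal. The number of retained features and the
#' per-sample fraction of total abundance they represent are messaged
#' and stored in \code{metadata(x)$filter}.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param threshold proportion in [0, 1); e.g. 1e-4 for 0.01\%.
#' @return filtered \linkS4class{AsvExperiment}.
#' @export
filterMinRelAbundance <- function(x, threshold) {
  stopifnot(is(x, "AsvExperiment"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must be a proportion in [0, 1)")
  ra <- relativeAbundance(x)              # samples x features
  keep <- apply(ra, 2, max) >= threshold
  retained_fraction <- rowSums(ra[, keep, drop = FALSE])
  message(sum(keep), "/", length(keep), " features retained; ",
          "retained abundance per sample ",
          round(100 * min(retained_fraction), 1), "%-",
          round(100 * max(retained_fraction), 1), "%")
  out <- x[keep, ]
  S4Vectors::metadata(out)$filter <-
    list(threshold = threshold, n_retained = sum(keep),
         retained_fraction = retained_fraction)
  out
}
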