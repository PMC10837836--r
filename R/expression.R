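# ORF-level quantification chain: transcript expected counts ->
# length-apportioned peptide counts -> peptide TPM -> KO aggregation,
# plus TMM scaling factors and CPM for the differential arm.

#' Apportion transcript expected counts to peptides by length
#'
#' Bacterial transcripts commonly carry several ORFs; to quantify
#' proteins individually each transcript's expected count is divided
#' among its peptides proportionally to peptide length (amino acids):
#' \code{count(p,s) = count(t,s) * len(p) / sum(len(p') over p' in t)}.
#' Transcripts with counts but no annotation are dropped (tallied in the
#' returned object and messaged); annotation records whose transcript has
#' no counts are ignored likewise.
#'
#' @param tc transcript-by-sample expected count matrix.
#' @param ann ORF annotation data.frame with columns \code{transcript_id},
#'   \code{peptide_id}, \code{peptide_length} (aa), \code{ko}, \code{taxon}.
#' @return a \linkS4class{PeptideExpression} (TPM slot empty).
#' @examples
#' tc <- matrix(100, 1, 1, dimnames = list("t1", "S1"))
#' ann <- data.frame(transcript_id = "t1", peptide_id = c("p1", "p2"),
#'                   peptide_length = c(100, 300), ko = NA, taxon = NA)
#' apportioned(apportionCounts(tc, ann))   # 25 and 75
#' @export
apportionCounts <- function(tc, ann) {
  .assertCountMatrix(tc, "transcript counts")
  need <- c("transcript_id", "peptide_id", "peptide_length")
  if (!all(need %in% names(ann)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$peptide_id)) stop("peptide ids must be unique")
  if (any(ann$peptide_length < 1)) stop("peptide lengths must be >= 1")

  orphan <- !(ann$transcript_id %in% rownames(tc))
  if (any(orphan)) {
    message(sum(orphan), " annotation records without transcript counts ignored")
    ann <- ann[!orphan, , drop = FALSE]
  }
  annotated_tx <- unique(ann$transcript_id)
  dropped <- setdiff(rownames(tc), annotated_tx)
  if (length(dropped))
    message(length(dropped), " transcripts without ORF annotation dropped")
  if (!nrow(ann)) stop("no annotated transcripts left to apportion")

  len <- as.numeric(ann$peptide_length)
  tot <- rowsum(len, ann$transcript_id)
  tx_tot <- setNames(tot[, 1], rownames(tot))
  if (any(tx_tot <= 0))
    stop("zero total peptide length for transcript ",
         names(tx_tot)[tx_tot <= 0][1])
  frac <- len / tx_tot[ann$transcript_id]
  pc <- tc[ann$transcript_id, , drop = FALSE] * frac
  rownames(pc) <- ann$peptide_id
  new("PeptideExpression",
      counts = pc, tpm = matrix(numeric(), 0, 0),
      length = setNames(len, ann$peptide_id),
      nDroppedTranscripts = length(dropped),
      nOrphanRecords = as.integer(sum(orphan)))
}

#' Convert apportioned peptide counts to TPM
#'
#' Standard TPM on peptides: per-length read rate
#' \code{count(p,s)/len(p)}, normalized per sample to sum to 1e6.
#' Lengths are in amino acids throughout; since TPM is a within-sample
#' proportion, the aa-vs-nt factor of 3 cancels.
#'
#' @param pe a \linkS4class{PeptideExpression} from
#'   \code{\link{apportionCounts}}.
#' @return the object with the \code{tpm} slot filled.
#' @export
peptideTpm <- function(pe) {
  stopifnot(is(pe, "PeptideExpression"))
  rate <- pe@counts / pe@length
  cs <- colSums(rate)
  if (any(cs <= 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(rate)[cs <= 0], collapse = ", "))
  pe@tpm <- sweep(rate, 2, cs, "/") * 1e6
  validObject(pe)
  pe
}

#' Aggregate peptide TPM to KO terms
#'
#' Peptides annotated with the same KEGG Orthology term are summed into
#' one aggregated expression value per sample; aTPM is the unweighted
#' arithmetic mean across samples. Peptides without a KO are pooled into
#' a per-sample unannotated mass (kept so that KO TPM plus unannotated
#' mass always reconstitutes the 1e6 column total).
#'
#' @param pe a \linkS4class{PeptideExpression} with TPM computed.
#' @param ann ORF annotation data.frame (column \code{ko}, NA allowed).
#' @return a \linkS4class{KoExpression}.
#' @export
aggregateToKo <- function(pe, ann) {
  stopifnot(is(pe, "PeptideExpression"))
  if (!nrow(pe@tpm)) stop("TPM not computed; run peptideTpm() first")
  ko <- ann$ko[match(rownames(pe@tpm), ann$peptide_id)]
  keep <- !is.na(ko)
  message(sum(!keep), " peptides without KO annotation pooled as unannotated")
  ko_tpm <- if (any(keep)) rowsum(pe@tpm[keep, , drop = FALSE], ko[keep])
            else matrix(numeric(), 0, ncol(pe@tpm),
                        dimnames = list(NULL, colnames(pe@tpm)))
  unann <- if (any(!keep)) colSums(pe@tpm[!keep, , drop = FALSE])
           else setNames(numeric(ncol(pe@tpm)), colnames(pe@tpm))
  new("KoExpression", tpm = ko_tpm, atpm = rowMeans(ko_tpm),
      unannotated = unann)
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values between-sample normalization factors as
#' defined for edgeR (weighted trimmed mean of log-ratios against a
#' reference sample, doubly trimmed on M and A, factors re-centred to
#' geometric mean 1). The reference is the sample whose 75th-percentile
#' count fraction is closest to the mean across samples. Computation is
#' delegated to \code{edgeR::calcNormFactors}.
#'
#' @param counts feature-by-sample count matrix (>= 2 samples, no empty
#'   library).
#' @param trim_M two-sided trim proportion on log-ratios (default 0.30).
#' @param trim_A two-sided trim proportion on mean log-abundance
#'   (default 0.05).
#' @return object of class \code{TmmFactors}: list with \code{factors}
#'   (named, geometric mean 1) and \code{ref} (reference sample id).
#' @export
tmmFactors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  .assertCountMatrix(counts, "counts")
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("empty library: ", paste(colnames(counts)[lib <= 0], collapse = ", "))
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  shared <- colSums(counts > 0 & counts[, ref] > 0)
  if (any(shared == 0))
    stop("sample sharing no expressed features with reference: ",
         paste(colnames(counts)[shared == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = trim_M, sumTrim = trim_A)
  f <- f / .geomean(f)
  structure(list(factors = setNames(f, colnames(counts)),
                 ref = colnames(counts)[ref]),
            class = "TmmFactors")
}

#' @export
print.TmmFactors <- function(x, ...) {
  cat("TMM factors (ref:", x$ref, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Counts per million with optional TMM factors
#'
#' \code{cpm(f,s) = count(f,s) / (libsize_s * factor_s) * 1e6}. A sample
#' with an all-zero column yields zeros.
#'
#' @param counts feature-by-sample count matrix.
#' @param factors a \code{TmmFactors} object, a named numeric vector, or
#'   NULL for plain library-size CPM.
#' @return numeric matrix of the same shape.
#' @export
cpmMatrix <- function(counts, factors = NULL) {
  .assertCountMatrix(counts, "counts")
  f <- if (is.null(factors)) rep(1, ncol(counts))
       else if (inherits(factors, "TmmFactors")) factors$factors[colnames(counts)]
       else factors[colnames(counts)]
  if (anyNA(f)) stop("factors do not cover all samples")
  eff <- colSums(counts) * f
  out <- counts
  nz <- eff > 0
  out[, nz] <- sweep(counts[, nz, drop = FALSE], 2, eff[nz], "/") * 1e6
  out[, !nz] <- 0
  out
}
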