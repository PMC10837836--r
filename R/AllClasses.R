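#' @import methods
#' @importFrom stats aov anova as.dist dist p.adjust quantile rgamma rlnorm
#'   rmultinom rpois runif sd var cmdscale median setNames
#' @importFrom utils head combn read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' AsvExperiment: an ASV count table with taxonomy and sample metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a
#' non-negative integer ASV-by-sample count matrix in the \code{"counts"}
#' assay, per-ASV taxonomic lineages (ranks domain through genus) in
#' \code{rowData}, and per-sample metadata (\code{species},
#' \code{location}, \code{habitat}) in \code{colData}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases AsvExperiment-class
#' @exportClass AsvExperiment
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts) || any(cts < 0))
      msg <- c(msg, "counts must be non-negative and complete")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("species", "location", "habitat")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(.TAX_RANKS %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain ranks:",
                        paste(.TAX_RANKS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an AsvExperiment
#'
#' @param counts ASV-by-sample non-negative count matrix with dimnames.
#' @param taxonomy either a data.frame with columns
#'   \code{domain,phylum,class,order,family,genus} and one row per ASV
#'   (rownames = ASV ids), or a character vector of semicolon-separated
#'   lineages named by ASV id.
#' @param metadata data.frame with columns \code{species}, \code{location},
#'   \code{habitat} and rownames = sample ids.
#' @return an \linkS4class{AsvExperiment}.
#' @examples
#' cts <- matrix(rpois(12, 50), 4, 3,
#'               dimnames = list(paste0("ASV", 1:4), paste0("S", 1:3)))
#' tax <- setNames(rep("Bacteria;Chloroflexi;Dehalococcoidia;;;", 4),
#'                 rownames(cts))
#' md <- data.frame(species = "sp1", location = "L1", habitat = "deep",
#'                  row.names = colnames(cts))
#' ae <- AsvExperiment(cts, tax, md)
#' @export
AsvExperiment <- function(counts, taxonomy, metadata) {
  .assertCountMatrix(counts, "ASV counts")
  if (is.character(taxonomy)) taxonomy <- .lineageToRanks(taxonomy)
  .checkIds(rownames(taxonomy), rownames(counts), "ASV ids in taxonomy")
  .checkIds(rownames(metadata), colnames(counts), "sample ids in metadata")
  taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  metadata <- metadata[colnames(counts), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy),
    colData = S4Vectors::DataFrame(metadata))
  new("AsvExperiment", se)
}

# split "Bacteria;Chloroflexi;...;genus" lineages into rank columns
.lineageToRanks <- function(lin) {
  parts <- strsplit(lin, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(.TAX_RANKS)
    p
  }, character(length(.TAX_RANKS))))
  m[is.na(m) | m == ""] <- NA_character_
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- .TAX_RANKS
  rownames(df) <- names(lin)
  df
}

#' Peptide-level expression (apportioned counts and TPM)
#'
#' Holds transcript expected counts apportioned to individual peptides
#' (ORFs) proportionally to peptide length, and the derived peptide TPM
#' matrix. Columns are samples, rows are peptide ids.
#'
#' @slot counts apportioned expected counts (peptides x samples).
#' @slot tpm peptide TPM (filled by \code{\link{peptideTpm}}; may be a
#'   0-row matrix before that).
#' @slot length peptide lengths in amino acids, named by peptide id.
#' @slot nDroppedTranscripts number of transcripts with counts but no
#'   annotation (excluded, tallied).
#' @slot nOrphanRecords number of annotation records whose transcript has
#'   no counts (ignored, tallied).
#' @exportClass PeptideExpression
setClass("PeptideExpression", representation(
  counts = "matrix", tpm = "matrix", length = "numeric",
  nDroppedTranscripts = "integer", nOrphanRecords = "integer"))

setValidity("PeptideExpression", function(object) {
  msg <- character()
  if (length(object@length) != nrow(object@counts))
    msg <- c(msg, "one length per peptide required")
  if (any(object@length < 1)) msg <- c(msg, "peptide lengths must be >= 1")
  if (nrow(object@tpm) > 0 && !identical(dim(object@tpm), dim(object@counts)))
    msg <- c(msg, "tpm and counts dimensions differ")
  if (length(msg)) msg else TRUE
})

#' KO-level aggregated expression
#'
#' @slot tpm KO-by-sample TPM matrix (sum of member-peptide TPM).
#' @slot atpm per-KO arithmetic mean of TPM across samples.
#' @slot unannotated per-sample TPM mass carried by peptides without a KO.
#' @exportClass KoExpression
setClass("KoExpression", representation(
  tpm = "matrix", atpm = "numeric", unannotated = "numeric"))

setValidity("KoExpression", function(object) {
  msg <- character()
  if (length(object@atpm) != nrow(object@tpm))
    msg <- c(msg, "one aTPM value per KO required")
  if (nrow(object@tpm) > 0 &&
      max(abs(object@atpm - rowMeans(object@tpm))) > 1e-6)
    msg <- c(msg, "atpm must equal rowMeans(tpm)")
  if (length(object@unannotated) != ncol(object@tpm))
    msg <- c(msg, "one unannotated mass per sample required")
  if (length(msg)) msg else TRUE
})

#' A catalog of KEGG-style module definitions
#'
#' @slot entries data.frame with columns \code{module_id}, \code{name},
#'   \code{level_B}, \code{level_C}, \code{definition}.
#' @slot trees named list of parsed definition trees (see
#'   \code{\link{parseDefinition}}), one per module, eagerly validated.
#' @exportClass ModuleCatalog
setClass("ModuleCatalog", representation(entries = "data.frame", trees = "list"))

setValidity("ModuleCatalog", function(object) {
  msg <- character()
  need <- c("module_id", "name", "level_B", "level_C", "definition")
  if (!all(need %in% colnames(object@entries)))
    msg <- c(msg, paste("entries must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@entries$module_id))
      msg <- c(msg, "module ids must be unique")
    if (!identical(names(object@trees), object@entries$module_id))
      msg <- c(msg, "trees must be named by module_id, in entry order")
  }
  if (length(msg)) msg else TRUE
})

#' Module-level expression profile with completeness
#'
#' @slot expression module-by-sample TPM matrix.
#' @slot atpm per-module mean TPM across samples.
#' @slot complete logical completeness call per module.
#' @slot fraction fraction of (non-optional) steps satisfied per module.
#' @slot hierarchy data.frame with \code{module_id}, \code{level_B},
#'   \code{level_C}.
#' @slot taxonSplit optional long data.frame (\code{module_id},
#'   \code{taxon}, \code{sample}, \code{tpm}); 0 rows when absent.
#' @exportClass ModuleProfile
setClass("ModuleProfile", representation(
  expression = "matrix", atpm = "numeric", complete = "logical",
  fraction = "numeric", hierarchy = "data.frame", taxonSplit = "data.frame"))

setValidity("ModuleProfile", function(object) {
  msg <- character()
  n <- nrow(object@expression)
  if (length(object@atpm) != n || length(object@complete) != n ||
      length(object@fraction) != n)
    msg <- c(msg, "per-module slots must align with the expression matrix")
  if (any(object@expression < 0)) msg <- c(msg, "expression must be >= 0")
  if (n > 0 && !identical(object@complete, unname(object@fraction == 1)))
    msg <- c(msg, "complete must hold exactly when all steps are satisfied")
  if (length(msg)) msg else TRUE
})

#' A simulated holobiont dataset with planted ground truth
#'
#' @slot asv an \linkS4class{AsvExperiment}.
#' @slot transcriptCounts transcript-by-sample expected-count matrix.
#' @slot orfAnnotation data.frame of transcript/peptide/KO/taxon records.
#' @slot truth list recording planted differential features, group-effect
#'   ASVs, complete module ids and withheld KOs.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset", representation(
  asv = "AsvExperiment", transcriptCounts = "matrix",
  orfAnnotation = "data.frame", truth = "list"))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (!identical(colnames(object@asv), colnames(object@transcriptCounts)))
    msg <- c(msg, "ASV and transcript matrices must share sample ids")
  td <- object@truth$differential
  if (!is.null(td) &&
      !all(td$transcript_id %in% rownames(object@transcriptCounts)))
    msg <- c(msg, "truth differential ids must be generated transcripts")
  if (length(msg)) msg else TRUE
})
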