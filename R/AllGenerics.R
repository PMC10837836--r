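#' Accessors for spongefunc containers
#'
#' Small accessor generics so that user code never touches slots:
#' \code{asvCounts} returns the ASV count matrix, \code{taxonomy} the
#' rank table, \code{sampleData} the sample metadata, \code{tpm} the
#' TPM matrix of a \linkS4class{PeptideExpression},
#' \linkS4class{KoExpression} or \linkS4class{ModuleProfile},
#' \code{atpm} the across-sample mean expression, \code{apportioned}
#' the length-apportioned counts, \code{unannotatedMass} the per-sample
#' TPM mass without KO annotation, \code{moduleComplete} /
#' \code{moduleFraction} the completeness calls, \code{catalogEntries} /
#' \code{moduleTrees} the catalog content, and \code{truth} the planted
#' ground truth of a \linkS4class{SyntheticDataset}.
#'
#' @param x an object of the documented class.
#' @return see the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("asvCounts", function(x) standardGeneric("asvCounts"))
#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))
#' @rdname accessors
#' @export
setGeneric("atpm", function(x) standardGeneric("atpm"))
#' @rdname accessors
#' @export
setGeneric("apportioned", function(x) standardGeneric("apportioned"))
#' @rdname accessors
#' @export
setGeneric("unannotatedMass", function(x) standardGeneric("unannotatedMass"))
#' @rdname accessors
#' @export
setGeneric("moduleComplete", function(x) standardGeneric("moduleComplete"))
#' @rdname accessors
#' @export
setGeneric("moduleFraction", function(x) standardGeneric("moduleFraction"))
#' @rdname accessors
#' @export
setGeneric("moduleHierarchy", function(x) standardGeneric("moduleHierarchy"))
#' @rdname accessors
#' @export
setGeneric("taxonSplit", function(x) standardGeneric("taxonSplit"))
#' @rdname accessors
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))
#' @rdname accessors
#' @export
setGeneric("moduleTrees", function(x) standardGeneric("moduleTrees"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname accessors
#' @export
setMethod("asvCounts", "AsvExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("taxonomy", "AsvExperiment", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)[, .TAX_RANKS, drop = FALSE]))

#' @rdname accessors
#' @export
setMethod("sampleData", "AsvExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setMethod("tpm", "PeptideExpression", function(x) x@tpm)
#' @rdname accessors
#' @export
setMethod("tpm", "KoExpression", function(x) x@tpm)
#' @rdname accessors
#' @export
setMethod("tpm", "ModuleProfile", function(x) x@expression)
#' @rdname accessors
#' @export
setMethod("atpm", "KoExpression", function(x) x@atpm)
#' @rdname accessors
#' @export
setMethod("atpm", "ModuleProfile", function(x) x@atpm)
#' @rdname accessors
#' @export
setMethod("apportioned", "PeptideExpression", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("unannotatedMass", "KoExpression", function(x) x@unannotated)
#' @rdname accessors
#' @export
setMethod("moduleComplete", "ModuleProfile", function(x)
  setNames(x@complete, rownames(x@expression)))
#' @rdname accessors
#' @export
setMethod("moduleFraction", "ModuleProfile", function(x)
  setNames(x@fraction, rownames(x@expression)))
#' @rdname accessors
#' @export
setMethod("moduleHierarchy", "ModuleProfile", function(x) x@hierarchy)
#' @rdname accessors
#' @export
setMethod("taxonSplit", "ModuleProfile", function(x) x@taxonSplit)
#' @rdname accessors
#' @export
setMethod("catalogEntries", "ModuleCatalog", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("moduleTrees", "ModuleCatalog", function(x) x@trees)
#' @rdname accessors
#' @export
setMethod("truth", "SyntheticDataset", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("asvCounts", "SyntheticDataset", function(x) asvCounts(x@asv))

#' @rdname accessors
#' @export
setGeneric("asvExperiment", function(x) standardGeneric("asvExperiment"))
#' @rdname accessors
#' @export
setMethod("asvExperiment", "SyntheticDataset", function(x) x@asv)
#' @rdname accessors
#' @export
setGeneric("transcriptCounts", function(x) standardGeneric("transcriptCounts"))
#' @rdname accessors
#' @export
setMethod("transcriptCounts", "SyntheticDataset", function(x) x@transcriptCounts)
#' @rdname accessors
#' @export
setGeneric("orfAnnotation", function(x) standardGeneric("orfAnnotation"))
#' @rdname accessors
#' @export
setMethod("orfAnnotation", "SyntheticDataset", function(x) x@orfAnnotation)

setMethod("show", "PeptideExpression", function(object) {
  cat("PeptideExpression:", nrow(object@counts), "peptides x",
      ncol(object@counts), "samples\n")
  cat("  TPM computed:", nrow(object@tpm) > 0, "\n")
  cat("  transcripts without annotation (dropped):",
      object@nDroppedTranscripts, "\n")
  cat("  annotation records without counts (ignored):",
      object@nOrphanRecords, "\n")
})

setMethod("show", "KoExpression", function(object) {
  cat("KoExpression:", nrow(object@tpm), "KO terms x", ncol(object@tpm),
      "samples\n")
  cat("  unannotated TPM mass per sample: mean",
      round(mean(object@unannotated), 1), "\n")
})

setMethod("show", "ModuleCatalog", function(object) {
  cat("ModuleCatalog:", nrow(object@entries), "modules,",
      length(unique(object@entries$level_C)), "level-C categories\n")
})

setMethod("show", "ModuleProfile", function(object) {
  cat("ModuleProfile:", nrow(object@expression), "modules x",
      ncol(object@expression), "samples;",
      sum(object@complete), "complete\n")
  if (nrow(object@taxonSplit)) cat("  taxon split attached\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nrow(object@asv), "ASVs,",
      nrow(object@transcriptCounts), "transcripts,",
      ncol(object@asv), "samples\n")
  cat("  planted differential features:",
      NROW(object@truth$differential), "\n")
})
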