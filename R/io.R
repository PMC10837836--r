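# Tabular interchange formats. All files are UTF-8 TSV with a header row,
# no quoting, and the literal string NA for missing KO/taxon fields.

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, quote = "",
             check.names = FALSE, stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path, rowname_col = NULL) {
  if (!is.null(rowname_col)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rowname_col), df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ASV table from three TSV files
#'
#' \code{counts_path} holds the sample-by-ASV count table (first column
#' \code{sample_id}, remaining columns one per ASV); \code{taxonomy_path}
#' holds one row per ASV with columns \code{asv_id} and either a
#' \code{lineage} column (semicolon-separated ranks) or the six rank
#' columns; \code{metadata_path} holds \code{sample_id}, \code{species},
#' \code{location}, \code{habitat}. Sample or ASV id mismatches between
#' the files raise errors naming the offending ids; negative counts and
#' duplicated ids are rejected.
#'
#' @param counts_path,taxonomy_path,metadata_path TSV file paths.
#' @return an \linkS4class{AsvExperiment} (ASVs in rows).
#' @seealso \code{\link{writeAsvTable}}
#' @export
readAsvTable <- function(counts_path, taxonomy_path, metadata_path) {
  cts <- .readTsv(counts_path)
  if (ncol(cts) < 2) stop("counts table needs sample_id plus ASV columns")
  sample_ids <- as.character(cts[[1]])
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids in counts: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  m <- as.matrix(cts[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count values in ", counts_path)
  if (anyNA(m)) stop("missing count values in ", counts_path)
  if (any(m < 0)) stop("negative counts in ", counts_path)
  counts <- t(m)                       # store ASVs x samples
  colnames(counts) <- sample_ids
  if (anyDuplicated(rownames(counts)))
    stop("duplicated ASV ids in counts header")

  tax <- .readTsv(taxonomy_path)
  if (!"asv_id" %in% names(tax)) stop("taxonomy needs an asv_id column")
  if (anyDuplicated(tax$asv_id)) stop("duplicated ASV ids in taxonomy")
  if ("lineage" %in% names(tax)) {
    taxdf <- .lineageToRanks(setNames(as.character(tax$lineage), tax$asv_id))
  } else {
    .checkIds(names(tax), c("asv_id", .TAX_RANKS), "taxonomy columns")
    taxdf <- tax[, .TAX_RANKS, drop = FALSE]
    rownames(taxdf) <- tax$asv_id
  }

  md <- .readTsv(metadata_path)
  need <- c("sample_id", "species", "location", "habitat")
  if (!all(need %in% names(md)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicated sample ids in metadata")
  mdf <- md[, setdiff(names(md), "sample_id"), drop = FALSE]
  rownames(mdf) <- md$sample_id

  AsvExperiment(counts, taxdf, mdf)
}

#' Write an AsvExperiment to the three-file TSV layout
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param counts_path,taxonomy_path,metadata_path output TSV paths.
#' @return the three paths, invisibly.
#' @export
writeAsvTable <- function(x, counts_path, taxonomy_path, metadata_path) {
  cts <- as.data.frame(t(asvCounts(x)))
  .writeTsv(cts, counts_path, rowname_col = "sample_id")
  tax <- taxonomy(x)
  .writeTsv(tax, taxonomy_path, rowname_col = "asv_id")
  md <- sampleData(x)
  .writeTsv(md, metadata_path, rowname_col = "sample_id")
  invisible(c(counts_path, taxonomy_path, metadata_path))
}

#' Read/write a transcript expected-count matrix
#'
#' The TSV has one row per transcript (first column \code{transcript_id},
#' remaining columns one per sample). Values must be finite and
#' non-negative; expected counts from upstream mapping may be fractional.
#'
#' @param path TSV file path.
#' @return numeric matrix, transcripts x samples.
#' @export
readTranscriptCounts <- function(path) {
  df <- .readTsv(path)
  if (anyDuplicated(df[[1]])) stop("duplicated transcript ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("transcript counts must be finite numbers")
  if (any(m < 0)) stop("negative transcript counts in ", path)
  m
}

#' @rdname readTranscriptCounts
#' @param x transcript count matrix.
#' @export
writeTranscriptCounts <- function(x, path) {
  .writeTsv(as.data.frame(x), path, rowname_col = "transcript_id")
}

#' Read/write ORF annotation records
#'
#' Columns: \code{transcript_id}, \code{peptide_id}, \code{peptide_length}
#' (amino acids, >= 1), \code{ko} (NA when unannotated), \code{taxon}
#' (semicolon-separated lineage, NA when unannotated).
#'
#' @param path TSV file path.
#' @return data.frame of annotation records.
#' @export
readOrfAnnotation <- function(path) {
  df <- .readTsv(path)
  need <- c("transcript_id", "peptide_id", "peptide_length", "ko", "taxon")
  if (!all(need %in% names(df)))
    stop("ORF annotation needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$peptide_id))
    stop("duplicated peptide ids: ",
         paste(head(unique(df$peptide_id[duplicated(df$peptide_id)]), 5),
               collapse = ", "))
  if (anyNA(df$peptide_length) || any(df$peptide_length < 1))
    stop("peptide_length must be >= 1 amino acids")
  df$ko[df$ko %in% c("", "NA")] <- NA_character_
  df$taxon[df$taxon %in% c("", "NA")] <- NA_character_
  df
}

#' @rdname readOrfAnnotation
#' @param x ORF annotation data.frame.
#' @export
writeOrfAnnotation <- function(x, path) {
  .writeTsv(x, path)
}

#' Read a module catalog from flat text
#'
#' One entry per line: \code{module_id TAB name TAB level_B TAB level_C
#' TAB definition}. Every definition is parsed eagerly under the module
#' grammar (see \code{\link{parseDefinition}}); a malformed definition
#' aborts the read with the module id and offending position.
#'
#' @param path flat-text file path (a header line is optional and
#'   detected by a leading \code{module_id} field).
#' @return a \linkS4class{ModuleCatalog}.
#' @export
readModuleCatalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[[1]], "module_id"))
    lines <- lines[-1]
  if (!length(lines)) return(moduleCatalog(
    data.frame(module_id = character(), name = character(),
               level_B = character(), level_C = character(),
               definition = character(), stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop("catalog line ", bad[1], " does not have 5 tab-separated fields")
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- c("module_id", "name", "level_B", "level_C", "definition")
  moduleCatalog(df)
}

#' Build a ModuleCatalog from a definition table
#'
#' @param entries data.frame with columns \code{module_id}, \code{name},
#'   \code{level_B}, \code{level_C}, \code{definition}.
#' @return a \linkS4class{ModuleCatalog} with all definitions parsed.
#' @export
moduleCatalog <- function(entries) {
  if (anyDuplicated(entries$module_id))
    stop("duplicated module ids: ",
         paste(unique(entries$module_id[duplicated(entries$module_id)]),
               collapse = ", "))
  trees <- lapply(seq_len(nrow(entries)), function(i) {
    tryCatch(parseDefinition(entries$definition[i]),
             error = function(e) stop("module ", entries$module_id[i], ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(trees) <- entries$module_id
  rownames(entries) <- NULL
  new("ModuleCatalog", entries = entries, trees = trees)
}

#' @rdname readModuleCatalog
#' @param x a \linkS4class{ModuleCatalog}.
#' @export
writeModuleCatalog <- function(x, path) {
  .writeTsv(catalogEntries(x), path)
}

#' Read/write the planted-truth sidecar of a simulated dataset
#'
#' @param path JSON file path.
#' @return for \code{readTruth}, the truth list.
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname readTruth
#' @param x truth list from a \linkS4class{SyntheticDataset}.
#' @export
writeTruth <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
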