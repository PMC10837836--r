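# KEGG-style module definitions and completeness evaluation.
#
# Grammar (tightest binding first):
#   '+' complex        all components required
#   '-' optional       component never required (non-essential subunit)
#   ',' alternative    any one branch suffices
#   ' ' step sequence  all steps required
#   '(...)'            grouping overrides precedence
# Leaves are KO identifiers. A module is complete when every
# non-optional step is satisfied by the present-KO set.

.NODE <- function(type, children = list(), ko = NULL)
  structure(list(type = type, children = children, ko = ko),
            class = "ModuleExpr")

#' Parse a module definition string
#'
#' Parses a KEGG-style definition ("K00169+K00170 K01007",
#' "(K1,K2)+K3", ...) into a tree of nodes of types \code{seq} (ordered
#' steps, all required), \code{alt} (any branch suffices), \code{cpx}
#' (protein complex, all subunits required), \code{opt} (optional
#' component, never required) and \code{leaf} (a KO identifier).
#' Operator precedence, tightest first: \code{+}/\code{-}, then
#' \code{,}, then space; parentheses group.
#'
#' @param s a non-empty definition string.
#' @return the parse tree, class \code{ModuleExpr}. The top node is
#'   always a \code{seq} whose children are the module's steps.
#' @examples
#' parseDefinition("K00001")
#' parseDefinition("K00169+K00170 K01007,K01008")
#' @seealso \code{\link{serializeDefinition}},
#'   \code{\link{evaluateCompleteness}}
#' @export
parseDefinition <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(trimws(s)))
    stop("definition must be a non-empty string")
  toks <- .tokenizeDefinition(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  node <- .parseSeq(st)
  if (st$i <= length(st$toks))
    stop("unexpected token '", st$toks[[st$i]]$text, "' at position ",
         st$toks[[st$i]]$pos)
  if (!identical(node$type, "seq")) node <- .NODE("seq", list(node))
  node
}

.tokenizeDefinition <- function(s) {
  chars <- strsplit(s, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == " ") {
      # collapse runs of spaces into one step separator
      if (length(toks) && toks[[length(toks)]]$text != " ")
        toks[[length(toks) + 1L]] <- list(text = " ", pos = i)
      i <- i + 1L
    } else if (ch %in% c("(", ")", "+", "-", ",")) {
      toks[[length(toks) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
    } else if (grepl("[A-Za-z0-9_.]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.]", chars[j])) j <- j + 1L
      toks[[length(toks) + 1L]] <-
        list(text = paste(chars[i:(j - 1L)], collapse = ""), pos = i)
      i <- j
    } else {
      stop("invalid character '", ch, "' at position ", i)
    }
  }
  # trim leading/trailing step separators
  while (length(toks) && toks[[1]]$text == " ") toks <- toks[-1]
  while (length(toks) && toks[[length(toks)]]$text == " ")
    toks <- toks[-length(toks)]
  if (!length(toks)) stop("empty definition")
  toks
}

.peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]]$text else NULL
.pos <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]]$pos else -1L

.parseSeq <- function(st) {
  children <- list(.parseAlt(st))
  while (identical(.peek(st), " ")) {
    st$i <- st$i + 1L
    children[[length(children) + 1L]] <- .parseAlt(st)
  }
  if (length(children) == 1L) children[[1]] else .NODE("seq", children)
}

.parseAlt <- function(st) {
  children <- list(.parseCpx(st))
  while (identical(.peek(st), ",")) {
    st$i <- st$i + 1L
    children[[length(children) + 1L]] <- .parseCpx(st)
  }
  if (length(children) == 1L) children[[1]] else .NODE("alt", children)
}

.parseCpx <- function(st) {
  children <- list(.parseUnit(st))
  while (!is.null(.peek(st)) && .peek(st) %in% c("+", "-")) {
    op <- .peek(st)
    st$i <- st$i + 1L
    unit <- .parseUnit(st)
    if (op == "-") unit <- .NODE("opt", list(unit))
    children[[length(children) + 1L]] <- unit
  }
  if (length(children) == 1L) children[[1]] else .NODE("cpx", children)
}

.parseUnit <- function(st) {
  tok <- .peek(st)
  if (is.null(tok))
    stop("dangling operator at end of definition")
  if (tok == "(") {
    open_pos <- .pos(st)
    st$i <- st$i + 1L
    node <- .parseSeq(st)
    if (!identical(.peek(st), ")"))
      stop("unbalanced parenthesis opened at position ", open_pos)
    st$i <- st$i + 1L
    return(node)
  }
  if (tok %in% c(")", "+", "-", ",", " "))
    stop("unexpected '", tok, "' at position ", .pos(st))
  st$i <- st$i + 1L
  .NODE("leaf", ko = tok)
}

#' Serialize a parse tree back to a definition string
#'
#' Inverse of \code{\link{parseDefinition}} up to semantic equivalence:
#' re-parsing the output yields a tree with identical satisfying KO sets.
#'
#' @param node a \code{ModuleExpr} tree.
#' @return definition string.
#' @export
serializeDefinition <- function(node) {
  ser <- function(nd, ctx) {
    switch(nd$type,
      leaf = nd$ko,
      opt  = ser(nd$children[[1]], "cpx"),
      seq  = {
        s <- paste(vapply(nd$children, ser, "", ctx = "seq"), collapse = " ")
        if (ctx %in% c("alt", "cpx")) paste0("(", s, ")") else s
      },
      alt  = {
        s <- paste(vapply(nd$children, ser, "", ctx = "alt"), collapse = ",")
        if (ctx == "cpx") paste0("(", s, ")") else s
      },
      cpx  = {
        parts <- vapply(seq_along(nd$children), function(i) {
          ch <- nd$children[[i]]
          op <- if (i == 1L) "" else if (identical(ch$type, "opt")) "-" else "+"
          paste0(op, ser(ch, "cpx"))
        }, "")
        paste(parts, collapse = "")
      },
      stop("unknown node type: ", nd$type))
  }
  ser(node, "top")
}

# satisfaction of one node against a present-KO set
.satisfied <- function(node, present) {
  switch(node$type,
    leaf = node$ko %in% present,
    opt  = TRUE,
    alt  = any(vapply(node$children, .satisfied, TRUE, present = present)),
    cpx  = all(vapply(node$children, .satisfied, TRUE, present = present)),
    seq  = all(vapply(node$children, .satisfied, TRUE, present = present)),
    stop("unknown node type: ", node$type))
}

#' Evaluate module completeness against a set of present KOs
#'
#' A step (top-level child of the definition's step sequence) is
#' satisfied when its expression evaluates true under: leaf = KO present,
#' complex = all non-optional subunits satisfied, alternative = any
#' branch satisfied, optional = always satisfied. The module is complete
#' when every step is satisfied; the returned fraction is the proportion
#' of satisfied steps (steps that are entirely optional are excluded
#' from the count).
#'
#' @param expr a \code{ModuleExpr} from \code{\link{parseDefinition}}, or
#'   a definition string (parsed on the fly).
#' @param present character vector of present KO identifiers.
#' @return list with elements \code{complete} (logical) and
#'   \code{fraction} (satisfied steps / counted steps).
#' @examples
#' evaluateCompleteness("K1,K2", "K2")          # alternatives: complete
#' evaluateCompleteness("(K1+K2) K3", c("K1", "K3"))  # fraction 0.5
#' @export
evaluateCompleteness <- function(expr, present) {
  if (is.character(expr)) expr <- parseDefinition(expr)
  steps <- if (identical(expr$type, "seq")) expr$children else list(expr)
  counted <- !vapply(steps, function(s) identical(s$type, "opt"), TRUE)
  steps <- steps[counted]
  if (!length(steps)) return(list(complete = TRUE, fraction = 1))
  sat <- vapply(steps, .satisfied, TRUE, present = present)
  list(complete = all(sat), fraction = mean(sat))
}

# all KO ids appearing in a tree; optionally skipping optional subtrees
.leafKos <- function(node, skip_optional = FALSE) {
  if (identical(node$type, "leaf")) return(node$ko)
  if (skip_optional && identical(node$type, "opt")) return(character())
  unique(unlist(lapply(node$children, .leafKos, skip_optional = skip_optional)))
}

#' KOs required for a guaranteed-complete module
#'
#' The set of all non-optional leaf KOs; expressing every one of them
#' satisfies each step regardless of the alternative structure.
#' @param expr parse tree or definition string.
#' @return character vector of KO ids.
#' @export
requiredKos <- function(expr) {
  if (is.character(expr)) expr <- parseDefinition(expr)
  .leafKos(expr, skip_optional = TRUE)
}

#' Roll KO expression up to modules
#'
#' Each module's per-sample expression is the sum of the TPM of its
#' distinct leaf KOs (a KO listed twice inside one definition counts
#' once; a KO appearing in several modules contributes fully to each, so
#' module totals may exceed the sample TPM total). Completeness is
#' evaluated with "present" meaning TPM above \code{presence_threshold}
#' in at least one sample.
#'
#' @param ko a \linkS4class{KoExpression}.
#' @param catalog a \linkS4class{ModuleCatalog}.
#' @param presence_threshold TPM strictly above this counts as present
#'   (default 0).
#' @return a \linkS4class{ModuleProfile}.
#' @export
moduleExpression <- function(ko, catalog, presence_threshold = 0) {
  stopifnot(is(ko, "KoExpression"), is(catalog, "ModuleCatalog"))
  tpm_mat <- tpm(ko)
  present <- rownames(tpm_mat)[rowSums(tpm_mat > presence_threshold) >= 1L]
  entries <- catalogEntries(catalog)
  trees <- moduleTrees(catalog)
  nmod <- nrow(entries)
  expr <- matrix(0, nmod, ncol(tpm_mat),
                 dimnames = list(entries$module_id, colnames(tpm_mat)))
  complete <- logical(nmod)
  fraction <- numeric(nmod)
  for (i in seq_len(nmod)) {
    kos <- .leafKos(trees[[i]])
    hit <- intersect(kos, rownames(tpm_mat))
    if (length(hit))
      expr[i, ] <- colSums(tpm_mat[hit, , drop = FALSE])
    ev <- evaluateCompleteness(trees[[i]], present)
    complete[i] <- ev$complete
    fraction[i] <- ev$fraction
  }
  new("ModuleProfile",
      expression = expr, atpm = rowMeans(expr), complete = complete,
      fraction = fraction,
      hierarchy = entries[, c("module_id", "level_B", "level_C")],
      taxonSplit = .emptyTaxonSplit())
}

.emptyTaxonSplit <- function()
  data.frame(module_id = character(), taxon = character(),
             sample = character(), tpm = numeric(), stringsAsFactors = FALSE)

#' Sum module expression over a hierarchy level
#'
#' @param profile a \linkS4class{ModuleProfile}.
#' @param level \code{"level_B"} or \code{"level_C"}.
#' @return list with \code{expression} (label-by-sample matrix) and
#'   \code{atpm}.
#' @export
rollupHierarchy <- function(profile, level = c("level_C", "level_B")) {
  level <- match.arg(level)
  lab <- moduleHierarchy(profile)[[level]]
  ex <- rowsum(tpm(profile), lab)
  list(expression = ex, atpm = rowMeans(ex))
}

#' Split module expression by contributing taxon
#'
#' Decomposes KO TPM by the taxon (at \code{rank}) of the contributing
#' peptides before module rollup; peptides without a taxonomic
#' annotation are pooled as \code{"unclassified"}. Per module and sample
#' the taxon shares sum exactly to the module total.
#'
#' @param pe a \linkS4class{PeptideExpression} with TPM computed.
#' @param ann ORF annotation data.frame (see
#'   \code{\link{readOrfAnnotation}}).
#' @param catalog a \linkS4class{ModuleCatalog}.
#' @param rank lineage rank at which to split (default \code{"phylum"}).
#' @return long data.frame with columns \code{module_id}, \code{taxon},
#'   \code{sample}, \code{tpm}.
#' @export
taxonSplitExpression <- function(pe, ann, catalog, rank = "phylum") {
  stopifnot(is(pe, "PeptideExpression"))
  if (!rank %in% .TAX_RANKS) stop("unknown rank: ", rank)
  tpm_mat <- tpm(pe)
  if (!nrow(tpm_mat)) stop("peptide TPM not computed; run peptideTpm() first")
  idx <- match(rownames(tpm_mat), ann$peptide_id)
  ko <- ann$ko[idx]
  lev <- match(rank, .TAX_RANKS)
  tax <- vapply(strsplit(ifelse(is.na(ann$taxon[idx]), "", ann$taxon[idx]),
                         ";", fixed = TRUE),
                function(p) if (length(p) >= lev && nzchar(trimws(p[lev])))
                  trimws(p[lev]) else "unclassified", "")
  keep <- !is.na(ko)
  if (!any(keep)) return(.emptyTaxonSplit())
  key <- paste(ko[keep], tax[keep], sep = "\r")
  ko_tax <- rowsum(tpm_mat[keep, , drop = FALSE], key)
  parts <- strsplit(rownames(ko_tax), "\r", fixed = TRUE)
  kt_ko <- vapply(parts, `[`, "", 1L)
  kt_tax <- vapply(parts, `[`, "", 2L)

  entries <- catalogEntries(catalog)
  trees <- moduleTrees(catalog)
  out <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    kos <- .leafKos(trees[[i]])
    sel <- kt_ko %in% kos
    if (!any(sel)) next
    sub <- rowsum(ko_tax[sel, , drop = FALSE], kt_tax[sel])
    out[[i]] <- data.frame(
      module_id = entries$module_id[i],
      taxon = rep(rownames(sub), ncol(sub)),
      sample = rep(colnames(sub), each = nrow(sub)),
      tpm = as.vector(sub), stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(.emptyTaxonSplit())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attach a taxon split to a ModuleProfile
#'
#' @param profile a \linkS4class{ModuleProfile}.
#' @param split output of \code{\link{taxonSplitExpression}}.
#' @return the profile with the split stored.
#' @export
setTaxonSplit <- function(profile, split) {
  profile@taxonSplit <- split
  validObject(profile)
  profile
}

#' KO multiplicity across a catalog
#'
#' How many modules contain each KO (each module counted once however
#' often the KO recurs inside its definition), and the fraction of KOs
#' contained in more than one module -- the degree to which module-level
#' expression totals double-count shared enzymes.
#'
#' @param catalog a \linkS4class{ModuleCatalog}.
#' @return data.frame with columns \code{ko} and \code{n_modules},
#'   carrying the summary in \code{attr(, "fraction_multi")}.
#' @export
koMultiplicity <- function(catalog) {
  per_mod <- lapply(moduleTrees(catalog), .leafKos)
  tab <- table(unlist(per_mod))
  df <- data.frame(ko = names(tab), n_modules = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_modules, df$ko), ]
  rownames(df) <- NULL
  attr(df, "fraction_multi") <-
    if (nrow(df)) mean(df$n_modules > 1L) else 0
  df
}

#' @export
print.ModuleExpr <- function(x, ...) {
  cat("ModuleExpr:", serializeDefinition(x), "\n")
  invisible(x)
}
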