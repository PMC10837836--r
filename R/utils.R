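# Internal helpers shared across modules.

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' internals never disturb user-level reproducibility.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-stage substream seed from one master seed. Stages are
# isolated so that, e.g., regenerating the metatranscriptome does not
# perturb the ASV draw. Kept below 2^31 - 1.
substreamSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (abs(as.integer(seed)) * 7919 + 104729 * stage) %% 2147483647L
}

.assertCountMatrix <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, " contains missing or non-finite values", call. = FALSE)
  if (any(x < 0))
    stop(what, " contains negative values", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names", call. = FALSE)
  invisible(x)
}

.checkIds <- function(have, need, what) {
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing ", what, ": ", paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ..." else "", call. = FALSE)
  extra <- setdiff(have, need)
  if (length(extra))
    stop("unknown ", what, ": ", paste(utils::head(extra, 10L), collapse = ", "),
         if (length(extra) > 10L) " ..." else "", call. = FALSE)
  invisible(TRUE)
}

.geomean <- function(x) exp(mean(log(x)))

#' log2 transform for abundance matrices
#'
#' Applies \code{log2(x * scale + 1)} to a relative-abundance (or otherwise
#' normalized) matrix prior to Bray-Curtis computation. Proportions are
#' rescaled (default to a per-million basis) so that the +1 pseudocount
#' acts on a count-like magnitude rather than on values below one.
#'
#' @param x numeric matrix of non-negative abundances.
#' @param scale multiplier applied before the pseudocount; default 1e6.
#' @return matrix of the same shape.
#' @export
log2Abundance <- function(x, scale = 1e6) {
  if (any(x < 0)) stop("abundances must be non-negative")
  log2(x * scale + 1)
}
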