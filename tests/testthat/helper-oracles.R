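# Independent oracles, deliberately written from first principles and
# kept apart from the package's implementation paths.

# ---- PERMANOVA: direct sums-of-squares and exhaustive enumeration ----

oracle_pseudo_f <- function(dmat, groups) {
  n <- nrow(dmat)
  lev <- unique(groups)
  a <- length(lev)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_tot <- ss_tot + dmat[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      for (i in seq_along(idx)[-length(idx)])
        for (j in (i + 1):length(idx))
          ss_w <- ss_w + dmat[idx[i], idx[j]]^2 / length(idx)
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# exact p over every assignment of n1 labels "a" among n samples
oracle_permanova_p <- function(dmat, groups) {
  n <- nrow(dmat)
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  n1 <- sum(groups == lev[1])
  f_obs <- oracle_pseudo_f(dmat, groups)
  sets <- combn(n, n1)
  f_all <- apply(sets, 2, function(s) {
    g <- rep(lev[2], n)
    g[s] <- lev[1]
    oracle_pseudo_f(dmat, g)
  })
  mean(f_all >= f_obs - 1e-12)
}

# ---- KEGG-definition semantics: random trees + direct evaluation ----

# random definition tree over a KO pool; shapes mirror the grammar:
# seq / alt / cpx with optional members / leaf
random_def_tree <- function(n_leaves, kos) {
  pool <- sample(kos, n_leaves)
  build <- function(leaves, depth) {
    if (length(leaves) == 1L)
      return(list(op = "leaf", ko = leaves[[1]]))
    type <- if (depth == 0L) "seq"
            else sample(c("seq", "alt", "cpx"), 1)
    k <- sample(2:min(4, length(leaves)), 1)
    cuts <- sort(sample(seq_len(length(leaves) - 1L), k - 1L))
    parts <- split(leaves, findInterval(seq_along(leaves), cuts + 1L) + 1L)
    children <- lapply(parts, build, depth = depth + 1L)
    if (type == "cpx" && length(children) > 1L) {
      optional <- c(FALSE, runif(length(children) - 1L) < 0.25)
      return(list(op = "cpx", children = children, optional = optional))
    }
    list(op = type, children = children,
         optional = rep(FALSE, length(children)))
  }
  build(pool, 0L)
}

# serialize with explicit parentheses everywhere except the top step
# sequence (so top-level steps stay identifiable)
serialize_def_tree <- function(tree, top = TRUE) {
  if (tree$op == "leaf") return(tree$ko)
  parts <- vapply(tree$children, serialize_def_tree, "", top = FALSE)
  out <- switch(tree$op,
    seq = paste(parts, collapse = " "),
    alt = paste(parts, collapse = ","),
    cpx = paste0(parts[1], paste0(
      ifelse(tree$optional[-1], "-", "+"), parts[-1], collapse = "")))
  if (top && tree$op == "seq") out else paste0("(", out, ")")
}

# direct truth-value of a tree under a present-KO set
eval_def_tree <- function(tree, present) {
  if (tree$op == "leaf") return(tree$ko %in% present)
  vals <- vapply(seq_along(tree$children), function(i) {
    if (tree$op == "cpx" && tree$optional[i]) TRUE
    else eval_def_tree(tree$children[[i]], present)
  }, logical(1))
  switch(tree$op, seq = all(vals), cpx = all(vals), alt = any(vals))
}

tree_leaves <- function(tree) {
  if (tree$op == "leaf") return(tree$ko)
  unique(unlist(lapply(tree$children, tree_leaves)))
}

all_subsets <- function(items) {
  n <- length(items)
  lapply(seq_len(2^n) - 1L, function(mask)
    items[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
}

# ---- misc ----

# toy ASV experiment built in code
toy_asv <- function(counts = NULL) {
  if (is.null(counts))
    counts <- matrix(c(10, 5, 5, 0,
                       2, 2, 4, 12,
                       1, 0, 3, 6), nrow = 4,
                     dimnames = list(paste0("ASV", 1:4), paste0("S", 1:3)))
  tax <- data.frame(
    domain = "Bacteria",
    phylum = c("Chloroflexi", "Chloroflexi", "Proteobacteria", "Poribacteria"),
    class = c("Dehalococcoidia", "Dehalococcoidia", "Gammaproteobacteria", NA),
    order = c("o1", "o1", "o2", NA), family = c("f1", "f1", "f2", NA),
    genus = c("g1", "g1", "g2", NA),
    row.names = rownames(counts), stringsAsFactors = FALSE)
  md <- data.frame(species = c("sp1", "sp1", "sp2"),
                   location = "loc1", habitat = "deep",
                   row.names = colnames(counts), stringsAsFactors = FALSE)
  AsvExperiment(counts, tax, md)
}
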