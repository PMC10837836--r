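# Definition grammar, completeness evaluation and module rollups.

test_that("parser produces the forced structures", {
  t1 <- parseDefinition("K00001")
  expect_identical(t1$type, "seq")
  expect_length(t1$children, 1)
  expect_identical(t1$children[[1]]$type, "leaf")
  expect_identical(t1$children[[1]]$ko, "K00001")

  t2 <- parseDefinition("K1+K2 K3,K4")
  expect_length(t2$children, 2)
  expect_identical(t2$children[[1]]$type, "cpx")
  expect_identical(t2$children[[2]]$type, "alt")
  expect_identical(t2$children[[2]]$children[[1]]$ko, "K3")

  # parenthesized alternative bound into a complex: satisfied only with
  # K3 plus at least one of K1/K2 (checked by enumeration)
  t3 <- parseDefinition("(K1,K2)+K3")
  sat <- vapply(all_subsets(c("K1", "K2", "K3")), function(s)
    evaluateCompleteness(t3, s)$complete, logical(1))
  expected <- vapply(all_subsets(c("K1", "K2", "K3")), function(s)
    ("K3" %in% s) && any(c("K1", "K2") %in% s), logical(1))
  expect_identical(sat, expected)
})

test_that("malformed definitions are rejected with positions", {
  expect_error(parseDefinition("(K1 K2"), "unbalanced.*position 1")
  expect_error(parseDefinition("K1+"), "dangling")
  expect_error(parseDefinition("K1,,K2"), "unexpected")
  expect_error(parseDefinition(""), "non-empty")
  expect_error(parseDefinition("K1 & K2"), "invalid character")
})

test_that("completeness matches the spec'd step semantics", {
  expect_true(evaluateCompleteness("K1 K2", c("K1", "K2"))$complete)
  expect_true(evaluateCompleteness("K1,K2", "K2")$complete)
  ev <- evaluateCompleteness("(K1+K2) K3", c("K1", "K3"))
  expect_false(ev$complete)
  expect_equal(ev$fraction, 0.5)
  # optional subunits never required and never counted
  expect_true(evaluateCompleteness("K1-K2", "K1")$complete)
  expect_false(evaluateCompleteness("K1-K2", "K2")$complete)
})

test_that("evaluator agrees with brute-force enumeration on random trees", {
  set.seed(11)
  kos <- sprintf("K%05d", 1:40)
  for (rep in 1:60) {
    tree <- random_def_tree(sample(1:8, 1), kos)
    def <- serialize_def_tree(tree)
    parsed <- parseDefinition(def)
    for (s in all_subsets(tree_leaves(tree))) {
      expect_identical(evaluateCompleteness(parsed, s)$complete,
                       eval_def_tree(tree, s),
                       label = paste("def:", def, "present:",
                                     paste(s, collapse = "+")))
    }
  }
})

test_that("parse-serialize-parse is semantically idempotent", {
  set.seed(12)
  kos <- sprintf("K%05d", 1:30)
  for (rep in 1:40) {
    tree <- random_def_tree(sample(2:7, 1), kos)
    p1 <- parseDefinition(serialize_def_tree(tree))
    p2 <- parseDefinition(serializeDefinition(p1))
    for (s in all_subsets(tree_leaves(tree)))
      expect_identical(evaluateCompleteness(p1, s)$complete,
                       evaluateCompleteness(p2, s)$complete)
  }
})

test_that("module expression is additive, multiplicity-aware and monotone", {
  samples <- c("S1", "S2")
  tpm_mat <- matrix(c(100, 80, 50, 40, 30, 20), 3, 2, byrow = TRUE,
                    dimnames = list(c("K1", "K2", "K3"), samples))
  ko <- new("KoExpression", tpm = tpm_mat, atpm = rowMeans(tpm_mat),
            unannotated = setNames(c(0, 0), samples))
  cat <- moduleCatalog(data.frame(
    module_id = c("MA", "MB"), name = c("a", "b"),
    level_B = "B", level_C = "C",
    definition = c("K1 K2", "K1 K1,K9"), stringsAsFactors = FALSE))
  prof <- moduleExpression(ko, cat)
  expect_equal(unname(tpm(prof)["MA", ]), c(150, 120))
  # K1 appears in both modules and fully in each; duplicated K1 within
  # MB's definition counts once
  expect_equal(unname(tpm(prof)["MB", ]), c(100, 80))
  # cross-module multiplicity may overcount relative to the KO total
  expect_gt(sum(tpm(prof)[, "S1"]), sum(tpm_mat[, "S1"]))
  expect_true(all(moduleComplete(prof)))

  # monotonicity: adding KO expression never decreases a module value
  tpm2 <- tpm_mat
  tpm2["K2", ] <- tpm2["K2", ] + 5
  ko2 <- new("KoExpression", tpm = tpm2, atpm = rowMeans(tpm2),
             unannotated = setNames(c(0, 0), samples))
  prof2 <- moduleExpression(ko2, cat)
  expect_true(all(tpm(prof2) >= tpm(prof)))

  # empty KO matrix: all zero and incomplete
  ko0 <- new("KoExpression",
             tpm = matrix(numeric(), 0, 2, dimnames = list(NULL, samples)),
             atpm = numeric(), unannotated = setNames(c(0, 0), samples))
  prof0 <- moduleExpression(ko0, cat)
  expect_true(all(tpm(prof0) == 0))
  expect_false(any(moduleComplete(prof0)))
})

test_that("taxon split partitions module expression exactly", {
  tc <- matrix(c(90, 60, 30, 20), 2, 2,
               dimnames = list(c("t1", "t2"), c("S1", "S2")))
  ann <- data.frame(
    transcript_id = c("t1", "t1", "t2"),
    peptide_id = c("p1", "p2", "p3"),
    peptide_length = c(100, 200, 150),
    ko = c("K1", "K1", "K2"),
    taxon = c("Bacteria;Chloroflexi;c;o;f;g",
              "Bacteria;Proteobacteria;c;o;f;g", NA),
    stringsAsFactors = FALSE)
  pe <- peptideTpm(apportionCounts(tc, ann))
  cat <- moduleCatalog(data.frame(
    module_id = "M1", name = "m", level_B = "B", level_C = "C",
    definition = "K1 K2", stringsAsFactors = FALSE))
  split <- taxonSplitExpression(pe, ann, cat, rank = "phylum")
  ko <- suppressMessages(aggregateToKo(pe, ann))
  prof <- moduleExpression(ko, cat)
  for (s in c("S1", "S2")) {
    expect_equal(sum(split$tpm[split$sample == s]),
                 unname(tpm(prof)["M1", s]), tolerance = 1e-9)
  }
  expect_setequal(unique(split$taxon),
                  c("Chloroflexi", "Proteobacteria", "unclassified"))

  # single-phylum degenerate case: the split equals the total
  ann1 <- ann
  ann1$taxon <- "Bacteria;Poribacteria;c;o;f;g"
  pe1 <- peptideTpm(apportionCounts(tc, ann1))
  s1 <- taxonSplitExpression(pe1, ann1, cat, rank = "phylum")
  expect_identical(unique(s1$taxon), "Poribacteria")
})

test_that("KO multiplicity counts containing modules", {
  cat <- moduleCatalog(data.frame(
    module_id = c("M1", "M2", "M3"), name = "x", level_B = "B",
    level_C = "C",
    definition = c("K1 K2", "K1,K3", "K1+K4 K1"), stringsAsFactors = FALSE))
  mult <- koMultiplicity(cat)
  expect_equal(mult$n_modules[mult$ko == "K1"], 3L)
  expect_equal(mult$n_modules[mult$ko == "K2"], 1L)
  expect_equal(attr(mult, "fraction_multi"), 0.25)

  disjoint <- moduleCatalog(data.frame(
    module_id = c("M1", "M2"), name = "x", level_B = "B", level_C = "C",
    definition = c("K1 K2", "K3 K4"), stringsAsFactors = FALSE))
  md <- koMultiplicity(disjoint)
  expect_true(all(md$n_modules == 1L))
  expect_equal(attr(md, "fraction_multi"), 0)
})

test_that("hierarchy rollup sums member modules", {
  samples <- c("S1", "S2")
  tpm_mat <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE,
                    dimnames = list(c("K1", "K2"), samples))
  ko <- new("KoExpression", tpm = tpm_mat, atpm = rowMeans(tpm_mat),
            unannotated = setNames(c(0, 0), samples))
  cat <- moduleCatalog(data.frame(
    module_id = c("M1", "M2"), name = "x", level_B = "B",
    level_C = c("N metabolism", "N metabolism"),
    definition = c("K1", "K2"), stringsAsFactors = FALSE))
  prof <- moduleExpression(ko, cat)
  roll <- rollupHierarchy(prof, "level_C")
  expect_equal(unname(roll$expression["N metabolism", ]),
               unname(colSums(tpm(prof))))
})
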