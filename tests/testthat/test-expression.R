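# Length apportionment, TPM, KO aggregation, TMM and CPM.

test_that("apportionment divides counts by peptide length share", {
  tc <- matrix(100, 1, 1, dimnames = list("t1", "S1"))
  ann <- data.frame(transcript_id = "t1", peptide_id = c("p1", "p2"),
                    peptide_length = c(100, 300), ko = NA, taxon = NA,
                    stringsAsFactors = FALSE)
  pe <- apportionCounts(tc, ann)
  expect_equal(unname(apportioned(pe)[, 1]), c(25, 75))

  # single-peptide transcript inherits the full count
  ann1 <- data.frame(transcript_id = "t1", peptide_id = "p1",
                     peptide_length = 123, ko = NA, taxon = NA)
  expect_equal(unname(apportioned(apportionCounts(tc, ann1))[, 1]), 100)
})

test_that("apportionment conserves transcript mass on random input", {
  set.seed(21)
  n_tx <- 50
  tc <- matrix(rpois(n_tx * 4, 200) + runif(n_tx * 4), n_tx, 4,
               dimnames = list(sprintf("t%02d", 1:n_tx), paste0("S", 1:4)))
  k <- sample(1:5, n_tx, replace = TRUE)
  ann <- data.frame(
    transcript_id = rep(rownames(tc), k),
    peptide_id = paste0("p", seq_len(sum(k))),
    peptide_length = sample(50:500, sum(k), replace = TRUE),
    ko = NA, taxon = NA, stringsAsFactors = FALSE)
  pe <- apportionCounts(tc, ann)
  per_tx <- rowsum(apportioned(pe), ann$transcript_id)
  expect_equal(per_tx[rownames(tc), ], tc, tolerance = 1e-12)
})

test_that("apportionment tallies dropped and orphan records and rejects bad input", {
  tc <- matrix(c(10, 20), 2, 1, dimnames = list(c("t1", "t2"), "S1"))
  ann <- data.frame(transcript_id = c("t1", "t3"),
                    peptide_id = c("p1", "p2"),
                    peptide_length = c(100, 100), ko = NA, taxon = NA)
  expect_message(expect_message(pe <- apportionCounts(tc, ann),
                                "1 annotation records"),
                 "1 transcripts without")
  expect_identical(pe@nDroppedTranscripts, 1L)
  expect_identical(pe@nOrphanRecords, 1L)
  ann$peptide_id <- c("p1", "p1")
  expect_error(apportionCounts(tc, ann), "unique")
})

test_that("peptide TPM normalizes each sample to one million", {
  tc <- matrix(c(10, 10), 2, 1, dimnames = list(c("t1", "t2"), "S1"))
  ann <- data.frame(transcript_id = c("t1", "t2"),
                    peptide_id = c("p1", "p2"),
                    peptide_length = c(100, 200), ko = NA, taxon = NA)
  pe <- peptideTpm(apportionCounts(tc, ann))
  # equal counts, double length -> half the rate -> TPM ratio 2:1
  v <- tpm(pe)[, 1]
  expect_equal(unname(v["p1"] / v["p2"]), 2)
  expect_equal(sum(v), 1e6)

  # symmetric case: equal everything -> 5e5 each
  ann2 <- transform(ann, peptide_length = c(150, 150))
  v2 <- tpm(peptideTpm(apportionCounts(tc, ann2)))[, 1]
  expect_equal(unname(v2), c(5e5, 5e5))

  # random fixture: every column sums to 1e6
  set.seed(22)
  tc3 <- matrix(rpois(60, 100), 20, 3,
                dimnames = list(paste0("t", 1:20), paste0("S", 1:3)))
  ann3 <- data.frame(transcript_id = rownames(tc3),
                     peptide_id = paste0("p", 1:20),
                     peptide_length = sample(60:900, 20), ko = NA, taxon = NA)
  expect_equal(unname(colSums(tpm(peptideTpm(apportionCounts(tc3, ann3))))),
               rep(1e6, 3), tolerance = 1e-9)

  # all-zero sample is an error naming the sample
  tc4 <- tc3; tc4[, 2] <- 0
  expect_error(peptideTpm(apportionCounts(tc4, ann3)), "S2")
})

test_that("KO aggregation is additive and conserves the TPM budget", {
  tc <- matrix(c(30, 15, 10), 3, 1, dimnames = list(c("t1", "t2", "t3"), "S1"))
  ann <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    peptide_id = c("p1", "p2", "p3"),
                    peptide_length = c(100, 100, 100),
                    ko = c("K1", "K1", NA), taxon = NA,
                    stringsAsFactors = FALSE)
  pe <- peptideTpm(apportionCounts(tc, ann))
  ko <- suppressMessages(aggregateToKo(pe, ann))
  v <- tpm(pe)[, 1]
  expect_equal(unname(tpm(ko)["K1", 1]), unname(v["p1"] + v["p2"]))
  expect_equal(unname(colSums(tpm(ko)) + unannotatedMass(ko)),
               1e6, tolerance = 1e-6)
  expect_equal(unname(atpm(ko)), unname(rowMeans(tpm(ko))))
  # a KO with no expressed peptide is simply absent
  expect_false("K9" %in% rownames(tpm(ko)))
})

test_that("TMM factors are 1 for identical samples and re-centred overall", {
  set.seed(23)
  base <- rpois(300, 50) + 1
  m <- cbind(A = base, B = base, C = base)
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  f <- tmmFactors(m)
  expect_equal(unname(f$factors), rep(1, 3), tolerance = 1e-9)

  m2 <- cbind(A = base, B = 2L * base, C = sample(base))
  rownames(m2) <- paste0("f", seq_len(nrow(m2)))
  f2 <- tmmFactors(m2)
  expect_equal(exp(mean(log(f2$factors))), 1, tolerance = 1e-6)
})

test_that("global scaling of a sample leaves TMM-CPM invariant", {
  set.seed(24)
  base <- 2L * (rpois(400, 40) + 1L)    # even, so 0.5x stays integral
  for (c_scale in c(0.5, 2, 5)) {
    m <- cbind(A = base, B = base * c_scale, C = base)
    rownames(m) <- paste0("f", seq_len(nrow(m)))
    cpm <- cpmMatrix(m, tmmFactors(m))
    rel <- abs(cpm[, "B"] - cpm[, "A"]) / pmax(cpm[, "A"], 1)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("cpm arithmetic and degenerate columns", {
  m <- matrix(c(10, 990990, 0, 0), 2, 2,
              dimnames = list(c("f1", "f2"), c("S1", "S2")))
  expect_equal(cpmMatrix(m)["f1", "S1"], 10 / 991000 * 1e6)
  expect_equal(unname(cpmMatrix(m)[, "S2"]), c(0, 0))
})
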