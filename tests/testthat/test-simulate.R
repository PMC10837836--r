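# The synthetic-data generator: determinism, planted structure, and the
# statistical shape it promises.

small_cfg <- function(...) {
  simConfig(n_asvs = 120, seq_depth_mean = 5000, n_transcripts = 300,
            tx_depth_mean = 5e4, ...)
}

test_that("fixed seed gives bit-identical datasets", {
  cfg <- small_cfg(seed = 5, planted_complete_modules = "M_C1",
                   planted_absent_kos = "K00150")
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(asvCounts(d1), asvCounts(d2))
  expect_identical(transcriptCounts(d1), transcriptCounts(d2))
  expect_identical(orfAnnotation(d1), orfAnnotation(d2))
  expect_identical(truth(d1), truth(d2))
  d3 <- simulateDataset(small_cfg(seed = 6, planted_complete_modules = "M_C1",
                                  planted_absent_kos = "K00150"))
  expect_false(identical(asvCounts(d1), asvCounts(d3)))
})

test_that("config invariants are enforced", {
  expect_error(simConfig(single_orf_fraction = 1.2), "single_orf_fraction")
  expect_error(simConfig(max_orfs = 0), "max_orfs")
  expect_error(simConfig(dirichlet_concentration = 0), "positive")
  expect_error(simConfig(seq_depth_mean = -1), "positive")
  expect_error(simConfig(planted_absent_kos = "K99999"), "ko_universe")
})

test_that("ASV tables carry the design and the planted group effects", {
  cfg <- small_cfg(seed = 2, n_locations = 2)
  ae <- simulateAsvTable(cfg)
  md <- sampleData(ae)
  expect_equal(ncol(ae), 3 * 2 * 3)
  expect_equal(sort(unique(md$species)), paste0("sp", 1:3))
  expect_equal(sort(unique(md$location)), paste0("loc", 1:2))
  planted <- S4Vectors::metadata(ae)$planted
  expect_setequal(names(planted$species_effect), unique(md$species))
  expect_true(all(unlist(planted$species_effect) %in% rownames(ae)))
  # round-robin designation keeps the subsets disjoint
  all_ids <- unlist(c(planted$species_effect, planted$location_effect))
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("ORF counts follow the single-ORF fraction and bounds", {
  cfg1 <- small_cfg(single_orf_fraction = 1, seed = 3)
  mt1 <- simulateMetatranscriptome(cfg1)
  expect_true(all(table(mt1$annotation$transcript_id) == 1))

  cfg <- simConfig(n_transcripts = 10000, single_orf_fraction = 0.366,
                   tx_depth_mean = 1e5, seed = 4)
  mt <- simulateMetatranscriptome(cfg)
  k <- table(mt$annotation$transcript_id)
  obs <- mean(k == 1)
  se <- sqrt(0.366 * (1 - 0.366) / 10000)
  expect_lt(abs(obs - 0.366), 3 * se)
  expect_true(all(k >= 1 & k <= cfg$max_orfs))
})

test_that("peptide lengths respect the truncation floor", {
  mt <- simulateMetatranscriptome(small_cfg(seed = 8))
  expect_true(all(mt$annotation$peptide_length >= 50))
})

test_that("withheld KOs never appear; planted-module KOs always do", {
  cfg <- small_cfg(seed = 9, planted_complete_modules = c("M_C1", "M_C2"),
                   planted_absent_kos = c("K00149", "K00150"))
  cat <- syntheticModuleCatalog(cfg)
  mt <- simulateMetatranscriptome(cfg, cat)
  kos <- mt$annotation$ko
  expect_false(any(c("K00149", "K00150") %in% kos))
  expect_true(all(mt$truth$required_kos %in% kos))
  # a planted module requiring a KO outside the universe is a config error
  cfg1 <- small_cfg(seed = 9, planted_complete_modules = "M_C1")
  bad_cat <- moduleCatalog(data.frame(
    module_id = "M_C1", name = "x", level_B = "B", level_C = "C",
    definition = "K99999", stringsAsFactors = FALSE))
  expect_error(simulateMetatranscriptome(cfg1, bad_cat), "outside ko_universe")
})

test_that("planted completeness is recovered end to end", {
  cfg <- small_cfg(seed = 10, planted_complete_modules = c("M_C1", "M_C2"),
                   planted_absent_kos = "K00150")
  cat <- syntheticModuleCatalog(cfg)
  mt <- simulateMetatranscriptome(cfg, cat)
  pe <- suppressMessages(peptideTpm(apportionCounts(mt$counts, mt$annotation)))
  ko <- suppressMessages(aggregateToKo(pe, mt$annotation))
  prof <- moduleExpression(ko, cat)
  cm <- moduleComplete(prof)
  expect_true(all(cm[c("M_C1", "M_C2")]))
  expect_false(any(cm[grep("M_INC", names(cm))]))
})

test_that("planted differential truth ids are generated features", {
  ds <- simulateDataset(small_cfg(seed = 11, n_differential_features = 10))
  td <- truth(ds)$differential
  expect_equal(nrow(td), 10)
  expect_true(all(td$transcript_id %in% rownames(transcriptCounts(ds))))
  expect_setequal(unique(td$up_group),
                  unique(sampleData(asvExperiment(ds))$species))
})
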