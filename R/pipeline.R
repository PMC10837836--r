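# End-to-end orchestration: simulate -> amplicon -> diversity ->
# expression -> modules -> compare, driven by one YAML/list config and a
# single reproducibility seed. Each stage writes TSV outputs into the
# output directory; a manifest.json records parameters, versions and
# output checksums so that a rerun with the same config is verifiably
# identical for the deterministic stages.

#' Run the full analysis pipeline
#'
#' @param config a YAML file path or an equivalent named list. Top-level
#'   keys: \code{outdir} (required), \code{seed}, \code{stages}
#'   (character subset of simulate, amplicon, diversity, expression,
#'   modules, compare; default all), \code{simulate} (arguments for
#'   \code{\link{simConfig}}), \code{inputs} (paths for
#'   counts/taxonomy/metadata/transcripts/orfs/catalog when not
#'   simulating), \code{amplicon} (\code{depth}, \code{rank},
#'   \code{min_ra}), \code{diversity} (\code{n_permutations}),
#'   \code{modules} (\code{taxon_rank}), \code{compare} (\code{by},
#'   \code{alpha}, \code{fc}, \code{shared_ra}, \code{shared_tmm}).
#' @return invisibly, the manifest list. On a stage failure the outputs
#'   written so far are renamed with a \code{.partial} suffix and the
#'   error is re-thrown.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||%
    c("simulate", "amplicon", "diversity", "expression", "modules", "compare")
  seed <- config$seed %||% 1L
  written <- character()
  emit <- function(df, name, rowname_col = NULL) {
    path <- file.path(outdir, name)
    .writeTsv(as.data.frame(df), path, rowname_col = rowname_col)
    written <<- c(written, path)
    path
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      for (p in written) if (file.exists(p))
        file.rename(p, paste0(p, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  asv <- NULL; tc <- NULL; ann <- NULL; catalog <- NULL; ds <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- seed
      cfg <- do.call(simConfig, sim_args)
      catalog <<- if (length(cfg$planted_complete_modules) ||
                      length(cfg$planted_absent_kos))
        syntheticModuleCatalog(cfg) else NULL
      ds <<- simulateDataset(cfg, catalog)
      asv <<- asvExperiment(ds); tc <<- transcriptCounts(ds)
      ann <<- orfAnnotation(ds)
      writeAsvTable(asv, file.path(outdir, "asv_counts.tsv"),
                    file.path(outdir, "asv_taxonomy.tsv"),
                    file.path(outdir, "sample_metadata.tsv"))
      writeTranscriptCounts(tc, file.path(outdir, "transcript_counts.tsv"))
      writeOrfAnnotation(ann, file.path(outdir, "orf_annotation.tsv"))
      if (!is.null(catalog))
        writeModuleCatalog(catalog, file.path(outdir, "module_catalog.tsv"))
      writeTruth(truth(ds), file.path(outdir, "truth.json"))
      written <<- c(written, file.path(outdir, c(
        "asv_counts.tsv", "asv_taxonomy.tsv", "sample_metadata.tsv",
        "transcript_counts.tsv", "orf_annotation.tsv", "truth.json")))
    })
  } else {
    run_stage("load-inputs", function() {
      inp <- config$inputs
      if (is.null(inp)) stop("config needs 'inputs' when not simulating")
      asv <<- readAsvTable(inp$counts, inp$taxonomy, inp$metadata)
      if (!is.null(inp$transcripts)) tc <<- readTranscriptCounts(inp$transcripts)
      if (!is.null(inp$orfs)) ann <<- readOrfAnnotation(inp$orfs)
      if (!is.null(inp$catalog)) catalog <<- readModuleCatalog(inp$catalog)
    })
  }

  if ("amplicon" %in% stages) {
    run_stage("amplicon", function() {
      ac <- config$amplicon %||% list()
      depth <- ac$depth %||% min(colSums(asvCounts(asv)))
      asv <<- rarefyCounts(asv, depth, seed = substreamSeed(seed, 20L))
      if (!is.null(ac$rank)) asv <<- collapseTaxonomy(asv, ac$rank)
      if (!is.null(ac$min_ra)) asv <<- filterMinRelAbundance(asv, ac$min_ra)
      emit(t(asvCounts(asv)), "asv_processed.tsv", rowname_col = "sample_id")
    })
  }

  div <- NULL
  if ("diversity" %in% stages) {
    run_stage("diversity", function() {
      dc <- config$diversity %||% list()
      nperm <- dc$n_permutations %||% 999
      ra <- relativeAbundance(asv)
      d <- brayCurtis(log2Abundance(ra))
      groups <- sampleData(asv)$species
      alpha <- shannonIndex(asv)
      ord <- pcoaOrdination(d)
      pmv <- permanova(d, groups, n_permutations = nperm,
                       seed = substreamSeed(seed, 21L))
      disp <- dispersionHomogeneity(d, groups)
      div <<- list(distance = d, groups = groups)
      emit(data.frame(sample = names(alpha), shannon = alpha), "shannon.tsv")
      emit(as.data.frame(as.matrix(d)), "bray_curtis.tsv",
           rowname_col = "sample_id")
      emit(as.data.frame(ord$coordinates), "pcoa_coordinates.tsv",
           rowname_col = "sample_id")
      emit(as.data.frame(pmv), "permanova.tsv")
      emit(data.frame(F = disp$F, p_value = disp$p_value), "dispersion.tsv")
    })
  }

  ko <- NULL; pe <- NULL
  if ("expression" %in% stages && !is.null(tc) && !is.null(ann)) {
    run_stage("expression", function() {
      pe <<- peptideTpm(apportionCounts(tc, ann))
      ko <<- aggregateToKo(pe, ann)
      emit(as.data.frame(tpm(ko)), "ko_tpm.tsv", rowname_col = "ko")
      emit(data.frame(ko = names(atpm(ko)), atpm = atpm(ko)), "ko_atpm.tsv")
    })
  }

  if ("modules" %in% stages && !is.null(ko) && !is.null(catalog)) {
    run_stage("modules", function() {
      mc <- config$modules %||% list()
      prof <- moduleExpression(ko, catalog)
      split <- taxonSplitExpression(pe, ann, catalog,
                                    rank = mc$taxon_rank %||% "phylum")
      emit(data.frame(module_id = rownames(tpm(prof)),
                      atpm = atpm(prof),
                      complete = moduleComplete(prof),
                      fraction = moduleFraction(prof)),
           "module_profile.tsv")
      emit(as.data.frame(tpm(prof)), "module_tpm.tsv",
           rowname_col = "module_id")
      emit(split, "taxon_split.tsv")
    })
  }

  if ("compare" %in% stages) {
    run_stage("compare", function() {
      cc <- config$compare %||% list()
      groups <- sampleData(asv)[[cc$by %||% "species"]]
      ra_t <- t(relativeAbundance(asv))     # features x samples
      sh <- sharedFeatures(ra_t, groups, threshold = cc$shared_ra %||% 1e-4)
      emit(sh$pairwise, "shared_asvs.tsv")
      if (length(unique(groups)) == 2) {
        dr <- differentialFeatures(asvCounts(asv), groups, kind = "asv",
                                   alpha = cc$alpha %||% 0.01,
                                   fc_threshold = cc$fc %||% 2,
                                   seed = substreamSeed(seed, 22L))
        emit(dr, "differential_asvs.tsv")
      }
      if (!is.null(tc)) {
        fct <- tmmFactors(tc)
        tmm <- cpmMatrix(tc, fct)
        sht <- sharedFeatures(tmm, groups, threshold = cc$shared_tmm %||% 1)
        emit(sht$pairwise, "shared_transcripts.tsv")
        if (length(unique(groups)) == 2) {
          drt <- differentialFeatures(tc, groups, kind = "transcript",
                                      alpha = cc$alpha %||% 0.01,
                                      fc_threshold = cc$fc %||% 2,
                                      seed = substreamSeed(seed, 23L))
          emit(drt, "differential_transcripts.tsv")
        }
      }
    })
  }

  manifest <- list(
    package = as.character(packageVersion("spongefunc")),
    seed = seed, stages = stages,
    parameters = config[setdiff(names(config), c("outdir"))],
    outputs = as.list(tools::md5sum(written[file.exists(written)])))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
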