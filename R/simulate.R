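# Synthetic holobiont data with planted, recoverable structure.
#
# The generator emulates the statistical shape of a deep-sea HMA sponge
# study: an uneven (log-normal base abundance) ASV community sampled
# Dirichlet-multinomially per sample with group (species/location)
# effects on designated ASV subsets, and a metatranscriptome whose
# transcripts carry 1-12 ORFs (single-ORF fraction ~36.6%), sparse KO
# and taxon annotation, planted complete/incomplete KEGG modules and
# planted differential transcripts.

.DEFAULT_TAXA <- c(
  "Bacteria;Chloroflexi;Dehalococcoidia;Dehalococcoidales;Dehalococcoidaceae;Dehalococcoidia_gen",
  "Bacteria;Chloroflexi;Dehalococcoidia;SAR202_clade;SAR202_fam;SAR202_gen",
  "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae;Nitrosopumilus",
  "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;Nitrososphaera",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Endozoicomonadaceae;Endozoicomonas",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Magnetospiraceae;Magnetospira",
  "Bacteria;Poribacteria;Poribacteria_cl;Poribacteria_or;Poribacteria_fam;Poribacteria_gen",
  "Bacteria;Acidobacteria;Subgroup_6;Subgroup_6_or;Subgroup_6_fam;Subgroup_6_gen",
  "Bacteria;Actinobacteria;Acidimicrobiia;Microtrichales;Microtrichaceae;Sva0996_group",
  "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira",
  "Bacteria;Gemmatimonadetes;Gemmatimonadetes_cl;Gemmatimonadales;Gemmatimonadaceae;Gemmatimonas",
  "Bacteria;Spirochaetes;Spirochaetia;Spirochaetales;Spirochaetaceae;Spirochaeta")

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-data
#' generator. Defaults mirror the study design the package targets:
#' three sponge species sampled in triplicate at one deep-sea site, an
#' uneven community of 800 ASVs sequenced to ~1e5 16S reads, and a
#' metatranscriptome of 2000 transcripts at ~1e6 expected counts per
#' sample in which 36.6% of transcripts carry a single ORF and the rest
#' 2 to \code{max_orfs}.
#'
#' @param n_species,n_locations,replicates_per_group sampling design;
#'   samples are the full species x location cross with
#'   \code{replicates_per_group} replicates each.
#' @param n_asvs,seq_depth_mean community size and mean 16S depth
#'   (per-sample depths are Poisson around the mean).
#' @param dirichlet_concentration total concentration of the Dirichlet
#'   abundance draw; larger = less sample-to-sample dispersion (deep-sea
#'   like).
#' @param group_effect_size log-scale abundance shift applied to the
#'   designated ASV subset of each species/location group.
#' @param effect_asv_fraction fraction of ASVs designated per group
#'   (round-robin, recorded in the planted truth).
#' @param habitat habitat class label for the simulated samples.
#' @param n_transcripts,tx_depth_mean metatranscriptome size and mean
#'   per-sample expected-count depth.
#' @param single_orf_fraction probability a transcript carries exactly
#'   one ORF (default 0.366); otherwise the ORF number is uniform on
#'   2..\code{max_orfs}.
#' @param max_orfs maximum ORFs per transcript (default 12).
#' @param length_meanlog,length_sdlog,length_min peptide lengths are
#'   log-normal(meanlog, sdlog) amino acids, truncated at
#'   \code{length_min}.
#' @param baseline_sdlog per-transcript baseline expression is
#'   log-normal(0, \code{baseline_sdlog}).
#' @param ko_universe,ko_annotation_fraction KO identifiers available to
#'   the annotator and the fraction of peptides that receive one.
#' @param taxon_universe,taxon_annotation_fraction lineage strings and
#'   the fraction of peptides that receive one.
#' @param planted_complete_modules module ids whose required KOs are
#'   guaranteed to be expressed (see
#'   \code{\link{syntheticModuleCatalog}}).
#' @param planted_absent_kos KO ids never assigned to any peptide;
#'   modules requiring one are guaranteed incomplete.
#' @param n_differential_features,differential_log2fc number of
#'   transcripts planted as differential, and the log2 fold change
#'   applied in their assigned (round-robin) species group.
#' @param seed master seed; expanded internally into per-stage
#'   substreams so stages are independently reproducible.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_species = 3, n_locations = 1,
                      replicates_per_group = 3,
                      n_asvs = 800, seq_depth_mean = 1e5,
                      dirichlet_concentration = 200,
                      group_effect_size = 2, effect_asv_fraction = 0.05,
                      habitat = "deep",
                      n_transcripts = 2000, tx_depth_mean = 1e6,
                      single_orf_fraction = 0.366, max_orfs = 12,
                      length_meanlog = 5.2, length_sdlog = 0.6,
                      length_min = 50, baseline_sdlog = 1.5,
                      ko_universe = sprintf("K%05d", seq_len(150)),
                      ko_annotation_fraction = 0.6,
                      taxon_universe = .DEFAULT_TAXA,
                      taxon_annotation_fraction = 0.7,
                      planted_complete_modules = character(),
                      planted_absent_kos = character(),
                      n_differential_features = 20,
                      differential_log2fc = 2,
                      seed = 1) {
  cfg <- mget(names(formals()))
  class(cfg) <- "SimConfig"
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  with(cfg, {
    if (seq_depth_mean <= 0 || tx_depth_mean <= 0)
      stop("sequencing depths must be positive")
    if (dirichlet_concentration <= 0)
      stop("dirichlet_concentration must be positive")
    if (single_orf_fraction < 0 || single_orf_fraction > 1)
      stop("single_orf_fraction must be in [0, 1]")
    if (max_orfs < 1) stop("max_orfs must be >= 1")
    if (group_effect_size < 0) stop("group_effect_size must be >= 0")
    if (!all(planted_absent_kos %in% ko_universe))
      stop("planted_absent_kos must be drawn from ko_universe")
    if (n_species < 1 || n_locations < 1 || replicates_per_group < 1)
      stop("design dimensions must be >= 1")
    if (n_differential_features > n_transcripts)
      stop("more differential features than transcripts")
  })
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_species, "species x", x$n_locations,
      "locations x", x$replicates_per_group, "replicates;",
      x$n_asvs, "ASVs,", x$n_transcripts, "transcripts; seed", x$seed, "\n")
  invisible(x)
}

# the shared sampling design: sample ids consistent across both arms
.sampleDesign <- function(cfg) {
  grid <- expand.grid(rep = seq_len(cfg$replicates_per_group),
                      location = sprintf("loc%d", seq_len(cfg$n_locations)),
                      species = sprintf("sp%d", seq_len(cfg$n_species)),
                      stringsAsFactors = FALSE)
  data.frame(sample = sprintf("S%02d", seq_len(nrow(grid))),
             species = grid$species, location = grid$location,
             habitat = cfg$habitat, stringsAsFactors = FALSE)
}

# round-robin designation of effect ASVs per group level
.effectAsvs <- function(n_asvs, n_eff, levels, offset = 0L) {
  out <- lapply(seq_along(levels), function(k) {
    idx <- offset + seq(k, by = length(levels), length.out = n_eff)
    idx[idx <= n_asvs]
  })
  names(out) <- levels
  out
}

#' Simulate an ASV table with planted group effects
#'
#' Per-ASV base abundances are log-normal; each sample's composition is
#' Dirichlet(concentration x base) with the designated ASV subset of its
#' species (and location) group multiplied by
#' \code{exp(group_effect_size)}, and counts are multinomial at a
#' Poisson-distributed depth. The planted assignments are stored in
#' \code{metadata()$planted}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return an \linkS4class{AsvExperiment}.
#' @export
simulateAsvTable <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .validateSimConfig(cfg)
  design <- .sampleDesign(cfg)
  n_eff <- max(1L, round(cfg$effect_asv_fraction * cfg$n_asvs))
  sp_lev <- unique(design$species)
  loc_lev <- unique(design$location)
  sp_eff <- .effectAsvs(cfg$n_asvs, n_eff, sp_lev)
  loc_eff <- if (length(loc_lev) > 1)
    .effectAsvs(cfg$n_asvs, n_eff, loc_lev, offset = n_eff * length(sp_lev))
    else NULL

  base <- withSeed(substreamSeed(cfg$seed, 1L),
                   rlnorm(cfg$n_asvs, meanlog = 0, sdlog = 2))
  counts <- withSeed(substreamSeed(cfg$seed, 2L), {
    sapply(seq_len(nrow(design)), function(s) {
      w <- base
      bump <- sp_eff[[design$species[s]]]
      w[bump] <- w[bump] * exp(cfg$group_effect_size)
      if (!is.null(loc_eff)) {
        bump <- loc_eff[[design$location[s]]]
        w[bump] <- w[bump] * exp(cfg$group_effect_size)
      }
      alpha <- cfg$dirichlet_concentration * w / sum(w)
      p <- rgamma(cfg$n_asvs, shape = alpha, rate = 1)
      p <- p / sum(p)
      depth <- max(1L, rpois(1, cfg$seq_depth_mean))
      rmultinom(1, depth, p)[, 1]
    })
  })
  asv_ids <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
  dimnames(counts) <- list(asv_ids, design$sample)
  lineages <- withSeed(substreamSeed(cfg$seed, 3L),
                       sample(cfg$taxon_universe, cfg$n_asvs, replace = TRUE))
  names(lineages) <- asv_ids
  md <- design[, c("species", "location", "habitat")]
  rownames(md) <- design$sample
  ae <- AsvExperiment(counts, lineages, md)
  S4Vectors::metadata(ae)$planted <- list(
    species_effect = lapply(sp_eff, function(i) asv_ids[i]),
    location_effect = if (is.null(loc_eff)) NULL
                      else lapply(loc_eff, function(i) asv_ids[i]),
    group_effect_size = cfg$group_effect_size)
  ae
}

#' Simulate a metatranscriptome (counts + ORF annotation)
#'
#' Each transcript carries one ORF with probability
#' \code{single_orf_fraction}, otherwise a uniform 2..\code{max_orfs}.
#' Peptide lengths are truncated log-normal; a fraction of peptides gets
#' a KO (never one of \code{planted_absent_kos}) and a taxon lineage.
#' Every KO required by a planted complete module is assigned to a
#' peptide of a highly expressed transcript so the module is recoverable
#' downstream. Expected counts are multinomial draws over log-normal
#' per-transcript baselines at a Poisson per-sample depth; planted
#' differential transcripts have \code{differential_log2fc} applied in
#' their assigned species group.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param catalog a \linkS4class{ModuleCatalog} resolving
#'   \code{planted_complete_modules}; required when any are configured.
#' @return list with \code{counts} (transcript x sample matrix),
#'   \code{annotation} (ORF records) and \code{truth}.
#' @export
simulateMetatranscriptome <- function(cfg, catalog = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  .validateSimConfig(cfg)
  design <- .sampleDesign(cfg)

  req_kos <- character()
  if (length(cfg$planted_complete_modules)) {
    if (is.null(catalog))
      stop("a module catalog is required to resolve planted modules")
    .checkIds(catalogEntries(catalog)$module_id,
              union(catalogEntries(catalog)$module_id,
                    cfg$planted_complete_modules), "module ids")
    trees <- moduleTrees(catalog)[cfg$planted_complete_modules]
    req_kos <- unique(unlist(lapply(trees, .leafKos, skip_optional = TRUE)))
    if (!all(req_kos %in% cfg$ko_universe))
      stop("planted module requires KO(s) outside ko_universe: ",
           paste(setdiff(req_kos, cfg$ko_universe), collapse = ", "))
    clash <- intersect(req_kos, cfg$planted_absent_kos)
    if (length(clash))
      stop("KO(s) both required by a planted module and planted absent: ",
           paste(clash, collapse = ", "))
  }

  tx_ids <- sprintf("T%05d", seq_len(cfg$n_transcripts))
  n_orfs <- withSeed(substreamSeed(cfg$seed, 4L), {
    single <- runif(cfg$n_transcripts) < cfg$single_orf_fraction
    k <- rep(1L, cfg$n_transcripts)
    if (cfg$max_orfs > 1 && any(!single))
      k[!single] <- sample(2:cfg$max_orfs, sum(!single), replace = TRUE)
    k
  })
  n_pep <- sum(n_orfs)
  pep_tx <- rep(tx_ids, n_orfs)
  pep_ids <- paste0(pep_tx, "_p", unlist(lapply(n_orfs, seq_len)))

  lengths <- withSeed(substreamSeed(cfg$seed, 5L), {
    len <- round(rlnorm(n_pep, cfg$length_meanlog, cfg$length_sdlog))
    while (any(len < cfg$length_min))
      len[len < cfg$length_min] <-
        round(rlnorm(sum(len < cfg$length_min),
                     cfg$length_meanlog, cfg$length_sdlog))
    len
  })

  assignable <- setdiff(cfg$ko_universe, cfg$planted_absent_kos)
  anno <- withSeed(substreamSeed(cfg$seed, 6L), {
    ko <- rep(NA_character_, n_pep)
    has_ko <- runif(n_pep) < cfg$ko_annotation_fraction
    ko[has_ko] <- sample(assignable, sum(has_ko), replace = TRUE)
    taxon <- rep(NA_character_, n_pep)
    has_tax <- runif(n_pep) < cfg$taxon_annotation_fraction
    taxon[has_tax] <- sample(cfg$taxon_universe, sum(has_tax), replace = TRUE)
    list(ko = ko, taxon = taxon)
  })

  baseline <- withSeed(substreamSeed(cfg$seed, 7L),
                       rlnorm(cfg$n_transcripts, 0, cfg$baseline_sdlog))

  # pin each required KO to the first peptide of a high-expression
  # transcript, guaranteeing nonzero expression of planted modules
  if (length(req_kos)) {
    top_tx <- order(baseline, decreasing = TRUE)[seq_along(req_kos)]
    pin <- match(tx_ids[top_tx], pep_tx)   # first peptide of each
    anno$ko[pin] <- req_kos
  }

  sp_lev <- unique(design$species)
  diff_truth <- withSeed(substreamSeed(cfg$seed, 8L), {
    if (cfg$n_differential_features > 0 && length(sp_lev) >= 2) {
      ids <- sample(cfg$n_transcripts, cfg$n_differential_features)
      data.frame(transcript_id = tx_ids[ids],
                 up_group = rep(sp_lev,
                                length.out = cfg$n_differential_features),
                 stringsAsFactors = FALSE)
    } else
      data.frame(transcript_id = character(), up_group = character(),
                 stringsAsFactors = FALSE)
  })

  counts <- withSeed(substreamSeed(cfg$seed, 9L), {
    sapply(seq_len(nrow(design)), function(s) {
      w <- baseline
      if (nrow(diff_truth)) {
        bump <- diff_truth$transcript_id[diff_truth$up_group ==
                                           design$species[s]]
        idx <- match(bump, tx_ids)
        w[idx] <- w[idx] * 2^cfg$differential_log2fc
      }
      depth <- max(1L, rpois(1, cfg$tx_depth_mean))
      rmultinom(1, depth, w / sum(w))[, 1]
    })
  })
  dimnames(counts) <- list(tx_ids, design$sample)

  annotation <- data.frame(
    transcript_id = pep_tx, peptide_id = pep_ids,
    peptide_length = lengths, ko = anno$ko, taxon = anno$taxon,
    stringsAsFactors = FALSE)
  truth <- list(differential = diff_truth,
                complete_modules = cfg$planted_complete_modules,
                absent_kos = cfg$planted_absent_kos,
                required_kos = req_kos)
  list(counts = counts, annotation = annotation, truth = truth)
}

#' Simulate a complete holobiont dataset
#'
#' Runs \code{\link{simulateAsvTable}} and
#' \code{\link{simulateMetatranscriptome}} over the same sampling
#' design and bundles them with the merged planted truth.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param catalog optional \linkS4class{ModuleCatalog}; generated with
#'   \code{\link{syntheticModuleCatalog}} when planted modules are
#'   configured and none is supplied.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
simulateDataset <- function(cfg, catalog = NULL) {
  if (is.null(catalog) && (length(cfg$planted_complete_modules) ||
                           length(cfg$planted_absent_kos)))
    catalog <- syntheticModuleCatalog(cfg)
  asv <- simulateAsvTable(cfg)
  mtx <- simulateMetatranscriptome(cfg, catalog)
  truth <- c(mtx$truth,
             list(asv_effects = S4Vectors::metadata(asv)$planted))
  new("SyntheticDataset", asv = asv, transcriptCounts = mtx$counts,
      orfAnnotation = mtx$annotation, truth = truth)
}

#' A synthetic module catalog aligned with a simulation config
#'
#' Builds a deterministic catalog (given the config seed) containing:
#' one module per id in \code{planted_complete_modules}, whose
#' definitions only use KOs the generator can express; one
#' guaranteed-incomplete module per KO in \code{planted_absent_kos}
#' (the withheld KO is a required plain step); and \code{n_filler}
#' random modules mixing alternatives, complexes and optional subunits.
#' Labelled \emph{synthetic}: this stands in for a curated KEGG module
#' resource, which the package deliberately does not fetch.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param n_filler number of additional random modules (default 6).
#' @param steps_per_module steps per generated definition (default 3).
#' @return a \linkS4class{ModuleCatalog}.
#' @export
syntheticModuleCatalog <- function(cfg, n_filler = 6, steps_per_module = 3) {
  stopifnot(inherits(cfg, "SimConfig"))
  assignable <- setdiff(cfg$ko_universe, cfg$planted_absent_kos)
  lev_b <- c("Energy metabolism", "Carbohydrate metabolism",
             "Metabolism of cofactors and vitamins")
  lev_c <- c("Nitrogen metabolism", "Carbon fixation", "Methane metabolism",
             "Central carbohydrate metabolism", "Cofactor biosynthesis")
  withSeed(substreamSeed(cfg$seed, 10L), {
    rows <- list()
    add <- function(id, name, def)
      rows[[length(rows) + 1L]] <<- data.frame(
        module_id = id, name = name,
        level_B = sample(lev_b, 1), level_C = sample(lev_c, 1),
        definition = def, stringsAsFactors = FALSE)
    for (id in cfg$planted_complete_modules)
      add(id, paste0("planted complete ", id),
          .randomDefinition(assignable, steps_per_module))
    for (i in seq_along(cfg$planted_absent_kos)) {
      ko <- cfg$planted_absent_kos[i]
      ctx <- sample(assignable, 2)
      add(sprintf("M_INC%02d", i), paste0("requires withheld ", ko),
          paste(ctx[1], ko, ctx[2]))
    }
    for (i in seq_len(n_filler))
      add(sprintf("M_FIL%02d", i), sprintf("filler %02d", i),
          .randomDefinition(assignable, steps_per_module))
    moduleCatalog(do.call(rbind, rows))
  })
}

# one random definition: steps drawn from leaf / alternative / complex /
# complex-with-optional forms
.randomDefinition <- function(kos, n_steps) {
  steps <- vapply(seq_len(n_steps), function(i) {
    form <- sample(c("leaf", "alt", "cpx", "cpx_opt"), 1,
                   prob = c(0.4, 0.25, 0.25, 0.1))
    k <- sample(kos, 3)
    switch(form,
      leaf = k[1],
      alt = paste0(k[1], ",", k[2]),
      cpx = paste0(k[1], "+", k[2]),
      cpx_opt = paste0(k[1], "+", k[2], "-", k[3]))
  }, "")
  paste(steps, collapse = " ")
}
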