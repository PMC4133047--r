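# Configuration-driven orchestration of the full analysis pipeline.

#' Default pipeline configuration
#'
#' Returns the full default configuration: study-standard parameter values
#' (QC missingness cap 0.10, whole-sample MAF 0.05, block threshold 0.5
#' cM/Mb with sizes 5-15, LD pruning 50/10/0.1, 82 individuals per
#' resampling group with 1000 replicates, 30 ancestry runs per K, SSC
#' threshold 0.9, generation time 25 years), a master seed, and desk-scale
#' simulation sizes for the synthetic fixture.
#'
#' @return Nested list of defaults; override any element via the
#'   \code{config} argument of \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    output_dir = "admixpulse_output",
    stages = c("simulate", "qc", "blocks", "het", "geo", "fst", "tree",
               "asd", "mds", "procrustes", "l0test", "ancestry", "modes", "date"),
    input = list(ped = NULL, map_file = NULL, recomb_map = NULL,
                 populations = NULL),
    simulate = list(),        # overrides for makeStudyFixture
    qc = list(max_missing = 0.10, drop_monomorphic = TRUE, min_maf = 0,
              hwe_alpha = 0),
    blocks = list(min_size = 5, max_size = 15, threshold = 0.5),
    geo = list(d_km = 350),
    fst = list(min_maf = 0.05, n_boot = 100),
    prune = list(window = 50, step = 10, r2_max = 0.1),
    mds = list(n_per_group = 82, replicates = 100),
    ancestry = list(runs = 10, K = c(2, 3), tol = 1e-4, ssc_threshold = 0.9),
    date = list(generation_years = 25)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every
#' intermediate artifact (QC report, block table, heterozygosity table,
#' regression report, FST matrix, MDS coordinates, Newick tree, ASD matrix,
#' permutation-test report, membership matrices, mode report, dating report)
#' to the output directory, plus a JSON manifest with parameters, derived
#' seeds and file checksums. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config list of overrides to \code{\link{defaultPipelineConfig}},
#'   or a path to a YAML file of such overrides.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  deps <- list(het = "blocks", geo = "het", procrustes = "mds", l0test = "mds",
               modes = "ancestry", date = "modes")
  for (st in names(deps))
    if (st %in% stages && !all(deps[[st]] %in% stages))
      stop(sprintf("stage '%s' requires stage(s): %s", st,
                   paste(setdiff(deps[[st]], stages), collapse = ", ")))
  seed <- cfg$seed
  manifest <- list(package_version = as.character(utils::packageVersion("admixpulse")),
                   seed = seed, stages = stages, files = list())
  note <- function(name, path) {
    manifest$files[[name]] <<- list(path = path,
                                    md5 = unname(tools::md5sum(path)))
    manifest
  }
  logmsg <- function(...) message(sprintf("[admixpulse] %s", sprintf(...)))

  fixture <- NULL
  if ("simulate" %in% stages) {
    logmsg("simulate: generating study fixture")
    fixture <- do.call(makeStudyFixture,
                       c(cfg$simulate, list(seed = deriveSeed(seed, "simulate"))))
    paths <- writeStudyFixture(fixture, out, "fixture")
    for (nm in names(paths)) manifest <- note(paste0("fixture_", nm), paths[[nm]])
    g <- fixture$genotypes
    popTable <- fixture$populationTable
    rmap <- fixture$map
  } else {
    if (is.null(cfg$input$ped)) stop("no input: enable the simulate stage or provide input paths")
    g <- readPedMap(cfg$input$ped, cfg$input$map_file)
    rmap <- if (!is.null(cfg$input$recomb_map))
      utils::read.table(cfg$input$recomb_map, header = TRUE, sep = "\t") else NULL
    popTable <- if (!is.null(cfg$input$populations))
      utils::read.table(cfg$input$populations, header = TRUE, sep = "\t") else NULL
  }

  if ("qc" %in% stages) {
    logmsg("qc: filtering %d SNPs", nrow(g))
    res <- qcFilter(g, maxMissing = cfg$qc$max_missing,
                    dropMonomorphic = cfg$qc$drop_monomorphic,
                    minMAF = cfg$qc$min_maf, hweAlpha = cfg$qc$hwe_alpha)
    g <- res$genotypes
    p <- file.path(out, "qc_report.tsv"); writeTsv(res$report, p)
    manifest <- note("qc_report", p)
  }

  blocks <- NULL
  if ("blocks" %in% stages) {
    logmsg("blocks: building haplotype blocks")
    rates <- intervalRates(rmap, snpInfo(g))
    blocks <- buildBlocks(rates, cfg$blocks$min_size, cfg$blocks$max_size,
                          cfg$blocks$threshold, mode = "below")
    b <- blockTable(blocks)
    si <- snpInfo(g)
    bed <- data.frame(chromosome = b$chromosome,
                      start_bp = si$position_bp[b$first],
                      end_bp = si$position_bp[b$last],
                      n_snps = b$n_snps)
    p <- file.path(out, "blocks.tsv"); writeTsv(bed, p)
    manifest <- note("blocks", p)
  }

  het <- NULL
  if ("het" %in% stages) {
    logmsg("het: EM haplotype heterozygosity")
    het <- genomewideHeterozygosity(g, blocks)
    p <- file.path(out, "heterozygosity.tsv"); writeTsv(het$table, p)
    manifest <- note("heterozygosity", p)
  }

  if ("geo" %in% stages && !is.null(popTable)) {
    logmsg("geo: waypoint distances and serial-founder regression")
    routes <- defaultRoutes()
    routes[setdiff(unique(popTable$region), names(routes))] <- list(NULL)
    popTable <- populationDistances(popTable, routes)
    reg <- hetDistanceRegression(het$table, popTable)
    p <- file.path(out, "regression.tsv")
    writeTsv(data.frame(slope = reg$slope, intercept = reg$intercept,
                        r2 = reg$r2, p_value = reg$p, n = reg$n), p)
    manifest <- note("regression", p)
    p2 <- file.path(out, "population_distances.tsv"); writeTsv(popTable, p2)
    manifest <- note("population_distances", p2)
  }

  fst <- NULL
  if ("fst" %in% stages) {
    logmsg("fst: Weir-Cockerham FST matrix")
    fst <- fstMatrix(g, minMAF = cfg$fst$min_maf)
    p <- file.path(out, "fst_matrix.tsv")
    writeTsv(data.frame(population = rownames(distanceMatrix(fst)),
                        distanceMatrix(fst), check.names = FALSE), p)
    manifest <- note("fst_matrix", p)
    popMds <- classicalMDS(fst)
    p2 <- file.path(out, "fst_mds.tsv")
    writeTsv(data.frame(population = rownames(mdsPoints(popMds)),
                        mdsPoints(popMds), rho = mdsRho(popMds)), p2)
    manifest <- note("fst_mds", p2)
  }

  if ("tree" %in% stages) {
    logmsg("tree: BIONJ with %d bootstraps", cfg$fst$n_boot)
    tree <- bootstrapSupport(g, nBoot = cfg$fst$n_boot,
                             seed = deriveSeed(seed, "bootstrap"),
                             minMAF = cfg$fst$min_maf)
    p <- file.path(out, "fst_bionj.nwk")
    ape::write.tree(tree, p)
    manifest <- note("tree", p)
  }

  asd <- mdsRes <- scheme <- NULL
  if ("asd" %in% stages) {
    logmsg("asd: allele-sharing dissimilarities")
    asd <- asdMatrix(g)
    p <- file.path(out, "asd_matrix.tsv")
    writeTsv(data.frame(id = rownames(distanceMatrix(asd)),
                        distanceMatrix(asd), check.names = FALSE), p)
    manifest <- note("asd_matrix", p)
  }

  if ("mds" %in% stages && !is.null(asd) && !is.null(popTable)) {
    logmsg("mds: balanced resampling MDS (%d replicates)", cfg$mds$replicates)
    scheme <- buildGroups(popTable, d = cfg$geo$d_km)
    mdsRes <- resampledMDS(asd, scheme, populations(g),
                           nPerGroup = cfg$mds$n_per_group,
                           replicates = cfg$mds$replicates,
                           seed = deriveSeed(seed, "mds"))
    pts <- mdsPoints(mdsRes$mds)
    p <- file.path(out, "individual_mds.tsv")
    writeTsv(data.frame(id = rownames(pts), pts,
                        population = populations(g)[rownames(pts)]), p)
    manifest <- note("individual_mds", p)
    p2 <- file.path(out, "mds_replicates.tsv"); writeTsv(mdsRes$log, p2)
    manifest <- note("mds_replicates", p2)
  }

  if ("procrustes" %in% stages && !is.null(mdsRes)) {
    logmsg("procrustes: full vs resampled configuration")
    full <- classicalMDS(distanceMatrix(asd))
    pro <- procrustesAlign(full, mdsRes$mds)
    p <- file.path(out, "procrustes.tsv")
    writeTsv(data.frame(t0 = pro$t0, D = pro$D, n_shared = length(pro$labels)), p)
    manifest <- note("procrustes", p)
  }

  if ("l0test" %in% stages && !is.null(mdsRes) && !is.null(popTable)) {
    coastal <- popTable$population[popTable$special_group == "indigenous_NW" &
                                     grepl("^Coast", popTable$population)]
    interior <- popTable$population[popTable$special_group == "indigenous_NW" &
                                      grepl("^Int", popTable$population)]
    if (length(coastal) && length(interior)) {
      logmsg("l0test: coastal vs interior permutation test")
      pops <- populations(g)
      pts <- mdsPoints(mdsRes$mds)
      gA <- rownames(pts)[pops[rownames(pts)] %in% coastal]
      gB <- rownames(pts)[pops[rownames(pts)] %in% interior]
      l0 <- l0Test(mdsRes$mds, gA, gB, nPerm = 1000,
                   seed = deriveSeed(seed, "l0"))
      p <- file.path(out, "l0_test.tsv")
      writeTsv(data.frame(l0 = l0$l0, sd = l0$sdBetween, n_perm = l0$nPerm,
                          p_value = l0$p, display = l0$pDisplay), p)
      manifest <- note("l0_test", p)
    }
  }

  runsPerK <- NULL
  if ("ancestry" %in% stages) {
    logmsg("ancestry: %d unsupervised runs per K", cfg$ancestry$runs)
    pruned <- ldPrune(g, cfg$prune$window, cfg$prune$step, cfg$prune$r2_max)
    runsPerK <- list()
    for (K in cfg$ancestry$K) {
      runsPerK[[as.character(K)]] <- lapply(seq_len(cfg$ancestry$runs), function(r)
        estimateAncestryUnsupervised(pruned, K,
                                     seed = deriveSeed(seed, sprintf("anc_K%d_r%d", K, r)),
                                     tol = cfg$ancestry$tol))
      Q <- membershipQ(runsPerK[[as.character(K)]][[1]])
      p <- file.path(out, sprintf("ancestry_K%d_run1.Q", K))
      utils::write.table(format(Q, digits = 6), p, quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      manifest <- note(sprintf("ancestry_K%d", K), p)
    }
  }

  modesPerK <- NULL
  if ("modes" %in% stages && !is.null(runsPerK)) {
    logmsg("modes: SSC grouping at threshold %.2f", cfg$ancestry$ssc_threshold)
    modesPerK <- lapply(runsPerK, groupModes, threshold = cfg$ancestry$ssc_threshold)
    rep_ <- do.call(rbind, lapply(names(modesPerK), function(k) {
      ms <- modesPerK[[k]]
      data.frame(K = as.integer(k), mode = seq_along(modeRuns(ms)),
                 n_runs = lengths(modeRuns(ms)))
    }))
    p <- file.path(out, "mode_report.tsv"); writeTsv(rep_, p)
    manifest <- note("mode_report", p)
  }

  if ("date" %in% stages && !is.null(modesPerK) && !is.null(fixture)) {
    logmsg("date: moment-based admixture dating")
    qPerK <- lapply(modesPerK, modeMembership, mode = 1L)
    pops <- populations(g)
    adm <- fixture$admixed
    groups <- list(coastal = adm$label[adm$group == "coastal"],
                   interior = adm$label[adm$group == "interior"])
    srcPops <- rownames(fixture$sourceFreqs)[1:2]
    sourceRefs <- lapply(srcPops, function(sp) names(pops)[pops == sp])
    names(sourceRefs) <- srcPops
    dr <- datingReport(qPerK, groups, sourceRefs, pops,
                       generationYears = cfg$date$generation_years)
    if (!is.null(dr$perK)) {
      p <- file.path(out, "dating_perK.tsv"); writeTsv(dr$perK, p)
      manifest <- note("dating_perK", p)
      p2 <- file.path(out, "dating_summary.tsv"); writeTsv(dr$summary, p2)
      manifest <- note("dating_summary", p2)
    } else {
      logmsg("date: no identifiable source cluster at any K; report skipped")
    }
  }

  mPath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
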