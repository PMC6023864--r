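## End-to-end orchestration: synthetic multi-scenario runs through the
## geographical track (SDM transferability tables) and the environmental
## track (niche-overlap table). Every stage seed is derived from the
## master seed and a stage label, so whole runs and single stages replay
## deterministically.

#' Default run configuration (synthetic mode)
#'
#' Describes a four-scenario study: a current scenario plus three
#' paleo-scenario analogues. The Last Interglacial analogue applies
#' +3.8 degrees C to the quarterly temperature variables and a 16%
#' precipitation decrease; the glacial-maximum analogue is cold with
#' mildly reduced precipitation and the mid-Holocene analogue slightly
#' warmer and moister than current. Occurrence sample sizes default to
#' 404 current records and 28/16/13 fossil records for the three
#' paleo-scenarios.
#'
#' @param masterSeed integer master seed; all stage seeds derive from it.
#' @param conserved logical: fossils drawn under the same niche truth
#'   (TRUE) or under a niche whose optimum is displaced by
#'   `nicheShiftSD` pooled SDs of temperature seasonality (FALSE).
#' @param nicheShiftSD niche-shift magnitude for the shifted condition,
#'   in per-variable SD units (default 2).
#' @param ... named overrides merged over the defaults (nested lists are
#'   replaced wholesale).
#' @return a RunConfig list.
#' @export
defaultRunConfig <- function(masterSeed = 1L, conserved = TRUE,
                             nicheShiftSD = 2, ...) {
  cfg <- list(
    master_seed = as.integer(masterSeed),
    grid = list(rows = 120L, cols = 120L, autocorr_length = 6),
    niche = list(
      optimum = c(bio4 = 6300, bio8 = 14, bio9 = 20, bio18 = 95, bio19 = 320),
      tolerance = c(bio4 = 600, bio8 = 3.5, bio9 = 4, bio18 = 25, bio19 = 65),
      max_prevalence = 0.9
    ),
    conserved = conserved,
    niche_shift_sd = nicheShiftSD,
    scenarios = list(
      list(name = "MIS1", offset = c(0, 0.8, 0.8, 0, 0),
           factor = c(1, 1, 1, 1.08, 1.08), n_fossils = 28L),
      list(name = "MIS2", offset = c(0, -5, -5, 0, 0),
           factor = c(1, 1, 1, 0.9, 0.9), n_fossils = 16L),
      list(name = "MIS5e", offset = c(0, 3.8, 3.8, 0, 0),
           factor = c(1, 1, 1, 0.84, 0.84), n_fossils = 13L)
    ),
    n_presences = 404L,
    background_fraction = 0.2,
    thin_cell_size = 1,
    preprocess = list(r_threshold = 0.7, vif_threshold = 5),
    sdm = list(degree = 2L, n_trees = 500L, reg_multiplier = 3,
               features = c("linear", "quadratic")),
    eval = list(iterations = 20L, test_fraction = 0.4),
    envspace = list(resolution = 100L, replicates = 100L,
                    corrected = TRUE, similarity_null = "random-points"),
    output_dir = NULL
  )
  mergeConfig(cfg, list(...))
}

# Named sub-lists are merged key-by-key; anything else (including
# unnamed lists such as `scenarios`) is replaced wholesale.
mergeConfig <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    o <- overrides[[nm]]
    if (is.list(o) && is.list(cfg[[nm]]) &&
        !is.null(names(o)) && all(nzchar(names(o))))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], o)
    else cfg[[nm]] <- o
  }
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Fields present in the file override [defaultRunConfig()] values.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a RunConfig list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  mergeConfig(defaultRunConfig(), user)
}

#' Niche displacement along the leading pooled-climate axis
#'
#' Returns a per-variable offset (variable units) that moves a niche
#' optimum by `k` pooled standard deviations along the first principal
#' axis of the pooled climate space — the canonical "shifted niche"
#' condition. Displacing along PC1 ensures the shift is fully expressed
#' in the two-axis analysis plane rather than diluted across unresolved
#' dimensions.
#'
#' @param stacks list of \linkS4class{ClimateStack}s defining the pooled
#'   space.
#' @param k shift magnitude in pooled-SD units (default 2).
#' @return named numeric offset vector in variable units.
#' @export
nicheShiftVector <- function(stacks, k = 2) {
  if (is(stacks, "ClimateStack")) stacks <- list(stacks)
  pca <- fitGlobalPCA(stacks)
  vars <- rownames(pca@loadings)
  env <- do.call(rbind, lapply(stacks, function(s)
    unmaskedEnv(s)$env[, vars, drop = FALSE]))
  s1 <- stats::sd(pcaScores(pca, env)[, 1])
  k * s1 * pca@loadings[, 1] * pca@scale
}

# Build all scenario stacks, niche truths and occurrence sets declared by
# a config. Shared by both tracks so they see identical worlds.
buildSyntheticWorld <- function(config) {
  seed <- config$master_seed
  sc <- scenarioConfig(gridRows = config$grid$rows,
                       gridCols = config$grid$cols,
                       autocorrLength = config$grid$autocorr_length,
                       seed = deriveSeed(seed, "climate"))
  current <- generateClimateStack(sc, scenarioId = "current")
  niche <- nicheTruth(config$niche$optimum, config$niche$tolerance,
                      config$niche$max_prevalence)
  stacks <- list(current = current)
  for (s in config$scenarios)
    stacks[[s$name]] <- shiftScenario(current, shiftSpec(s$offset, s$factor),
                                      scenarioId = s$name)
  fossilNiche <- niche
  if (!isTRUE(config$conserved))
    fossilNiche <- nicheTruth(
      config$niche$optimum +
        nicheShiftVector(stacks, k = config$niche_shift_sd),
      config$niche$tolerance, config$niche$max_prevalence)
  fossils <- list()
  for (s in config$scenarios) {
    suit <- trueSuitability(stacks[[s$name]], fossilNiche)
    occ <- sampleOccurrences(suit, s$n_fossils,
                             seed = deriveSeed(seed, paste0("fossils_", s$name)),
                             role = "fossil", period = s$name)
    fossils[[s$name]] <- thinToGrid(occ, config$thin_cell_size)
  }
  suitCur <- trueSuitability(current, niche)
  presences <- sampleOccurrences(suitCur, config$n_presences,
                                 seed = deriveSeed(seed, "presences"),
                                 role = "presence", period = "current")
  presences <- thinToGrid(presences, config$thin_cell_size)
  list(stacks = stacks, niche = niche, fossilNiche = fossilNiche,
       presences = presences, fossils = fossils, truth = suitCur,
       scenarioConfig = sc)
}

# The four algorithm x contrast rows of the transferability tables.
modelRows <- function() {
  list(
    list(algorithm = "glm_poly", contrast = "pseudoabsence"),
    list(algorithm = "random_forest", contrast = "pseudoabsence"),
    list(algorithm = "maxent_like", contrast = "background"),
    list(algorithm = "glm_poly", contrast = "background")
  )
}

fitRow <- function(row, stack, presences, background, pseudo, config, seed) {
  contrastOcc <- if (row$contrast == "background") background else pseudo
  tab <- buildTrainingTable(stack, presences, contrastOcc,
                            contrastKind = row$contrast)
  model <- fitSdm(tab, algorithm = row$algorithm,
                  degree = config$sdm$degree, nTrees = config$sdm$n_trees,
                  features = config$sdm$features,
                  regMultiplier = config$sdm$reg_multiplier,
                  seed = seed)
  list(table = tab, model = model)
}

#' Run the geographical (SDM transferability) track
#'
#' For each algorithm x contrast row: calibrate in the current scenario,
#' bootstrap-validate, project (clamped) to every paleo-scenario and
#' validate against that scenario's independent fossil presences, and
#' compute the MESS/MoD extrapolation surface. The reverse direction
#' (calibrate in each paleo-scenario on its fossil records, transfer to
#' current, validate with the current presences) yields the
#' cross-projection table.
#'
#' @param config a RunConfig list (see [defaultRunConfig()]).
#' @param world optional pre-built synthetic world (internal reuse).
#' @return list with `forward` and `cross` data.frames, fitted `models`,
#'   projected `maps`, `mess` results and the `world` used.
#' @export
runGeographic <- function(config = defaultRunConfig(), world = NULL) {
  if (is.null(world)) world <- buildSyntheticWorld(config)
  seed <- config$master_seed
  current <- world$stacks$current
  paleoNames <- setdiff(names(world$stacks), "current")
  background <- sampleBackground(current, config$background_fraction,
                                 seed = deriveSeed(seed, "background"))
  pseudo <- samplePseudoabsences(current, world$presences,
                                 seed = deriveSeed(seed, "pseudoabsence"))
  forward <- list(); maps <- list(); messes <- list(); models <- list()
  targetBg <- lapply(paleoNames, function(nm)
    sampleBackground(world$stacks[[nm]], config$background_fraction,
                     seed = deriveSeed(seed, paste0("target_bg_", nm))))
  names(targetBg) <- paleoNames
  for (row in modelRows()) {
    rowId <- paste(row$algorithm, row$contrast, sep = "/")
    fr <- fitRow(row, current, world$presences, background, pseudo,
                 config, deriveSeed(seed, paste0("fit_", rowId)))
    ev <- bootstrapValidate(fr$table, algorithm = row$algorithm,
                            iterations = config$eval$iterations,
                            testFraction = config$eval$test_fraction,
                            seed = deriveSeed(seed, paste0("boot_", rowId)),
                            degree = config$sdm$degree,
                            nTrees = config$sdm$n_trees,
                            features = config$sdm$features,
                            regMultiplier = config$sdm$reg_multiplier)
    extAuc <- numeric(0)
    for (nm in paleoNames) {
      map <- projectModel(fr$model, world$stacks[[nm]], clamp = TRUE,
                          modelId = rowId)
      maps[[paste(rowId, nm, sep = "->")]] <- map
      extAuc[nm] <- externalValidate(map, world$fossils[[nm]], targetBg[[nm]])
    }
    models[[rowId]] <- fr$model
    forward[[rowId]] <- data.frame(
      model = row$algorithm, dataset = row$contrast,
      fit_metric = names(fitMetric(fr$model)),
      fit_value = unname(fitMetric(fr$model)),
      auc_internal = ev@aucInternalMean,
      auc_internal_sd = ev@aucInternalSd,
      t(extAuc), stringsAsFactors = FALSE)
    if (row$algorithm == "glm_poly" && row$contrast == "pseudoabsence")
      for (nm in paleoNames)
        messes[[nm]] <- messSurface(world$stacks[[nm]], fr$table)
  }
  cross <- list()
  curBg <- sampleBackground(current, config$background_fraction,
                            seed = deriveSeed(seed, "cross_current_bg"))
  for (nm in paleoNames) {
    stk <- world$stacks[[nm]]
    bgP <- sampleBackground(stk, config$background_fraction,
                            seed = deriveSeed(seed, paste0("cross_bg_", nm)))
    psP <- samplePseudoabsences(stk, world$fossils[[nm]],
                                seed = deriveSeed(seed, paste0("cross_ps_", nm)))
    for (row in modelRows()) {
      rowId <- paste(row$algorithm, row$contrast, sep = "/")
      fr <- fitRow(row, stk, world$fossils[[nm]], bgP, psP, config,
                   deriveSeed(seed, paste0("cross_fit_", rowId, nm)))
      ev <- bootstrapValidate(fr$table, algorithm = row$algorithm,
                              iterations = config$eval$iterations,
                              testFraction = config$eval$test_fraction,
                              seed = deriveSeed(seed, paste0("cross_boot_", rowId, nm)),
                              degree = config$sdm$degree,
                              nTrees = config$sdm$n_trees,
                              features = config$sdm$features,
                              regMultiplier = config$sdm$reg_multiplier)
      map <- projectModel(fr$model, current, clamp = TRUE, modelId = rowId)
      cross[[paste(rowId, nm)]] <- data.frame(
        model = row$algorithm, dataset = row$contrast, scenario = nm,
        auc_calibrated = ev@aucInternalMean,
        auc_projection_to_current =
          externalValidate(map, world$presences, curBg),
        stringsAsFactors = FALSE)
    }
  }
  list(forward = do.call(rbind, c(forward, list(make.row.names = FALSE))),
       cross = do.call(rbind, c(cross, list(make.row.names = FALSE))),
       models = models, maps = maps, mess = messes, world = world)
}

#' Run the environmental (niche-overlap) track
#'
#' Fits the pooled-scenario PCA, then for every current/paleo pair builds
#' the two kernel occupancy grids on a shared extent and computes
#' Schoener's D, the equivalency test, the similarity test in both
#' directions, the expansion/stability/unfilling indices and the
#' centroid shifts.
#'
#' @param config a RunConfig list.
#' @param world optional pre-built synthetic world (internal reuse).
#' @return list with `table` (one row per scenario pair), the
#'   \linkS4class{OverlapReport} objects, `grids`, the `pca` and `world`.
#' @export
runEnvironmental <- function(config = defaultRunConfig(), world = NULL) {
  if (is.null(world)) world <- buildSyntheticWorld(config)
  seed <- config$master_seed
  es <- config$envspace
  pca <- fitGlobalPCA(world$stacks)
  current <- world$stacks$current
  curOccEnv <- extractEnv(current, world$presences)
  curBgEnv <- unmaskedEnv(current)$env
  paleoNames <- setdiff(names(world$stacks), "current")
  reports <- list(); grids <- list(); shifts <- list()
  for (nm in paleoNames) {
    stk <- world$stacks[[nm]]
    fosEnv <- extractEnv(stk, world$fossils[[nm]])
    bgEnv <- unmaskedEnv(stk)$env
    extent <- scoreExtent(rbind(pcaScores(pca, curBgEnv),
                                pcaScores(pca, bgEnv)))
    gCur <- buildNicheGrid(pca, curOccEnv, curBgEnv,
                           resolution = es$resolution, extent = extent,
                           entityId = "current", scenarioId = "current")
    gPal <- buildNicheGrid(pca, fosEnv, bgEnv,
                           resolution = es$resolution, extent = extent,
                           entityId = nm, scenarioId = nm)
    D <- schoenerD(gCur, gPal, corrected = es$corrected)
    eq <- equivalencyTest(curOccEnv, fosEnv, curBgEnv, bgEnv, pca,
                          resolution = es$resolution,
                          replicates = es$replicates,
                          seed = deriveSeed(seed, paste0("equiv_", nm)),
                          corrected = es$corrected)
    simAB <- similarityTest(gCur, fosEnv, bgEnv, pca,
                            replicates = es$replicates,
                            seed = deriveSeed(seed, paste0("sim_ab_", nm)),
                            nullModel = es$similarity_null,
                            corrected = es$corrected)
    simBA <- similarityTest(gPal, curOccEnv, curBgEnv, pca,
                            replicates = es$replicates,
                            seed = deriveSeed(seed, paste0("sim_ba_", nm)),
                            nullModel = es$similarity_null,
                            corrected = es$corrected)
    dyn <- nicheDynamics(gCur, gPal)
    pairId <- paste0("current-", nm)
    reports[[pairId]] <- new("OverlapReport", pair = pairId, D = D,
      equivalencyP = eq$p, similarityPAToB = simAB$p,
      similarityPBToA = simBA$p,
      expansion = unname(dyn["expansion"]),
      stability = unname(dyn["stability"]),
      unfilling = unname(dyn["unfilling"]),
      nReplicates = as.integer(es$replicates))
    grids[[pairId]] <- list(current = gCur, paleo = gPal)
    shifts[[pairId]] <- centroidShift(gCur, gPal)
  }
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  rownames(tab) <- NULL
  list(table = tab, reports = reports, grids = grids, shifts = shifts,
       pca = pca, world = world)
}

#' Run both tracks and write all reports
#'
#' @param config a RunConfig list.
#' @param outputDir directory for JSON/CSV reports and projection rasters;
#'   defaults to `config$output_dir` (no files written when NULL).
#' @return list with `geographic` and `environmental` results.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        outputDir = config$output_dir) {
  world <- buildSyntheticWorld(config)
  geo <- runGeographic(config, world = world)
  env <- runEnvironmental(config, world = world)
  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    writeReport(geo$forward, file.path(outputDir, "forward_table.json"))
    writeReport(geo$cross, file.path(outputDir, "cross_table.json"))
    writeReport(env$table, file.path(outputDir, "overlap_table.json"))
    utils::write.csv(geo$forward,
                     file.path(outputDir, "forward_table.csv"),
                     row.names = FALSE)
    utils::write.csv(geo$cross, file.path(outputDir, "cross_table.csv"),
                     row.names = FALSE)
    utils::write.csv(env$table, file.path(outputDir, "overlap_table.csv"),
                     row.names = FALSE)
    for (nm in names(geo$maps))
      writeRaster(geo$maps[[nm]],
                  file.path(outputDir, paste0(gsub("[^A-Za-z0-9]+", "_", nm),
                                              ".asc")))
  }
  list(geographic = geo, environmental = env)
}
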