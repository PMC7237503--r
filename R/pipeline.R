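table1Md5 <- "5dd61649c4c0ef3bd8c96ccc6feb6a70"

#' Load the bundled six-comparison resistance-panel fixture
#'
#' Returns the packaged 13-protein x 6-comparison log2 fold-change matrix
#' of the cross-inhibitor, cross-format resistance panel (three resistant
#' derivatives vs wild type, each in 2D and 3D culture). The file's
#' checksum is verified on load.
#'
#' @return data.frame with `gene`, `protein` and six log2FC columns
#'   (`bicalut_2D` ... `enzalut_3D`).
#' @examples
#' fx <- loadTable1Fixture()
#' fx[fx$gene == "DECR1", ]
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1_log2fc.tsv",
                      package = "ResistOmics", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), table1Md5))
    stop("fixture corruption: checksum mismatch for table1_log2fc.tsv")
  fx <- read.delim(path, check.names = FALSE)
  stopifnot(nrow(fx) == 13L, ncol(fx) == 8L)
  fx
}

#' Turn a wide log2FC fixture into a comparison table
#'
#' Reshapes a wide per-feature log2 fold-change matrix (such as
#' [loadTable1Fixture()]) into the tidy format of [differentialTable()],
#' assigning a fixed p-value to every cell. Useful to apply
#' [selectConsistent()] to published fold-change tables for which raw
#' replicate data are unavailable.
#'
#' @param fixture data.frame with a `gene` column and
#'   `<group>_<format>` log2FC columns.
#' @param p p-value assigned to every cell (default 0.01, i.e. flagged
#'   significant at the usual 0.05 cut).
#' @return Tidy comparison data.frame with `feature`, `group`, `format`,
#'   `log2fc`, `p`, `q`, `sign`.
#' @export
fixtureToComparison <- function(fixture, p = 0.01) {
  cols <- grep("_", colnames(fixture), value = TRUE)
  long <- do.call(rbind, lapply(cols, function(cn) {
    gf <- strsplit(cn, "_", fixed = TRUE)[[1]]
    data.frame(feature = fixture$gene, group = gf[1], format = gf[2],
               log2fc = fixture[[cn]], p = p, q = p,
               sign = sign(fixture[[cn]]), row.names = NULL)
  }))
  rownames(long) <- NULL
  long
}

#' Generate decoy rows that fail the consistency filter
#'
#' Produces `n` random six-comparison log2FC decoy rows, each guaranteed
#' to fall below the fold-change threshold in at least one comparison, to
#' exercise the consistency filter alongside a real panel.
#'
#' @param n number of decoy rows.
#' @param comparisons comparison column names to generate.
#' @param fcThreshold linear fold-change threshold the decoys must fail.
#' @param seed integer seed.
#' @return data.frame in the wide fixture layout with `gene` =
#'   `decoy01...`.
#' @export
table1Decoys <- function(n = 20,
                         comparisons = c("bicalut_2D", "apalut_2D",
                                         "enzalut_2D", "bicalut_3D",
                                         "apalut_3D", "enzalut_3D"),
                         fcThreshold = 1.5, seed = 1) {
  cut <- log2(fcThreshold)
  withr::with_seed(seed, {
    m <- matrix(runif(n * length(comparisons), -3, 3), n)
    fail <- sample.int(length(comparisons), n, replace = TRUE)
    for (i in seq_len(n)) m[i, fail[i]] <- runif(1, -0.9, 0.9) * cut
    out <- data.frame(gene = sprintf("decoy%02d", seq_len(n)),
                      protein = "synthetic decoy")
    for (j in seq_along(comparisons)) out[[comparisons[j]]] <- m[, j]
    out
  })
}

#' Count the panel retained from the bundled fixture plus decoys
#'
#' Worked example of the consistency filter: the bundled panel fixture is
#' augmented with `nDecoys` synthetic decoy rows, every cell is flagged
#' significant, and [selectConsistent()] is applied requiring the
#' fold-change threshold in all six comparisons with one consistent sign.
#'
#' @param fcThreshold linear fold-change threshold (default 1.5).
#' @param nDecoys number of decoy rows appended.
#' @param seed seed for the decoys.
#' @return List with `nRetained`, `retained` (feature ids) and `nInput`.
#' @examples
#' table1PanelCount()$nRetained
#' @export
table1PanelCount <- function(fcThreshold = 1.5, nDecoys = 20, seed = 1) {
  fx <- loadTable1Fixture()
  decoys <- table1Decoys(nDecoys, fcThreshold = fcThreshold, seed = seed)
  combined <- rbind(fx, decoys)
  res <- fixtureToComparison(combined)
  sel <- selectConsistent(res, fcThreshold = fcThreshold,
                          pThreshold = 0.05, kOfN = 6, requireSign = TRUE)
  list(nRetained = nrow(sel), retained = sel$feature,
       nInput = nrow(combined))
}

#' Default pipeline configuration
#'
#' Returns the full default configuration for [runPipeline()]: one global
#' seed, stage toggles, and per-stage parameter blocks with the standard
#' thresholds (fold change 1.5, p 0.05, lipid fold change 1.2, QC floor
#' 60,000, crop window 2800-3020 cm^-1, anchor 2933 cm^-1, k = 3 strata).
#'
#' @param outdir output directory for stage tables.
#' @param seed global integer seed, hierarchically split per stage.
#' @return Nested configuration list.
#' @export
defaultConfig <- function(outdir = tempfile("resistomics_run"), seed = 1) {
  list(
    outdir = outdir, seed = seed,
    stages = list(simulate = TRUE, diffsig = TRUE, trace = TRUE,
                  lipid = TRUE, raman = TRUE, clinical = TRUE),
    diffsig = list(fc = 1.5, p = 0.05, useQ = TRUE, requireSign = TRUE),
    trace = list(formula = "C16H32O2", mode = "all-elements", purity = 1,
                 trueMid = NULL, nReps = 3, noiseCv = 0.05),
    lipid = list(fc = 1.2, p = 0.05, minGroups = 1, mode = "logFC"),
    raman = list(floor = 60000, sdK = 1, anchor = 2933,
                 crop = c(2800, 3020), nMapsPerGroup = 3, nx = 8, ny = 8,
                 groupDelta = 0.3),
    clinical = list(k = 3, restarts = 20, n = 300,
                    hazardRatios = c(1, 1.5, 2), censorRate = 0.2),
    simulate = list(proteome = list(nFeatures = 500, fracSignature = 0.05,
                                    repsPerGroup = 4, noiseSdLog = 0.3),
                    lipidome = list(nPerClass = 8, koEffect = 2))
  )
}

validateConfig <- function(config) {
  need <- c("outdir", "seed", "stages")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config error: missing field(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config error: 'seed' must be a single integer")
  invisible(TRUE)
}

writeStageTable <- function(x, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the multi-omics pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic inputs
#' generated under the global seed: proteome simulation and differential
#' signature selection (per-format selection, cross-format intersection,
#' truth scoring), isotope-tracing simulation and correction, lipidome
#' simulation and saturation profiling, Raman map simulation and
#' band-ratio comparison, cohort simulation with k-means stratification
#' and logrank testing, plus the bundled-fixture worked example. Every
#' random procedure derives its seed from the global one, so a config is
#' fully reproducible. Stage tables are written as delimited text under
#' `config$outdir` and a machine-readable JSON report is produced.
#'
#' @param config configuration list (see [defaultConfig()]) or the path
#'   to a YAML file with the same structure.
#' @return Invisible run report (list): per-stage parameters, key counts,
#'   output paths, and the package version. Also written as
#'   `report.json` in the output directory.
#' @examples
#' \donttest{
#' cfg <- defaultConfig(seed = 7)
#' cfg$stages[c("raman", "clinical")] <- FALSE
#' rep <- runPipeline(cfg)
#' names(rep$stages)
#' }
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- defaultConfig()
  config <- utils::modifyList(def, config)
  validateConfig(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  report <- list(seed = seed, outdir = config$outdir,
                 package = as.character(utils::packageVersion("ResistOmics")),
                 stages = list())
  on <- function(s) isTRUE(config$stages[[s]])

  if (on("simulate")) {
    pp <- config$simulate$proteome
    lp <- config$simulate$lipidome
    simP <- simProteome(nFeatures = pp$nFeatures,
                        fracSignature = pp$fracSignature,
                        repsPerGroup = pp$repsPerGroup,
                        noiseSdLog = pp$noiseSdLog, seed = seed + 101L)
    cd <- as.data.frame(SummarizedExperiment::colData(simP$matrix))
    cd <- cbind(sample = rownames(cd), cd)
    simT <- simTracingSamples(config$trace$formula,
                              c(0.6, 0, 0.4,
                                rep(0, unname(parseFormula(
                                  config$trace$formula)["C"]) - 2)),
                              seed = seed + 103L)
    simL <- simLipidome(nPerClass = lp$nPerClass,
                        koEffect = lp$koEffect, seed = seed + 104L)
    simR <- simRamanMap(nx = config$raman$nx, ny = config$raman$ny,
                        seed = seed + 201L)
    simC <- simCohort(n = config$clinical$n,
                      hazardRatios = config$clinical$hazardRatios,
                      censorRate = config$clinical$censorRate,
                      seed = seed + 105L)
    ramanTab <- cbind(wavenumber = wavenumbers(simR$map),
                      as.data.frame(spectraMatrix(simR$map)))
    report$stages$simulate <- list(
      generators = c("proteome", "tracing", "lipidome", "raman", "cohort"),
      paths = c(
        writeStageTable(cbind(feature = featureIds(simP$matrix),
                              as.data.frame(abundances(simP$matrix))),
                        config$outdir, "sim_proteome"),
        writeStageTable(cd, config$outdir, "sim_design"),
        writeStageTable(simP$truth, config$outdir, "sim_proteome_truth"),
        writeStageTable(simT, config$outdir, "sim_isotopologues"),
        writeStageTable(cbind(name = featureIds(simL$matrix),
                              as.data.frame(abundances(simL$matrix))),
                        config$outdir, "sim_lipidome"),
        writeStageTable(ramanTab, config$outdir, "sim_raman_map"),
        writeStageTable(cbind(pixel = rownames(pixelCoords(simR$map)),
                              pixelCoords(simR$map)),
                        config$outdir, "sim_raman_coords"),
        writeStageTable(simC, config$outdir, "sim_cohort")))
  }

  if (on("diffsig")) {
    pp <- config$simulate$proteome
    sim <- simProteome(nFeatures = pp$nFeatures,
                       fracSignature = pp$fracSignature,
                       repsPerGroup = pp$repsPerGroup,
                       noiseSdLog = pp$noiseSdLog, seed = seed + 101L)
    res <- differentialTable(sim$matrix)
    ds <- config$diffsig
    sels <- lapply(split(res, res$format), selectConsistent,
                   fcThreshold = ds$fc, pThreshold = ds$p,
                   requireSign = ds$requireSign, useQ = ds$useQ)
    panel <- intersectContexts(sels, res = res,
                               requireSign = ds$requireSign)
    score <- scoreSelection(panel$feature, sim$truth)
    fixture <- table1PanelCount(fcThreshold = ds$fc, seed = seed + 102L)
    report$stages$diffsig <- list(
      params = ds, nFeatures = nrow(sim$matrix),
      panelSize = nrow(panel), sensitivity = score$sensitivity,
      observedFdr = score$observedFdr,
      fixturePanelSize = fixture$nRetained,
      paths = c(writeStageTable(res, config$outdir, "comparisons"),
                writeStageTable(panel, config$outdir, "panel")))
  }

  if (on("trace")) {
    tc <- config$trace
    nC <- unname(parseFormula(tc$formula)["C"])
    trueMid <- tc$trueMid
    if (is.null(trueMid)) {
      trueMid <- numeric(nC + 1); trueMid[1] <- 0.6
      trueMid[min(3, nC + 1)] <- 0.4
    }
    raw <- simTracingSamples(tc$formula, trueMid, nReps = tc$nReps,
                             noiseCv = tc$noiseCv, seed = seed + 103L,
                             mode = tc$mode, purity = tc$purity)
    corrected <- correctTracingTable(raw, mode = tc$mode,
                                     purity = tc$purity)
    report$stages$trace <- list(
      params = tc,
      meanLabelledFraction = mean(corrected$labelledFraction),
      paths = c(writeStageTable(raw, config$outdir, "isotopologues_raw"),
                writeStageTable(corrected, config$outdir,
                                "isotopologues_corrected")))
  }

  if (on("lipid")) {
    lp <- config$simulate$lipidome
    sim <- simLipidome(nPerClass = lp$nPerClass, koEffect = lp$koEffect,
                       seed = seed + 104L)
    lc <- config$lipid
    hm <- lipidDiffMatrix(sim$matrix, sim$species, mode = lc$mode,
                          fcThreshold = lc$fc, pThreshold = lc$p,
                          minGroups = lc$minGroups)
    report$stages$lipid <- list(
      params = lc, nSpecies = nrow(sim$species),
      nRetained = nrow(hm$annotation),
      nHighUnsat = sum(hm$annotation$saturationClass == "high_unsat"),
      paths = writeStageTable(
        cbind(hm$annotation, as.data.frame(hm$values)),
        config$outdir, "lipid_heatmap"))
  }

  if (on("raman")) {
    rc <- config$raman
    runs <- lapply(seq_len(2 * rc$nMapsPerGroup), function(i) {
      grp <- if (i <= rc$nMapsPerGroup) "CTL" else "KO"
      delta <- if (grp == "CTL") 0 else rc$groupDelta
      sim <- simRamanMap(nx = rc$nx, ny = rc$ny, groupDelta = delta,
                         seed = seed + 200L + i)
      out <- ramanPipeline(sim$map, cropLo = rc$crop[1],
                           cropHi = rc$crop[2],
                           intensityFloor = rc$floor, sdK = rc$sdK,
                           anchor = rc$anchor)
      data.frame(map = i, group = grp,
                 meanLipid = out$ratios$summary$mean[1],
                 meanChol = out$ratios$summary$mean[2],
                 retained = out$qcReport$retained)
    })
    perMap <- do.call(rbind, runs)
    cmp <- compareRatioGroups(perMap$meanLipid, perMap$group)
    report$stages$raman <- list(
      params = rc, nMaps = nrow(perMap), lipidRatioP = cmp$p,
      meanRatioByGroup = tapply(perMap$meanLipid, perMap$group, mean),
      paths = writeStageTable(perMap, config$outdir, "raman_ratios"))
  }

  if (on("clinical")) {
    cc <- config$clinical
    coh <- simCohort(n = cc$n, hazardRatios = cc$hazardRatios,
                     censorRate = cc$censorRate, seed = seed + 105L)
    strat <- stratifyKmeans(coh$expression, k = cc$k,
                            restarts = cc$restarts, seed = seed + 106L)
    lr <- logrankTest(strat$stratum, coh$time, coh$event)
    coh$stratum <- strat$stratum
    report$stages$clinical <- list(
      params = cc, n = nrow(coh), strataSizes = table(strat$stratum),
      logrank = lr,
      paths = writeStageTable(coh, config$outdir, "cohort_strata"))
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
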