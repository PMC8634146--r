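#' Experiment configuration
#'
#' Bundles every choice that determines a run: cue condition, semantics
#' condition, article and role handling, split, training regime, production
#' settings and an optional pruning sweep. A config plus a lexicon fully
#' determines the report (all randomness is seeded from \code{seed}).
#'
#' @param unit,n cue unit and n-gram size.
#' @param d semantic dimensionality; NULL means "same as the number of cues".
#' @param sdLexeme,sdFeature,sdNoise,featureScale simulated-semantics
#'   parameters (see \code{\link{simulateSemanticSpace}}).
#' @param numberCoding "equipollent" or "privative".
#' @param articles FALSE, "definite_only" or "definite_and_indefinite".
#' @param roles FALSE, or a role table (TRUE means
#'   \code{\link{defaultRoleTable}}); roles imply simulated role
#'   frequencies.
#' @param trainFraction,splitMode split settings.
#' @param trainingMode "endstate" or "incremental".
#' @param eta,checkpoints incremental-training settings (eta NULL: half the
#'   stability bound).
#' @param production NULL to skip production, or a
#'   \code{\link{productionConfig}} ("theta" may be the string "auto" to
#'   calibrate it on the training data).
#' @param pruningFractions NULL, or fractions (e.g. seq(0, .9, .1)) at which
#'   to prune the comprehension mapping and re-measure training accuracy.
#' @param seed master seed.
#' @return list of class "ExperimentConfig".
#' @export
experimentConfig <- function(unit = "phone", n = 3L, d = NULL,
                             sdLexeme = 4, sdFeature = 4, sdNoise = 1,
                             featureScale = 1,
                             numberCoding = "equipollent",
                             articles = FALSE, roles = FALSE,
                             trainFraction = 0.8, splitMode = "random",
                             trainingMode = "endstate", eta = NULL,
                             checkpoints = NULL,
                             production = productionConfig(),
                             pruningFractions = NULL,
                             seed = 1L) {
  structure(list(unit = unit, n = as.integer(n), d = d,
                 sdLexeme = sdLexeme, sdFeature = sdFeature,
                 sdNoise = sdNoise, featureScale = featureScale,
                 numberCoding = numberCoding, articles = articles,
                 roles = roles, trainFraction = trainFraction,
                 splitMode = splitMode, trainingMode = trainingMode,
                 eta = eta, checkpoints = checkpoints,
                 production = production,
                 pruningFractions = pruningFractions,
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run a full comprehension/production experiment
#'
#' Orchestrates one cell of the experiment grid on any input lexicon:
#' optional article attachment and semantic-role expansion (with simulated
#' role frequencies), train/validation split, cue matrix over the training
#' inventory (validation vectorized against the frozen inventory), a
#' simulated semantic space, end-state or single-pass incremental mapping
#' estimation, comprehension evaluation under the full taxonomy, optional
#' production evaluation via path synthesis, optional learning-trajectory
#' checkpoints and an optional pruning sweep.
#'
#' @param lex input \linkS4class{Lexicon}.
#' @param config an \code{\link{experimentConfig}}.
#' @return a report list: \code{config}, \code{configHash}, \code{sizes},
#'   \code{comprehension} and (optionally) \code{production} accuracy
#'   grids, \code{trajectory} (checkpoint accuracies) and \code{pruning}
#'   (fractions and accuracies). Deterministic given the config.
#' @export
runExperiment <- function(lex, config = experimentConfig()) {
  seed <- config$seed
  if (!isFALSE(config$articles))
    lex <- attachArticles(lex, mode = config$articles)
  if (!isFALSE(config$roles)) {
    roles <- if (isTRUE(config$roles)) defaultRoleTable() else config$roles
    lex <- expandRoles(lex, roles)
    lex <- simulateRoleFrequencies(lex, roles, seed = seed)
  }
  split <- splitTrainValidation(lex, config$trainFraction,
                                mode = config$splitMode,
                                cueExtractor = function(f)
                                  extractNgramCues(f, config$n),
                                seed = seed)
  trainLex <- trainLexicon(split); valLex <- validationLexicon(split)
  Ctrain <- buildCueMatrix(trainLex, unit = config$unit, n = config$n)
  inventory <- cueInventory(Ctrain)
  Cval <- suppressWarnings(
    buildCueMatrix(valLex, unit = config$unit, n = config$n,
                   inventory = inventory))
  d <- if (is.null(config$d)) length(cues(inventory)) else config$d
  useRoles <- !all(is.na(entries(trainLex)$role))
  feats <- unique(c(semanticFeatures(trainLex, useRoles),
                    semanticFeatures(valLex, useRoles)))
  lemmas <- unique(c(entries(trainLex)$lemma, entries(valLex)$lemma))
  space <- simulateSemanticSpace(lemmas, feats, d,
                                 sdLexeme = config$sdLexeme,
                                 sdFeature = config$sdFeature,
                                 sdNoise = config$sdNoise,
                                 featureScale = config$featureScale,
                                 seed = seed)
  Strain <- buildSemanticMatrix(trainLex, space, config$numberCoding,
                                seed = seed)
  Sval <- buildSemanticMatrix(valLex, space, config$numberCoding,
                              seed = seed + 1L)

  trajectory <- NULL
  if (config$trainingMode == "endstate") {
    Fmap <- estimateEndstate(Ctrain, Strain, "comprehension")
  } else {
    stream <- sampleTokenStream(trainLex, scheme = "shuffled_census",
                                seed = seed)
    eta <- if (is.null(config$eta)) 0.5 * stableLearningRate(Ctrain) else
      config$eta
    cps <- if (is.null(config$checkpoints)) integer(0) else
      as.integer(config$checkpoints)
    if (any(cps > length(stream))) {
      warning("dropping checkpoint(s) beyond the stream length (",
              length(stream), " events)")
      cps <- cps[cps <= length(stream)]
    }
    fit <- trainIncremental(Ctrain, Strain, stream, eta = eta,
                            direction = "comprehension", checkpoints = cps)
    Fmap <- fit$mapping
    if (length(cps) > 0) {
      endF <- estimateEndstate(Ctrain, Strain, "comprehension")
      evalAcc <- function(m)
        evaluateComprehension(m, Ctrain, Cval, Strain, Sval,
                              split)$accuracies
      trajectory <- list(
        events = cps,
        accuracy = t(vapply(fit$checkpoints, evalAcc, numeric(6))),
        endstate = evalAcc(endF))
    }
  }
  comp <- evaluateComprehension(Fmap, Ctrain, Cval, Strain, Sval, split)

  prod <- NULL
  if (!is.null(config$production)) {
    G <- estimateEndstate(Strain, Ctrain, "production")
    trainPaths <- lapply(entries(trainLex)$form, function(f)
      match(cuePath(f, inventory), cues(inventory)))
    pc <- config$production
    if (identical(pc$supportThreshold, "auto"))
      pc$supportThreshold <- calibrateThreshold(G, Strain, trainPaths)
    FmapEnd <- if (config$trainingMode == "endstate") Fmap else
      estimateEndstate(Ctrain, Strain, "comprehension")
    candsTrain <- learnPaths(Strain, G, FmapEnd, inventory, config = pc,
                             mode = "graph", trainPaths = trainPaths)
    candsVal <- learnPaths(Sval, G, FmapEnd, inventory, config = pc,
                           mode = "graph", trainPaths = trainPaths)
    prodEval <- evaluateProduction(candsTrain, candsVal, split)
    prod <- list(accuracies = prodEval$accuracies, counts = prodEval$counts,
                 theta = pc$supportThreshold)
  }

  pruning <- NULL
  if (!is.null(config$pruningFractions)) {
    w <- abs(mappingWeights(Fmap))
    accs <- vapply(config$pruningFractions, function(fr) {
      theta <- if (fr <= 0) 0 else stats::quantile(w, fr)
      pr <- pruneWeights(Fmap, theta)
      evaluateComprehension(pr$mapping, Ctrain, Cval, Strain, Sval,
                            split)$accuracies[["train"]]
    }, numeric(1))
    pruning <- list(fractions = config$pruningFractions, trainAccuracy = accs)
  }

  list(config = config, configHash = .configHash(config),
       sizes = c(entries = length(lex), train = length(trainLex),
                 validation = length(valLex),
                 cues = length(cues(inventory)), d = d),
       comprehension = list(accuracies = comp$accuracies,
                            counts = comp$counts),
       production = prod, trajectory = trajectory, pruning = pruning)
}

#' Write an experiment report as JSON
#'
#' @param report result of \code{\link{runExperiment}}.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  report$config <- unclass(report$config)
  report$config$production <- unclass(report$config$production)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
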