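#' End-to-end run configuration
#'
#' Bundles the per-module configurations for [runPipeline()]. Unknown keys
#' in `...` are rejected.
#'
#' @param task `"TPP2"` or `"TPP3"` (the cross-validated tasks).
#' @param folds how many folds of the 10-fold assignment to actually train
#'   and evaluate (desk-scale runs often use fewer).
#' @param nFolds the fold count of the assignment itself.
#' @param repeats repeated cross-validation runs (aggregate = mean +/- SEM).
#' @param negDef negative-sampling definition (`"any_part"` or
#'   `"cdr3b_only"`).
#' @param ratio negatives per positive.
#' @param valFraction validation fraction carved from the labelled train
#'   partition.
#' @param embedDim mock-embedder dimension.
#' @param maxLens sequence length maxima, as in [encodeExample()].
#' @param synth a [synthConfig()] (used when no `dataPath` is given).
#' @param model a [modelConfig()].
#' @param train a [trainConfig()].
#' @param dataPath optional canonical TSV to use instead of synthetic data.
#' @param outDir output directory (`NULL` = no files written).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return named list of class `"tcrpairRunConfig"`.
#' @export
runConfig <- function(task = c("TPP2", "TPP3"), folds = 1L, nFolds = 10L,
                      repeats = 1L, negDef = c("any_part", "cdr3b_only"),
                      ratio = 5L, valFraction = 0.1, embedDim = 16L,
                      maxLens = list(l = 25L, le = 15L),
                      synth = synthConfig(), model = modelConfig(),
                      train = trainConfig(), dataPath = NULL, outDir = NULL,
                      seed = 1L) {
  structure(list(task = match.arg(task), folds = as.integer(folds),
                 nFolds = as.integer(nFolds), repeats = as.integer(repeats),
                 negDef = match.arg(negDef), ratio = as.integer(ratio),
                 valFraction = valFraction, embedDim = as.integer(embedDim),
                 maxLens = maxLens, synth = synth, model = model, train = train,
                 dataPath = dataPath, outDir = outDir, seed = as.integer(seed)),
            class = "tcrpairRunConfig")
}

# Random validation carve on a labelled partition (paper's chosen setting);
# "unseen_epitope" moves whole epitopes instead.
carveValidationLabelled <- function(df, valMode = "random", valFraction = 0.1,
                                    seed = 1L) {
  if (valFraction <= 0)
    return(list(train = df, val = df[0, , drop = FALSE]))
  withSeed(seed, {
    if (valMode == "random") {
      idx <- sample.int(nrow(df), floor(valFraction * nrow(df)))
    } else {
      eps <- sampleVec(unique(df$epitope))
      cum <- cumsum(vapply(eps, function(e) sum(df$epitope == e), numeric(1)))
      chosen <- eps[seq_len(max(1L, which.max(cum >= valFraction * nrow(df))))]
      idx <- which(df$epitope %in% chosen)
    }
    list(train = df[-idx, , drop = FALSE], val = df[idx, , drop = FALSE])
  })
}

#' Materialize one fold: positives split + negatives per partition
#'
#' Negatives are generated separately for the train(+validation) and test
#' partitions (restricting test-to-train leakage), then the validation set
#' is carved from the labelled train partition.
#'
#' @param dataset positives [TcrDataset-class].
#' @param split a [FoldSplit-class] (built with `valFraction = 0`; any
#'   validation indices are merged back into train here).
#' @param negDef,ratio negative-sampling settings.
#' @param valFraction,valMode validation carve settings.
#' @param seed integer seed.
#' @return list of labelled data.frames `train`, `val`, `test`.
#' @export
prepareFoldData <- function(dataset, split, negDef = "any_part", ratio = 5L,
                            valFraction = 0.1, valMode = "random", seed = 1L) {
  rec <- records(dataset)
  trainPos <- rec[sort(c(split@train, split@validation)), , drop = FALSE]
  testPos <- rec[split@test, , drop = FALSE]
  extraUnits <- NULL
  if (length(split@extraTrainEpitopes)) {
    extraUnits <- unique(testPos[testPos$epitope %in% split@extraTrainEpitopes,
                                 c("epitope", "mhc"), drop = FALSE])
  }
  trainLab <- buildPartition(trainPos, negDef, ratio,
                             seed = deriveSeed(seed, "neg_train"),
                             extraUnits = extraUnits)
  testLab <- buildPartition(testPos, negDef, ratio,
                            seed = deriveSeed(seed, "neg_test"))
  cv <- carveValidationLabelled(trainLab, valMode, valFraction,
                                deriveSeed(seed, "val"))
  list(train = cv$train, val = cv$val, test = testLab)
}

#' Train and evaluate one materialized fold
#'
#' @param dataset the positives dataset (vocabulary source).
#' @param foldData from [prepareFoldData()].
#' @param cfg a [runConfig()].
#' @param embedder embedding backend (default: mock at `cfg$embedDim`).
#' @param germline optional germline table for full-TCR context.
#' @return list with `report` (an `EvalReport`), `history`, `model`.
#' @export
trainEvaluateFold <- function(dataset, foldData, cfg, embedder = NULL,
                              germline = NULL) {
  embedder <- embedder %||% mockEmbedder(cfg$embedDim)
  cache <- newEmbedCache()
  packs <- lapply(foldData[c("train", "val", "test")], packExamples,
                  dataset = dataset, embedder = embedder, germline = germline,
                  maxLens = cfg$maxLens, cache = cache)
  model <- buildModel(cfg$model, dataset, embedDim = cfg$embedDim,
                      maxLens = cfg$maxLens, seed = deriveSeed(cfg$seed, "init"))
  fit <- trainModel(model, packs$train, packs$val, cfg$train)
  scores <- predictScores(fit$model, packs$test)
  report <- evalReport(scores, foldData$test,
                       trainEpitopes = unique(foldData$train$epitope),
                       meta = list(task = cfg$task, seed = cfg$seed))
  list(report = report, history = fit$history, model = fit$model)
}

#' Run the full pipeline: data, splits, negatives, training, evaluation
#'
#' Executes the workflow end to end: obtain positives (synthetic repertoire
#' or a canonical TSV), build task splits for each repeat, generate
#' negatives per partition, encode, train with early stopping (+ SWA if
#' configured), and evaluate per fold. When `outDir` is set, per-fold
#' reports, the aggregate and the resolved configuration are written there
#' (JSON/TSV), each stamped with the configuration hash and seed.
#'
#' @param cfg a [runConfig()].
#' @param verbose print progress.
#' @return list with `reports` (nested: repeats, folds), `aggregate`
#'   (mean +/- SEM across repeats), `dataset`.
#' @export
runPipeline <- function(cfg = runConfig(), verbose = FALSE) {
  dataset <- if (!is.null(cfg$dataPath)) {
    readDataset(cfg$dataPath, "Dab_a_b")
  } else {
    sc <- cfg$synth
    sc$seed <- deriveSeed(cfg$seed, "synth")
    generateRepertoire(sc)
  }
  rec <- records(dataset)
  posCounts <- table(rec$epitope[rec$label == 1])
  reports <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    repSeed <- deriveSeed(cfg$seed, paste0("rep", r))
    foldReports <- vector("list", cfg$folds)
    assignment <- NULL
    if (cfg$task == "TPP3")
      assignment <- assignTpp3Folds(setNames(as.numeric(posCounts), names(posCounts)),
                                    nFolds = cfg$nFolds, block = cfg$nFolds,
                                    seed = repSeed)
    for (f in seq_len(cfg$folds)) {
      split <- if (cfg$task == "TPP3") {
        makeTpp3Split(dataset, assignment, f - 1L, valFraction = 0, seed = repSeed)
      } else {
        makeTpp2Split(dataset, nFolds = cfg$nFolds, foldIndex = f - 1L,
                      tcrKeyDef = if (cfg$negDef == "cdr3b_only") "cdr3b" else "strict",
                      seed = repSeed, valFraction = 0)
      }
      foldData <- prepareFoldData(dataset, split, cfg$negDef, cfg$ratio,
                                  cfg$valFraction, seed = repSeed + f)
      fcfg <- cfg
      fcfg$seed <- repSeed + f
      out <- trainEvaluateFold(dataset, foldData, fcfg)
      foldReports[[f]] <- out$report
      if (verbose)
        message(sprintf("repeat %d fold %d: AUROC %.3f AP %.3f", r, f,
                        out$report$overall_auroc, out$report$overall_ap))
    }
    reports[[r]] <- foldReports
  }
  agg <- aggregateRuns(reports)
  if (!is.null(cfg$outDir)) writePipelineOutputs(cfg, reports, agg)
  list(reports = reports, aggregate = agg, dataset = dataset)
}

# Write per-fold and aggregate outputs with config-hash provenance sidecars.
writePipelineOutputs <- function(cfg, reports, agg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  cfgJson <- jsonlite::toJSON(rapply(unclass(cfg), unclass, how = "replace"),
                              auto_unbox = TRUE, null = "null", force = TRUE)
  cfgHash <- hashString(as.character(cfgJson))
  writeLines(as.character(cfgJson), file.path(cfg$outDir, "config.json"))
  for (r in seq_along(reports)) for (f in seq_along(reports[[r]])) {
    rep <- reports[[r]][[f]]
    base <- file.path(cfg$outDir, sprintf("rep%d_fold%d", r, f))
    data.table::fwrite(rep$per_epitope, paste0(base, "_per_epitope.tsv"), sep = "\t")
    jsonlite::write_json(list(overall_auroc = rep$overall_auroc,
                              overall_ap = rep$overall_ap,
                              config_hash = cfgHash, seed = cfg$seed),
                         paste0(base, ".json"), auto_unbox = TRUE)
  }
  data.table::fwrite(agg, file.path(cfg$outDir, "aggregate.tsv"), sep = "\t")
  invisible(NULL)
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds the architecture and dimensions as JSON and
#' the flat named-parameter archive.
#'
#' @param model a [TcrModel-class].
#' @param path checkpoint directory.
#' @return `saveModel()`: invisibly `path`; `loadModel()`: the model.
#' @export
saveModel <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(config = model@config, dims = model@dims),
                       file.path(path, "config.json"), auto_unbox = TRUE)
  saveRDS(model@params, file.path(path, "params.rds"))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "config.json"), simplifyVector = TRUE)
  new("TcrModel", config = as.list(meta$config),
      params = readRDS(file.path(path, "params.rds")),
      dims = as.list(meta$dims))
}
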