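test_that("masked weighted BCE matches closed forms", {
  expect_equal(maskedWeightedBce(1, 0.5, wPos = 5), 5 * log(2), tolerance = 1e-12)
  # a confident correct negative approaches zero loss
  expect_lt(maskedWeightedBce(0, 1e-9), 1e-6)
  # missing labels contribute nothing
  y <- cbind(yb = c(1, NA), ya = c(NA, NA), yab = c(NA, 0))
  yhat <- cbind(yb = c(0.5, 0.9), ya = c(0.1, 0.2), yab = c(0.3, 0.25))
  want <- mean(c(5 * -log(0.5), -log(1 - 0.25)))
  expect_equal(maskedWeightedBce(y, yhat), want, tolerance = 1e-12)
  # mixed batch: one paired positive + one beta-only negative, hand-summed
  y2 <- cbind(yb = c(NA, 0), ya = c(NA, NA), yab = c(1, NA))
  yhat2 <- cbind(yb = c(0.8, 0.3), ya = c(0.5, 0.5), yab = c(0.6, 0.9))
  want2 <- mean(c(5 * -log(0.6), -log(0.7)))
  expect_equal(maskedWeightedBce(y2, yhat2), want2, tolerance = 1e-12)
})

test_that("the training loss equals a scalar per-example oracle on random batches", {
  ds <- smallRepertoire(nEpitopes = 10, nPositives = 150, seed = 23)
  pack <- tinyPack(ds, rows = 1:60)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 4)
  preds <- forwardModel(m, pack)
  set.seed(31)
  for (rep in 1:200) {
    idx <- sample(60, sample(2:20, 1))
    labels <- sample(0:1, length(idx), replace = TRUE)
    p2 <- pack
    p2$label[idx] <- labels
    p2$weight <- ifelse(p2$label == 1, 5, 1)
    got <- tcrpair:::nn_loss_grad_cpp(modelParams(m), p2, as.integer(idx),
                                      m@config, FALSE, 0L)$loss
    obsScores <- observedHeadScores(preds, p2)[idx]
    want <- mean(mapply(bceScalar, p2$label[idx], obsScores, p2$weight[idx]))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Adam training on a separable toy drives validation AP near one", {
  # disjoint verbatim motifs (zero mutation): the rule is fully recoverable
  ds <- generateRepertoire(synthConfig(nEpitopes = 12, nPositives = 600,
                                       mutationRate = 0, availability =
                                         c(beta = 1, paired = 0, alpha = 0),
                                       seed = 77))
  lab <- buildPartition(records(ds), "any_part", ratio = 2, seed = 1)
  cv <- tcrpair:::carveValidationLabelled(lab, "random", 0.2, seed = 2)
  emb <- mockEmbedder(4)
  trainPack <- packExamples(cv$train, ds, emb, maxLens = tinyMaxLens)
  valPack <- packExamples(cv$val, ds, emb, maxLens = tinyMaxLens)
  m <- buildModel(modelConfig(channels = 16, heads = 2, geneDim = 4, mhcDim = 4,
                              hidden = 16, dropout = 0), ds, embedDim = 4,
                  maxLens = tinyMaxLens, seed = 5)
  fit <- trainModel(m, trainPack, valPack,
                    trainConfig(lr = 5e-3, maxEpochs = 50, patience = 50,
                                batchSize = 64, swaEpochs = 0, seed = 1))
  expect_gte(fit$bestAp, 0.9)
  # best epoch snapshot is what the returned model carries
  expect_equal(tcrpair:::valAp(modelParams(fit$model), valPack, m@config),
               fit$bestAp, tolerance = 1e-12)
})

test_that("early-stopping bookkeeping: history bounds and running-max best", {
  ds <- smallRepertoire(nEpitopes = 8, nPositives = 120, seed = 29)
  lab <- buildPartition(records(ds), "any_part", ratio = 2, seed = 1)
  cv <- tcrpair:::carveValidationLabelled(lab, "random", 0.2, seed = 2)
  emb <- mockEmbedder(4)
  trainPack <- packExamples(cv$train, ds, emb, maxLens = tinyMaxLens)
  valPack <- packExamples(cv$val, ds, emb, maxLens = tinyMaxLens)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 5)
  cfgs <- list(trainConfig(maxEpochs = 5, patience = 2, batchSize = 64,
                           swaEpochs = 0, seed = 3),
               trainConfig(maxEpochs = 5, patience = 0, batchSize = 64,
                           swaEpochs = 0, seed = 3))
  fit <- trainModel(m, trainPack, valPack, cfgs[[1]])
  expect_lte(nrow(fit$history), 5)
  expect_equal(fit$bestAp, max(fit$history$val_ap), tolerance = 1e-12)
  expect_identical(fit$bestEpoch, fit$history$epoch[which.max(fit$history$val_ap)])
  # patience 0 trains exactly one epoch
  fit0 <- trainModel(m, trainPack, valPack, cfgs[[2]])
  expect_identical(nrow(fit0$history), 1L)
  expect_error(trainModel(m, trainPack, NULL, cfgs[[1]]), "validation")
})

test_that("training is reproducible under a fixed seed", {
  ds <- smallRepertoire(nEpitopes = 8, nPositives = 120, seed = 29)
  lab <- buildPartition(records(ds), "any_part", ratio = 2, seed = 1)
  cv <- tcrpair:::carveValidationLabelled(lab, "random", 0.2, seed = 2)
  emb <- mockEmbedder(4)
  trainPack <- packExamples(cv$train, ds, emb, maxLens = tinyMaxLens)
  valPack <- packExamples(cv$val, ds, emb, maxLens = tinyMaxLens)
  m <- buildModel(tinyModelConfig(dropout = 0.1), ds, embedDim = 4,
                  maxLens = tinyMaxLens, seed = 5)
  cfg <- trainConfig(maxEpochs = 3, patience = 3, batchSize = 64,
                     swaEpochs = 0, seed = 11)
  f1 <- trainModel(m, trainPack, valPack, cfg)
  f2 <- trainModel(m, trainPack, valPack, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(modelParams(f1$model), modelParams(f2$model))
})

test_that("parameter averaging is the exact elementwise mean of snapshots", {
  ds <- toyDataset()
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, seed = 1)
  p1 <- modelParams(m)
  p2 <- lapply(p1, function(x) x + 1)
  p3 <- lapply(p1, function(x) x * 3)
  avg <- averageParams(list(p1, p2, p3))
  for (k in names(p1))
    expect_equal(avg[[k]], (p1[[k]] + p2[[k]] + p3[[k]]) / 3, tolerance = 1e-12)
  # snapshots forced constant -> the average is that constant
  same <- averageParams(list(p1, p1, p1))
  expect_identical(same, p1)
})

test_that("SWA with zero epochs is the identity; otherwise it averages a run", {
  ds <- smallRepertoire(nEpitopes = 8, nPositives = 120, seed = 29)
  pack <- tinyPack(ds, rows = 1:60)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 5)
  expect_identical(modelParams(swaFinalize(m, pack, swaEpochs = 0)),
                   modelParams(m))
  # learning rate zero freezes the parameters: the average equals them
  frozen <- swaFinalize(m, pack, swaEpochs = 3, swaLr = 0, batchSize = 32,
                        seed = 2)
  expect_equal(modelParams(frozen), modelParams(m), tolerance = 1e-12)
  moved <- swaFinalize(m, pack, swaEpochs = 3, swaLr = 1e-3, batchSize = 32,
                       seed = 2)
  expect_false(identical(modelParams(moved), modelParams(m)))
})
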