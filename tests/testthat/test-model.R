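test_that("a tiny model builds, runs forward, and licenses heads by availability", {
  ds <- toyDataset()
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 1)
  pack <- tinyPack(ds)
  out <- forwardModel(m, pack)
  # all licensed outputs in [0,1]
  vals <- unlist(out)
  expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
  # beta-only rows: yb present, ya/yab absent; paired rows: all three
  expect_false(anyNA(out$yb[pack$hasB == 1]))
  expect_true(all(is.na(out$ya[pack$hasA == 0])))
  expect_true(all(is.na(out$yab[!(pack$hasB & pack$hasA)])))
  expect_false(anyNA(out$yab[pack$hasB == 1 & pack$hasA == 1]))
})

test_that("parameter count equals the analytic layer-by-layer sum", {
  ds <- toyDataset()
  cfg <- tinyModelConfig()        # C=8, K=3, h=2, dg=4, dm=4, H=8
  m <- buildModel(cfg, ds, embedDim = 4, maxLens = tinyMaxLens, seed = 1)
  e <- 4 + 20
  C <- 8; K <- 3; dg <- 4; dm <- 4; H <- 8
  gv <- geneVocab(ds)
  convs <- 3 * (C * K * e + C)                       # epitope + two chains
  attn <- 2 * 4 * C * C                              # q/k/v/o per chain
  embs <- dg * (length(gv$bv) + 1 + length(gv$bj) + 1 +
                  length(gv$av) + 1 + length(gv$aj) + 1) +
    dm * (length(mhcVocab(ds)) + 1)
  inB <- C + 2 * dg + dm
  inAB <- 2 * C + 4 * dg + dm
  heads <- 2 * (H * inB + H + H + 1) + (H * inAB + H + H + 1)
  expect_identical(nParams(m), as.integer(convs + attn + embs + heads))
})

test_that("identical seeds give identical initial parameters", {
  ds <- toyDataset()
  m1 <- buildModel(tinyModelConfig(), ds, embedDim = 4, seed = 7)
  m2 <- buildModel(tinyModelConfig(), ds, embedDim = 4, seed = 7)
  expect_identical(modelParams(m1), modelParams(m2))
  m3 <- buildModel(tinyModelConfig(), ds, embedDim = 4, seed = 8)
  expect_false(identical(modelParams(m1), modelParams(m3)))
})

test_that("analytic gradients match numerical differentiation", {
  ds <- smallRepertoire(nEpitopes = 6, nPositives = 60, seed = 5)
  pack <- tinyPack(ds, rows = 1:6)
  pack$label[c(2, 4)] <- 0L
  pack$weight <- ifelse(pack$label == 1, 5, 1)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 3)
  res <- tcrpair:::nnLossGrad(m, pack, idx = 1:6)
  params <- modelParams(m)
  set.seed(12)
  for (k in names(params)) {
    n <- length(params[[k]])
    for (i in sample(n, min(3, n))) {
      eps <- 1e-5
      pp <- params; pp[[k]][i] <- pp[[k]][i] + eps
      m@params <- pp
      lp <- tcrpair:::nnLossGrad(m, pack, 1:6)$loss
      pp[[k]][i] <- pp[[k]][i] - 2 * eps
      m@params <- pp
      lm <- tcrpair:::nnLossGrad(m, pack, 1:6)$loss
      numGrad <- (lp - lm) / (2 * eps)
      expect_equal(res$grads[[k]][i], numGrad, tolerance = 1e-5,
                   label = sprintf("grad %s[%d]", k, i))
    }
  }
})

test_that("the beta head never reads alpha inputs (and vice versa)", {
  ds <- smallRepertoire(nEpitopes = 6, nPositives = 60, seed = 5)
  rec <- records(ds)
  paired <- which(!is.na(rec$cdr3b) & !is.na(rec$cdr3a))[1:4]
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 3)
  pack1 <- tinyPack(ds, rows = paired)
  pack2 <- pack1
  # perturb alpha features, genes and lengths arbitrarily
  pack2$alpha <- pack2$alpha + array(rnorm(length(pack2$alpha)), dim(pack2$alpha))
  pack2$av <- rep(1L, 4)
  pack2$aj <- rep(1L, 4)
  out1 <- forwardModel(m, pack1)
  out2 <- forwardModel(m, pack2)
  expect_identical(out1$yb, out2$yb)          # beta path blind to alpha
  expect_false(isTRUE(all.equal(out1$ya, out2$ya)))
  # symmetric direction
  pack3 <- pack1
  pack3$beta <- pack3$beta + array(rnorm(length(pack3$beta)), dim(pack3$beta))
  pack3$bv <- rep(1L, 4)
  out3 <- forwardModel(m, pack3)
  expect_identical(out1$ya, out3$ya)
})

test_that("extending the padding never changes any head's output", {
  ds <- smallRepertoire(nEpitopes = 6, nPositives = 60, seed = 5)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 3)
  packSmall <- tinyPack(ds, rows = 1:10, maxLens = tinyMaxLens)
  packBig <- tinyPack(ds, rows = 1:10, maxLens = list(l = 30L, le = 18L))
  outS <- forwardModel(m, packSmall)
  outB <- forwardModel(m, packBig)
  expect_equal(as.matrix(outS), as.matrix(outB), tolerance = 1e-5)
})

test_that("batch order permutes outputs with no cross-example leakage", {
  ds <- smallRepertoire(nEpitopes = 6, nPositives = 60, seed = 5)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 3)
  rows <- 1:12
  perm <- c(5, 1, 12, 3, 7, 2, 11, 6, 10, 4, 8, 9)
  out1 <- forwardModel(m, tinyPack(ds, rows = rows))
  out2 <- forwardModel(m, tinyPack(ds, rows = rows[perm]))
  expect_identical(as.matrix(out1)[perm, ], as.matrix(out2)[, , drop = TRUE])
})

test_that("alpha-exclusive parameters get zero gradient on beta-only batches", {
  ds <- smallRepertoire(nEpitopes = 6, nPositives = 60, seed = 5)
  rec <- records(ds)
  betaOnly <- which(!is.na(rec$cdr3b) & is.na(rec$cdr3a))[1:6]
  pack <- tinyPack(ds, rows = betaOnly)
  pack$label[c(1, 3)] <- 0L
  pack$weight <- ifelse(pack$label == 1, 5, 1)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 3)
  g <- tcrpair:::nnLossGrad(m, pack, idx = seq_along(betaOnly))$grads
  alphaOnlyParams <- c("conv_a_W", "conv_a_b", "att_a_Wq", "att_a_Wk",
                       "att_a_Wv", "att_a_Wo", "emb_av", "emb_aj",
                       "head_a_W1", "head_a_b1", "head_a_w2", "head_a_b2",
                       "head_ab_W1", "head_ab_b1", "head_ab_w2", "head_ab_b2")
  for (k in alphaOnlyParams)
    expect_true(all(g[[k]] == 0), label = k)
  # while shared parameters do receive gradient
  expect_gt(max(abs(g$conv_ep_W)), 0)
  expect_gt(max(abs(g$conv_b_W)), 0)
})

test_that("gradients reach both chains for a paired example", {
  ds <- smallRepertoire(nEpitopes = 6, nPositives = 60, seed = 5)
  rec <- records(ds)
  paired <- which(!is.na(rec$cdr3b) & !is.na(rec$cdr3a))[1:4]
  pack <- tinyPack(ds, rows = paired)
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 3)
  g <- tcrpair:::nnLossGrad(m, pack, idx = 1:4)$grads
  expect_gt(max(abs(g$conv_b_W)), 0)
  expect_gt(max(abs(g$conv_a_W)), 0)
  expect_gt(max(abs(g$head_ab_W1)), 0)
  # the single-chain heads are unobserved for paired labels
  expect_true(all(g$head_b_W1 == 0))
  expect_true(all(g$head_a_W1 == 0))
})

test_that("shared-chain mode reuses beta weights for the alpha path", {
  ds <- toyDataset()
  m <- buildModel(tinyModelConfig(shareChains = TRUE), ds, embedDim = 4,
                  maxLens = tinyMaxLens, seed = 2)
  pack <- tinyPack(ds, rows = 6)   # alpha-only record
  g <- tcrpair:::nnLossGrad(m, pack, idx = 1)$grads
  expect_gt(max(abs(g$conv_b_W)), 0)     # beta stack carries the alpha pass
  expect_true(all(g$conv_a_W == 0))
})

test_that("model checkpoints round-trip through save/load", {
  ds <- toyDataset()
  m <- buildModel(tinyModelConfig(), ds, embedDim = 4, maxLens = tinyMaxLens,
                  seed = 1)
  pack <- tinyPack(ds)
  dir <- tempfile()
  saveModel(m, dir)
  m2 <- loadModel(dir)
  expect_equal(forwardModel(m2, pack), forwardModel(m, pack))
})
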