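#' Masked, positively-weighted binary cross-entropy
#'
#' The training objective: over all observed label entries,
#' \eqn{-\frac{1}{N}\sum_n w_n (y_n \log \hat y_n + (1-y_n)\log(1-\hat y_n))}
#' where \eqn{w_n} is `wPos` for positives and 1 for negatives, missing
#' labels (`NA` in `y`) contribute nothing to loss or gradient, and `N`
#' counts the observed label terms. Predictions are clipped to
#' `[eps, 1-eps]` before the logarithm.
#'
#' @param y numeric matrix/data.frame of labels (columns e.g. `yb`, `ya`,
#'   `yab`) with `NA` marking missing heads; a plain vector works too.
#' @param yhat predictions aligned with `y`.
#' @param wPos weight for positive datapoints.
#' @param eps log-clipping constant.
#' @return scalar loss.
#' @examples
#' maskedWeightedBce(1, 0.5, wPos = 5)  # 5 * log(2)
#' @export
maskedWeightedBce <- function(y, yhat, wPos = 5, eps = 1e-7) {
  y <- as.numeric(as.matrix(y))
  yhat <- as.numeric(as.matrix(yhat))
  obs <- !is.na(y)
  stopifnot(any(obs), all(!is.na(yhat[obs])))
  y <- y[obs]
  p <- pmin(pmax(yhat[obs], eps), 1 - eps)
  w <- ifelse(y == 1, wPos, 1)
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Training configuration
#'
#' Learning-rate defaults follow the task: 1e-4 for seen-epitope (TPP2)
#' training, 1e-3 with an exponential schedule (gamma 0.95/epoch) for the
#' unseen-epitope task (TPP3). Early stopping monitors validation average
#' precision; the parameters of the best-AP epoch are kept. Positives are
#' weighted 5x in the loss (applied when packing examples).
#'
#' @param lr learning rate for the main training.
#' @param scheduler `"none"` or `"exponential"`.
#' @param gamma per-epoch decay factor for the exponential scheduler.
#' @param maxEpochs,patience early-stopping budget (patience 0 = exactly one
#'   epoch).
#' @param batchSize minibatch size.
#' @param swaEpochs epochs of stochastic weight averaging after the main
#'   training (0 disables).
#' @param swaLr learning rate during SWA (default: `lr`).
#' @param seed integer seed controlling shuffling, dropout and SWA.
#' @return named list of class `"tcrpairTrainConfig"`.
#' @export
trainConfig <- function(lr = 1e-4, scheduler = c("none", "exponential"),
                        gamma = 0.95, maxEpochs = 100L, patience = 10L,
                        batchSize = 512L, swaEpochs = 20L, swaLr = NULL,
                        seed = 1L) {
  structure(list(lr = lr, scheduler = match.arg(scheduler), gamma = gamma,
                 maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
                 batchSize = as.integer(batchSize), swaEpochs = as.integer(swaEpochs),
                 swaLr = swaLr %||% lr, seed = as.integer(seed)),
            class = "tcrpairTrainConfig")
}

# One Adam step over a named parameter list.
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     adamEps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    # the C++ side returns column/row vectors as 1-margin matrices; keep the
    # parameter's own shape
    if (is.null(dim(params[[k]]))) g <- as.vector(g)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + adamEps)
  }
  list(params = params, state = state)
}

newAdamState <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One optimization epoch over a pack; returns updated params/state and the
# mean batch loss.
runEpoch <- function(params, state, pack, config, lr, batchSize, epochSeed,
                     training = TRUE) {
  idxAll <- withSeed(epochSeed, sample.int(pack$n))
  batches <- split(idxAll, ceiling(seq_along(idxAll) / batchSize))
  losses <- numeric(length(batches))
  for (b in seq_along(batches)) {
    res <- nn_loss_grad_cpp(params, pack, as.integer(batches[[b]]), config,
                            training, as.integer((epochSeed + 104729L * b) %% 2147483647L))
    losses[b] <- res$loss
    upd <- adamStep(params, res$grads, state, lr)
    params <- upd$params
    state <- upd$state
  }
  list(params = params, state = state, loss = mean(losses))
}

# Validation score used for early stopping: average precision of the main
# score on the as-generated validation set.
valAp <- function(params, pack, config) {
  p <- nn_forward_cpp(params, pack, config)
  score <- ifelse(!is.na(p[, "yab"]), p[, "yab"],
                  ifelse(!is.na(p[, "yb"]), p[, "yb"], p[, "ya"]))
  averagePrecision(score, pack$label)
}

#' Train a model with early stopping on validation average precision
#'
#' Adam minimizes the masked weighted binary cross-entropy over shuffled
#' minibatches; after every epoch the validation AP is computed and the
#' parameters of the best epoch are retained. Training halts when the
#' validation score has not improved for `patience` epochs (or at
#' `maxEpochs`). With `swaEpochs > 0`, stochastic weight averaging then
#' continues from the best parameters (see [swaFinalize()]).
#'
#' @param model a [TcrModel-class].
#' @param trainPack,valPack packed arrays from [packExamples()]; the
#'   validation pack must be non-empty.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best parameters, SWA-averaged if requested),
#'   `history` (data.frame epoch/loss/val_ap), `bestEpoch`, `bestAp`.
#' @export
trainModel <- function(model, trainPack, valPack, config = trainConfig(),
                       verbose = FALSE) {
  if (is.null(valPack) || valPack$n == 0)
    stop("early stopping requires a non-empty validation set")
  params <- model@params
  state <- newAdamState(params)
  bestAp <- -Inf
  bestParams <- params
  bestEpoch <- 0L
  sinceBest <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_ap = numeric(0))
  for (epoch in seq_len(config$maxEpochs)) {
    lr <- if (config$scheduler == "exponential")
      config$lr * config$gamma^(epoch - 1) else config$lr
    res <- runEpoch(params, state, trainPack, model@config, lr,
                    config$batchSize, epochSeed = (as.numeric(config$seed) + 7919 * epoch) %% 2147483647)
    params <- res$params
    state <- res$state
    ap <- valAp(params, valPack, model@config)
    history <- rbind(history, data.frame(epoch = epoch, loss = res$loss, val_ap = ap))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AP %.4f", epoch, res$loss, ap))
    if (ap > bestAp) {
      bestAp <- ap
      bestParams <- params
      bestEpoch <- epoch
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
    }
    if (sinceBest > config$patience) break
    if (config$patience == 0L) break
  }
  model@params <- bestParams
  if (config$swaEpochs > 0L)
    model <- swaFinalize(model, trainPack, swaEpochs = config$swaEpochs,
                         swaLr = config$swaLr, batchSize = config$batchSize,
                         seed = config$seed)
  list(model = model, history = history, bestEpoch = bestEpoch, bestAp = bestAp)
}

#' Elementwise mean of parameter snapshots
#'
#' @param snapshots list of named parameter lists with identical shapes.
#' @return a parameter list; each entry is the arithmetic mean over
#'   snapshots.
#' @export
averageParams <- function(snapshots) {
  stopifnot(length(snapshots) >= 1)
  out <- snapshots[[1]]
  if (length(snapshots) == 1) return(out)
  for (k in names(out)) {
    # accumulate differences from the first snapshot: constant snapshot
    # sequences average to the constant exactly
    delta <- snapshots[[2]][[k]] - out[[k]]
    for (s in snapshots[-(1:2)]) delta <- delta + (s[[k]] - out[[k]])
    out[[k]] <- out[[k]] + delta / length(snapshots)
  }
  out
}

#' Stochastic weight averaging
#'
#' Continues training from the model's current parameters for `swaEpochs`
#' epochs at the (constant) SWA learning rate, snapshotting the parameters
#' after each epoch; the final parameters are the elementwise arithmetic
#' mean of the snapshots. With `swaEpochs = 0` the model is returned
#' unchanged.
#'
#' @param model a [TcrModel-class] (best main-training parameters).
#' @param trainPack packed training arrays.
#' @param swaEpochs number of averaged epochs.
#' @param swaLr learning rate during the averaging phase.
#' @param batchSize minibatch size.
#' @param seed integer seed.
#' @return the model with averaged parameters.
#' @export
swaFinalize <- function(model, trainPack, swaEpochs = 20L, swaLr = 1e-4,
                        batchSize = 512L, seed = 1L) {
  if (swaEpochs == 0L) return(model)
  params <- model@params
  state <- newAdamState(params)
  snapshots <- vector("list", swaEpochs)
  for (epoch in seq_len(swaEpochs)) {
    res <- runEpoch(params, state, trainPack, model@config, swaLr, batchSize,
                    epochSeed = (as.numeric(seed) + 15485863 + 7919 * epoch) %% 2147483647)
    params <- res$params
    state <- res$state
    snapshots[[epoch]] <- params
  }
  model@params <- averageParams(snapshots)
  model
}
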