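#' Architecture configuration
#'
#' Defaults are the package's declared architecture: one 1-D convolution
#' layer (kernel 3, 128 channels, ReLU) per sequence, one multi-head
#' self-attention block (4 heads, width = channels) over each
#' CDR3+epitope token sequence, 32-dim learned gene and MHC embeddings, a
#' 256-unit ReLU MLP per head, dropout 0.1. `shareChains = TRUE` makes the
#' alpha chain reuse the beta conv/attention weights (default: separate
#' stacks; the epitope convolution is always shared).
#'
#' @param channels conv output channels = attention width.
#' @param kernel conv kernel size (odd).
#' @param heads attention heads; must divide `channels`.
#' @param geneDim,mhcDim embedding dimensions for gene and MHC one-hots.
#' @param hidden MLP hidden width.
#' @param dropout dropout rate on the head hidden layer (training only).
#' @param shareChains share conv/attention weights between chains.
#' @return named list of class `"tcrpairModelConfig"`.
#' @export
modelConfig <- function(channels = 128L, kernel = 3L, heads = 4L,
                        geneDim = 32L, mhcDim = 32L, hidden = 256L,
                        dropout = 0.1, shareChains = FALSE) {
  stopifnot(channels %% heads == 0, kernel %% 2 == 1,
            channels > 0, geneDim > 0, mhcDim > 0, hidden > 0)
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 heads = as.integer(heads), geneDim = as.integer(geneDim),
                 mhcDim = as.integer(mhcDim), hidden = as.integer(hidden),
                 dropout = dropout, shareChains = shareChains),
            class = "tcrpairModelConfig")
}

# Glorot-style initial matrix.
glorot <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)

#' Build a model for a dataset's vocabularies and feature dimensions
#'
#' Initializes all parameters (Glorot-scaled weights, zero biases,
#' small-scale embeddings) for the three-headed architecture. Gene and MHC
#' embedding tables carry one extra reserved row for unknown names at
#' inference time.
#'
#' @param config from [modelConfig()].
#' @param dataset a [TcrDataset-class] (supplies vocabulary sizes).
#' @param embedDim per-residue embedding dimension of the backend in use.
#' @param maxLens list with `l` and `le` as in [encodeExample()].
#' @param seed integer seed for the initialization.
#' @return a [TcrModel-class].
#' @export
buildModel <- function(config, dataset, embedDim = 16L,
                       maxLens = list(l = 25L, le = 15L), seed = 1L) {
  e <- embedDim + length(AA_ALPHABET)
  C <- config$channels; K <- config$kernel
  dg <- config$geneDim; dm <- config$mhcDim; H <- config$hidden
  gv <- geneVocab(dataset)
  sizes <- c(bv = length(gv$bv) + 1L, bj = length(gv$bj) + 1L,
             av = length(gv$av) + 1L, aj = length(gv$aj) + 1L,
             mhc = length(mhcVocab(dataset)) + 1L)
  inB <- C + 2L * dg + dm
  inAB <- 2L * C + 4L * dg + dm
  params <- withSeed(seed, {
    mkHead <- function(inDim) list(W1 = glorot(H, inDim), b1 = rep(0, H),
                                   w2 = glorot(1, H), b2 = 0)
    hb <- mkHead(inB); ha <- mkHead(inB); hab <- mkHead(inAB)
    list(conv_ep_W = glorot(C, K * e), conv_ep_b = rep(0, C),
         conv_b_W = glorot(C, K * e), conv_b_b = rep(0, C),
         conv_a_W = glorot(C, K * e), conv_a_b = rep(0, C),
         att_b_Wq = glorot(C, C), att_b_Wk = glorot(C, C),
         att_b_Wv = glorot(C, C), att_b_Wo = glorot(C, C),
         att_a_Wq = glorot(C, C), att_a_Wk = glorot(C, C),
         att_a_Wv = glorot(C, C), att_a_Wo = glorot(C, C),
         emb_bv = matrix(rnorm(sizes[["bv"]] * dg, sd = 0.1), sizes[["bv"]], dg),
         emb_bj = matrix(rnorm(sizes[["bj"]] * dg, sd = 0.1), sizes[["bj"]], dg),
         emb_av = matrix(rnorm(sizes[["av"]] * dg, sd = 0.1), sizes[["av"]], dg),
         emb_aj = matrix(rnorm(sizes[["aj"]] * dg, sd = 0.1), sizes[["aj"]], dg),
         emb_mhc = matrix(rnorm(sizes[["mhc"]] * dm, sd = 0.1), sizes[["mhc"]], dm),
         head_b_W1 = hb$W1, head_b_b1 = hb$b1, head_b_w2 = hb$w2, head_b_b2 = hb$b2,
         head_a_W1 = ha$W1, head_a_b1 = ha$b1, head_a_w2 = ha$w2, head_a_b2 = ha$b2,
         head_ab_W1 = hab$W1, head_ab_b1 = hab$b1, head_ab_w2 = hab$w2,
         head_ab_b2 = hab$b2)
  })
  new("TcrModel", config = unclass(config), params = params,
      dims = list(e = e, l = maxLens$l, le = maxLens$le,
                  embedDim = embedDim, vocabSizes = sizes))
}

#' Forward pass over packed examples
#'
#' @param model a [TcrModel-class].
#' @param pack packed arrays from [packExamples()].
#' @return data.frame with columns `yb`, `ya`, `yab`; each row holds the
#'   heads licensed by the example's chain availability (others `NA`), all
#'   values in `[0, 1]`.
#' @export
forwardModel <- function(model, pack) {
  stopifnot(dim(pack$beta)[2] == model@dims$e)
  out <- nn_forward_cpp(model@params, pack, model@config)
  as.data.frame(out)
}

#' Single binding score per example
#'
#' The paired head where both chains are present, otherwise the available
#' chain's head.
#'
#' @param model a [TcrModel-class].
#' @param pack packed arrays.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predictScores <- function(model, pack) {
  p <- forwardModel(model, pack)
  ifelse(!is.na(p$yab), p$yab, ifelse(!is.na(p$yb), p$yb, p$ya))
}

# Loss and gradients on a subset of a pack (thin wrapper over the C++ core);
# training = TRUE draws dropout masks.
nnLossGrad <- function(model, pack, idx = seq_len(pack$n), training = FALSE,
                       dropoutSeed = 0L) {
  nn_loss_grad_cpp(model@params, pack, as.integer(idx), model@config,
                   training, as.integer(dropoutSeed))
}
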