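# Shared fixtures and independent oracles for the test suite.

# A small hand-built canonical record table: 3 beta-only, 2 paired, 1
# alpha-only record over 3 epitopes.
toyRecords <- function() {
  data.frame(
    cdr3b = c("CASSLGQAYEQYF", "CASSPDRGEQFF", "CASSQETQYF", "CASRGDSYEQYF",
              "CSARDGGEQFF", NA),
    vb = c("TRBV20-1", "TRBV19", "TRBV9", "TRBV28", "TRBV20-1", NA),
    jb = c("TRBJ2-7", "TRBJ2-1", "TRBJ2-5", "TRBJ2-7", "TRBJ2-1", NA),
    cdr3a = c(NA, NA, NA, "CAVRDSNYQLIW", "CAGGGSQGNLIF", "CAVNTGNQFYF"),
    va = c(NA, NA, NA, "TRAV1-2", "TRAV12-1", "TRAV8-1"),
    ja = c(NA, NA, NA, "TRAJ33", "TRAJ42", "TRAJ49"),
    epitope = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "NLVPMVATV",
                "ELAGIGILTV", "ELAGIGILTV"),
    mhc = c("HLA-A*02:01", "HLA-A*02:01", "HLA-B*07:02", "HLA-B*07:02",
            "HLA-A*02:01", "HLA-A*02:01"),
    label = 1L,
    source_id = sprintf("toy%02d", 1:6),
    stringsAsFactors = FALSE)
}

toyDataset <- function(variant = "Dab_a_b") buildDataset(toyRecords(), variant)

# Cached small synthetic repertoire shared across tests in one file.
smallRepertoire <- local({
  cache <- new.env()
  function(nEpitopes = 20, nPositives = 400, seed = 42, ...) {
    key <- paste(nEpitopes, nPositives, seed, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- generateRepertoire(
        synthConfig(nEpitopes = nEpitopes, nPositives = nPositives,
                    seed = seed, ...))
    cache[[key]]
  }
})

tinyModelConfig <- function(dropout = 0, ...) {
  modelConfig(channels = 8L, kernel = 3L, heads = 2L, geneDim = 4L,
              mhcDim = 4L, hidden = 8L, dropout = dropout, ...)
}

tinyMaxLens <- list(l = 20L, le = 12L)

tinyPack <- function(dataset, rows = NULL, embedDim = 4L, maxLens = tinyMaxLens) {
  rec <- records(dataset)
  if (!is.null(rows)) rec <- rec[rows, , drop = FALSE]
  packExamples(rec, dataset, mockEmbedder(embedDim), maxLens = maxLens)
}

# --- independent oracles ------------------------------------------------

# AUROC by exhaustive pairwise concordance (ties count one half).
aurocBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AP by explicit rank-by-rank summation (assumes distinct scores).
apBruteForce <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  nPos <- sum(y == 1)
  tp <- 0
  ap <- 0
  for (k in seq_along(y)) {
    if (y[k] == 1) {
      tp <- tp + 1
      ap <- ap + (tp / k) * (1 / nPos)
    }
  }
  ap
}

# Levenshtein distance by the full dynamic-programming matrix.
levenshteinDp <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  D <- matrix(0L, na + 1, nb + 1)
  D[, 1] <- 0:na
  D[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb))
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                           D[i, j] + (A[i] != B[j]))
  D[na + 1, nb + 1]
}

# Scalar weighted BCE for one observed label.
bceScalar <- function(y, p, w, eps = 1e-7) {
  p <- min(max(p, eps), 1 - eps)
  -w * (y * log(p) + (1 - y) * log(1 - p))
}

# The observed-head prediction for each packed example (paired -> yab).
observedHeadScores <- function(preds, pack) {
  ifelse(pack$hasB & pack$hasA, preds$yab,
         ifelse(pack$hasB == 1, preds$yb, preds$ya))
}

randomAaString <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE), collapse = "")
}
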