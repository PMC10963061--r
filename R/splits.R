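#' TCR identity keys for seen/unseen bookkeeping
#'
#' Under the `"strict"` definition a TCR is identified by the full
#' six-field tuple (beta CDR3/V/J, alpha CDR3/V/J); under `"cdr3b"` by the
#' beta CDR3 alone (records without a beta chain fall back to the full alpha
#' tuple).
#'
#' @param recordsDf canonical record data.frame.
#' @param def `"strict"` or `"cdr3b"`.
#' @return character vector of keys, one per record.
#' @export
tcrKeys <- function(recordsDf, def = c("strict", "cdr3b")) {
  def <- match.arg(def)
  if (def == "strict") {
    paste(recordsDf$cdr3b, recordsDf$vb, recordsDf$jb,
          recordsDf$cdr3a, recordsDf$va, recordsDf$ja, sep = "|")
  } else {
    k <- recordsDf$cdr3b
    noBeta <- is.na(k)
    k[noBeta] <- paste("A", recordsDf$cdr3a[noBeta], recordsDf$va[noBeta],
                       recordsDf$ja[noBeta], sep = "|")
    k
  }
}

#' Assign epitopes to folds with frequency blocking (TPP3)
#'
#' Epitopes are ordered by descending positive count (ties broken by
#' lexicographic epitope order) and, within each consecutive block of
#' `nFolds` epitopes, the fold labels `0..nFolds-1` are a uniform random
#' permutation -- every fold receives exactly one epitope per complete
#' block, so all folds get both frequent and rare epitopes. The trailing
#' partial block receives a random subset of distinct fold labels. Set
#' `blocked = FALSE` for a plain independent-uniform assignment (sensitivity
#' checks only).
#'
#' @param epitopeCounts named numeric vector, positive datapoint count per
#'   epitope.
#' @param nFolds number of folds; must equal the block length.
#' @param block block length (the `k` consecutive epitopes sharing one label
#'   permutation).
#' @param seed integer seed.
#' @param blocked use the blocked permutation scheme (default) or
#'   independent uniform labels.
#' @return named integer vector epitope -> fold index (0-based).
#' @export
assignTpp3Folds <- function(epitopeCounts, nFolds = 10L, block = 10L, seed = 1L,
                            blocked = TRUE) {
  if (nFolds != block) stop("unsupported configuration: nFolds must equal block")
  if (!length(epitopeCounts)) stop("at least one epitope required")
  o <- order(-epitopeCounts, names(epitopeCounts))
  eps <- names(epitopeCounts)[o]
  withSeed(seed, {
    if (!blocked) {
      folds <- sample.int(nFolds, length(eps), replace = TRUE) - 1L
    } else {
      folds <- integer(length(eps))
      i <- 1L
      while (i <= length(eps)) {
        m <- min(block, length(eps) - i + 1L)
        folds[i:(i + m - 1L)] <- sample.int(nFolds, m) - 1L
        i <- i + block
      }
    }
    setNames(folds, eps)
  })
}

# Carve a validation set out of train indices. random: uniform datapoint
# sample; unseen_epitope: whole epitopes moved until the fraction is reached.
carveValidation <- function(recordsDf, trainIdx, valMode, valFraction, seed) {
  if (valFraction <= 0) return(list(train = trainIdx, validation = integer(0)))
  withSeed(seed + 7L, {
    if (valMode == "random") {
      nVal <- floor(valFraction * length(trainIdx))
      val <- sort(sampleVec(trainIdx, nVal))
    } else {
      eps <- sampleVec(unique(recordsDf$epitope[trainIdx]))
      target <- valFraction * length(trainIdx)
      cum <- cumsum(vapply(eps, function(e)
        sum(recordsDf$epitope[trainIdx] == e), numeric(1)))
      chosen <- eps[seq_len(max(1L, which.max(cum >= target)))]
      val <- sort(trainIdx[recordsDf$epitope[trainIdx] %in% chosen])
    }
    list(train = sort(setdiff(trainIdx, val)), validation = val)
  })
}

#' Build one TPP3 (unseen epitope, unseen TCR) fold split
#'
#' Test = all datapoints whose epitope carries the given fold label; no
#' epitope occurs on both sides. Validation is carved from train, by default
#' as a naive random datapoint sample.
#'
#' @param dataset a [TcrDataset-class] (positives).
#' @param foldAssignment from [assignTpp3Folds()]; must cover all epitopes.
#' @param foldIndex which fold forms the test set.
#' @param valMode `"random"` or `"unseen_epitope"`.
#' @param valFraction fraction of train carved out for validation.
#' @param seed integer seed.
#' @param tcrKeyDef TCR identity definition recorded on the split.
#' @return a [FoldSplit-class].
#' @export
makeTpp3Split <- function(dataset, foldAssignment, foldIndex,
                          valMode = c("random", "unseen_epitope"),
                          valFraction = 0.1, seed = 1L,
                          tcrKeyDef = c("strict", "cdr3b")) {
  valMode <- match.arg(valMode)
  tcrKeyDef <- match.arg(tcrKeyDef)
  rec <- records(dataset)
  if (!all(unique(rec$epitope) %in% names(foldAssignment)))
    stop("fold assignment does not cover all epitopes")
  testIdx <- which(foldAssignment[rec$epitope] == foldIndex)
  if (!length(testIdx)) stop("empty test fold ", foldIndex)
  cv <- carveValidation(rec, setdiff(seq_len(nrow(rec)), testIdx),
                        valMode, valFraction, seed)
  new("FoldSplit", task = "TPP3", foldIndex = as.integer(foldIndex),
      train = as.integer(cv$train), validation = as.integer(cv$validation),
      test = sort(as.integer(testIdx)), seed = as.integer(seed),
      tcrKeyDef = tcrKeyDef, extraTrainEpitopes = character(0))
}

#' Build one TPP2 (seen epitope, unseen TCR) fold split
#'
#' Unique TCR keys are shuffled and partitioned into `nFolds` groups; the
#' test set holds the datapoints of group `foldIndex`. Test epitopes with no
#' positive train datapoints are recorded in `extraTrainEpitopes`: the
#' negative generator must inject train negatives for them so the
#' seen-epitope constraint holds (their 1:5 ratio cannot be retained).
#'
#' @inheritParams makeTpp3Split
#' @param nFolds number of folds the TCR keys are partitioned into.
#' @return a [FoldSplit-class].
#' @export
makeTpp2Split <- function(dataset, nFolds = 10L, foldIndex = 0L,
                          tcrKeyDef = c("strict", "cdr3b"), seed = 1L,
                          valMode = "random", valFraction = 0.1) {
  tcrKeyDef <- match.arg(tcrKeyDef)
  rec <- records(dataset)
  keys <- tcrKeys(rec, tcrKeyDef)
  uk <- unique(keys)
  # partition keys round-robin over a random permutation for near-equal sizes
  fold <- withSeed(seed, {
    perm <- sampleVec(uk)
    setNames(rep_len(0:(nFolds - 1L), length(uk)), perm)
  })
  testIdx <- which(fold[keys] == foldIndex)
  if (!length(testIdx)) stop("empty test fold ", foldIndex)
  trainAll <- setdiff(seq_len(nrow(rec)), testIdx)
  cv <- carveValidation(rec, trainAll, valMode, valFraction, seed)
  extra <- setdiff(unique(rec$epitope[testIdx]), unique(rec$epitope[cv$train]))
  new("FoldSplit", task = "TPP2", foldIndex = as.integer(foldIndex),
      train = as.integer(cv$train), validation = as.integer(cv$validation),
      test = sort(as.integer(testIdx)), seed = as.integer(seed),
      tcrKeyDef = tcrKeyDef, extraTrainEpitopes = extra)
}

#' Build one TPP1 (seen TCR, seen epitope, unseen pair) fold split
#'
#' Greedily moves datapoints into the test set whose TCR key and epitope
#' both retain at least one other occurrence in train, so every test
#' datapoint's TCR and epitope are seen in training but the pair is not.
#'
#' @inheritParams makeTpp2Split
#' @param testFraction target fraction of datapoints placed in test.
#' @return a [FoldSplit-class].
#' @export
makeTpp1Split <- function(dataset, testFraction = 0.1, foldIndex = 0L,
                          tcrKeyDef = c("strict", "cdr3b"), seed = 1L,
                          valMode = "random", valFraction = 0.1) {
  tcrKeyDef <- match.arg(tcrKeyDef)
  rec <- records(dataset)
  keys <- tcrKeys(rec, tcrKeyDef)
  keyCount <- table(keys)
  epCount <- table(rec$epitope)
  target <- max(1L, floor(testFraction * nrow(rec)))
  testIdx <- integer(0)
  withSeed(seed, {
    for (i in sample.int(nrow(rec))) {
      if (length(testIdx) >= target) break
      k <- keys[i]; e <- rec$epitope[i]
      if (keyCount[[k]] >= 2L && epCount[[e]] >= 2L) {
        testIdx <- c(testIdx, i)
        keyCount[[k]] <- keyCount[[k]] - 1L
        epCount[[e]] <- epCount[[e]] - 1L
      }
    }
  })
  if (!length(testIdx))
    stop("TPP1 split infeasible: no datapoint has both its TCR and epitope ",
         "occurring elsewhere")
  cv <- carveValidation(rec, setdiff(seq_len(nrow(rec)), testIdx),
                        valMode, valFraction, seed)
  new("FoldSplit", task = "TPP1", foldIndex = as.integer(foldIndex),
      train = as.integer(cv$train), validation = as.integer(cv$validation),
      test = sort(as.integer(testIdx)), seed = as.integer(seed),
      tcrKeyDef = tcrKeyDef, extraTrainEpitopes = character(0))
}

#' Build one TPP4 (seen TCR, unseen epitope) fold split
#'
#' The mirror image of TPP2: epitopes are partitioned into folds and test
#' TCR keys absent from train are recorded for extra-negative injection.
#' Shipped untested against published results -- on database data TCRs
#' rarely pair with more than one epitope, making the task degenerate.
#'
#' @inheritParams makeTpp2Split
#' @return a [FoldSplit-class].
#' @export
makeTpp4Split <- function(dataset, nFolds = 10L, foldIndex = 0L,
                          tcrKeyDef = c("strict", "cdr3b"), seed = 1L,
                          valMode = "random", valFraction = 0.1) {
  tcrKeyDef <- match.arg(tcrKeyDef)
  rec <- records(dataset)
  eps <- unique(rec$epitope)
  fold <- withSeed(seed, {
    perm <- sampleVec(eps)
    setNames(rep_len(0:(nFolds - 1L), length(eps)), perm)
  })
  testIdx <- which(fold[rec$epitope] == foldIndex)
  if (!length(testIdx)) stop("empty test fold ", foldIndex)
  cv <- carveValidation(rec, setdiff(seq_len(nrow(rec)), testIdx),
                        valMode, valFraction, seed)
  keys <- tcrKeys(rec, tcrKeyDef)
  extra <- setdiff(unique(keys[testIdx]), unique(keys[cv$train]))
  new("FoldSplit", task = "TPP4", foldIndex = as.integer(foldIndex),
      train = as.integer(cv$train), validation = as.integer(cv$validation),
      test = sort(as.integer(testIdx)), seed = as.integer(seed),
      tcrKeyDef = tcrKeyDef, extraTrainEpitopes = extra)
}

#' Restrict a TPP3 fold assignment by cross-fold epitope distance
#'
#' Guarantees a minimum Levenshtein distance between any two epitopes in
#' different folds: epitopes are single-linkage clustered with edges at
#' distance `< minDist`, and whole clusters are assigned to folds by the
#' same descending-frequency blocked permutation used for single epitopes.
#'
#' @param epitopeCounts named positive-count vector.
#' @param minDist minimum cross-fold edit distance (default 5).
#' @param nFolds,seed as in [assignTpp3Folds()].
#' @return named integer vector epitope -> fold; clustered epitopes share a
#'   fold.
#' @export
restrictFoldsByDistance <- function(epitopeCounts, minDist = 5L, nFolds = 10L,
                                    seed = 1L) {
  eps <- names(epitopeCounts)
  d <- adist(eps, eps)
  # union-find single linkage: edges between epitopes closer than minDist
  parent <- seq_along(eps)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(eps)) for (j in seq_len(max(0L, i - 1L))) {
    if (d[i, j] < minDist) {
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_along(eps), findRoot, integer(1))
  comp <- match(comp, unique(comp))
  if (length(unique(comp)) < nFolds)
    stop("distance restriction infeasible: only ", length(unique(comp)),
         " epitope cluster(s) for ", nFolds, " folds")
  clusterCount <- tapply(epitopeCounts, comp, sum)
  clusterFold <- assignTpp3Folds(setNames(as.numeric(clusterCount),
                                          names(clusterCount)),
                                 nFolds = nFolds, block = nFolds, seed = seed)
  setNames(unname(clusterFold[as.character(comp)]), eps)
}

#' Exclude low-frequency epitopes from a split
#'
#' Epitopes with fewer than `minTcrs` positive datapoints (counted on the
#' full dataset, before splitting) are removed from the designated side(s)
#' of the split.
#'
#' @param dataset a [TcrDataset-class] (positives).
#' @param split a [FoldSplit-class].
#' @param minTcrs minimum positive count for an epitope to be retained.
#' @param where `"train"`, `"test"` or `"both"`.
#' @return the filtered [FoldSplit-class]; removal counts in attribute
#'   `"excluded"`.
#' @export
excludeLowFrequencyEpitopes <- function(dataset, split, minTcrs = 15L,
                                        where = c("train", "test", "both")) {
  where <- match.arg(where)
  rec <- records(dataset)
  counts <- table(rec$epitope[rec$label == 1])
  low <- names(counts)[counts < minTcrs]
  dropFrom <- function(idx) idx[!rec$epitope[idx] %in% low]
  nBefore <- c(train = length(split@train), test = length(split@test))
  if (where %in% c("train", "both")) {
    split@train <- dropFrom(split@train)
    split@validation <- dropFrom(split@validation)
  }
  if (where %in% c("test", "both")) split@test <- dropFrom(split@test)
  attr(split, "excluded") <- list(
    epitopes = low,
    removed = c(train = nBefore[["train"]] - length(split@train),
                test = nBefore[["test"]] - length(split@test)))
  split
}

#' Few-shot epitope-inclusion protocol
#'
#' Emulates screening a panel of novel epitopes against known TCRs: screen
#' epitopes (disjoint from the base dataset's epitopes) are partitioned
#' across repeats in groups of 1 to `maxPerRepeat`; in each repeat the
#' chosen epitopes' positives move into train, paired with negatives at the
#' given ratio built from random TCRs of the base training set, while the
#' remaining screen positives form the test set. Across all repeats every
#' screen positive enters train exactly once.
#'
#' @param trainRecords canonical records of the base training set (TCR
#'   donors for the generated negatives).
#' @param screenPositives canonical records of the screen positives; their
#'   epitopes must be disjoint from `trainRecords`' epitopes.
#' @param repeats number of repeats.
#' @param maxPerRepeat maximum number of distinct screen epitopes included
#'   per repeat.
#' @param ratio negatives per included positive.
#' @param seed integer seed.
#' @return list of length `repeats`; each element has `trainExtra` (included
#'   positives plus generated negatives, canonical columns) and `testIdx`
#'   (row indices into `screenPositives` forming the test set).
#' @export
fewShotInclusionSplit <- function(trainRecords, screenPositives, repeats = 10L,
                                  maxPerRepeat = 4L, ratio = 5L, seed = 1L) {
  eps <- unique(screenPositives$epitope)
  if (any(eps %in% trainRecords$epitope))
    stop("screen epitopes must be disjoint from training epitopes")
  if (repeats > length(eps))
    stop("more repeats than screen epitopes")
  if (length(eps) > repeats * maxPerRepeat)
    stop("cannot cover ", length(eps), " epitopes in ", repeats,
         " repeats of at most ", maxPerRepeat)
  withSeed(seed, {
    perm <- sampleVec(eps)
    sizes <- rep(1L, repeats)
    extra <- length(eps) - repeats
    while (extra > 0L) {
      i <- sample(which(sizes < maxPerRepeat), 1L)
      sizes[i] <- sizes[i] + 1L
      extra <- extra - 1L
    }
    groups <- split(perm, rep(seq_len(repeats), sizes))
    tcrCols <- c("cdr3b", "vb", "jb", "cdr3a", "va", "ja")
    lapply(seq_len(repeats), function(r) {
      chosen <- groups[[r]]
      inIdx <- which(screenPositives$epitope %in% chosen)
      pos <- screenPositives[inIdx, , drop = FALSE]
      negs <- do.call(rbind, lapply(chosen, function(e) {
        epPos <- pos[pos$epitope == e, , drop = FALSE]
        n <- ratio * nrow(epPos)
        donors <- trainRecords[sample.int(nrow(trainRecords), n, replace = n >
                                            nrow(trainRecords)), tcrCols, drop = FALSE]
        cbind(donors,
              data.frame(epitope = e, mhc = epPos$mhc[1], label = 0L,
                         source_id = sprintf("fewshot_neg_%s_%d", e, seq_len(n)),
                         stringsAsFactors = FALSE))
      }))
      list(trainExtra = rbind(pos[, RECORD_COLUMNS], negs[, RECORD_COLUMNS]),
           testIdx = setdiff(seq_len(nrow(screenPositives)), inIdx),
           epitopes = chosen)
    })
  })
}

#' Independently validate a fold split's task constraint
#'
#' Re-derives the seen/unseen sets from scratch (separately from the split
#' constructors) and checks the defining property of the split's task, plus
#' index disjointness. For TPP2, test epitopes missing from train must be
#' covered by the split's `extraTrainEpitopes` bookkeeping.
#'
#' @param split a [FoldSplit-class].
#' @param dataset the [TcrDataset-class] it indexes.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validateSplit <- function(split, dataset) {
  rec <- records(dataset)
  v <- character(0)
  te <- split@test; va <- split@validation
  if (length(intersect(split@train, te)) || length(intersect(split@train, va)) ||
      length(intersect(va, te)))
    v <- c(v, "index sets overlap")
  # the validation set is carved out of the training partition; seen/unseen
  # bookkeeping treats both as training data
  tr <- c(split@train, va)
  if (any(c(tr, te, va) < 1L) || any(c(tr, te, va) > nrow(rec)))
    v <- c(v, "indices outside dataset")
  keys <- tcrKeys(rec, split@tcrKeyDef)
  trKeys <- unique(keys[tr]); teKeys <- unique(keys[te])
  trEps <- unique(rec$epitope[tr]); teEps <- unique(rec$epitope[te])
  if (split@task == "TPP3") {
    if (length(intersect(trEps, teEps))) v <- c(v, "TPP3: epitope seen in train")
    if (length(intersect(trKeys, teKeys))) v <- c(v, "TPP3: TCR seen in train")
  } else if (split@task == "TPP2") {
    if (length(intersect(trKeys, teKeys))) v <- c(v, "TPP2: TCR seen in train")
    uncovered <- setdiff(teEps, c(trEps, split@extraTrainEpitopes))
    if (length(uncovered))
      v <- c(v, paste("TPP2: test epitope(s) unseen and not marked for extra",
                      "negatives:", paste(head(uncovered, 3), collapse = ",")))
  } else if (split@task == "TPP1") {
    pairs <- paste(keys, rec$epitope, sep = "\r")
    bad <- te[!(keys[te] %in% trKeys) | !(rec$epitope[te] %in% trEps) |
                (pairs[te] %in% pairs[tr])]
    if (length(bad)) v <- c(v, sprintf("TPP1: %d invalid test datapoint(s)", length(bad)))
  } else if (split@task == "TPP4") {
    if (length(intersect(trEps, teEps))) v <- c(v, "TPP4: epitope seen in train")
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Serialize a FoldSplit to JSON
#'
#' @param split a [FoldSplit-class].
#' @param dataset the dataset it indexes (for the content checksum).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSplit <- function(split, dataset, path) {
  checksum <- hashString(paste(do.call(paste, c(records(dataset), sep = "|")),
                               collapse = "\n"))
  jsonlite::write_json(list(
    task = split@task, fold_index = split@foldIndex, seed = split@seed,
    tcr_key_def = split@tcrKeyDef,
    train = split@train, validation = split@validation, test = split@test,
    extra_train_epitopes = split@extraTrainEpitopes,
    dataset_checksum = checksum), path, auto_unbox = TRUE)
  invisible(path)
}
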