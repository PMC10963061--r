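TCR_COLUMNS <- c("cdr3b", "vb", "jb", "cdr3a", "va", "ja")

# TCR-difference key used to decide whether a shuffled candidate collides
# with a positive: full tuple under "any_part", beta CDR3 under "cdr3b_only".
negDefKey <- function(df, definition) {
  if (definition == "any_part") do.call(paste, c(df[TCR_COLUMNS], sep = "|"))
  else tcrKeys(df, "cdr3b")
}

#' Generate negatives by constrained TCR-epitope shuffling
#'
#' Within one split partition, pairs TCRs drawn from the partition's own
#' TCRs with each epitope-MHC unit (kept atomic) to reach `ratio` negatives
#' per positive for every epitope. A candidate is admissible only if it
#' differs from every positive TCR of that epitope under the active
#' definition: `"any_part"` (any of CDR3/V/J on either chain differs) or
#' `"cdr3b_only"` (at least the beta CDR3 differs). Candidates are drawn by
#' rejection sampling (attempt cap 100x the target), after which the
#' admissible set is enumerated exactly, guaranteeing termination and exact
#' detection of exhaustion. No duplicate negatives are admitted.
#'
#' @param positives canonical record data.frame of the partition's positives.
#' @param definition `"any_part"` or `"cdr3b_only"`.
#' @param ratio negatives per positive (per epitope).
#' @param seed integer seed.
#' @param extraUnits optional data.frame (`epitope`, `mhc`) of epitope-MHC
#'   units without partition positives (TPP2 extra-negative injection);
#'   each receives `ratio` negatives, admissibility unconstrained.
#' @return list with `negatives` (canonical records, label 0), `achieved`
#'   (named integer: negatives per epitope) and `target` (named integer).
#' @export
generateNegatives <- function(positives, definition = c("any_part", "cdr3b_only"),
                              ratio = 5L, seed = 1L, extraUnits = NULL) {
  definition <- match.arg(definition)
  if (!nrow(positives))
    return(list(negatives = positives[0, ], achieved = integer(0), target = integer(0)))
  tcrPool <- unique(positives[TCR_COLUMNS])
  rownames(tcrPool) <- NULL
  poolKeys <- negDefKey(tcrPool, definition)
  posKeysByEp <- split(negDefKey(positives, definition), positives$epitope)

  units <- unique(positives[c("epitope", "mhc")])
  units$n_pos <- vapply(seq_len(nrow(units)), function(i) {
    sameEp <- positives$epitope == units$epitope[i]
    sameMhc <- (!is.na(positives$mhc) & !is.na(units$mhc[i]) &
                  positives$mhc == units$mhc[i]) |
      (is.na(positives$mhc) & is.na(units$mhc[i]))
    sum(sameEp & sameMhc)
  }, numeric(1))
  if (!is.null(extraUnits) && nrow(extraUnits)) {
    extraUnits$n_pos <- 0
    units <- rbind(units, extraUnits[c("epitope", "mhc", "n_pos")])
  }

  negs <- list()
  achieved <- target <- integer(0)
  withSeed(seed, {
    for (i in seq_len(nrow(units))) {
      e <- units$epitope[i]
      tgt <- if (units$n_pos[i] > 0) ratio * units$n_pos[i] else ratio
      bad <- poolKeys %in% (posKeysByEp[[e]] %||% character(0))
      # rejection sampling over the TCR pool, then exact enumeration
      cap <- 100L * tgt
      cand <- sample.int(nrow(tcrPool), min(cap, 100L * tgt), replace = TRUE)
      cand <- unique(cand[!bad[cand]])
      if (length(cand) < tgt) {
        admissible <- which(!bad)
        rest <- setdiff(admissible, cand)
        cand <- c(cand, sampleVec(rest, min(length(rest), tgt - length(cand))))
      }
      chosen <- cand[seq_len(min(tgt, length(cand)))]
      if (length(chosen)) {
        block <- tcrPool[chosen, , drop = FALSE]
        block$epitope <- e
        block$mhc <- units$mhc[i]
        block$label <- 0L
        block$source_id <- sprintf("neg_s%d_%s_%d", seed, e,
                                   length(negs) + seq_along(chosen))
        negs[[length(negs) + 1L]] <- block[, RECORD_COLUMNS]
      }
      prevA <- if (e %in% names(achieved)) achieved[[e]] else 0L
      achieved[e] <- prevA + length(chosen)
      prevT <- if (e %in% names(target)) target[[e]] else 0L
      target[e] <- prevT + tgt
    }
  })
  negatives <- if (length(negs)) do.call(rbind, negs) else positives[0, RECORD_COLUMNS]
  rownames(negatives) <- NULL
  attr(negatives, "neg_seed") <- seed
  attr(negatives, "definition") <- definition
  list(negatives = negatives, achieved = achieved, target = target)
}

#' Enforce the exact per-epitope positive:negative ratio
#'
#' For epitopes where shuffling could not produce `ratio` negatives per
#' positive, positives are discarded uniformly at random until negatives
#' equal `ratio` times the kept positives exactly; surplus negatives are
#' trimmed likewise.
#'
#' @param positives canonical positive records of the partition.
#' @param pool result of [generateNegatives()].
#' @param ratio target negatives per positive.
#' @param seed integer seed for the random discards.
#' @return list with `positives` (kept), `negatives` (trimmed) and
#'   `discarded` (named integer per epitope).
#' @export
enforceRatio <- function(positives, pool, ratio = 5L, seed = 1L) {
  negatives <- pool$negatives
  discarded <- integer(0)
  keepPos <- rep(TRUE, nrow(positives))
  keepNeg <- rep(TRUE, nrow(negatives))
  withSeed(seed + 13L, {
    for (e in unique(positives$epitope)) {
      posIdx <- which(positives$epitope == e)
      negIdx <- which(negatives$epitope == e)
      k <- min(length(posIdx), floor(length(negIdx) / ratio))
      if (k < length(posIdx)) {
        drop <- sampleVec(posIdx, length(posIdx) - k)
        keepPos[drop] <- FALSE
        discarded[e] <- length(drop)
      }
      if (length(negIdx) > ratio * k)
        keepNeg[sampleVec(negIdx, length(negIdx) - ratio * k)] <- FALSE
    }
  })
  list(positives = positives[keepPos, , drop = FALSE],
       negatives = negatives[keepNeg, , drop = FALSE],
       discarded = discarded)
}

#' Generate and ratio-enforce negatives for one partition
#'
#' Convenience wrapper: [generateNegatives()] followed by [enforceRatio()],
#' returning the combined labelled partition.
#'
#' @inheritParams generateNegatives
#' @return data.frame of kept positives and negatives (canonical columns),
#'   with attributes `discarded` and `neg_seed`.
#' @export
buildPartition <- function(positives, definition = c("any_part", "cdr3b_only"),
                           ratio = 5L, seed = 1L, extraUnits = NULL) {
  definition <- match.arg(definition)
  pool <- generateNegatives(positives, definition, ratio, seed, extraUnits)
  extraEps <- if (!is.null(extraUnits)) unique(extraUnits$epitope) else character(0)
  # extra-injected epitopes have no positives; exempt from ratio enforcement
  enforceable <- !(pool$negatives$epitope %in% extraEps)
  poolMain <- list(negatives = pool$negatives[enforceable, , drop = FALSE])
  adj <- enforceRatio(positives, poolMain, ratio, seed)
  out <- rbind(adj$positives, adj$negatives,
               pool$negatives[!enforceable, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "discarded") <- adj$discarded
  attr(out, "neg_seed") <- seed
  attr(out, "definition") <- definition
  out
}

#' Check for label leakage between train and test partitions
#'
#' Reports any generated negative in one partition that equals (under the
#' active definition) a positive of the same epitope in the other partition.
#'
#' @param trainRecords labelled train partition (positives + negatives).
#' @param testRecords labelled test partition.
#' @param definition `"any_part"` or `"cdr3b_only"`.
#' @return list with `ok` and a data.frame `violations` (`where`, `epitope`,
#'   `key`).
#' @export
validateNoLeakage <- function(trainRecords, testRecords,
                              definition = c("any_part", "cdr3b_only")) {
  definition <- match.arg(definition)
  pk <- function(df) paste(negDefKey(df, definition), df$epitope, sep = "\r")
  hits <- function(negDf, posDf, where) {
    bad <- pk(negDf) %in% pk(posDf)
    if (!any(bad)) return(NULL)
    data.frame(where = where, epitope = negDf$epitope[bad],
               key = negDefKey(negDf, definition)[bad], stringsAsFactors = FALSE)
  }
  v <- rbind(hits(trainRecords[trainRecords$label == 0, ],
                  testRecords[testRecords$label == 1, ], "train_neg_vs_test_pos"),
             hits(testRecords[testRecords$label == 0, ],
                  trainRecords[trainRecords$label == 1, ], "test_neg_vs_train_pos"))
  list(ok = is.null(v) || nrow(v) == 0L,
       violations = v %||% data.frame(where = character(0), epitope = character(0),
                                      key = character(0)))
}
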