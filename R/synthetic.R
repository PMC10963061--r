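#' Configuration for the synthetic repertoire generator
#'
#' The generator emulates the statistical structure of public TCR-epitope
#' databases: a strongly skewed epitope frequency distribution (a power law
#' whose default exponent makes the top three epitopes own more than a
#' quarter of all datapoints), mixed chain availability (most records
#' beta-only, a large paired fraction, a small alpha-only tail), real
#' IMGT-style functional gene names with epitope-biased V usage, and a small
#' MHC class I allele vocabulary. Binding follows a planted, recoverable
#' rule: each epitope donates a random `motifLen`-mer of its own sequence,
#' and a cognate CDR3 carries a (possibly point-mutated) copy of that motif
#' at a random interior position.
#'
#' @param nEpitopes number of distinct epitopes.
#' @param nPositives total positive datapoints.
#' @param exponent power-law exponent of the epitope frequency law.
#' @param motifLen planted motif length (k-mer shared between epitope and
#'   cognate CDR3).
#' @param mutationRate probability that a planted motif copy carries one
#'   random point substitution.
#' @param availability length-3 numeric (beta-only, paired, alpha-only)
#'   fractions summing to 1.
#' @param epitopeLen integer range of epitope lengths.
#' @param cdr3Len integer range of CDR3 lengths (interior grown to fit the
#'   motif).
#' @param nMhc number of MHC class I allele strings.
#' @param vBias probability that a cognate TCR uses its epitope's preferred
#'   V gene (the remainder uniform), planting gene-usage signal.
#' @param motifMode `"epitope_kmer"` draws each motif as a random k-mer of
#'   its epitope's own sequence; `"shared_core"` derives all motifs from one
#'   common core k-mer by a single random substitution each and splices the
#'   motif into the epitope, so motifs of different epitopes are correlated
#'   (a rule partially transferable to unseen epitopes).
#' @param seed integer seed.
#' @return named list of class `"tcrpairSynthConfig"`.
#' @export
synthConfig <- function(nEpitopes = 60L, nPositives = 3000L, exponent = 1.5,
                        motifLen = 4L, mutationRate = 0.05,
                        availability = c(beta = 0.55, paired = 0.40, alpha = 0.05),
                        epitopeLen = c(9L, 11L), cdr3Len = c(12L, 16L),
                        nMhc = 6L, vBias = 0.5,
                        motifMode = c("epitope_kmer", "shared_core"),
                        seed = 1L) {
  stopifnot(abs(sum(availability) - 1) < 1e-9, motifLen < min(cdr3Len) - 2,
            motifLen <= min(epitopeLen))
  structure(list(nEpitopes = as.integer(nEpitopes),
                 nPositives = as.integer(nPositives), exponent = exponent,
                 motifLen = as.integer(motifLen), mutationRate = mutationRate,
                 availability = availability, epitopeLen = as.integer(epitopeLen),
                 cdr3Len = as.integer(cdr3Len), nMhc = as.integer(nMhc),
                 vBias = vBias, motifMode = match.arg(motifMode),
                 seed = as.integer(seed)),
            class = "tcrpairSynthConfig")
}

randomAa <- function(n) paste(sampleVec(AA_ALPHABET, n, replace = TRUE), collapse = "")

mutateOne <- function(seq) {
  i <- sample.int(nchar(seq), 1)
  letter <- sampleVec(setdiff(AA_ALPHABET, substr(seq, i, i)), 1)
  paste0(substr(seq, 1, i - 1), letter, substring(seq, i + 1))
}

# Functional genes of a locus from the packaged reference.
functionalGenes <- function(locus) {
  tab <- loadGeneReference()
  tab$gene[tab$locus == locus & tab$functionality == "F"]
}

#' Generate a synthetic positive repertoire
#'
#' Draws epitopes, their motifs, per-epitope positive counts from the
#' power law, and cognate TCRs whose available CDR3s carry the epitope's
#' planted motif. A candidate CDR3 accidentally containing another
#' epitope's motif is rejected and redrawn, so the signal stays
#' epitope-specific. All CDR3s are canonical (C...F/W), all genes are
#' functional names from the packaged reference, all records are human MHC
#' class I -- the output passes the preprocessing module unchanged.
#'
#' @param config a [synthConfig()].
#' @return a [TcrDataset-class] of positives (variant `Dab_a_b`), with the
#'   generator's ground truth (epitope motifs, preferred V genes) in
#'   attribute `"truth"`.
#' @export
generateRepertoire <- function(config = synthConfig()) {
  cfg <- config
  withSeed(cfg$seed, {
    tbv <- functionalGenes("TRBV"); tbj <- functionalGenes("TRBJ")
    tav <- functionalGenes("TRAV"); taj <- functionalGenes("TRAJ")
    mhcAlleles <- sprintf("HLA-%s*%02d:01",
                          sampleVec(rep(c("A", "B", "C"), length.out = cfg$nMhc)),
                          sample.int(40, cfg$nMhc))
    # distinct epitopes with distinct motifs
    epitopes <- character(0)
    while (length(epitopes) < cfg$nEpitopes) {
      cand <- randomAa(sample(seq(cfg$epitopeLen[1], cfg$epitopeLen[2]), 1))
      if (!cand %in% epitopes) epitopes <- c(epitopes, cand)
    }
    if (cfg$motifMode == "shared_core") {
      core <- randomAa(cfg$motifLen)
      motifs <- vapply(seq_along(epitopes), function(i) mutateOne(core),
                       character(1))
      # splice each motif into its epitope at a random position
      pos <- vapply(epitopes, function(e)
        sample.int(nchar(e) - cfg$motifLen + 1L, 1), integer(1))
      epitopes <- vapply(seq_along(epitopes), function(i)
        paste0(substr(epitopes[i], 1, pos[i] - 1L), motifs[i],
               substring(epitopes[i], pos[i] + cfg$motifLen)), character(1))
      stopifnot(!anyDuplicated(epitopes))
    } else {
      motifStart <- vapply(epitopes, function(e)
        sample.int(nchar(e) - cfg$motifLen + 1L, 1), integer(1))
      motifs <- substr(epitopes, motifStart, motifStart + cfg$motifLen - 1L)
    }
    prefV <- setNames(sampleVec(tbv, cfg$nEpitopes, replace = TRUE), epitopes)
    prefVa <- setNames(sampleVec(tav, cfg$nEpitopes, replace = TRUE), epitopes)
    epMhc <- setNames(sampleVec(mhcAlleles, cfg$nEpitopes, replace = TRUE), epitopes)

    w <- seq_len(cfg$nEpitopes)^(-cfg$exponent)
    nPer <- pmax(1L, round(cfg$nPositives * w / sum(w)))

    drawCdr3 <- function(motif, avoid) {
      # canonical CDR3 with the (possibly mutated) motif at a random
      # interior position; redraw on collision with another epitope's motif
      for (attempt in 1:50) {
        len <- sample(seq(cfg$cdr3Len[1], cfg$cdr3Len[2]), 1)
        m <- if (runif(1) < cfg$mutationRate) mutateOne(motif) else motif
        interiorLen <- len - 2L - nchar(m)
        npre <- sample(0:interiorLen, 1)
        cdr3 <- paste0("C", randomAa(npre), m, randomAa(interiorLen - npre), "F")
        if (!any(vapply(avoid, function(x) grepl(x, cdr3, fixed = TRUE),
                        logical(1))))
          return(cdr3)
      }
      cdr3
    }

    n <- sum(nPer)
    col <- function() rep(NA_character_, n)
    cdr3b <- col(); vb <- col(); jb <- col()
    cdr3a <- col(); va <- col(); ja <- col()
    epitope <- col(); mhcCol <- col()
    k <- 0L
    for (ei in seq_len(cfg$nEpitopes)) {
      e <- epitopes[ei]
      avoid <- setdiff(motifs[-ei], motifs[ei])
      for (j in seq_len(nPer[ei])) {
        k <- k + 1L
        kind <- sample.int(3L, 1, prob = cfg$availability)
        hasB <- kind %in% c(1L, 2L)
        hasA <- kind %in% c(2L, 3L)
        if (hasB) {
          cdr3b[k] <- drawCdr3(motifs[ei], avoid)
          vb[k] <- if (runif(1) < cfg$vBias) prefV[[e]] else sampleVec(tbv, 1)
          jb[k] <- sampleVec(tbj, 1)
        }
        if (hasA) {
          cdr3a[k] <- drawCdr3(motifs[ei], avoid)
          va[k] <- if (runif(1) < cfg$vBias) prefVa[[e]] else sampleVec(tav, 1)
          ja[k] <- sampleVec(taj, 1)
        }
        epitope[k] <- e
        mhcCol[k] <- epMhc[[e]]
      }
    }
    rec <- data.frame(cdr3b = cdr3b, vb = vb, jb = jb, cdr3a = cdr3a,
                      va = va, ja = ja, epitope = epitope, mhc = mhcCol,
                      label = 1L, source_id = sprintf("synth%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    # exact duplicates would violate the no-duplicate-datapoint rule
    rec <- rec[!duplicated(rec[c("cdr3b", "cdr3a", "epitope")]), , drop = FALSE]
    ds <- buildDataset(rec, "Dab_a_b")
    attr(ds, "truth") <- list(motifs = setNames(motifs, epitopes),
                              preferredV = prefV, preferredVa = prefVa,
                              epitopeMhc = epMhc)
    ds
  })
}

#' Check the planted binding signal in a synthetic dataset
#'
#' Reports how often the cognate CDR3 of a positive contains its epitope's
#' motif verbatim, versus how often a mismatched (shuffled) TCR-epitope
#' pair does -- the prevalence gap is the learnable signal strength. The
#' background rate for mismatched pairs is governed by the chance of a
#' random k-mer collision.
#'
#' @param dataset output of [generateRepertoire()] (needs the `"truth"`
#'   attribute).
#' @param nShuffle number of mismatched pairs sampled for the background
#'   estimate.
#' @param seed integer seed for the shuffle.
#' @return list with `prevalencePositives`, `prevalenceShuffled`, `gap`.
#' @export
plantCheck <- function(dataset, nShuffle = 2000L, seed = 1L) {
  truth <- attr(dataset, "truth")
  stopifnot(!is.null(truth))
  rec <- records(dataset)
  motifOf <- truth$motifs
  hasMotif <- function(cdr3b, cdr3a, epitope) {
    m <- motifOf[[epitope]]
    (!is.na(cdr3b) && grepl(m, cdr3b, fixed = TRUE)) ||
      (!is.na(cdr3a) && grepl(m, cdr3a, fixed = TRUE))
  }
  prevPos <- mean(vapply(seq_len(nrow(rec)), function(i)
    hasMotif(rec$cdr3b[i], rec$cdr3a[i], rec$epitope[i]), logical(1)))
  prevShuf <- withSeed(seed, {
    i <- sample.int(nrow(rec), nShuffle, replace = TRUE)
    j <- sample.int(nrow(rec), nShuffle, replace = TRUE)
    keep <- rec$epitope[i] != rec$epitope[j]
    mean(vapply(which(keep), function(k)
      hasMotif(rec$cdr3b[i[k]], rec$cdr3a[i[k]], rec$epitope[j[k]]), logical(1)))
  })
  list(prevalencePositives = prevPos, prevalenceShuffled = prevShuf,
       gap = prevPos - prevShuf)
}

#' Motif-matching reference classifier
#'
#' Scores a record 1 if any available CDR3 contains the epitope's planted
#' motif verbatim, else 0 -- an oracle upper bound for classifiers on
#' mutation-free synthetic data.
#'
#' @param recordsDf canonical records.
#' @param motifs named motif vector (epitope -> motif).
#' @return numeric scores.
#' @export
motifClassifier <- function(recordsDf, motifs) {
  vapply(seq_len(nrow(recordsDf)), function(i) {
    m <- motifs[[recordsDf$epitope[i]]]
    if (is.null(m) || is.na(m)) return(0)
    hit <- (!is.na(recordsDf$cdr3b[i]) && grepl(m, recordsDf$cdr3b[i], fixed = TRUE)) ||
      (!is.na(recordsDf$cdr3a[i]) && grepl(m, recordsDf$cdr3a[i], fixed = TRUE))
    as.numeric(hit)
  }, numeric(1))
}
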