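#' Construct a deterministic mock embedding backend
#'
#' Satisfies the embedder contract used by the encoder: a backend is a list
#' with `name`, `dim` and `embed(seq) -> length x dim matrix`. The mock
#' backend produces hash-seeded pseudo-random rows: each row depends on the
#' whole input sequence and the position (contextual, like a language
#' model), is deterministic for a fixed input, and leaves the caller's RNG
#' stream untouched. A production protein-language-model backend (e.g.
#' ProtBERT served externally, 1024-dim) plugs in through the same contract.
#'
#' @param dim embedding dimension per residue.
#' @param name backend name (part of the hash, so different names give
#'   different embeddings).
#' @return an embedder (list with `name`, `dim`, `embed`).
#' @examples
#' emb <- mockEmbedder(8)
#' m <- emb$embed("CASSF")
#' dim(m)  # 5 x 8
#' @export
mockEmbedder <- function(dim = 16L, name = "mock") {
  force(dim); force(name)
  list(name = name, dim = dim,
       embed = function(seq) {
         stopifnot(isAaSeq(seq))
         L <- nchar(seq)
         withSeed(hashString(paste0(name, ":", seq)) %% 2100000000L,
                  matrix(rnorm(L * dim), nrow = L, ncol = dim))
       })
}

#' Load a germline V/J segment table
#'
#' Two-column TSV (`gene`, `segment`). By convention V segments end at the
#' conserved cysteine (the CDR3's first residue) and J segments start at the
#' F/W anchor (the CDR3's last residue). A toy table with invented segments
#' ships with the package for tests and examples.
#'
#' @param path TSV path; default is the packaged toy table.
#' @return named character vector gene -> amino-acid segment.
#' @export
loadGermline <- function(path = system.file("extdata", "toy_germline.tsv",
                                            package = "tcrpair")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$segment, tab$gene)
}

# Germline lookup with allele -> gene fallback.
germlineLookup <- function(gene, germline) {
  if (is.na(gene)) return(NA_character_)
  if (gene %in% names(germline)) return(germline[[gene]])
  base <- sub("\\*.*$", "", gene)
  if (base %in% names(germline)) return(germline[[base]])
  NA_character_
}

#' Reconstruct a full-length TCR chain around its CDR3
#'
#' Splices the CDR3 into its germline context: V segment up to and including
#' its conserved C (which is the CDR3's first residue), the CDR3 interior,
#' then the J segment from its F/W anchor (the CDR3's last residue) onward.
#' The returned span locates the CDR3 within the full sequence exactly; the
#' round trip `substr(full, span)` == `cdr3` is asserted, never assumed.
#'
#' @param cdr3 canonical CDR3 sequence (starts `C`, ends `F`/`W`).
#' @param vGene,jGene unified gene names.
#' @param germline named segment vector from [loadGermline()].
#' @return list with `full` (sequence) and `span` (0-based half-open
#'   `c(start, end)`), or `NULL` when either gene is missing from the table
#'   or the germline anchors disagree with the CDR3's own (caller falls back
#'   to CDR3-only embedding).
#' @export
reconstructFullTcr <- function(cdr3, vGene, jGene, germline) {
  vSeg <- germlineLookup(vGene, germline)
  jSeg <- germlineLookup(jGene, germline)
  if (is.na(vSeg) || is.na(jSeg)) return(NULL)
  stopifnot(substr(vSeg, nchar(vSeg), nchar(vSeg)) == "C",
            substr(jSeg, 1, 1) %in% c("F", "W"))
  # anchors must agree with the CDR3's own (e.g. a W-ending CDR3 cannot sit
  # on an F-anchored J segment); mismatches fall back to CDR3-only embedding
  if (substr(cdr3, 1, 1) != substr(vSeg, nchar(vSeg), nchar(vSeg)) ||
      substr(cdr3, nchar(cdr3), nchar(cdr3)) != substr(jSeg, 1, 1))
    return(NULL)
  # vSeg supplies the CDR3's leading C, jSeg its trailing F/W
  interior <- substr(cdr3, 2, nchar(cdr3) - 1)
  full <- paste0(vSeg, interior, jSeg)
  span <- c(nchar(vSeg) - 1L, nchar(vSeg) - 1L + nchar(cdr3))
  got <- substr(full, span[1] + 1L, span[2])
  if (!identical(got, cdr3))
    stop("internal error: reconstructed CDR3 span mismatch (", got,
         " != ", cdr3, ")")
  list(full = full, span = span)
}

#' Embed a CDR3 with or without germline context
#'
#' If the chain's full-length sequence can be reconstructed from the
#' germline table, the full sequence is embedded and only the CDR3-span rows
#' are extracted; otherwise the CDR3 alone is embedded. Both paths return a
#' matrix with one row per CDR3 residue.
#'
#' @param cdr3 canonical CDR3 sequence.
#' @param vGene,jGene unified gene names (may be `NA`).
#' @param embedder an embedding backend (see [mockEmbedder()]).
#' @param germline germline segment vector, or `NULL` to force the
#'   CDR3-only path.
#' @return numeric matrix, `nchar(cdr3) x embedder$dim`.
#' @export
embedCdr3 <- function(cdr3, vGene, jGene, embedder, germline = NULL) {
  rec <- if (!is.null(germline)) reconstructFullTcr(cdr3, vGene, jGene, germline)
  m <- if (!is.null(rec)) {
    fullEmb <- embedder$embed(rec$full)
    fullEmb[(rec$span[1] + 1L):rec$span[2], , drop = FALSE]
  } else {
    embedder$embed(cdr3)
  }
  stopifnot(nrow(m) == nchar(cdr3))
  m
}

#' One-hot encode an amino-acid sequence
#'
#' @param seq amino-acid sequence over the canonical 20-letter alphabet.
#' @param alphabet column order (default: the 20 residues alphabetically).
#' @return numeric matrix `nchar(seq) x length(alphabet)`; each row has
#'   exactly one 1.
#' @export
oneHotSeq <- function(seq, alphabet = AA_ALPHABET) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) stop("character outside alphabet in: ", seq)
  m <- matrix(0, nrow = length(chars), ncol = length(alphabet))
  m[cbind(seq_along(chars), idx)] <- 1
  m
}

# Small content-addressed cache for [embedding||one-hot] blocks, keyed by
# (backend name, context genes, sequence).
newEmbedCache <- function() new.env(parent = emptyenv())

cdr3Block <- function(cdr3, vGene, jGene, embedder, germline, cache = NULL) {
  key <- paste(embedder$name, vGene %||% NA, jGene %||% NA, cdr3, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  block <- cbind(embedCdr3(cdr3, vGene, jGene, embedder, germline),
                 oneHotSeq(cdr3))
  if (!is.null(cache)) cache[[key]] <- block
  block
}

epitopeBlock <- function(epitope, embedder, cache = NULL) {
  key <- paste(embedder$name, "ep", epitope, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  block <- cbind(embedder$embed(epitope), oneHotSeq(epitope))
  if (!is.null(cache)) cache[[key]] <- block
  block
}

# Map a name to its vocabulary index; unseen names take the reserved
# unknown index g+1 so inference degrades gracefully.
vocabIndex <- function(name, vocab) {
  if (is.na(name)) return(NA_integer_)
  i <- vocab[name]
  if (is.na(i)) length(vocab) + 1L else unname(i)
}

#' Encode one record into padded numeric feature blocks
#'
#' Each available chain's CDR3 becomes an `l x e` block (contextual
#' embedding concatenated with the one-hot channels, zero-padded to the
#' maximum CDR3 length `l`), the epitope an `le x e` block, with
#' `e = embedder$dim + 20`. Gene and MHC names map to vocabulary indices
#' (the reserved unknown index for unseen names). Availability and true
#' lengths are carried alongside; padded rows are all zero.
#'
#' @param record one-row canonical record data.frame.
#' @param vocabs list with `gene` (from [geneVocab()]) and `mhc` (from
#'   [mhcVocab()]).
#' @param embedder embedding backend.
#' @param germline germline segment vector or `NULL`.
#' @param maxLens list `l` (max CDR3 length, default 25) and `le` (max
#'   epitope length, default 15); over-length sequences are rejected.
#' @param cache optional cache from `newEmbedCache()`.
#' @return an `EncodedExample`: list with `beta`, `alpha` (`l x e` matrices
#'   or `NULL`), `epitope` (`le x e`), `lens` (named true lengths), `genes`
#'   (named indices), `mhc` index, `hasBeta`, `hasAlpha`, `label`.
#' @export
encodeExample <- function(record, vocabs, embedder, germline = NULL,
                          maxLens = list(l = 25L, le = 15L), cache = NULL) {
  e <- embedder$dim + length(AA_ALPHABET)
  pad <- function(block, maxLen, what) {
    if (nrow(block) > maxLen)
      stop("over-length ", what, ": ", nrow(block), " > ", maxLen)
    out <- matrix(0, nrow = maxLen, ncol = e)
    out[seq_len(nrow(block)), ] <- block
    out
  }
  hasBeta <- !is.na(record$cdr3b)
  hasAlpha <- !is.na(record$cdr3a)
  stopifnot(hasBeta || hasAlpha)
  beta <- if (hasBeta)
    pad(cdr3Block(record$cdr3b, record$vb, record$jb, embedder, germline, cache),
        maxLens$l, "beta CDR3")
  alpha <- if (hasAlpha)
    pad(cdr3Block(record$cdr3a, record$va, record$ja, embedder, germline, cache),
        maxLens$l, "alpha CDR3")
  list(beta = beta, alpha = alpha,
       epitope = pad(epitopeBlock(record$epitope, embedder, cache),
                     maxLens$le, "epitope"),
       lens = c(beta = if (hasBeta) nchar(record$cdr3b) else 0L,
                alpha = if (hasAlpha) nchar(record$cdr3a) else 0L,
                epitope = nchar(record$epitope)),
       genes = c(bv = if (hasBeta) vocabIndex(record$vb, vocabs$gene$bv) else NA_integer_,
                 bj = if (hasBeta) vocabIndex(record$jb, vocabs$gene$bj) else NA_integer_,
                 av = if (hasAlpha) vocabIndex(record$va, vocabs$gene$av) else NA_integer_,
                 aj = if (hasAlpha) vocabIndex(record$ja, vocabs$gene$aj) else NA_integer_),
       mhc = vocabIndex(record$mhc, vocabs$mhc),
       hasBeta = hasBeta, hasAlpha = hasAlpha,
       label = as.integer(record$label))
}

#' Pack labelled records into dense batch arrays for the model
#'
#' Encodes every record (with a shared embedding cache) and packs the blocks
#' into the arrays the C++ forward/backward pass consumes: feature cubes
#' `l x e x n` for beta, alpha and epitope, integer vectors for lengths,
#' gene/MHC indices (0 where absent; the reserved unknown index is
#' `g + 1`), availability flags, labels and loss weights.
#'
#' @param recordsDf labelled canonical records.
#' @param dataset the [TcrDataset-class] supplying the vocabularies.
#' @param embedder embedding backend.
#' @param germline optional germline table.
#' @param maxLens as in [encodeExample()].
#' @param wPos loss weight for positives (the packed `weights`).
#' @param cache optional shared embedding cache.
#' @return list of packed arrays (`beta`, `alpha`, `epi` cubes; `lenB`,
#'   `lenA`, `lenE`, `bv`, `bj`, `av`, `aj`, `mhc`, `hasB`, `hasA`, `label`,
#'   `weight` vectors; `n`, `e` scalars).
#' @export
packExamples <- function(recordsDf, dataset, embedder, germline = NULL,
                         maxLens = list(l = 25L, le = 15L), wPos = 5,
                         cache = newEmbedCache()) {
  vocabs <- list(gene = geneVocab(dataset), mhc = mhcVocab(dataset))
  n <- nrow(recordsDf)
  e <- embedder$dim + length(AA_ALPHABET)
  beta <- array(0, dim = c(maxLens$l, e, n))
  alpha <- array(0, dim = c(maxLens$l, e, n))
  epi <- array(0, dim = c(maxLens$le, e, n))
  lenB <- lenA <- lenE <- bv <- bj <- av <- aj <- mhc <- integer(n)
  hasB <- hasA <- integer(n)
  label <- integer(n)
  for (i in seq_len(n)) {
    ex <- encodeExample(recordsDf[i, , drop = FALSE], vocabs, embedder,
                        germline, maxLens, cache)
    if (ex$hasBeta) beta[, , i] <- ex$beta
    if (ex$hasAlpha) alpha[, , i] <- ex$alpha
    epi[, , i] <- ex$epitope
    lenB[i] <- ex$lens[["beta"]]; lenA[i] <- ex$lens[["alpha"]]
    lenE[i] <- ex$lens[["epitope"]]
    bv[i] <- ex$genes[["bv"]] %|NA|% 0L; bj[i] <- ex$genes[["bj"]] %|NA|% 0L
    av[i] <- ex$genes[["av"]] %|NA|% 0L; aj[i] <- ex$genes[["aj"]] %|NA|% 0L
    mhc[i] <- ex$mhc %|NA|% 0L
    hasB[i] <- as.integer(ex$hasBeta); hasA[i] <- as.integer(ex$hasAlpha)
    label[i] <- ex$label
  }
  list(beta = beta, alpha = alpha, epi = epi,
       lenB = lenB, lenA = lenA, lenE = lenE,
       bv = bv, bj = bj, av = av, aj = aj, mhc = mhc,
       hasB = hasB, hasA = hasA, label = label,
       weight = ifelse(label == 1, wPos, 1), n = n, e = e)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
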