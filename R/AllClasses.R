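# Canonical record column order used everywhere a record table is read or
# written. Absent chains/fields are NA.
RECORD_COLUMNS <- c("cdr3b", "vb", "jb", "cdr3a", "va", "ja",
                    "epitope", "mhc", "label", "source_id")

#' TcrDataset: a cleaned TCR-epitope-MHC dataset
#'
#' Holds canonical records (one row per TCR-pMHC datapoint with a binary
#' label) together with dense gene and MHC vocabularies built from the
#' retained records. Vocabulary indices are assigned by lexicographic sort of
#' the unified names so that they are stable under record reordering.
#'
#' @slot records data.frame with columns `cdr3b, vb, jb, cdr3a, va, ja,
#'   epitope, mhc, label, source_id`; chain fields are NA when the chain is
#'   absent.
#' @slot geneVocab named list of four named integer vectors (`bv`, `bj`,
#'   `av`, `aj`) mapping unified gene names to dense 1..g indices.
#' @slot mhcVocab named integer vector mapping MHC allele strings (at their
#'   observed precision) to dense 1..g indices.
#' @slot variant character; which dataset variant was built (`"Dab_b"`,
#'   `"Dab"` or `"Dab_a_b"`).
#'
#' @seealso [buildDataset()]
#' @export
setClass("TcrDataset",
  representation(records = "data.frame",
                 geneVocab = "list",
                 mhcVocab = "integer",
                 variant = "character"))

setValidity("TcrDataset", function(object) {
  rec <- object@records
  msgs <- character(0)
  if (!all(RECORD_COLUMNS %in% names(rec)))
    msgs <- c(msgs, "records must contain the canonical columns")
  if (!all(c("bv", "bj", "av", "aj") %in% names(object@geneVocab)))
    msgs <- c(msgs, "geneVocab must have entries bv, bj, av, aj")
  for (nm in c("bv", "bj", "av", "aj")) {
    v <- object@geneVocab[[nm]]
    if (length(v) && !identical(sort(unname(v)), seq_along(v)))
      msgs <- c(msgs, sprintf("geneVocab$%s indices must be dense 1..g", nm))
  }
  col <- c(bv = "vb", bj = "jb", av = "va", aj = "ja")
  for (nm in names(col)) {
    seen <- unique(rec[[col[[nm]]]])
    seen <- seen[!is.na(seen)]
    if (!all(seen %in% names(object@geneVocab[[nm]])))
      msgs <- c(msgs, sprintf("geneVocab$%s does not cover all records", nm))
  }
  seenMhc <- unique(rec$mhc[!is.na(rec$mhc)])
  if (!all(seenMhc %in% names(object@mhcVocab)))
    msgs <- c(msgs, "mhcVocab does not cover all records")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TcrDataset number of records
#' @param x,object a `TcrDataset`.
#' @export
setMethod("length", "TcrDataset", function(x) nrow(x@records))

#' Accessors for TcrDataset
#'
#' @param x a [TcrDataset-class].
#' @return `records()` the canonical record data.frame; `geneVocab()` the
#'   list of gene-name vocabularies; `mhcVocab()` the MHC vocabulary;
#'   `datasetVariant()` the variant tag.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "TcrDataset", function(x) x@records)

#' @rdname records
#' @export
setGeneric("geneVocab", function(x) standardGeneric("geneVocab"))

#' @rdname records
#' @export
setMethod("geneVocab", "TcrDataset", function(x) x@geneVocab)

#' @rdname records
#' @export
setGeneric("mhcVocab", function(x) standardGeneric("mhcVocab"))

#' @rdname records
#' @export
setMethod("mhcVocab", "TcrDataset", function(x) x@mhcVocab)

#' @rdname records
#' @export
setGeneric("datasetVariant", function(x) standardGeneric("datasetVariant"))

#' @rdname records
#' @export
setMethod("datasetVariant", "TcrDataset", function(x) x@variant)

setMethod("show", "TcrDataset", function(object) {
  rec <- object@records
  cat(sprintf("TcrDataset (%s) with %d records\n", object@variant, nrow(rec)))
  cat(sprintf("  positives: %d, negatives: %d\n",
              sum(rec$label == 1), sum(rec$label == 0)))
  cat(sprintf("  epitopes: %d, MHC alleles: %d\n",
              length(unique(rec$epitope)), length(object@mhcVocab)))
  cat(sprintf("  gene vocab sizes: bV=%d bJ=%d aV=%d aJ=%d\n",
              length(object@geneVocab$bv), length(object@geneVocab$bj),
              length(object@geneVocab$av), length(object@geneVocab$aj)))
})

#' FoldSplit: one cross-validation fold with a task constraint
#'
#' Train/validation/test index sets into a [TcrDataset-class], carrying the
#' task (TPP1-TPP4) whose seen/unseen constraint the split satisfies.
#'
#' @slot task character, one of `"TPP1".."TPP4"`.
#' @slot foldIndex integer fold number (0-based).
#' @slot train,validation,test integer index vectors into the dataset,
#'   pairwise disjoint.
#' @slot seed integer seed the split was built from.
#' @slot tcrKeyDef character, `"strict"` (full six-field TCR identity) or
#'   `"cdr3b"` (beta CDR3 alone) -- the definition used for seen/unseen TCR
#'   bookkeeping.
#' @slot extraTrainEpitopes character; test epitopes absent from the train
#'   positives, for which extra train negatives must be generated to satisfy
#'   the TPP2 seen-epitope constraint.
#' @export
setClass("FoldSplit",
  representation(task = "character", foldIndex = "integer",
                 train = "integer", validation = "integer", test = "integer",
                 seed = "integer", tcrKeyDef = "character",
                 extraTrainEpitopes = "character"))

setValidity("FoldSplit", function(object) {
  msgs <- character(0)
  if (!object@task %in% c("TPP1", "TPP2", "TPP3", "TPP4"))
    msgs <- c(msgs, "task must be one of TPP1..TPP4")
  idx <- c(object@train, object@validation, object@test)
  if (anyDuplicated(idx))
    msgs <- c(msgs, "train/validation/test must be pairwise disjoint")
  if (!object@tcrKeyDef %in% c("strict", "cdr3b"))
    msgs <- c(msgs, "tcrKeyDef must be 'strict' or 'cdr3b'")
  if (length(msgs)) msgs else TRUE
})

#' Accessors for FoldSplit
#'
#' @param x a [FoldSplit-class].
#' @return the respective index vector or metadata field.
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))

#' @rdname trainIndices
#' @export
setMethod("trainIndices", "FoldSplit", function(x) x@train)

#' @rdname trainIndices
#' @export
setGeneric("valIndices", function(x) standardGeneric("valIndices"))

#' @rdname trainIndices
#' @export
setMethod("valIndices", "FoldSplit", function(x) x@validation)

#' @rdname trainIndices
#' @export
setGeneric("testIndices", function(x) standardGeneric("testIndices"))

#' @rdname trainIndices
#' @export
setMethod("testIndices", "FoldSplit", function(x) x@test)

#' @rdname trainIndices
#' @export
setGeneric("splitTask", function(x) standardGeneric("splitTask"))

#' @rdname trainIndices
#' @export
setMethod("splitTask", "FoldSplit", function(x) x@task)

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit %s fold %d (seed %d, key %s): train %d / val %d / test %d\n",
              object@task, object@foldIndex, object@seed, object@tcrKeyDef,
              length(object@train), length(object@validation), length(object@test)))
  if (length(object@extraTrainEpitopes))
    cat(sprintf("  %d test epitope(s) need extra train negatives\n",
                length(object@extraTrainEpitopes)))
})

#' TcrModel: the three-headed attention binding model
#'
#' Parameters and configuration of the convolution + multi-head attention
#' network with beta-only, alpha-only and paired output heads.
#'
#' @slot config list of architecture hyperparameters (see [modelConfig()]).
#' @slot params named list of numeric parameter matrices/vectors.
#' @slot dims list of input dimensions the model was built for (feature width
#'   `e`, max CDR3 length `l`, max epitope length `le`, vocabulary sizes).
#' @export
setClass("TcrModel",
  representation(config = "list", params = "list", dims = "list"))

#' @describeIn TcrModel total number of scalar parameters
#' @param object,x a `TcrModel`.
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname TcrModel-class
#' @export
setMethod("nParams", "TcrModel", function(x) sum(vapply(x@params, length, integer(1))))

#' @rdname TcrModel-class
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname TcrModel-class
#' @export
setMethod("modelParams", "TcrModel", function(x) x@params)

setMethod("show", "TcrModel", function(object) {
  cfg <- object@config
  cat(sprintf("TcrModel: conv %d ch (kernel %d), %d attention heads (width %d), %d parameters\n",
              cfg$channels, cfg$kernel, cfg$heads, cfg$channels, nParams(object)))
  cat(sprintf("  feature width e=%d, l=%d, le=%d; gene emb %d, MHC emb %d, MLP hidden %d\n",
              object@dims$e, object@dims$l, object@dims$le,
              cfg$geneDim, cfg$mhcDim, cfg$hidden))
})
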