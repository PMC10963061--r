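# Package-level cache for the gene reference table.
.tcrpairEnv <- new.env(parent = emptyenv())

#' Load the packaged TR gene reference table
#'
#' A curated, versioned subset of human TRAV/TRAJ/TRBV/TRBJ gene names with
#' IMGT-style functionality calls (`F`, `ORF`, `P`). Gene unification looks
#' names up here; names flagged `P` or `ORF` are rejected as nonfunctional.
#'
#' @param path optional path to an alternative table (same three-column
#'   schema: `locus`, `gene`, `functionality`).
#' @return data.frame with columns `locus`, `gene`, `functionality`.
#' @export
loadGeneReference <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.tcrpairEnv$geneRef)) return(.tcrpairEnv$geneRef)
    path <- system.file("extdata", "tcr_gene_reference.tsv", package = "tcrpair")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "gene", "functionality") %in% names(tab)))
  .tcrpairEnv$geneRef <- tab
  tab
}

# Best-effort normalizer applied before reference lookup: uppercase, strip
# whitespace, rewrite legacy TCRBV/TCRAV-style prefixes, drop leading zeros in
# the gene-number parts (TRBV05-01 -> TRBV5-1). Allele designators keep their
# zeros (*01 stays *01).
normalizeGeneName <- function(raw) {
  s <- toupper(gsub("\\s+", "", raw))
  s <- sub("^TCR([AB])([VJ])", "TR\\1\\2", s)
  star <- regexpr("*", s, fixed = TRUE)
  base <- ifelse(star > 0, substr(s, 1, star - 1), s)
  allele <- ifelse(star > 0, substring(s, star), "")
  base <- gsub("(?<=[VJ])0+(\\d)", "\\1", base, perl = TRUE)
  base <- gsub("-0+(\\d)", "-\\1", base)
  paste0(base, allele)
}

#' Unify a V/J gene name against the packaged reference
#'
#' Normalizes a raw gene name, looks it up in the packaged functionality
#' table, detects its precision level (family < gene < allele) and rejects
#' nonfunctional or unknown names.
#'
#' @param raw character scalar, the raw gene name.
#' @param locus one of `"TRAV"`, `"TRAJ"`, `"TRBV"`, `"TRBJ"`.
#' @param geneRef reference table (defaults to the packaged one).
#' @return a list with elements `unified` (canonical name or `NA`),
#'   `precision` (`"family"`, `"gene"`, `"allele"` or `NA`) and `reason`
#'   (`NA` on success, otherwise `"unknown gene"` or `"nonfunctional"`).
#' @examples
#' unifyGeneNotation("TRBV20-1*01", "TRBV")
#' unifyGeneNotation("TCRBV20-1", "TRBV")
#' unifyGeneNotation("TRBV1", "TRBV")   # pseudogene -> rejected
#' @export
unifyGeneNotation <- function(raw, locus = c("TRAV", "TRAJ", "TRBV", "TRBJ"),
                              geneRef = loadGeneReference()) {
  locus <- match.arg(locus)
  stopifnot(length(raw) == 1L)
  res <- unifyGenes(raw, locus, geneRef)
  list(unified = res$unified[1], precision = res$precision[1], reason = res$reason[1])
}

# Vectorized gene unification. NA input passes through as NA with no reason
# (absent field, not a rejection).
unifyGenes <- function(raw, locus, geneRef = loadGeneReference()) {
  tab <- geneRef[geneRef$locus == locus, ]
  n <- length(raw)
  out <- data.frame(unified = rep(NA_character_, n),
                    precision = rep(NA_character_, n),
                    reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  todo <- !is.na(raw) & nzchar(raw)
  if (!any(todo)) return(out)
  s <- normalizeGeneName(raw[todo])
  base <- sub("\\*.*$", "", s)
  hasAllele <- grepl("*", s, fixed = TRUE)
  hit <- match(base, tab$gene)
  unified <- rep(NA_character_, length(s))
  precision <- rep(NA_character_, length(s))
  reason <- rep(NA_character_, length(s))
  isGene <- !is.na(hit)
  func <- tab$functionality[hit]
  ok <- isGene & func == "F"
  unified[ok] <- s[ok]
  precision[ok] <- ifelse(hasAllele[ok], "allele", "gene")
  reason[isGene & func != "F"] <- "nonfunctional"
  # Family-level names: base matches a hyphenated prefix of known genes.
  fam <- !isGene
  if (any(fam)) {
    for (i in which(fam)) {
      members <- tab$gene[startsWith(tab$gene, paste0(base[i], "-"))]
      if (length(members) == 0L) {
        reason[i] <- "unknown gene"
      } else if (all(tab$functionality[match(members, tab$gene)] != "F")) {
        reason[i] <- "nonfunctional"
      } else {
        unified[i] <- base[i]    # allele on a family name is meaningless; drop it
        precision[i] <- "family"
      }
    }
  }
  out$unified[todo] <- unified
  out$precision[todo] <- precision
  out$reason[todo] <- reason
  out
}

#' Canonicalize a CDR3 amino-acid sequence
#'
#' CDR3 junctions are reported with or without their conserved anchor
#' residues. This repairs the anchors: a missing leading cysteine is
#' prepended and a missing trailing phenylalanine/tryptophan gets an `F`
#' appended. Sequences containing non-amino-acid characters, or shorter than
#' 5 residues after repair, are rejected (`NA`).
#'
#' @param seq character vector of CDR3 sequences.
#' @return character vector of canonical sequences (start `C`, end `F`/`W`),
#'   `NA` where rejected. Idempotent on canonical input.
#' @examples
#' canonicalizeCdr3(c("CASSLGQAYEQYF", "ASSLGQAYEQY", "CASSLGQW", "CAXSF"))
#' @export
canonicalizeCdr3 <- function(seq) {
  out <- rep(NA_character_, length(seq))
  ok <- isAaSeq(seq)
  s <- seq[ok]
  noC <- substr(s, 1, 1) != "C"
  s[noC] <- paste0("C", s[noC])
  lastChr <- substr(s, nchar(s), nchar(s))
  noFW <- !(lastChr %in% c("F", "W"))
  s[noFW] <- paste0(s[noFW], "F")
  s[nchar(s) < 5] <- NA_character_
  out[ok] <- s
  out
}

#' Filter records to MHC class I and human host
#'
#' Records whose `mhc_class` is not class I or whose `species` is not human
#' are removed; records with either field absent are dropped as well
#' (conservative: both filters apply). Removal counts are attached as the
#' `"counts"` attribute.
#'
#' @param raw data.frame of raw records carrying `mhc_class` and `species`.
#' @return the filtered data.frame.
#' @export
filterClassHost <- function(raw) {
  cls <- toupper(trimws(as.character(raw$mhc_class %||% rep(NA, nrow(raw)))))
  sp <- tolower(gsub("\\s+", "", as.character(raw$species %||% rep(NA, nrow(raw)))))
  okClass <- !is.na(cls) & cls %in% c("I", "1", "MHCI", "CLASS1", "CLASSI", "MHC CLASS I")
  okHost <- !is.na(sp) & sp %in% c("human", "homosapiens", "h.sapiens")
  out <- raw[okClass & okHost, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(input = nrow(raw),
                           removed_class = sum(!okClass),
                           removed_host = sum(okClass & !okHost),
                           kept = nrow(out))
  out
}

# Column maps for the supported input dialects. Each maps canonical field ->
# input column name.
DIALECT_COLUMNS <- list(
  generic = c(cdr3b = "cdr3b", vb = "vb", jb = "jb",
              cdr3a = "cdr3a", va = "va", ja = "ja",
              epitope = "epitope", mhc = "mhc", mhc_class = "mhc_class",
              species = "species", label = "label", source_id = "source_id"),
  vdjdb = c(complex_id = "complex.id", gene = "gene", cdr3 = "cdr3",
            v = "v.segm", j = "j.segm", epitope = "antigen.epitope",
            mhc = "mhc.a", mhc_class = "mhc.class", species = "species",
            source_id = "meta.subject.id"),
  iedb = c(cdr3a = "Chain 1 CDR3 Curated", va = "Chain 1 Curated V Gene",
           ja = "Chain 1 Curated J Gene", cdr3b = "Chain 2 CDR3 Curated",
           vb = "Chain 2 Curated V Gene", jb = "Chain 2 Curated J Gene",
           epitope = "Description", mhc = "MHC Allele Names",
           mhc_class = "MHC Class", species = "Host", source_id = "Receptor ID")
)

#' Parse a raw TCR-epitope-MHC table
#'
#' Reads a delimited text file (TSV or CSV, auto-detected; CRLF tolerated) in
#' one of three dialects and returns raw records in the canonical column
#' layout. `"generic"` expects canonical column names directly; `"vdjdb"`
#' expects VDJdb-export columns (one row per chain, alpha/beta rows paired via
#' `complex.id`); `"iedb"` expects IEDB receptor-export columns (one row per
#' receptor). Missing optional fields become `NA`; rows without an epitope are
#' skipped and counted.
#'
#' @param path file path.
#' @param dialect `"generic"`, `"vdjdb"` or `"iedb"`.
#' @param columns optional named character vector overriding the dialect's
#'   column map.
#' @return data.frame of raw records with the canonical columns plus
#'   `mhc_class` and `species`; attribute `"skipped"` counts dropped rows.
#' @export
parseRecords <- function(path, dialect = c("generic", "vdjdb", "iedb"),
                         columns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  map <- DIALECT_COLUMNS[[dialect]]
  if (!is.null(columns)) map[names(columns)] <- columns
  dt <- data.table::fread(path, sep = "auto", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  mandatory <- switch(dialect,
    generic = c("cdr3b", "epitope"),
    vdjdb = c("gene", "cdr3", "epitope"),
    iedb = c("cdr3b", "epitope"))
  missing <- setdiff(unname(map[mandatory]), names(dt))
  if (length(missing))
    stop("missing mandatory column(s) for dialect '", dialect, "': ",
         paste(missing, collapse = ", "))

  getcol <- function(field) {
    cn <- map[[field]]
    if (!is.null(cn) && cn %in% names(dt)) {
      v <- trimws(dt[[cn]])
      v[!nzchar(v)] <- NA_character_
      v
    } else rep(NA_character_, nrow(dt))
  }

  if (dialect == "vdjdb") {
    chain <- toupper(getcol("gene"))
    base <- data.frame(complex_id = getcol("complex_id"),
                       chain = chain, cdr3 = getcol("cdr3"),
                       v = getcol("v"), j = getcol("j"),
                       epitope = getcol("epitope"), mhc = getcol("mhc"),
                       mhc_class = getcol("mhc_class"), species = getcol("species"),
                       source_id = getcol("source_id"), stringsAsFactors = FALSE)
    base$mhc_class[base$mhc_class %in% c("MHCI", "MHCclass I")] <- "I"
    unpairedIdx <- which(is.na(base$complex_id) | base$complex_id == "0")
    paired <- base[setdiff(seq_len(nrow(base)), unpairedIdx), , drop = FALSE]
    rows <- list()
    mkrow <- function(brow, arow, pmhcRow, id) {
      data.frame(cdr3b = brow$cdr3 %||% NA_character_, vb = brow$v %||% NA_character_,
                 jb = brow$j %||% NA_character_,
                 cdr3a = arow$cdr3 %||% NA_character_, va = arow$v %||% NA_character_,
                 ja = arow$j %||% NA_character_,
                 epitope = pmhcRow$epitope, mhc = pmhcRow$mhc,
                 mhc_class = pmhcRow$mhc_class, species = pmhcRow$species,
                 label = "1", source_id = id, stringsAsFactors = FALSE)
    }
    none <- list(cdr3 = NA_character_, v = NA_character_, j = NA_character_)
    for (i in unpairedIdx) {
      r <- base[i, ]
      if (r$chain == "TRB") rows[[length(rows) + 1L]] <- mkrow(r, none, r, r$source_id)
      else rows[[length(rows) + 1L]] <- mkrow(none, r, r, r$source_id)
    }
    if (nrow(paired)) {
      for (cid in unique(paired$complex_id)) {
        grp <- paired[paired$complex_id == cid, ]
        b <- grp[grp$chain == "TRB", ][1, ]
        a <- grp[grp$chain == "TRA", ][1, ]
        pm <- grp[1, ]
        if (all(is.na(b))) b <- none
        if (all(is.na(a))) a <- none
        rows[[length(rows) + 1L]] <- mkrow(b, a, pm, cid)
      }
    }
    out <- do.call(rbind, rows)
  } else {
    out <- data.frame(cdr3b = getcol("cdr3b"), vb = getcol("vb"), jb = getcol("jb"),
                      cdr3a = getcol("cdr3a"), va = getcol("va"), ja = getcol("ja"),
                      epitope = getcol("epitope"), mhc = getcol("mhc"),
                      mhc_class = getcol("mhc_class"), species = getcol("species"),
                      label = getcol("label"), source_id = getcol("source_id"),
                      stringsAsFactors = FALSE)
  }
  out$label[is.na(out$label)] <- "1"   # database exports hold positives
  keep <- !is.na(out$epitope)
  skipped <- sum(!keep)
  if (skipped) message(skipped, " row(s) without an epitope skipped")
  out <- out[keep, , drop = FALSE]
  if (all(is.na(out$source_id)) && nrow(out))
    out$source_id <- sprintf("row%04d", seq_len(nrow(out)))
  out$label <- as.integer(out$label)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Precision-ancestry test for gene names: a is b at equal-or-lower precision.
geneAncestorOrEqual <- function(a, b) {
  bothNA <- is.na(a) & is.na(b)
  res <- bothNA | (!is.na(b) & is.na(a))     # absent info = lowest precision
  cmp <- !is.na(a) & !is.na(b)
  res[cmp] <- a[cmp] == b[cmp] |
    (startsWith(b[cmp], a[cmp]) &
       substr(b[cmp], nchar(a[cmp]) + 1, nchar(a[cmp]) + 1) %in% c("-", "*"))
  res
}

# Precision-ancestry for MHC strings: "HLA class 1" is below everything;
# otherwise prefix refinement at a '*' or ':' boundary.
mhcAncestorOrEqual <- function(a, b) {
  bothNA <- is.na(a) & is.na(b)
  res <- bothNA | (!is.na(b) & is.na(a))
  cmp <- !is.na(a) & !is.na(b)
  aClassOnly <- toupper(a) %in% c("HLA CLASS 1", "HLA CLASS I", "MHC CLASS I")
  res[cmp] <- a[cmp] == b[cmp] |
    (aClassOnly[cmp] & grepl("^HLA", b[cmp])) |
    (startsWith(b[cmp], a[cmp]) &
       substr(b[cmp], nchar(a[cmp]) + 1, nchar(a[cmp]) + 1) %in% c("*", ":"))
  res
}

#' Remove records that differ only in gene/MHC precision
#'
#' Among records identical in sequences and label but whose gene or MHC
#' fields sit on the same precision chain (e.g. `TRBV20-1` vs
#' `TRBV20-1*01`), only the most precise record(s) are kept. Two maximal
#' records that genuinely conflict (different alleles of the same gene) are
#' both kept: they are distinct datapoints. Exact duplicates collapse to one.
#'
#' @param recordsDf data.frame of canonical records.
#' @return the deduplicated data.frame (row order of survivors preserved).
#' @export
deduplicateByPrecision <- function(recordsDf) {
  if (!nrow(recordsDf)) return(recordsDf)
  key <- paste(recordsDf$cdr3b, recordsDf$cdr3a, recordsDf$epitope,
               recordsDf$label, sep = "\r")
  dominated <- logical(nrow(recordsDf))
  geneCols <- c("vb", "jb", "va", "ja")
  for (grp in split(seq_len(nrow(recordsDf)), key)) {
    if (length(grp) < 2L) next
    for (i in grp) for (j in grp) {
      if (i == j || dominated[i]) next
      allLe <- all(vapply(geneCols, function(cc)
        geneAncestorOrEqual(recordsDf[[cc]][i], recordsDf[[cc]][j]), logical(1))) &&
        mhcAncestorOrEqual(recordsDf$mhc[i], recordsDf$mhc[j])
      if (allLe) {
        identicalRec <- all(vapply(c(geneCols, "mhc"), function(cc)
          identical(recordsDf[[cc]][i], recordsDf[[cc]][j]), logical(1)))
        # strictly less precise, or an exact duplicate appearing later
        if (!identicalRec || i > j) dominated[i] <- TRUE
      }
    }
  }
  out <- recordsDf[!dominated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a TcrDataset for a chain-availability variant
#'
#' @param recordsDf preprocessed canonical records.
#' @param variant `"Dab_b"` keeps records with full beta information (alpha
#'   attached when available); `"Dab"` keeps only records with both chains
#'   complete; `"Dab_a_b"` additionally admits alpha-only records.
#' @return a [TcrDataset-class] with vocabularies built from the retained
#'   records (indices assigned by lexicographic sort of unified names).
#' @export
buildDataset <- function(recordsDf, variant = c("Dab_b", "Dab", "Dab_a_b")) {
  variant <- match.arg(variant)
  betaFull <- !is.na(recordsDf$cdr3b) & !is.na(recordsDf$vb) & !is.na(recordsDf$jb)
  alphaFull <- !is.na(recordsDf$cdr3a) & !is.na(recordsDf$va) & !is.na(recordsDf$ja)
  keep <- switch(variant,
    Dab_b = betaFull,
    Dab = betaFull & alphaFull,
    Dab_a_b = betaFull | alphaFull)
  if (!any(keep)) stop("no records satisfy variant ", variant)
  rec <- recordsDf[keep, RECORD_COLUMNS, drop = FALSE]
  # Alpha fields of Dab_b/Dab_a_b records missing any alpha component are
  # treated as absent chains entirely.
  partialAlpha <- !alphaFull[keep] & !is.na(rec$cdr3a)
  rec$cdr3a[partialAlpha] <- NA_character_
  rec$va[partialAlpha] <- NA_character_
  rec$ja[partialAlpha] <- NA_character_
  partialBeta <- !betaFull[keep] & !is.na(rec$cdr3b)
  rec$cdr3b[partialBeta] <- NA_character_
  rec$vb[partialBeta] <- NA_character_
  rec$jb[partialBeta] <- NA_character_
  rownames(rec) <- NULL
  mkVocab <- function(x) {
    nm <- sort(unique(x[!is.na(x)]))
    setNames(seq_along(nm), nm)
  }
  new("TcrDataset", records = rec,
      geneVocab = list(bv = mkVocab(rec$vb), bj = mkVocab(rec$jb),
                       av = mkVocab(rec$va), aj = mkVocab(rec$ja)),
      mhcVocab = mkVocab(rec$mhc),
      variant = variant)
}

#' Run the full preprocessing chain on raw records
#'
#' Applies, in order: class-I/human filtering, CDR3 canonicalization and gene
#' unification per chain (a chain whose CDR3 cannot be repaired or whose V/J
#' gene is rejected as unknown/nonfunctional is dropped as a whole; a record
#' is dropped when no chain survives or the epitope is invalid), precision
#' deduplication, and dataset assembly.
#'
#' @param raw data.frame from [parseRecords()].
#' @param variant dataset variant, see [buildDataset()].
#' @param geneRef gene reference table.
#' @return a [TcrDataset-class]; filter counts in attribute `"counts"`.
#' @export
preprocessRecords <- function(raw, variant = c("Dab_b", "Dab", "Dab_a_b"),
                              geneRef = loadGeneReference()) {
  variant <- match.arg(variant)
  counts <- c(input = nrow(raw))
  raw <- filterClassHost(raw)
  counts["after_class_host"] <- nrow(raw)

  betaCanon <- canonicalizeCdr3(raw$cdr3b)
  alphaCanon <- canonicalizeCdr3(raw$cdr3a)
  lostBeta <- !is.na(raw$cdr3b) & is.na(betaCanon)
  lostAlpha <- !is.na(raw$cdr3a) & is.na(alphaCanon)
  raw$cdr3b <- betaCanon
  raw$cdr3a <- alphaCanon

  for (spec in list(c("vb", "TRBV"), c("jb", "TRBJ"),
                    c("va", "TRAV"), c("ja", "TRAJ"))) {
    col <- spec[1]; locus <- spec[2]
    res <- unifyGenes(raw[[col]], locus, geneRef)
    bad <- !is.na(raw[[col]]) & is.na(res$unified)
    raw[[col]] <- res$unified
    if (col %in% c("va", "ja")) lostAlpha <- lostAlpha | bad
    else lostBeta <- lostBeta | bad
  }
  for (col in c("cdr3b", "vb", "jb")) raw[[col]][lostBeta] <- NA_character_
  for (col in c("cdr3a", "va", "ja")) raw[[col]][lostAlpha] <- NA_character_
  raw <- raw[isAaSeq(raw$epitope) &
               (!is.na(raw$cdr3b) | !is.na(raw$cdr3a)), , drop = FALSE]
  counts["after_canonical_genes"] <- nrow(raw)

  raw <- deduplicateByPrecision(raw)
  counts["after_dedup"] <- nrow(raw)

  ds <- buildDataset(raw, variant)
  counts["final"] <- length(ds)
  attr(ds, "counts") <- counts
  ds
}

#' Write a TcrDataset as TSV plus a JSON sidecar
#'
#' @param dataset a [TcrDataset-class].
#' @param path output TSV path; the sidecar (vocabularies, variant, counts)
#'   is written next to it as `<path>.json`.
#' @return invisibly, the TSV path.
#' @export
writeDataset <- function(dataset, path) {
  data.table::fwrite(records(dataset), path, sep = "\t", na = "NA", quote = FALSE)
  side <- list(variant = datasetVariant(dataset),
               n_records = length(dataset),
               gene_vocab = lapply(geneVocab(dataset), as.list),
               mhc_vocab = as.list(mhcVocab(dataset)),
               counts = as.list(attr(dataset, "counts") %||% list()))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a canonical dataset TSV back into a TcrDataset
#'
#' @param path TSV written by [writeDataset()] (the sidecar is not required;
#'   vocabularies are rebuilt from the records).
#' @param variant dataset variant to assemble.
#' @return a [TcrDataset-class].
#' @export
readDataset <- function(path, variant = c("Dab_b", "Dab", "Dab_a_b")) {
  rec <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  rec$label <- as.integer(rec$label)
  buildDataset(rec, match.arg(variant))
}
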