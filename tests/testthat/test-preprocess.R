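test_that("gene names are unified, precision detected, nonfunctional rejected", {
  cases <- list(
    list(raw = "TRBV20-1*01", locus = "TRBV", unified = "TRBV20-1*01",
         precision = "allele"),
    list(raw = "TRBV20-1", locus = "TRBV", unified = "TRBV20-1",
         precision = "gene"),
    list(raw = "TRBV20", locus = "TRBV", unified = "TRBV20",
         precision = "family"),
    list(raw = "tcrbv20-1", locus = "TRBV", unified = "TRBV20-1",
         precision = "gene"),
    list(raw = "TRBV05-01", locus = "TRBV", unified = "TRBV5-1",
         precision = "gene"),
    list(raw = "TRBV9", locus = "TRBV", unified = "TRBV9",
         precision = "gene"),
    list(raw = "TRAJ33", locus = "TRAJ", unified = "TRAJ33",
         precision = "gene"))
  for (cs in cases) {
    res <- unifyGeneNotation(cs$raw, cs$locus)
    expect_identical(res$unified, cs$unified, label = cs$raw)
    expect_identical(res$precision, cs$precision, label = cs$raw)
    expect_true(is.na(res$reason))
  }
  # pseudogenes / ORFs in the packaged functionality table are rejected
  ref <- loadGeneReference()
  pseudo <- ref[ref$functionality != "F", ]
  for (i in sample(nrow(pseudo), 5)) {
    res <- unifyGeneNotation(pseudo$gene[i], pseudo$locus[i])
    expect_identical(res$reason, "nonfunctional", label = pseudo$gene[i])
  }
  expect_identical(unifyGeneNotation("TRBV999", "TRBV")$reason, "unknown gene")
  # a family whose members are all pseudogenes is nonfunctional
  expect_identical(unifyGeneNotation("TRBV21", "TRBV")$reason, "nonfunctional")
})

test_that("CDR3 canonicalization repairs anchors and is idempotent", {
  expect_identical(canonicalizeCdr3("CASSLGQAYEQYF"), "CASSLGQAYEQYF")
  expect_identical(canonicalizeCdr3("ASSLGQAYEQY"), "CASSLGQAYEQYF")
  expect_identical(canonicalizeCdr3("CASSLGQW"), "CASSLGQW")
  expect_true(is.na(canonicalizeCdr3("CAXSF")))    # invalid letter
  expect_true(is.na(canonicalizeCdr3("AS")))       # too short after repair
  expect_true(is.na(canonicalizeCdr3("")))
  # idempotence on randomized accepted inputs
  set.seed(7)
  raw <- replicate(200, randomAaString(sample(3:18, 1)))
  once <- canonicalizeCdr3(raw)
  twice <- canonicalizeCdr3(once[!is.na(once)])
  expect_identical(twice, once[!is.na(once)])
  ok <- once[!is.na(once)]
  expect_true(all(substr(ok, 1, 1) == "C"))
  expect_true(all(substr(ok, nchar(ok), nchar(ok)) %in% c("F", "W")))
  expect_true(all(nchar(ok) >= 5))
})

test_that("class/host filter keeps only class-I human records", {
  raw <- data.frame(mhc_class = c("I", "II", "I", NA, "MHCI"),
                    species = c("human", "human", "mouse", "human", "HomoSapiens"),
                    x = 1:5)
  out <- filterClassHost(raw)
  expect_identical(out$x, c(1L, 5L))
  expect_identical(nrow(filterClassHost(raw[0, ])), 0L)
  # idempotence on all-passing input
  expect_identical(filterClassHost(out)$x, out$x)
})

test_that("precision deduplication keeps only maximal-precision records", {
  base <- toyRecords()[1, ]
  r1 <- base; r1$vb <- "TRBV20-1"
  r2 <- base; r2$vb <- "TRBV20-1*01"
  out <- deduplicateByPrecision(rbind(r1, r2))
  expect_identical(nrow(out), 1L)
  expect_identical(out$vb, "TRBV20-1*01")
  # family < gene < allele chain collapses to the allele record
  r0 <- base; r0$vb <- "TRBV20"
  out3 <- deduplicateByPrecision(rbind(r0, r1, r2))
  expect_identical(out3$vb, "TRBV20-1*01")
  # genuinely different records both kept (allele conflict = distinct datapoints)
  r3 <- base; r3$vb <- "TRBV20-1*02"
  expect_identical(nrow(deduplicateByPrecision(rbind(r2, r3))), 2L)
  # MHC precision chain
  m1 <- base; m1$mhc <- "HLA-A"
  m2 <- base; m2$mhc <- "HLA-A*02:01"
  expect_identical(deduplicateByPrecision(rbind(m1, m2))$mhc, "HLA-A*02:01")
  # exact duplicates collapse
  expect_identical(nrow(deduplicateByPrecision(rbind(base, base))), 1L)
})

test_that("deduplicated output has no precision-comparable pair (brute force)", {
  set.seed(11)
  base <- toyRecords()[1, ]
  variants <- c("TRBV20", "TRBV20-1", "TRBV20-1*01", "TRBV20-1*02",
                "TRBV19", "TRBV19*01")
  mhcs <- c("HLA class 1", "HLA-A", "HLA-A*02", "HLA-A*02:01")
  pool <- do.call(rbind, lapply(1:60, function(i) {
    r <- base
    r$vb <- sample(variants, 1)
    r$mhc <- sample(mhcs, 1)
    r$source_id <- sprintf("r%02d", i)
    r
  }))
  out <- deduplicateByPrecision(pool)
  anc <- tcrpair:::geneAncestorOrEqual
  ancM <- tcrpair:::mhcAncestorOrEqual
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i == j) next
    strictlyBelow <- anc(out$vb[i], out$vb[j]) && ancM(out$mhc[i], out$mhc[j]) &&
      !(out$vb[i] == out$vb[j] && out$mhc[i] == out$mhc[j])
    expect_false(strictlyBelow,
                 label = sprintf("%s/%s dominated by %s/%s",
                                 out$vb[i], out$mhc[i], out$vb[j], out$mhc[j]))
  }
})

test_that("dataset variants nest and vocabularies are dense, sorted, stable", {
  rec <- toyRecords()
  dsB <- buildDataset(rec, "Dab_b")
  dsAB <- buildDataset(rec, "Dab")
  dsAll <- buildDataset(rec, "Dab_a_b")
  expect_identical(length(dsB), 5L)     # beta-only + paired
  expect_identical(length(dsAB), 2L)    # paired only
  expect_identical(length(dsAll), 6L)
  key <- function(d) do.call(paste, records(d))
  expect_true(all(key(dsAB) %in% key(dsB)))
  expect_true(all(key(dsB) %in% key(dsAll)))
  for (v in geneVocab(dsAll)) {
    expect_identical(sort(unname(v)), seq_along(v))
    expect_identical(names(v), sort(names(v)))
  }
  # vocabulary indices stable under record reordering
  dsShuf <- buildDataset(rec[sample(nrow(rec)), ], "Dab_a_b")
  expect_identical(geneVocab(dsShuf), geneVocab(dsAll))
  expect_identical(mhcVocab(dsShuf), mhcVocab(dsAll))
  expect_error(buildDataset(rec[6, ], "Dab_b"), "no records satisfy")
})

test_that("generic TSV parsing preserves rows and tolerates CRLF", {
  tsv <- "cdr3b\tvb\tjb\tepitope\tmhc\nCASSF\tTRBV9\tTRBJ2-1\tGILGFVFTL\tHLA-A*02:01\nCASSY\tTRBV19\tTRBJ2-7\tNLVPMVATV\tHLA-B*07:02\nCASSW\tTRBV28\tTRBJ1-1\tGILGFVFTL\tHLA-A*02:01\n"
  fLf <- tempfile(fileext = ".tsv")
  writeLines(tsv, fLf, sep = "")
  fCrlf <- tempfile(fileext = ".tsv")
  writeLines(gsub("\n", "\r\n", tsv), fCrlf, sep = "")
  recLf <- parseRecords(fLf, "generic")
  recCrlf <- parseRecords(fCrlf, "generic")
  expect_identical(nrow(recLf), 3L)
  expect_identical(recLf[setdiff(names(recLf), "source_id")],
                   recCrlf[setdiff(names(recCrlf), "source_id")])
  expect_true(all(is.na(recLf$cdr3a)))
  expect_identical(recLf$label, rep(1L, 3))
  expect_error(parseRecords(fLf, "vdjdb"), "missing mandatory column")
})

test_that("vdjdb dialect pairs alpha/beta rows via complex.id", {
  txt <- paste(
    "complex.id\tgene\tcdr3\tv.segm\tj.segm\tspecies\tmhc.a\tmhc.class\tantigen.epitope",
    "0\tTRB\tCASSLGQAYEQYF\tTRBV20-1\tTRBJ2-7\tHomoSapiens\tHLA-A*02:01\tMHCI\tGILGFVFTL",
    "7\tTRB\tCASSPDRGEQFF\tTRBV19\tTRBJ2-1\tHomoSapiens\tHLA-A*02:01\tMHCI\tGILGFVFTL",
    "7\tTRA\tCAVRDSNYQLIW\tTRAV1-2\tTRAJ33\tHomoSapiens\tHLA-A*02:01\tMHCI\tGILGFVFTL",
    sep = "\n")
  f <- tempfile(fileext = ".tsv")
  writeLines(txt, f)
  rec <- parseRecords(f, "vdjdb")
  expect_identical(nrow(rec), 2L)
  paired <- rec[!is.na(rec$cdr3a) & !is.na(rec$cdr3b), ]
  expect_identical(nrow(paired), 1L)
  expect_identical(paired$cdr3b, "CASSPDRGEQFF")
  expect_identical(paired$cdr3a, "CAVRDSNYQLIW")
})

test_that("full preprocessing chain filters, canonicalizes and counts", {
  raw <- data.frame(
    cdr3b = c("ASSLGQAYEQY", "CASSPDRGEQFF", "CASSQETQYF", "CASSBADF"),
    vb = c("TRBV20-1", "TRBV1", "tcrbv9", "TRBV9"),
    jb = c("TRBJ2-7", "TRBJ2-1", "TRBJ2-5", "TRBJ2-5"),
    cdr3a = NA, va = NA, ja = NA,
    epitope = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "NLVPMVATV"),
    mhc = "HLA-A*02:01", mhc_class = "I",
    species = c("human", "human", "human", "mouse"),
    label = 1L, source_id = sprintf("r%d", 1:4), stringsAsFactors = FALSE)
  ds <- preprocessRecords(raw, "Dab_b")
  rec <- records(ds)
  # r1 repaired, r2 dropped (TRBV1 pseudogene), r3 normalized, r4 non-human
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$cdr3b[1], "CASSLGQAYEQYF")
  expect_identical(rec$vb[2], "TRBV9")
  counts <- attr(ds, "counts")
  expect_identical(unname(counts["input"]), 4L)
  expect_identical(unname(counts["final"]), 2L)
})

test_that("dataset TSV round trip preserves records", {
  ds <- toyDataset()
  f <- tempfile(fileext = ".tsv")
  writeDataset(ds, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- readDataset(f, "Dab_a_b")
  expect_identical(records(back), records(ds))
  expect_identical(geneVocab(back), geneVocab(ds))
})
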