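test_that("TPP3 fold assignment balances epitopes in frequency blocks", {
  counts <- setNames(100:81, sprintf("E%02d", 1:20))
  fa <- assignTpp3Folds(counts, seed = 1)
  expect_true(all(table(fa) == 2))                       # 2 per fold
  # each complete descending-frequency block contributes one epitope per fold
  o <- names(sort(-counts))
  expect_identical(sort(unname(fa[o[1:10]])), 0:9)
  expect_identical(sort(unname(fa[o[11:20]])), 0:9)
  # single block
  fa1 <- assignTpp3Folds(setNames(10:1, letters[1:10]), seed = 2)
  expect_true(all(table(fa1) == 1))
  # trailing partial block gets distinct labels
  fa2 <- assignTpp3Folds(setNames(23:1, sprintf("e%02d", 1:23)), seed = 3)
  tail3 <- fa2[names(sort(-setNames(23:1, sprintf("e%02d", 1:23))))[21:23]]
  expect_identical(anyDuplicated(tail3), 0L)
  # determinism
  expect_identical(fa, assignTpp3Folds(counts, seed = 1))
  expect_error(assignTpp3Folds(counts, nFolds = 10, block = 5),
               "unsupported configuration")
})

test_that("TPP3 fold epitope counts stay within one of E/nFolds", {
  set.seed(9)
  for (E in c(10, 17, 25, 53)) {
    counts <- setNames(sample(1:200, E), paste0("E", seq_len(E)))
    fa <- assignTpp3Folds(counts, seed = E)
    sizes <- table(factor(fa, levels = 0:9))
    expect_true(all(sizes %in% c(floor(E / 10), ceiling(E / 10))), label = E)
  }
})

test_that("TPP3 splits hold epitope disjointness and the test folds tile the data", {
  ds <- smallRepertoire()
  rec <- records(ds)
  counts <- table(rec$epitope)
  fa <- assignTpp3Folds(setNames(as.numeric(counts), names(counts)), seed = 5)
  allTest <- integer(0)
  for (f in 0:9) {
    sp <- makeTpp3Split(ds, fa, f, seed = 5)
    v <- validateSplit(sp, ds)
    expect_true(v$ok, label = paste("fold", f, paste(v$violations, collapse = ";")))
    expect_identical(sort(c(trainIndices(sp), valIndices(sp), testIndices(sp))),
                     seq_len(nrow(rec)))
    allTest <- c(allTest, testIndices(sp))
  }
  expect_identical(sort(allTest), seq_len(nrow(rec)))    # exact tiling
})

test_that("TPP3 validation modes behave as specified", {
  ds <- smallRepertoire()
  rec <- records(ds)
  counts <- table(rec$epitope)
  fa <- assignTpp3Folds(setNames(as.numeric(counts), names(counts)), seed = 5)
  spNone <- makeTpp3Split(ds, fa, 0, valFraction = 0, seed = 5)
  expect_identical(length(valIndices(spNone)), 0L)
  spEp <- makeTpp3Split(ds, fa, 0, valMode = "unseen_epitope",
                        valFraction = 0.15, seed = 5)
  expect_length(intersect(unique(rec$epitope[valIndices(spEp)]),
                          unique(rec$epitope[trainIndices(spEp)])), 0)
})

test_that("TPP2 splits separate TCR keys and book-keep uncovered epitopes", {
  ds <- smallRepertoire()
  for (f in 0:2) {
    sp <- makeTpp2Split(ds, foldIndex = f, seed = 4)
    v <- validateSplit(sp, ds)
    expect_true(v$ok, label = paste(v$violations, collapse = ";"))
  }
  # byte-identical regeneration under the same seed
  s1 <- makeTpp2Split(ds, foldIndex = 1, seed = 4)
  s2 <- makeTpp2Split(ds, foldIndex = 1, seed = 4)
  expect_identical(s1@train, s2@train)
  expect_identical(s1@test, s2@test)
  expect_identical(s1@validation, s2@validation)
})

test_that("strict and cdr3b TCR keys partition differently when CDR3b is shared", {
  base <- toyRecords()[1:2, ]
  # two TCRs sharing the beta CDR3 but differing in V
  base$cdr3b <- "CASSLGQAYEQYF"
  base$vb <- c("TRBV20-1", "TRBV19")
  base$epitope <- c("GILGFVFTL", "NLVPMVATV")
  keysStrict <- tcrKeys(base, "strict")
  keysB <- tcrKeys(base, "cdr3b")
  expect_identical(length(unique(keysStrict)), 2L)
  expect_identical(length(unique(keysB)), 1L)
})

test_that("TPP1 test pairs are unseen pairs of seen parts", {
  # on positives alone every TCR pairs with one epitope; shuffled negatives
  # make TCRs recur across epitopes, which populates TPP1
  pos <- smallRepertoire()
  lab <- buildPartition(records(pos), "any_part", 5, seed = 8)
  ds <- buildDataset(lab, "Dab_a_b")
  sp <- makeTpp1Split(ds, testFraction = 0.1, seed = 8)
  v <- validateSplit(sp, ds)
  expect_true(v$ok, label = paste(v$violations, collapse = ";"))
  # the validator detects a planted violation: move a test datapoint whose
  # pair also sits in train
  bad <- sp
  bad@train <- c(bad@train, bad@test[1])
  bad@test <- bad@test    # same pair now on both sides via duplicate epitope/TCR
  # simplest planted violation: a TPP3 split whose test epitope leaks to train
  rec <- records(ds)
  counts <- table(rec$epitope)
  fa <- assignTpp3Folds(setNames(as.numeric(counts), names(counts)), seed = 5)
  sp3 <- makeTpp3Split(ds, fa, 0, valFraction = 0, seed = 5)
  leak <- sp3
  leak@train <- sort(c(leak@train[-1], leak@test[1]))
  leak@test <- leak@test[-1]
  expect_false(validateSplit(leak, ds)$ok)
})

test_that("degenerate one-epitope-per-TCR data still yields valid TPP1 splits", {
  rec <- toyRecords()[1:4, ]
  rec$epitope <- "GILGFVFTL"            # one epitope, each TCR once
  ds <- buildDataset(rec, "Dab_b")
  # every TCR occurs once -> no datapoint can move to test
  expect_error(makeTpp1Split(ds, seed = 1), "infeasible")
})

test_that("distance restriction forces close epitopes into one fold", {
  eps <- c("AAAAAAAAA", "AAAAAAAAT", "TTTTTTTTT")
  counts <- setNames(c(30, 20, 10), eps)
  fa <- restrictFoldsByDistance(counts, minDist = 5, nFolds = 2, seed = 1)
  expect_identical(fa[["AAAAAAAAA"]], fa[["AAAAAAAAT"]])
  expect_false(fa[["AAAAAAAAA"]] == fa[["TTTTTTTTT"]])
  expect_error(restrictFoldsByDistance(counts[1:2], minDist = 9, nFolds = 2),
               "infeasible")
})

test_that("distance-restricted folds pass a brute-force cross-fold check", {
  set.seed(13)
  eps <- unique(replicate(60, randomAaString(9)))
  counts <- setNames(sample(1:50, length(eps), replace = TRUE), eps)
  fa <- restrictFoldsByDistance(counts, minDist = 5, nFolds = 10, seed = 2)
  d <- adist(eps, eps)
  for (i in seq_along(eps)) for (j in seq_len(i - 1)) {
    if (fa[[eps[i]]] != fa[[eps[j]]])
      expect_gte(d[i, j], 5)
  }
  # minDist = 1 is vacuous: all clusters are singletons
  fa1 <- restrictFoldsByDistance(counts, minDist = 1, nFolds = 10, seed = 2)
  expect_identical(length(unique(names(fa1))), length(eps))
})

test_that("low-frequency epitope exclusion respects side and boundary", {
  ds <- smallRepertoire()
  rec <- records(ds)
  counts <- table(rec$epitope[rec$label == 1])
  sp <- makeTpp2Split(ds, foldIndex = 0, seed = 4)
  cut <- as.integer(stats::median(counts))
  spTr <- excludeLowFrequencyEpitopes(ds, sp, minTcrs = cut, where = "train")
  low <- names(counts)[counts < cut]
  expect_length(intersect(unique(rec$epitope[trainIndices(spTr)]), low), 0)
  # test side untouched
  expect_identical(testIndices(spTr), testIndices(sp))
  # boundary: epitope with exactly minTcrs positives is retained
  boundary <- names(counts)[counts == cut]
  if (length(boundary))
    expect_true(any(rec$epitope[trainIndices(spTr)] %in% boundary))
  # minTcrs 0 is the identity
  sp0 <- excludeLowFrequencyEpitopes(ds, sp, minTcrs = 0, where = "both")
  expect_identical(trainIndices(sp0), trainIndices(sp))
  expect_identical(testIndices(sp0), testIndices(sp))
})

test_that("few-shot inclusion covers every screen positive exactly once", {
  ds <- smallRepertoire()
  trainRec <- records(ds)
  set.seed(21)
  screenEps <- replicate(26, randomAaString(9))
  screen <- do.call(rbind, lapply(seq_along(screenEps), function(i) {
    n <- sample(2:4, 1)
    data.frame(cdr3b = replicate(n, paste0("C", randomAaString(10), "F")),
               vb = "TRBV9", jb = "TRBJ2-1", cdr3a = NA, va = NA, ja = NA,
               epitope = screenEps[i], mhc = "HLA-B*27:05", label = 1L,
               source_id = sprintf("scr%d_%d", i, 1:n), stringsAsFactors = FALSE)
  }))
  res <- fewShotInclusionSplit(trainRec, screen, repeats = 10, ratio = 5, seed = 3)
  expect_length(res, 10)
  includedEps <- unlist(lapply(res, `[[`, "epitopes"))
  expect_identical(sort(includedEps), sort(screenEps))   # each epitope once
  for (r in res) {
    extra <- r$trainExtra
    pos <- extra[extra$label == 1, ]
    neg <- extra[extra$label == 0, ]
    expect_identical(nrow(neg), 5L * nrow(pos))          # stated ratio
    # test set = all screen rows not included this repeat
    expect_identical(sort(c(which(screen$epitope %in% r$epitopes), r$testIdx)),
                     seq_len(nrow(screen)))
    # negatives draw TCRs from the base training records
    expect_true(all(neg$cdr3b %in% trainRec$cdr3b))
  }
  # determinism
  res2 <- fewShotInclusionSplit(trainRec, screen, repeats = 10, ratio = 5, seed = 3)
  expect_identical(lapply(res, `[[`, "epitopes"), lapply(res2, `[[`, "epitopes"))
  expect_error(fewShotInclusionSplit(trainRec, screen, repeats = 30),
               "more repeats")
  expect_error(fewShotInclusionSplit(trainRec,
                                     transform(screen, epitope = trainRec$epitope[1]),
                                     repeats = 1), "disjoint")
})

test_that("TPP4 splits hold unseen-epitope constraint with seen-TCR bookkeeping", {
  ds <- smallRepertoire()
  sp <- makeTpp4Split(ds, foldIndex = 0, seed = 6)
  v <- validateSplit(sp, ds)
  expect_true(v$ok, label = paste(v$violations, collapse = ";"))
})

test_that("split JSON serialization captures indices and provenance", {
  ds <- smallRepertoire()
  sp <- makeTpp2Split(ds, foldIndex = 0, seed = 4)
  f <- tempfile(fileext = ".json")
  writeSplit(sp, ds, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$task, "TPP2")
  expect_identical(as.integer(back$train), trainIndices(sp))
  expect_true(is.numeric(back$dataset_checksum))
})
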