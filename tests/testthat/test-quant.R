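test_that("protein roll-up sums raw intensities with missing/zero semantics", {
  des <- toyDesign(conditions = "A", reps = 2, n_tt = 0, n_empty = 1)
  ints <- rbind(c(100, NA), c(250, 0))
  colnames(ints) <- c("ch1", "ch2")
  d <- toyPsmFrame(c("PEPA", "PEPB"), c("P1", "P1"), 1, intensities = ints)
  m <- rollupProtein(psmTable(d), des)
  expect_equal(assayScale(m), "raw")
  expect_equal(abundances(m)["P1", "A_R1"], 350)
  ## all contributors missing (NA and zero) -> missing
  expect_true(is.na(abundances(m)["P1", "A_R2"]))
  ## empty channels are excluded from the matrix
  expect_equal(ncol(m), 2)

  ## channel present in PSMs but absent from design is a validation error
  ints2 <- matrix(1, 1, 1, dimnames = list(NULL, "ch99"))
  d2 <- toyPsmFrame("PEPA", "P1", 1, intensities = ints2)
  expect_error(rollupProtein(psmTable(d2), des), "ch99")
})

test_that("site roll-up sums per site key; composite sites stay composite", {
  fasta <- c(P1 = "AAAACAAAAACAAAA")
  des <- toyDesign(conditions = "A", reps = 1, n_tt = 0, n_empty = 0)
  ints <- matrix(c(40, 60, 10), 3, 1, dimnames = list(NULL, "ch1"))
  d <- toyPsmFrame(c("AACAA", "ACAAA", "ACAAAAACAAA"),
                   c("P1", "P1", "P1"), c(3, 4, 4),
                   mods = c("nem@2", "nem@1", "nem@1;nem@7"),
                   intensities = ints)
  m <- rollupSite(psmTable(d, "redox"), des, "nem", fasta)
  x <- abundances(m)
  expect_equal(x["P1-C5", 1], 100)          # two peptides covering C5
  expect_equal(x["P1-C5C11", 1], 10)        # composite key only
  expect_equal(rownames(m), c("P1-C5", "P1-C5C11"))
  expect_equal(unname(rowData(m)$accession), c("P1", "P1"))
})

test_that("roll-up equals the brute-force accumulation oracle", {
  cfg <- simulationConfig(nProteins = 20, peptidesPerProtein = 5,
                          nSites = c(redox = 40), dropout = 0.15)
  tr <- generateTruth(cfg, seed = 42)
  g <- simulatePsmTables(tr, "global")$global   # 200 PSMs
  expect_equal(nrow(psmData(g)), 200)
  m <- rollupProtein(g, tr@design)
  oracle <- bruteForceRollup(psmData(g), designTable(tr@design),
                             psmData(g)$protein_accession)
  expect_identical(dim(abundances(m)), dim(oracle))
  expect_equal(abundances(m)[rownames(oracle), colnames(oracle)], oracle)

  r <- simulatePsmTables(tr, "redox")$redox
  ms <- rollupSite(r, tr@design, "nem", tr@sequences)
  keys <- mapToSites(r, tr@sequences, "nem")
  oracle_s <- bruteForceRollup(psmData(r), designTable(tr@design), keys)
  expect_equal(abundances(ms)[rownames(oracle_s), colnames(oracle_s)],
               oracle_s)
})

test_that("log2 transform maps the value grid and enforces scale state", {
  des <- toyDesign(conditions = "A", reps = 2, n_tt = 0, n_empty = 0)
  x <- matrix(c(8, 1, 2^5, 0), 2, 2,
              dimnames = list(c("f1", "f2"), c("A_R1", "A_R2")))
  m <- toyRawMatrix(x, conditions = "A")
  l <- log2Transform(m)
  expect_equal(abundances(l)["f1", "A_R1"], 3)
  expect_equal(abundances(l)["f2", "A_R1"], 0)
  expect_equal(abundances(l)["f1", "A_R2"], 5)
  expect_true(is.na(abundances(l)["f2", "A_R2"]))  # zero -> missing
  expect_equal(assayScale(l), "log2")
  expect_error(log2Transform(l), "state error")
})

test_that("median centering zeroes column medians and is idempotent", {
  x <- matrix(c(1, 2, 3, -1, 0, 1), 3, 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  m <- toyLogMatrix(x, conditions = c("A", "A"))
  c1 <- medianCenter(m)
  expect_equal(abundances(c1)[, "s1"], c(f1 = -1, f2 = 0, f3 = 1))
  expect_equal(abundances(c1)[, "s2"], c(f1 = -1, f2 = 0, f3 = 1))
  expect_equal(abundances(medianCenter(c1)), abundances(c1))

  set.seed(1)
  big <- matrix(rnorm(500 * 17), 500, 17,
                dimnames = list(paste0("f", 1:500), paste0("s", 1:17)))
  big[sample(length(big), 300)] <- NA
  mb <- medianCenter(toyLogMatrix(big, conditions = rep("A", 17)))
  meds <- apply(abundances(mb), 2, median, na.rm = TRUE)
  expect_lt(max(abs(meds)), 1e-9)
})

test_that("batch correction removes inter-batch mean shifts, preserves within-batch contrasts", {
  x <- matrix(c(4, 5, 6, 6, 7, 8), 1, 6,
              dimnames = list("f1", paste0("s", 1:6)))
  m <- toyLogMatrix(x, conditions = rep("A", 6),
                    batch = rep(c("B1", "B2"), each = 3))
  b <- batchCorrect(m)
  ## batch means 5 and 7, grand mean 6 -> +1 / -1
  expect_equal(abundances(b)[1, ], c(s1 = 5, s2 = 6, s3 = 7, s4 = 5,
                                     s5 = 6, s6 = 7))
  ## within-batch differences unchanged
  expect_equal(diff(abundances(b)[1, 1:3]), diff(x[1, 1:3]))
  ## idempotent
  expect_equal(abundances(batchCorrect(b)), abundances(b), tolerance = 1e-12)

  ## injected offsets are removed to < 1e-9 per feature
  set.seed(2)
  delta <- rnorm(2)
  big <- matrix(rnorm(200 * 8), 200, 8)
  dimnames(big) <- list(paste0("f", 1:200), paste0("s", 1:8))
  batches <- rep(c("B1", "B2"), each = 4)
  shifted <- big + matrix(delta[(batches == "B2") + 1], 200, 8, byrow = TRUE)
  bc <- batchCorrect(toyLogMatrix(shifted, conditions = rep("A", 8),
                                  batch = batches))
  y <- abundances(bc)
  bm_diff <- rowMeans(y[, 1:4]) - rowMeans(y[, 5:8])
  expect_lt(max(abs(bm_diff)), 1e-9)

  ## single-batch input is a warning no-op
  expect_warning(batchCorrect(toyLogMatrix(big, conditions = rep("A", 8))),
                 "single batch")
})

test_that("global-peptide scaling subtracts per-sample global medians", {
  site <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("P1-C5", "P2-C7"), c("s1", "s2")))
  glob <- matrix(c(0.5, 0.5, 0.5, 0, 0, 0), 3, 2,
                 dimnames = list(paste0("pep", 1:3), c("s1", "s2")))
  ms <- toyLogMatrix(site, conditions = c("A", "A"), modality = "redox")
  mg <- toyLogMatrix(glob, conditions = c("A", "A"))
  sc <- scaleToGlobal(ms, mg)
  expect_equal(abundances(sc)[, "s1"], site[, "s1"] - 0.5)
  expect_equal(abundances(sc)[, "s2"], site[, "s2"])  # median 0 -> unchanged
  expect_true(all(colData(sc)$global_scaled))
  expect_true("global-scaled" %in% processingLog(sc))

  ## sample missing from the global matrix passes through, tagged
  mg1 <- toyLogMatrix(glob[, 1, drop = FALSE], conditions = "A")
  sc1 <- scaleToGlobal(ms, mg1)
  expect_equal(abundances(sc1)[, "s2"], site[, "s2"])
  expect_equal(unname(colData(sc1)$global_scaled), c(TRUE, FALSE))

  ## a batch-corrected global matrix is rejected
  mg_bc <- mg
  metadata(mg_bc)$processing <- c(processingLog(mg_bc), "batch-corrected")
  expect_error(scaleToGlobal(ms, mg_bc), "not be batch corrected")

  ## injected channel loadings: site column medians return to ~0
  set.seed(3)
  lam <- rnorm(6, 0, 0.5)
  sitex <- matrix(rnorm(2000 * 6, sd = 0.5), 2000, 6) +
    matrix(lam, 2000, 6, byrow = TRUE)
  globx <- matrix(rnorm(3000 * 6, sd = 0.3), 3000, 6) +
    matrix(lam, 3000, 6, byrow = TRUE)
  dimnames(sitex) <- list(paste0("st", 1:2000), paste0("s", 1:6))
  dimnames(globx) <- list(paste0("pp", 1:3000), paste0("s", 1:6))
  sc2 <- scaleToGlobal(toyLogMatrix(sitex, rep("A", 6), modality = "phospho"),
                       toyLogMatrix(globx, rep("A", 6)))
  expect_lt(max(abs(apply(abundances(sc2), 2, median))), 0.05)
})

test_that("protein correction subtracts per-condition protein means with pass-through", {
  site <- matrix(c(5, 6, 7, 8), 1, 4,
                 dimnames = list("P1-C5", paste0("s", 1:4)))
  conds <- c("A", "A", "B", "B")
  ms <- toyLogMatrix(site, conds, modality = "redox",
                     processing = c("rollup", "log2", "global-scaled",
                                    "batch-corrected"))
  rowData(ms)$accession <- "P1"
  prot <- matrix(c(2, 2, 1, 1), 1, 4,
                 dimnames = list("P1", paste0("s", 1:4)))
  mp <- toyLogMatrix(prot, conds,
                     processing = c("rollup", "log2", "batch-corrected",
                                    "median-centered"))
  cc <- correctForProtein(ms, mp)
  expect_equal(abundances(cc)[1, ], c(s1 = 3, s2 = 4, s3 = 6, s4 = 7))
  expect_equal(rowData(cc)$uncorrected_conditions, "")

  ## protein missing in all condition-B samples -> B untouched, tagged
  prot_na <- prot; prot_na[1, 3:4] <- NA
  mp2 <- toyLogMatrix(prot_na, conds,
                      processing = c("rollup", "log2", "batch-corrected",
                                     "median-centered"))
  c2 <- correctForProtein(ms, mp2)
  expect_equal(abundances(c2)[1, ], c(s1 = 3, s2 = 4, s3 = 7, s4 = 8))
  expect_equal(rowData(c2)$uncorrected_conditions, "B")

  ## protein absent from the global matrix entirely -> all pass through
  rowData(ms)$accession <- "P9"
  c3 <- correctForProtein(ms, mp)
  expect_equal(abundances(c3)[1, ], site[1, ])
  expect_equal(rowData(c3)$uncorrected_conditions, "A,B")
})

test_that("normalization chain order is enforced through processing tags", {
  x <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  ms <- toyLogMatrix(x, c("A", "A"), modality = "phospho")
  rowData(ms)$accession <- c("P1", "P1")
  mp <- toyLogMatrix(x, c("A", "A"),
                     processing = c("rollup", "log2", "batch-corrected",
                                    "median-centered"))
  ## protein correction before scaling/batch correction is a state error
  expect_error(correctForProtein(ms, mp), "state error")
  ## scaling after batch correction is a state error
  ms_bc <- ms
  metadata(ms_bc)$processing <- c(processingLog(ms_bc), "batch-corrected")
  expect_error(scaleToGlobal(ms_bc, toyLogMatrix(x, c("A", "A"))),
               "state error")
  ## raw-scale operations reject log2 input and vice versa
  expect_error(medianCenter(toyRawMatrix(x, c("A", "A"))), "log2")
  expect_error(percentCV(ms), "raw")
})

test_that("the NA-per-condition filter reproduces a hand-enumerated drop list", {
  ## 10 features, 2 conditions x 4 replicates, hand-crafted NA patterns
  x <- matrix(1, 10, 8,
              dimnames = list(paste0("f", 1:10),
                              c(paste0("a", 1:4), paste0("b", 1:4))))
  x["f2", 1:3] <- NA            # 3 NA in A -> dropped
  x["f3", 1:2] <- NA            # exactly 2 NA in A -> retained
  x["f4", c(1, 2, 5, 6)] <- NA  # 2 + 2 -> retained
  x["f5", 5:8] <- NA            # 4 NA in B -> dropped
  x["f6", c(1, 2, 3, 5)] <- NA  # 3 in A -> dropped
  x["f7", 4] <- NA              # 1 NA -> retained
  x["f8", 5:7] <- NA            # 3 in B -> dropped
  x["f10", c(1:3, 5:7)] <- NA   # fails in both conditions -> dropped
  m <- toyLogMatrix(x, conditions = rep(c("A", "B"), each = 4))
  f <- filterMissing(m, maxNAPerCondition = 2)
  expect_setequal(metadata(f)$dropped_features,
                  c("f2", "f5", "f6", "f8", "f10"))
  expect_setequal(rownames(f), paste0("f", c(1, 3, 4, 7, 9)))
  ## relaxed scope: dropped only if every condition fails
  f2 <- filterMissing(m, maxNAPerCondition = 2, scope = "all")
  expect_setequal(metadata(f2)$dropped_features, "f10")
  ## under-replicated conditions raise a validation warning
  expect_warning(filterMissing(m[, 1:5], maxNAPerCondition = 2),
                 "fewer than 3 replicates")
})

test_that("abundance matrices round-trip through TSV + YAML sidecar", {
  des <- toyDesign(conditions = c("A", "B"), reps = 2, n_tt = 1, n_empty = 1)
  x <- matrix(rnorm(12), 3, 4)
  ann <- sampleAnnotation(des)[1:4, ]
  dimnames(x) <- list(paste0("f", 1:3), rownames(ann))
  m <- abundanceMatrix(x, ann, scale = "log2", modality = "phospho",
                       processing = c("rollup", "log2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAbundanceMatrix(m, path)
  m2 <- readAbundanceMatrix(path)
  expect_equal(abundances(m2), abundances(m))
  expect_equal(assayScale(m2), "log2")
  expect_equal(assayModality(m2), "phospho")
  expect_equal(processingLog(m2), processingLog(m))
  expect_equal(as.character(colData(m2)$condition),
               as.character(colData(m)$condition))
})
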