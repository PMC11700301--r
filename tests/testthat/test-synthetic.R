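noiseFreeConfig <- function(...) {
  simulationConfig(noiseSd = 0, channelLoadingSd = 0, batchOffsetSd = 0,
                   dropout = 0, qcFailRate = 0, labelingEfficiency = 1,
                   contaminantFraction = c(redox = 0, phospho = 0,
                                           acetyl = 0), ...)
}

test_that("truth generation is deterministic and bookkeeping exact", {
  cfg <- simulationConfig(nProteins = 60, nSites = c(redox = 30))
  t1 <- generateTruth(cfg, seed = 21)
  t2 <- generateTruth(cfg, seed = 21)
  expect_identical(t1@proteins, t2@proteins)
  expect_identical(t1@sites, t2@sites)
  expect_identical(t1@sequences, t2@sequences)
  p1 <- simulatePsmTables(t1)
  p2 <- simulatePsmTables(t2)
  expect_identical(lapply(p1, psmData), lapply(p2, psmData))
  ## different seed changes the draws
  expect_false(identical(t1@proteins$baseline,
                         generateTruth(cfg, seed = 22)@proteins$baseline))
  ## deterministic affected counts: 1000 proteins at 20% -> exactly 200
  big <- generateTruth(simulationConfig(nProteins = 1000,
                                        nSites = c(redox = 0),
                                        affectedFraction = 0.2), seed = 1)
  expect_equal(sum(big@proteins$effect != 0), 200)
  ## zero effect fraction -> all zero
  zero <- generateTruth(simulationConfig(nProteins = 50,
                                         nSites = c(phospho = 20),
                                         affectedFraction = 0), seed = 1)
  expect_true(all(zero@proteins$effect == 0))
  expect_true(all(zero@sites$phospho$effect == 0))
})

test_that("the generated design matches the stated layout and rejects overflow", {
  cfg <- simulationConfig()
  d <- designTable(makePlexDesign(cfg))
  expect_equal(nrow(d), 36)                       # 2 plexes x 18 channels
  expect_equal(sum(d$channel_role == "oxidation"), 24)   # 6 cond x 4 reps
  expect_equal(sum(d$channel_role == "total_thiol"), 6)  # singlets
  expect_equal(sum(d$channel_role == "empty"), 6)
  ## replicates balanced across plexes
  ox <- d[d$channel_role == "oxidation", ]
  expect_true(all(table(ox$condition, ox$plex_id) == 2))
  ## a design needing more channels than exist is a configuration error
  expect_error(makePlexDesign(simulationConfig(nReplicates = 20,
                                               nPlexes = 1)),
               "configuration error")
})

test_that("noise-free data recover effects, occupancies and stoichiometry exactly", {
  cfg <- noiseFreeConfig(nProteins = 40, peptidesPerProtein = 3,
                         nSites = c(redox = 30), affectedFraction = 0.25)
  tr <- generateTruth(cfg, seed = 23)
  tabs <- simulatePsmTables(tr)
  ## protein contrasts are exact after log2 + batch correction (median
  ## centering would add the condition-dependent column-median of the
  ## injected effects, which is an estimation property, not an error)
  prot <- batchCorrect(log2Transform(rollupProtein(tabs$global, tr@design)))
  de <- twoSampleTest(prot, "Cytokine_4h", "Control_4h")
  truth_fc <- tr@proteins$eff_Cytokine_4h[match(de$feature,
                                                tr@proteins$accession)]
  expect_equal(de$log2fc, truth_fc, tolerance = 1e-9)

  ## noise-free stoichiometry: percentOxidation returns the drawn s exactly
  site_raw <- rollupSite(tabs$redox, tr@design, "nem", tr@sequences)
  st <- percentOxidation(site_raw)
  truth <- tr@sites$redox
  st1 <- st[st$condition == "Cytokine_4h", ]
  i1 <- match(st1$site, truth$site)
  expect_equal(st1$pct_oxidation, truth$stoich_Cytokine_4h[i1],
               tolerance = 1e-9)
})

test_that("the full site chain recovers occupancy contrasts exactly without noise", {
  ## protein-level effects off: site intensity = protein abundance + occupancy
  cfg <- noiseFreeConfig(nProteins = 30, peptidesPerProtein = 3,
                         nSites = c(phospho = 60), affectedFraction = 0.5,
                         proteinEffectSize = 0, occupancyEffectSize = 1)
  tr <- generateTruth(cfg, seed = 26)
  tabs <- simulatePsmTables(tr)
  prot <- medianCenter(batchCorrect(log2Transform(
    rollupProtein(tabs$global, tr@design))))
  pep <- log2Transform(rollupPeptide(tabs$global, tr@design))
  site <- correctForProtein(batchCorrect(scaleToGlobal(
    log2Transform(rollupSite(tabs$phospho, tr@design, "phospho",
                             tr@sequences)), pep)), prot)
  expect_equal(processingLog(site),
               c("rollup", "log2", "global-scaled", "batch-corrected",
                 "protein-corrected"))
  de <- twoSampleTest(site, "Cytokine_4h", "Control_4h")
  truth <- tr@sites$phospho
  occ <- truth$occ_Cytokine_4h[match(de$feature, truth$site)]
  expect_equal(de$log2fc, occ, tolerance = 1e-9)
})

test_that("injected batch offsets appear as inter-plex shifts and are removed", {
  cfg <- noiseFreeConfig(nProteins = 30, peptidesPerProtein = 2,
                         nSites = c(redox = 0), affectedFraction = 0)
  cfg$batchOffsetSd <- 1
  tr <- generateTruth(cfg, seed = 24)
  delta <- tr@plexes$delta
  m <- log2Transform(rollupProtein(simulatePsmTables(tr, "global")$global,
                                   tr@design))
  cd <- as.data.frame(colData(m))
  x <- abundances(m)
  shift <- rowMeans(x[, cd$batch == "B1"]) - rowMeans(x[, cd$batch == "B2"])
  expect_equal(unname(shift), rep(delta[1] - delta[2], nrow(x)),
               tolerance = 1e-9)
  bc <- batchCorrect(m)
  y <- abundances(bc)
  resid <- rowMeans(y[, cd$batch == "B1"]) - rowMeans(y[, cd$batch == "B2"])
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("the full chain recovers injected protein effects under noise", {
  ## generator defaults (4 peptides/protein, 10% identification dropout)
  ## at the stated noise and replication
  cfg <- simulationConfig(nProteins = 2000, nSites = c(redox = 0),
                          affectedFraction = 0.2, noiseSd = 0.25)
  tr <- generateTruth(cfg, seed = 25)
  g <- filterPsms(simulatePsmTables(tr, "global")$global)
  prot <- medianCenter(batchCorrect(log2Transform(rollupProtein(g,
                                                                tr@design))))
  de <- twoSampleTest(subsetByRole(prot), "Cytokine_4h", "Control_4h")
  truth_fc <- tr@proteins$eff_Cytokine_4h[match(de$feature,
                                                tr@proteins$accession)]
  ok <- !is.na(de$log2fc)
  expect_lte(median(abs(de$log2fc - truth_fc)[ok]), 0.1)
  ## DE recall at |effect| = 1 under the standard cutoffs
  affected <- tr@proteins$accession[tr@proteins$effect != 0]
  hits <- deSignificant(de)
  expect_gte(length(intersect(hits, affected)) / length(affected), 0.9)
})

test_that("toy structure writing closes the loop with the structure module", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeToyStructure(c(1, 2), c("C", "K"), rbind(c(0, 0, 0), c(3, 4, 0)),
                    c(90, 50), path)
  m <- readStructure(path)
  expect_equal(distances(siteDistanceMatrix(m, c("C1", "K2")))["C1", "K2"],
               5.0)
  expect_equal(unname(flagLowConfidence(m, c("C1", "K2"), 70)),
               c(FALSE, TRUE))
})
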