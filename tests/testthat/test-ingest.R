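test_that("plex designs parse, validate and reject inconsistencies", {
  ## 18-channel plex: 13 oxidation, 4 total thiol, 1 empty
  df <- toyDesignFrame(conditions = c("A", "B", "C", "D", "E", "F", "G"),
                       reps = 2, n_tt = 4, n_empty = 1)
  df <- df[-1, ]  # 13 oxidation rows
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- readPlexDesign(path)
  tab <- designTable(d)
  expect_equal(nrow(tab), 18)
  expect_equal(sum(tab$channel_role != "empty"), 17)
  expect_equal(sum(tab$channel_role == "empty"), 1)

  dup <- rbind(df, df[1, ])
  expect_error(plexDesign(dup), "duplicate \\(plex, channel\\)")

  bad <- df
  bad$sample_id[bad$channel_role == "empty"] <- "oops"
  expect_error(plexDesign(bad), "empty channels")

  utils::write.table(df[, -1], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readPlexDesign(path), "plex_id")

  two <- rbind(toyDesignFrame(plex = "P1", batch = "B1"),
               toyDesignFrame(conditions = c("C", "D"), plex = "P2",
                              batch = "B2"))
  d2 <- plexDesign(two)
  expect_equal(sort(unique(designTable(d2)$batch)), c("B1", "B2"))
})

test_that("modification registry holds the search masses and the acetyl delta", {
  reg <- defaultModRegistry()
  expect_equal(modMass(reg, "oxidation"), 15.9949)
  expect_equal(modMass(reg, "nem"), 125.047679)
  expect_equal(modMass(reg, "phospho"), 79.9663)
  expect_equal(modMass(reg, "tmt"), 304.207146)
  expect_equal(acetylDeltaVsFixedTMT(reg), -262.196586)
  ## identity: a mod with the TMT mass has zero delta
  reg@entries$delta_mass[reg@entries$name == "acetyl"] <- 304.207146
  expect_equal(acetylDeltaVsFixedTMT(reg), 0)
  ## hypothetical phospho-vs-TMT delta, hand subtraction
  expect_equal(modMass(defaultModRegistry(), "phospho") -
                 modMass(defaultModRegistry(), "tmt"), -224.240846)
  expect_error(modMass(reg, "nosuch"), "not found")
})

test_that("PSM filtering applies inclusive ppm and strict PepQ bounds", {
  d <- toyPsmFrame(peptides = c("PEPA", "PEPB", "PEPC", "PEPD"),
                   proteins = "P1", starts = 1,
                   intensities = matrix(100, 4, 1,
                                        dimnames = list(NULL, "ch1")),
                   ppm = c(3, -9.9, 10.1, 10), pepq = c(0.001, 0.001,
                                                        0.001, 0.01))
  p <- psmTable(d)
  f <- filterPsms(p)
  expect_equal(psmData(f)$peptide, c("PEPA", "PEPB"))  # 10.1 ppm out
  expect_equal(nFiltered(f), 2L)                       # pepq == 0.01 out too
  ## ppm exactly 10 with passing pepq is retained (inclusive bound)
  d$pepq <- 0.001
  expect_true("PEPD" %in% psmData(filterPsms(psmTable(d)))$peptide)
  ## idempotence
  f2 <- filterPsms(f)
  expect_identical(psmData(f2), psmData(f))
})

test_that("injected quality failures are removed exactly, and only they", {
  cfg <- simulationConfig(nProteins = 100, peptidesPerProtein = 5,
                          nSites = c(redox = 0), qcFailRate = 0.05)
  tr <- generateTruth(cfg, seed = 11)
  g <- simulatePsmTables(tr, "global")$global
  expect_gte(nrow(psmData(g)), 1000)
  f <- filterPsms(g)
  expect_identical(nFiltered(f), sum(psmData(g)$qc_fail))
  expect_false(any(psmData(f)$qc_fail))
})

test_that("peptide modifications map to verified protein site ids", {
  fasta <- c(P12345 = "MMMMMMMMMACDEKGGGGG")
  d <- toyPsmFrame("ACDEK", "P12345", starts = 10, mods = "nem@1",
                   intensities = matrix(1, 1, 1,
                                        dimnames = list(NULL, "ch1")))
  expect_equal(mapToSites(psmTable(d), fasta, "nem"), "P12345-C11")

  ## composite key lists both positions ascending
  fasta2 <- c(P2 = "AASATAAAAA")
  d2 <- toyPsmFrame("ASATA", "P2", starts = 2,
                    mods = "phospho@3;phospho@1",
                    intensities = matrix(1, 1, 1,
                                         dimnames = list(NULL, "ch1")))
  expect_equal(mapToSites(psmTable(d2), fasta2, "phospho"), "P2-S3T5")

  ## PSMs without the target mod return NA
  expect_true(is.na(mapToSites(psmTable(d), fasta, "phospho")))

  ## peptide/FASTA mismatch is a mapping error naming the accession
  d3 <- toyPsmFrame("ACDEK", "P12345", starts = 2, mods = "nem@1",
                    intensities = matrix(1, 1, 1,
                                         dimnames = list(NULL, "ch1")))
  expect_error(mapToSites(psmTable(d3), fasta, "nem"), "P12345")
})

test_that("every mapped residue letter matches the FASTA on a synthetic digest", {
  cfg <- simulationConfig(nProteins = 50, peptidesPerProtein = 2,
                          nSites = c(redox = 100, phospho = 100))
  tr <- generateTruth(cfg, seed = 5)
  fa <- tr@sequences
  for (mod in c("redox", "phospho")) {
    tab <- simulatePsmTables(tr, mod)[[mod]]
    target <- if (mod == "redox") "nem" else "phospho"
    ids <- mapToSites(tab, fa, target)
    info <- parseSiteIds(ids[!is.na(ids)])
    for (i in seq_len(nrow(info))) {
      pos <- info$positions[[i]]
      expect_equal(unlist(info$residues[[i]]),
                   substring(fa[[info$accession[i]]], pos, pos),
                   ignore_attr = TRUE)
    }
  }
})

test_that("labeling efficiency counts labelable K and N-term positions", {
  ## 2 peptides: 3 labelable positions (2 nt + 1 K), 2 labeled
  d <- toyPsmFrame(c("AAKAA", "AAAAA"), "P1", 1,
                   mods = c("tmt@nt;tmt@2", ""),
                   intensities = matrix(1, 2, 1,
                                        dimnames = list(NULL, "ch1")))
  expect_equal(labelingEfficiency(psmTable(d)), 2 / 3)
  d$mods <- c("tmt@nt;tmt@2", "tmt@nt")
  expect_equal(labelingEfficiency(psmTable(d)), 1.0)
  expect_error(labelingEfficiency(psmTable(d[0, ])), "empty")

  ## generator truth: 97% labeling recovered within binomial error
  cfg <- simulationConfig(nProteins = 200, peptidesPerProtein = 5,
                          nSites = c(redox = 0), labelingEfficiency = 0.97)
  g <- simulatePsmTables(generateTruth(cfg, seed = 3), "global")$global
  eff <- labelingEfficiency(g)
  n_pos <- sum(vapply(gregexpr("K", psmData(g)$peptide),
                      function(x) sum(x > 0), 0L)) + nrow(psmData(g))
  expect_lt(abs(eff - 0.97), 4 * sqrt(0.97 * 0.03 / n_pos))

  ## invariance under row permutation
  perm <- psmTable(psmData(g)[sample(nrow(psmData(g))), ])
  expect_equal(labelingEfficiency(perm), eff)
})

test_that("enrichment selectivity is the fraction of target-bearing identifications", {
  peps <- c(sprintf("AAC%02dAA", 1:90), sprintf("AAA%02dAA", 1:10))
  d <- toyPsmFrame(peps, "P1", 1,
                   intensities = matrix(1, 100, 1,
                                        dimnames = list(NULL, "ch1")))
  p <- psmTable(d, "redox")
  expect_equal(enrichmentSelectivity(p, "cysteine"), 0.90)
  ## duplicated PSMs of the same peptide do not change the peptide-level value
  p2 <- psmTable(rbind(d, d[1:5, ]), "redox")
  expect_equal(enrichmentSelectivity(p2, "cysteine"), 0.90)
  expect_equal(enrichmentSelectivity(p2, "cysteine", unit = "psms"),
               95 / 105)
  d$mods <- "phospho@2"
  expect_equal(enrichmentSelectivity(psmTable(d), "phospho"), 1.0)
  expect_error(enrichmentSelectivity(psmTable(d[0, ]), "phospho"), "empty")

  ## generator truth: 8% non-Cys contaminants -> selectivity ~ 0.92
  cfg <- simulationConfig(nProteins = 100, nSites = c(redox = 500),
                          contaminantFraction = c(redox = 500 / 4600))
  tab <- simulatePsmTables(generateTruth(cfg, seed = 9), "redox")$redox
  sel <- enrichmentSelectivity(tab, "cysteine")
  expect_equal(sel, 500 / (500 + round(500 * 500 / 4600)),
               tolerance = 0.005)
})
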