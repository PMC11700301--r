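TMT18_CHANNELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                    "130N", "130C", "131N", "131C", "132N", "132C", "133N",
                    "133C", "134N", "134C", "135N")

#' Configuration for the synthetic multi-PTM experiment generator
#'
#' Defaults mirror the timecourse design emulated by the package: two TMT18
#' plexes; conditions Control/Cytokine at 4, 8 and 24 h; thiol-oxidation
#' samples in quadruplicate balanced across plexes; one total-thiol singlet
#' per condition; remaining channels empty. Intensities follow
#' `2^(baseline + condition effect + occupancy effect + lambda_channel +
#' delta_plex + epsilon)` with `epsilon ~ N(0, noiseSd^2)` on the log2
#' scale; redox oxidation channels scale the total-thiol level by the
#' site's stoichiometry s/100.
#'
#' @param nProteins number of proteins.
#' @param peptidesPerProtein global peptides simulated per protein.
#' @param nSites named integer vector of PTM site counts per modality
#'   (`redox`, `phospho`, `acetyl`; omit a name to skip that modality).
#' @param conditions condition labels (`<group>_<timepoint>`).
#' @param treatedPattern regex marking conditions that receive effects.
#' @param nReplicates oxidation-sample replicates per condition.
#' @param nPlexes number of TMT plexes (= batches).
#' @param affectedFraction fraction of features carrying a nonzero effect
#'   (deterministic count, alternating sign).
#' @param proteinEffectSize,occupancyEffectSize absolute log2FC injected
#'   into affected proteins / PTM-site occupancies in treated conditions.
#' @param redoxEffectSize absolute log2 fold change of stoichiometry for
#'   affected cysteine sites (capped at 100%).
#' @param oxidationLevels baseline stoichiometries (%) sampled per site.
#' @param baselineMean,baselineSd log2 protein baseline distribution.
#' @param siteOffsetSd,peptideOffsetSd log2 sd of per-site / per-peptide
#'   ionization offsets.
#' @param channelLoadingSd log2 sd of per-channel loading factors lambda.
#' @param batchOffsetSd log2 sd of per-plex batch offsets delta.
#' @param noiseSd log2 sd of measurement noise epsilon (0.25 ~ 19% CV).
#' @param dropout missing-at-random identification dropout: the probability
#'   that a peptide species is not observed in a given plex (all of that
#'   plex's channels become missing together, as in data-dependent
#'   acquisition).
#' @param qcFailRate fraction of PSMs given failing quality fields.
#' @param labelingEfficiency probability a labelable position carries TMT.
#' @param contaminantFraction named vector: non-target contaminant PSMs as
#'   a fraction of target PSMs per enriched modality.
#' @param proteinLength length of simulated protein sequences.
#' @return a named list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nProteins = 500,
                             peptidesPerProtein = 4,
                             nSites = c(redox = 800, phospho = 800,
                                        acetyl = 200),
                             conditions = paste(rep(c("Control", "Cytokine"),
                                                    each = 3),
                                                c("4h", "8h", "24h"),
                                                sep = "_"),
                             treatedPattern = "^Cytokine",
                             nReplicates = 4, nPlexes = 2,
                             affectedFraction = 0.2,
                             proteinEffectSize = 1,
                             occupancyEffectSize = 1,
                             redoxEffectSize = 1,
                             oxidationLevels = c(5, 25, 50, 75, 95),
                             baselineMean = 20, baselineSd = 1.5,
                             siteOffsetSd = 1, peptideOffsetSd = 1,
                             channelLoadingSd = 0.3, batchOffsetSd = 0.5,
                             noiseSd = 0.25, dropout = 0.1,
                             qcFailRate = 0.05,
                             labelingEfficiency = 0.993,
                             contaminantFraction = c(redox = 0.086,
                                                     phospho = 0.132,
                                                     acetyl = 0.1),
                             proteinLength = 300) {
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Build the plex design implied by a simulation configuration
#'
#' Oxidation replicates of each condition are balanced across plexes
#' (replicate r goes to plex `((r-1) mod nPlexes) + 1`); total-thiol
#' singlets are distributed round-robin; leftover channels are empty.
#'
#' @param config a [simulationConfig()].
#' @return a [PlexDesign-class].
#' @export
makePlexDesign <- function(config) {
  nP <- config$nPlexes
  rows <- list()
  for (cc in config$conditions)
    for (r in seq_len(config$nReplicates))
      rows[[length(rows) + 1]] <- data.frame(
        plex = (r - 1) %% nP + 1, sample_id = sprintf("%s_R%d", cc, r),
        condition = cc, replicate = r, channel_role = "oxidation",
        stringsAsFactors = FALSE)
  for (i in seq_along(config$conditions))
    rows[[length(rows) + 1]] <- data.frame(
      plex = (i - 1) %% nP + 1,
      sample_id = sprintf("TT_%s", config$conditions[i]),
      condition = config$conditions[i], replicate = 1L,
      channel_role = "total_thiol", stringsAsFactors = FALSE)
  samples <- do.call(rbind, rows)
  out <- list()
  for (p in seq_len(nP)) {
    sp <- samples[samples$plex == p, , drop = FALSE]
    if (nrow(sp) > length(TMT18_CHANNELS))
      stop(sprintf(
        "configuration error: plex %d needs %d channels but only %d exist",
        p, nrow(sp), length(TMT18_CHANNELS)))
    n_empty <- length(TMT18_CHANNELS) - nrow(sp)
    out[[p]] <- data.frame(
      plex_id = sprintf("P%d", p),
      channel_id = TMT18_CHANNELS,
      sample_id = c(sp$sample_id, rep("", n_empty)),
      condition = c(sp$condition, rep("", n_empty)),
      timepoint = c(sub("^.*_", "", sp$condition), rep("", n_empty)),
      replicate = c(sp$replicate, rep(NA_integer_, n_empty)),
      channel_role = c(sp$channel_role, rep("empty", n_empty)),
      batch = sprintf("B%d", p),
      stringsAsFactors = FALSE)
  }
  plexDesign(do.call(rbind, out))
}

AA_ALPHABET <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P",
                 "Q", "R", "V", "W")  # site letters (C/K/M/S/T/Y) planted

#' Draw the ground truth of a synthetic experiment
#'
#' All randomness flows from `seed`; each modality consumes its own seed
#' stream (fixed offsets from `seed`), so adding a modality does not
#' perturb the draws of the others. The affected-feature count is
#' deterministic (`round(affectedFraction * n)`, alternating sign), and
#' repeated calls with the same seed are identical.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @return a [SyntheticTruth-class].
#' @export
generateTruth <- function(config, seed = 1) {
  design <- makePlexDesign(config)
  conds <- config$conditions
  treated <- grepl(config$treatedPattern, conds)

  set.seed(seed)
  L <- config$proteinLength
  acc <- sprintf("SYNP%04d", seq_len(config$nProteins))
  seqs <- vapply(acc, function(a)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")

  set.seed(seed + 1L)
  n_aff <- round(config$affectedFraction * config$nProteins)
  signs <- rep_len(c(1, -1), n_aff)
  prot_eff <- c(signs * config$proteinEffectSize,
                rep(0, config$nProteins - n_aff))
  proteins <- data.frame(accession = acc,
                         baseline = stats::rnorm(config$nProteins,
                                                 config$baselineMean,
                                                 config$baselineSd),
                         n_peptides = config$peptidesPerProtein,
                         effect = prot_eff, stringsAsFactors = FALSE)
  for (i in seq_along(conds))
    proteins[[paste0("eff_", conds[i])]] <- if (treated[i]) prot_eff else 0

  site_letters <- list(redox = "C", phospho = c("S", "T", "Y"), acetyl = "K")
  mod_names <- list(redox = "nem", phospho = "phospho", acetyl = "acetyl")
  used_pos <- lapply(seq_len(config$nProteins), function(i) integer())
  sites <- list()
  offsets <- c(redox = 11L, phospho = 12L, acetyl = 13L)
  for (mod in intersect(names(config$nSites), names(site_letters))) {
    n <- config$nSites[[mod]]
    if (n == 0) next
    set.seed(seed + offsets[[mod]])
    prot_idx <- rep_len(seq_len(config$nProteins), n)
    pos <- integer(n)
    letter <- character(n)
    for (j in seq_len(n)) {
      pi_ <- prot_idx[j]
      cand <- setdiff(7:(L - 7), used_pos[[pi_]])
      pos[j] <- if (length(cand) == 1) cand else sample(cand, 1)
      used_pos[[pi_]] <- c(used_pos[[pi_]], pos[j])
      letter[j] <- if (length(site_letters[[mod]]) == 1)
        site_letters[[mod]] else sample(site_letters[[mod]], 1)
      substr(seqs[pi_], pos[j], pos[j]) <- letter[j]
    }
    n_aff_s <- round(config$affectedFraction * n)
    s_signs <- rep_len(c(1, -1), n_aff_s)
    st <- data.frame(site = paste0(acc[prot_idx], "-", letter, pos),
                     accession = acc[prot_idx], residue = letter,
                     position = pos, mod = mod_names[[mod]],
                     site_offset = stats::rnorm(n, 0, config$siteOffsetSd),
                     stringsAsFactors = FALSE)
    if (mod == "redox") {
      s0 <- sample(config$oxidationLevels, n, replace = TRUE)
      st$stoichiometry <- s0
      st$effect <- c(s_signs * config$redoxEffectSize, rep(0, n - n_aff_s))
      for (i in seq_along(conds))
        st[[paste0("stoich_", conds[i])]] <-
          if (treated[i]) pmin(100, s0 * 2^st$effect) else s0
    } else {
      st$effect <- c(s_signs * config$occupancyEffectSize, rep(0, n - n_aff_s))
      for (i in seq_along(conds))
        st[[paste0("occ_", conds[i])]] <- if (treated[i]) st$effect else 0
    }
    sites[[mod]] <- st
  }

  set.seed(seed + 21L)
  dt <- designTable(design)
  channels <- data.frame(plex_id = dt$plex_id, channel_id = dt$channel_id,
                         lambda = stats::rnorm(nrow(dt), 0,
                                               config$channelLoadingSd),
                         stringsAsFactors = FALSE)
  plex_ids <- unique(dt$plex_id)
  plexes <- data.frame(plex_id = plex_ids,
                       batch = dt$batch[match(plex_ids, dt$plex_id)],
                       delta = stats::rnorm(length(plex_ids), 0,
                                            config$batchOffsetSd),
                       stringsAsFactors = FALSE)

  params <- config
  params$seed <- seed
  class(params) <- NULL
  new("SyntheticTruth", proteins = proteins, sites = sites,
      channels = channels, plexes = plexes, design = design,
      sequences = seqs, params = params)
}

## quality fields: a qcFailRate fraction gets a failing ppm or PepQ;
## the truth label is kept in the synthetic table's qc_fail column
simulateQuality <- function(n, qcFailRate) {
  fail <- stats::runif(n) < qcFailRate
  ppm <- stats::runif(n, -8, 8)
  pepq <- stats::runif(n, 0, 0.009)
  mode_ppm <- stats::runif(n) < 0.5
  ppm[fail & mode_ppm] <- sample(c(-1, 1), sum(fail & mode_ppm),
                                 replace = TRUE) *
    stats::runif(sum(fail & mode_ppm), 10.5, 18)
  pepq[fail & !mode_ppm] <- stats::runif(sum(fail & !mode_ppm), 0.011, 0.05)
  list(ppm = ppm, pepq = pepq, fail = fail)
}

tmtModString <- function(peptide, efficiency) {
  kpos <- gregexpr("K", peptide, fixed = TRUE)[[1]]
  kpos <- kpos[kpos > 0]
  labelable <- c("nt", as.character(kpos - 1L))
  labeled <- labelable[stats::runif(length(labelable)) < efficiency]
  if (length(labeled) == 0) return("")
  paste0("tmt@", labeled, collapse = ";")
}

## intensity matrix for one plex: rows = features, columns = all channels of
## the plex; log2 mean per (row, channel) supplied by `mu` (rows x samples in
## the plex); empty channels come back NA
plexIntensities <- function(mu, noiseSd) {
  2^(mu + stats::rnorm(length(mu), 0, noiseSd))
}

#' Simulate per-modality PSM tables from a ground truth
#'
#' Emits one [PsmTable-class] per requested modality with the same column
#' layout the ingest functions read from disk. Peptides are subsequences of
#' the generated protein sequences; each site's peptide carries its
#' modification in `"name@pos"` encoding, and TMT labels are emitted per
#' labelable position at the configured labeling efficiency (as a
#' dynamic-label search would report them). Enriched modalities include the
#' configured fraction of non-target contaminant PSMs. Reporter intensities
#' follow the generative model of [simulationConfig()]; empty channels are
#' missing, and measurement-level dropout is applied at random. The
#' synthetic-only column `qc_fail` records which PSMs were given failing
#' quality fields.
#'
#' @param truth a [SyntheticTruth-class].
#' @param modalities subset of `c("global", "redox", "phospho", "acetyl")`.
#' @return named list of [PsmTable-class] objects.
#' @export
simulatePsmTables <- function(truth,
                              modalities = c("global",
                                             names(truth@sites))) {
  p <- truth@params
  dt <- designTable(truth@design)
  conds <- p$conditions
  lam <- stats::setNames(truth@channels$lambda,
                         paste(truth@channels$plex_id,
                               truth@channels$channel_id))
  delta <- stats::setNames(truth@plexes$delta, truth@plexes$plex_id)
  plex_ids <- unique(dt$plex_id)
  prot <- truth@proteins
  eff <- as.matrix(prot[, paste0("eff_", conds), drop = FALSE])
  rownames(eff) <- prot$accession
  colnames(eff) <- conds
  seed_off <- c(global = 101L, redox = 102L, phospho = 103L, acetyl = 104L)
  out <- list()

  buildTable <- function(meta, mu_fun) {
    ## meta: one row per PSM species (shared across plexes); mu_fun(meta_row
    ## indices, plex channels) returns the log2 mean matrix for one plex
    tabs <- list()
    for (px in plex_ids) {
      ch <- dt[dt$plex_id == px, , drop = FALSE]
      mu <- mu_fun(meta, ch, px)
      x <- plexIntensities(mu, p$noiseSd)
      x[, ch$channel_role == "empty"] <- NA
      if (p$dropout > 0) {
        ## identification-level dropout: a species missed in a plex loses
        ## all of that plex's reporter channels together (the missingness
        ## structure the per-condition NA rule is designed for)
        x[stats::runif(nrow(x)) < p$dropout, ] <- NA
      }
      colnames(x) <- paste0("intensity_", ch$channel_id)
      q <- simulateQuality(nrow(meta), p$qcFailRate)
      tab <- data.frame(
        psm_id = sprintf("%s_%s", meta$species_id, px),
        plex_id = px, peptide = meta$peptide, mods = meta$mods,
        protein_accession = meta$accession,
        peptide_start = meta$peptide_start,
        mass_error_ppm = q$ppm, pepq = q$pepq, qc_fail = q$fail,
        stringsAsFactors = FALSE)
      tabs[[px]] <- cbind(tab, as.data.frame(x))
    }
    do.call(rbind, tabs)
  }

  for (mod in modalities) {
    set.seed(p$seed + seed_off[[mod]])
    if (mod == "global") {
      k <- p$peptidesPerProtein
      idx <- rep(seq_len(nrow(prot)), each = k)
      pep_no <- rep(seq_len(k), nrow(prot))
      start <- (pep_no - 1) * 17 + 1
      peptide <- substring(truth@sequences[idx], start, start + 11)
      pep_off <- stats::rnorm(length(idx), 0, p$peptideOffsetSd)
      mods <- vapply(peptide, tmtModString, "",
                     efficiency = p$labelingEfficiency)
      meta <- data.frame(
        species_id = sprintf("G_%s_p%d", prot$accession[idx], pep_no),
        accession = prot$accession[idx], peptide = peptide,
        peptide_start = start, mods = unname(mods),
        base = prot$baseline[idx] + pep_off, stringsAsFactors = FALSE)
      mu_fun <- function(meta, ch, px) {
        mu <- outer(meta$base, rep(0, nrow(ch)), "+")
        for (j in seq_len(nrow(ch))) {
          if (ch$channel_role[j] == "empty") next
          mu[, j] <- meta$base + eff[meta$accession, ch$condition[j]] +
            lam[paste(px, ch$channel_id[j])] + delta[px]
        }
        mu
      }
      out[[mod]] <- psmTable(buildTable(meta, mu_fun), mod)
    } else {
      st <- truth@sites[[mod]]
      start <- pmax(1, st$position - 5)
      peptide <- substring(truth@sequences[st$accession], start, start + 11)
      within <- st$position - start
      mods <- paste0(st$mod, "@", within)
      tmt <- vapply(peptide, tmtModString, "",
                    efficiency = p$labelingEfficiency)
      mods <- ifelse(nzchar(tmt), paste(mods, tmt, sep = ";"), mods)
      base <- prot$baseline[match(st$accession, prot$accession)] +
        st$site_offset
      meta <- data.frame(
        species_id = sprintf("%s_%s", toupper(substr(mod, 1, 1)), st$site),
        accession = st$accession, peptide = peptide, peptide_start = start,
        mods = mods, base = base, stringsAsFactors = FALSE)
      ## contaminant (non-target) species emulating imperfect enrichment
      n_cont <- round(p$contaminantFraction[[mod]] * nrow(st))
      if (length(n_cont) == 0 || is.na(n_cont)) n_cont <- 0
      if (n_cont > 0) {
        cont_pep <- vapply(seq_len(n_cont), function(i)
          paste(sample(AA_ALPHABET, 12, replace = TRUE), collapse = ""), "")
        cont <- data.frame(
          species_id = sprintf("CONT_%s_%d", mod, seq_len(n_cont)),
          accession = sample(prot$accession, n_cont, replace = TRUE),
          peptide = cont_pep, peptide_start = 1L, mods = "",
          base = stats::rnorm(n_cont, p$baselineMean, p$baselineSd),
          stringsAsFactors = FALSE)
        meta <- rbind(meta, cont)
      }
      if (mod == "redox") {
        stoich <- as.matrix(st[, paste0("stoich_", conds), drop = FALSE])
        colnames(stoich) <- conds
      } else {
        occ <- as.matrix(st[, paste0("occ_", conds), drop = FALSE])
        colnames(occ) <- conds
      }
      n_target <- nrow(st)
      mu_fun <- function(meta, ch, px) {
        mu <- outer(meta$base, rep(0, nrow(ch)), "+")
        is_target <- seq_len(nrow(meta)) <= n_target
        for (j in seq_len(nrow(ch))) {
          if (ch$channel_role[j] == "empty") next
          cc <- ch$condition[j]
          mu[, j] <- meta$base + eff[meta$accession, cc] +
            lam[paste(px, ch$channel_id[j])] + delta[px]
          if (mod == "redox") {
            if (ch$channel_role[j] == "oxidation")
              mu[is_target, j] <- mu[is_target, j] +
                log2(stoich[, cc] / 100)
          } else {
            mu[is_target, j] <- mu[is_target, j] + occ[, cc]
          }
        }
        mu
      }
      out[[mod]] <- psmTable(buildTable(meta, mu_fun), mod)
    }
  }
  out
}

#' Write the synthetic protein sequences as FASTA
#' @param truth a [SyntheticTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSyntheticFasta <- function(truth, path) {
  aa <- Biostrings::AAStringSet(truth@sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

## ---- toy structures --------------------------------------------------------

#' Write a minimal single-chain CA-only structure file
#'
#' Produces a valid PDB (or mmCIF) file with one CA atom per residue and
#' the given per-residue confidence in the B-factor column, readable by
#' [readStructure()]. Intended for building toy models in tests and
#' examples; files are labelled synthetic via their `data_` block / header.
#'
#' @param positions integer residue numbers (unique).
#' @param aa one-letter residue codes, same length.
#' @param coords numeric matrix n x 3 of CA coordinates (Angstrom).
#' @param plddt numeric per-residue confidence (0-100).
#' @param path output path.
#' @param format `"pdb"` or `"cif"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
writeToyStructure <- function(positions, aa, coords, plddt, path,
                              format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  coords <- as.matrix(coords)
  if (anyDuplicated(positions)) stop("duplicate residue positions")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  stopifnot(length(positions) == length(aa),
            nrow(coords) == length(positions),
            length(plddt) == length(positions))
  o <- order(positions)
  positions <- positions[o]; aa <- aa[o]
  coords <- coords[o, , drop = FALSE]; plddt <- plddt[o]
  res3 <- bio3d::aa123(aa)
  if (format == "pdb") {
    lines <- c("REMARK   1 SYNTHETIC TOY MODEL", sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_along(positions), res3, positions,
      coords[, 1], coords[, 2], coords[, 3], 1.00, plddt),
      "TER", "END")
  } else {
    lines <- c(
      "data_synthetic_toy_model",
      "#",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num",
      sprintf(
        "ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s A CA 1",
        seq_along(positions), res3, positions,
        coords[, 1], coords[, 2], coords[, 3], plddt,
        positions, res3),
      "#")
  }
  writeLines(lines, path)
  invisible(path)
}
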