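#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix, features x samples (dimnames required).
#' @param sampleData data.frame of per-sample metadata, rownames matching
#'   `colnames(values)` (typically [sampleAnnotation] of the design).
#' @param rowData optional data.frame of per-feature metadata.
#' @param scale `"raw"` or `"log2"`.
#' @param modality `"global"`, `"redox"`, `"phospho"` or `"acetyl"`.
#' @param processing ordered character vector of steps already applied.
#' @return an [AbundanceMatrix-class].
#' @export
abundanceMatrix <- function(values, sampleData, rowData = NULL,
                            scale = "raw", modality = "global",
                            processing = character()) {
  values <- as.matrix(values)
  sampleData <- sampleData[colnames(values), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = DataFrame(sampleData),
    rowData = if (is.null(rowData)) NULL else DataFrame(rowData))
  md <- list(scale = scale, modality = modality, processing = processing)
  metadata(se) <- md
  new("AbundanceMatrix", se)
}

hasStep <- function(m, step) step %in% processingLog(m)

addStep <- function(m, step) {
  metadata(m)$processing <- c(processingLog(m), step)
  m
}

requireScale <- function(m, scale, op) {
  if (!identical(assayScale(m), scale))
    stop(sprintf("state error in %s: matrix must be on %s scale (is %s)",
                 op, scale, assayScale(m)))
  invisible(NULL)
}

requireSteps <- function(m, steps, op) {
  log <- processingLog(m)
  idx <- match(steps, log)
  if (any(is.na(idx)) || is.unsorted(idx))
    stop(sprintf(
      "state error in %s: processing log must contain [%s] in order (has [%s])",
      op, paste(steps, collapse = ", "), paste(log, collapse = ", ")))
  invisible(NULL)
}

forbidStep <- function(m, step, op) {
  if (hasStep(m, step))
    stop(sprintf("state error in %s: matrix already carries step '%s'",
                 op, step))
  invisible(NULL)
}

#' Subset an AbundanceMatrix by channel role
#'
#' Convenience selector, e.g. to restrict a matrix to the biological
#' (oxidation/standard) samples before statistics.
#'
#' @param m an [AbundanceMatrix-class] whose `colData` has `channel_role`.
#' @param roles roles to keep.
#' @return the column-subset [AbundanceMatrix-class].
#' @export
subsetByRole <- function(m, roles = c("oxidation", "standard")) {
  m[, colData(m)$channel_role %in% roles]
}

## ---- roll-up ---------------------------------------------------------------

## Sum raw reporter intensities per (feature key, sample). Zero intensities
## are treated as missing before summation (non-detections in reporter-ion
## data); a cell is missing only when all contributors are missing.
rollupByKey <- function(psms, design, keys, modality) {
  d <- psmData(psms)
  keep <- !is.na(keys)
  d <- d[keep, , drop = FALSE]
  keys <- keys[keep]
  ann <- sampleAnnotation(design)
  dt <- designTable(design)
  ichan <- sub("^intensity_", "", grep("^intensity_", colnames(d), value = TRUE))
  features <- sort(unique(keys))
  sums <- matrix(0, length(features), nrow(ann),
                 dimnames = list(features, rownames(ann)))
  counts <- matrix(0L, length(features), nrow(ann),
                   dimnames = list(features, rownames(ann)))
  for (p in unique(d$plex_id)) {
    dp <- dt[dt$plex_id == p, , drop = FALSE]
    if (nrow(dp) == 0)
      stop(sprintf("plex '%s' present in PSMs but absent from design", p))
    rows <- d$plex_id == p
    fac <- factor(keys[rows], levels = features)
    pres <- ichan[vapply(ichan, function(ch)
      any(!is.na(d[rows, paste0("intensity_", ch)])), logical(1))]
    bad <- setdiff(pres, dp$channel_id)
    if (length(bad) > 0)
      stop(sprintf("channel(s) %s present in PSMs but absent from design of plex %s",
                   paste(bad, collapse = ", "), p))
    use <- dp[dp$channel_role != "empty" & dp$channel_id %in% ichan, ,
              drop = FALSE]
    for (j in seq_len(nrow(use))) {
      v <- d[rows, paste0("intensity_", use$channel_id[j])]
      v[!is.na(v) & v == 0] <- NA
      ok <- !is.na(v)
      if (!any(ok)) next
      s <- rowsum(v[ok], fac[ok])
      n <- rowsum(rep(1L, sum(ok)), fac[ok])
      sums[rownames(s), use$sample_id[j]] <-
        sums[rownames(s), use$sample_id[j]] + s[, 1]
      counts[rownames(n), use$sample_id[j]] <-
        counts[rownames(n), use$sample_id[j]] + n[, 1]
    }
  }
  sums[counts == 0L] <- NA
  abundanceMatrix(sums, ann, scale = "raw", modality = modality,
                  processing = "rollup")
}

#' Roll PSM reporter intensities up to the protein level
#'
#' Aggregates to unique proteins by summing raw reporter-ion intensities of
#' each protein's PSMs per sample. Empty channels are excluded; zero
#' intensities are treated as missing before summation; a (protein, sample)
#' cell is missing only when all contributing intensities are missing.
#'
#' @param psms a filtered [PsmTable-class].
#' @param design a [PlexDesign-class] resolving (plex, channel) to samples.
#' @return a raw-scale [AbundanceMatrix-class], proteins x samples.
#' @export
rollupProtein <- function(psms, design) {
  stopifnot(is(psms, "PsmTable"), is(design, "PlexDesign"))
  rollupByKey(psms, design, psmData(psms)$protein_accession,
              psmModality(psms))
}

#' Roll PSM reporter intensities up to the unique-peptide level
#'
#' Peptide-level global data is the reference used to scale PTM site
#' abundances for TMT channel loading (see [scaleToGlobal()]).
#'
#' @inheritParams rollupProtein
#' @return a raw-scale [AbundanceMatrix-class], peptides x samples.
#' @export
rollupPeptide <- function(psms, design) {
  stopifnot(is(psms, "PsmTable"), is(design, "PlexDesign"))
  rollupByKey(psms, design, psmData(psms)$peptide, psmModality(psms))
}

#' Roll PSM reporter intensities up to the unique PTM-site level
#'
#' Sites are resolved via [mapToSites()]; a multi-site peptide contributes
#' only to its composite site key. PSMs without the target modification are
#' dropped.
#'
#' @inheritParams rollupProtein
#' @param targetMod modification defining the sites (e.g. `"nem"`).
#' @param fasta protein sequences (see [mapToSites()]).
#' @return a raw-scale [AbundanceMatrix-class], sites x samples, with
#'   `accession` in its `rowData`.
#' @export
rollupSite <- function(psms, design, targetMod, fasta) {
  stopifnot(is(psms, "PsmTable"), is(design, "PlexDesign"))
  sites <- mapToSites(psms, fasta, targetMod)
  m <- rollupByKey(psms, design, sites, psmModality(psms))
  info <- parseSiteIds(rownames(m))
  rowData(m)$accession <- info$accession
  m
}

## ---- normalization chain ---------------------------------------------------

#' Log2-transform a raw abundance matrix
#'
#' Zeros and missing values stay missing. Applying to an already-log2
#' matrix is a state error.
#'
#' @param m a raw-scale [AbundanceMatrix-class].
#' @return the log2-scale matrix, step `"log2"` appended.
#' @export
log2Transform <- function(m) {
  requireScale(m, "raw", "log2Transform")
  x <- abundances(m)
  x[!is.na(x) & x == 0] <- NA
  x <- log2(x)
  assay(m) <- x
  metadata(m)$scale <- "log2"
  addStep(m, "log2")
}

#' Median-center each sample column
#'
#' Subtracts each column's non-missing median so that per-sample medians
#' become 0. Columns that are entirely missing are left untouched with a
#' warning.
#'
#' @param m a log2-scale [AbundanceMatrix-class].
#' @return the centered matrix, step `"median-centered"` appended.
#' @export
medianCenter <- function(m) {
  requireScale(m, "log2", "medianCenter")
  x <- abundances(m)
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (any(is.na(med))) {
    warning(sprintf("column(s) entirely missing, left untouched: %s",
                    paste(colnames(x)[is.na(med)], collapse = ", ")))
    med[is.na(med)] <- 0
  }
  assay(m) <- sweep(x, 2, med, "-")
  addStep(m, "median-centered")
}

#' Correct for plex batch effects
#'
#' Per feature, subtracts the batch mean and restores the grand mean (both
#' over non-missing values), so inter-plex mean shifts are removed while
#' within-plex pairwise sample differences are preserved exactly. Features
#' observed in a single batch pass through unchanged and are flagged in
#' `rowData(m)$single_batch`. Single-batch input is a no-op with a warning.
#'
#' @param m a log2-scale [AbundanceMatrix-class] whose `colData` has `batch`.
#' @return the corrected matrix, step `"batch-corrected"` appended.
#' @export
batchCorrect <- function(m) {
  requireScale(m, "log2", "batchCorrect")
  x <- abundances(m)
  batch <- as.character(colData(m)$batch)
  ub <- unique(batch)
  if (length(ub) < 2) {
    warning("single batch: batch correction is a no-op")
    rowData(m)$single_batch <- rep(TRUE, nrow(m))
    return(addStep(m, "batch-corrected"))
  }
  grand <- rowMeans(x, na.rm = TRUE)
  n_batches_obs <- rep(0L, nrow(x))
  for (b in ub) {
    cols <- batch == b
    bm <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
    obs <- !is.nan(bm)
    n_batches_obs <- n_batches_obs + as.integer(obs)
    shift <- ifelse(obs, bm - grand, 0)
    x[, cols] <- x[, cols, drop = FALSE] - shift
  }
  assay(m) <- x
  rowData(m)$single_batch <- n_batches_obs <= 1L
  addStep(m, "batch-corrected")
}

#' Scale PTM site abundances by the global peptide data
#'
#' Subtracts, per sample, the non-missing median of the corresponding
#' *not-batch-corrected* log2 global peptide column from the PTM site
#' column. This removes TMT channel-loading offsets and median-centers the
#' site data in one step. Samples present in the site matrix but absent
#' from the global matrix pass through untouched and are flagged in
#' `colData(m)$global_scaled`.
#'
#' @param m a log2-scale site-level [AbundanceMatrix-class], not yet batch
#'   corrected.
#' @param global a log2-scale global *peptide* [AbundanceMatrix-class]; it
#'   must not be batch corrected.
#' @return the scaled matrix, step `"global-scaled"` appended.
#' @export
scaleToGlobal <- function(m, global) {
  requireScale(m, "log2", "scaleToGlobal")
  requireScale(global, "log2", "scaleToGlobal")
  forbidStep(m, "batch-corrected", "scaleToGlobal")
  if (hasStep(global, "batch-corrected"))
    stop("state error in scaleToGlobal: global matrix must not be batch corrected")
  shared <- intersect(colnames(m), colnames(global))
  x <- abundances(m)
  med <- apply(abundances(global)[, shared, drop = FALSE], 2,
               stats::median, na.rm = TRUE)
  x[, shared] <- sweep(x[, shared, drop = FALSE], 2, med, "-")
  assay(m) <- x
  colData(m)$global_scaled <- colnames(m) %in% shared
  addStep(m, "global-scaled")
}

#' Subtract per-condition protein abundances from PTM site abundances
#'
#' For a site on protein p observed in a sample of condition c, subtracts
#' the mean normalized abundance of p over the non-missing condition-c
#' samples of the protein matrix, so the corrected site values track
#' modification occupancy rather than protein amount. Sites whose protein
#' is absent from the protein matrix, or has fewer than two non-missing
#' replicates in a condition, pass through for that condition and the
#' affected conditions are listed in `rowData(m)$uncorrected_conditions`.
#'
#' The site matrix must carry the chain `log2 -> global-scaled ->
#' batch-corrected`; the protein matrix must be fully normalized
#' (`log2`, `batch-corrected`, `median-centered`).
#'
#' @param m a site-level [AbundanceMatrix-class] with `accession` in its
#'   `rowData` and `condition` in its `colData`.
#' @param protein the normalized global protein [AbundanceMatrix-class].
#' @param minReplicates minimum non-missing replicates for a usable
#'   condition mean; default 2.
#' @return the corrected matrix, step `"protein-corrected"` appended.
#' @export
correctForProtein <- function(m, protein, minReplicates = 2) {
  requireSteps(m, c("log2", "global-scaled", "batch-corrected"),
               "correctForProtein")
  forbidStep(m, "protein-corrected", "correctForProtein")
  requireScale(protein, "log2", "correctForProtein")
  if (!hasStep(protein, "batch-corrected") ||
      !hasStep(protein, "median-centered"))
    stop("state error in correctForProtein: protein matrix must be batch corrected and median centered")
  acc <- rowData(m)$accession
  if (is.null(acc))
    stop("site matrix must carry 'accession' in rowData")
  cond_site <- as.character(colData(m)$condition)
  cond_prot <- as.character(colData(protein)$condition)
  conds <- unique(cond_site)
  px <- abundances(protein)
  ## per-protein, per-condition means (NA where unusable)
  pm <- matrix(NA_real_, nrow(px), length(conds),
               dimnames = list(rownames(px), conds))
  for (cc in conds) {
    cols <- cond_prot == cc
    if (!any(cols)) next
    sub <- px[, cols, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[n_ok < minReplicates] <- NA
    pm[, cc] <- mu
  }
  x <- abundances(m)
  corr <- matrix(NA_real_, nrow(x), ncol(x))
  known <- acc %in% rownames(pm)
  corr[known, ] <- pm[acc[known], cond_site, drop = FALSE]
  x <- x - ifelse(is.na(corr), 0, corr)
  assay(m) <- x
  unc <- vapply(seq_len(nrow(x)), function(i) {
    bad <- unique(cond_site[is.na(corr[i, ])])
    paste(bad, collapse = ",")
  }, character(1))
  rowData(m)$uncorrected_conditions <- unc
  addStep(m, "protein-corrected")
}

#' Remove features with too many missing values per condition
#'
#' Drops any feature having more than `maxNAPerCondition` missing values
#' within any single condition (the strictest reading of the 2-of-4 rule;
#' set `scope = "all"` to drop only features failing in every condition).
#' The dropped feature ids are recorded in `metadata(m)$dropped_features`.
#'
#' @param m an [AbundanceMatrix-class] with `condition` in its `colData`.
#' @param maxNAPerCondition maximum missing values tolerated per condition;
#'   default 2 (of 4 replicates).
#' @param scope `"any"` (default) or `"all"`.
#' @return the filtered matrix, step `"na-filtered"` appended.
#' @export
filterMissing <- function(m, maxNAPerCondition = 2, scope = c("any", "all")) {
  scope <- match.arg(scope)
  cond <- as.character(colData(m)$condition)
  x <- abundances(m)
  conds <- unique(cond)
  small <- conds[table(cond)[conds] < maxNAPerCondition + 1]
  if (length(small) > 0)
    warning(sprintf("condition(s) with fewer than %d replicates: %s",
                    maxNAPerCondition + 1, paste(small, collapse = ", ")))
  na_counts <- vapply(conds, function(cc)
    rowSums(is.na(x[, cond == cc, drop = FALSE])), numeric(nrow(x)))
  if (nrow(x) == 1) na_counts <- matrix(na_counts, nrow = 1)
  fails <- na_counts > maxNAPerCondition
  drop <- if (scope == "any") apply(fails, 1, any) else apply(fails, 1, all)
  dropped <- rownames(x)[drop]
  out <- m[!drop, ]
  metadata(out)$dropped_features <- dropped
  addStep(out, "na-filtered")
}

## ---- i/o -------------------------------------------------------------------

#' Write an AbundanceMatrix as TSV plus a YAML metadata sidecar
#'
#' The TSV holds the matrix with a leading `feature` column; the sidecar
#' (`<path>.meta.yaml`) records scale, modality, the processing log and the
#' sample metadata, so [readAbundanceMatrix()] can reconstruct the object.
#'
#' @param m an [AbundanceMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAbundanceMatrix <- function(m, path) {
  x <- abundances(m)
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scale = assayScale(m), modality = assayModality(m),
               processing = as.list(processingLog(m)),
               samples = lapply(seq_len(ncol(m)), function(j) {
                 row <- lapply(as.list(as.data.frame(
                   colData(m))[j, , drop = FALSE]), unname)
                 row$sample_id <- colnames(m)[j]
                 row
               }))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an AbundanceMatrix written by [writeAbundanceMatrix()]
#' @param path TSV path (the `<path>.meta.yaml` sidecar must exist).
#' @return an [AbundanceMatrix-class].
#' @export
readAbundanceMatrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$feature
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  sd <- do.call(rbind, lapply(meta$samples, function(s)
    as.data.frame(s, stringsAsFactors = FALSE)))
  rownames(sd) <- sd$sample_id
  abundanceMatrix(x, sd[colnames(x), , drop = FALSE],
                  scale = meta$scale, modality = meta$modality,
                  processing = unlist(meta$processing))
}
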