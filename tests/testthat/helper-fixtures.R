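## in-code fixtures shared across test files

## minimal one-plex design: n_ox oxidation samples across `conditions`,
## n_tt total-thiol singlets, n_empty empty channels
toyDesignFrame <- function(conditions = c("A", "B"), reps = 2, n_tt = 1,
                           n_empty = 1, plex = "P1", batch = "B1") {
  rows <- expand.grid(replicate = seq_len(reps), condition = conditions,
                      stringsAsFactors = FALSE)
  n_ox <- nrow(rows)
  n <- n_ox + n_tt + n_empty
  data.frame(
    plex_id = plex,
    channel_id = paste0("ch", seq_len(n)),
    sample_id = c(sprintf("%s_R%d", rows$condition, rows$replicate),
                  if (n_tt > 0) sprintf("TT_%s_%d", plex, seq_len(n_tt)),
                  rep("", n_empty)),
    condition = c(rows$condition, rep(conditions[1], n_tt), rep("", n_empty)),
    timepoint = "4h",
    replicate = c(rows$replicate, rep(1L, n_tt), rep(NA_integer_, n_empty)),
    channel_role = c(rep("oxidation", n_ox), rep("total_thiol", n_tt),
                     rep("empty", n_empty)),
    batch = batch,
    stringsAsFactors = FALSE)
}

toyDesign <- function(...) plexDesign(toyDesignFrame(...))

## tiny PSM frame; `intensities` is a matrix (one row per PSM) whose column
## names are channel ids
toyPsmFrame <- function(peptides, proteins, starts, mods = "",
                        intensities, plex = "P1",
                        ppm = 0, pepq = 0.001) {
  n <- length(peptides)
  d <- data.frame(psm_id = paste0("psm", seq_len(n)), plex_id = plex,
                  peptide = peptides, mods = mods,
                  protein_accession = proteins, peptide_start = starts,
                  mass_error_ppm = rep_len(ppm, n),
                  pepq = rep_len(pepq, n), stringsAsFactors = FALSE)
  im <- as.matrix(intensities)
  colnames(im) <- paste0("intensity_", colnames(intensities))
  cbind(d, as.data.frame(im))
}

## log2 AbundanceMatrix straight from a matrix and a condition vector
toyLogMatrix <- function(x, conditions, roles = "oxidation",
                         batch = "B1", modality = "global",
                         processing = c("rollup", "log2")) {
  sd <- data.frame(sample_id = colnames(x), condition = conditions,
                   channel_role = rep_len(roles, ncol(x)),
                   batch = rep_len(batch, ncol(x)),
                   plex_id = rep_len(batch, ncol(x)),
                   stringsAsFactors = FALSE)
  rownames(sd) <- colnames(x)
  abundanceMatrix(x, sd, scale = "log2", modality = modality,
                  processing = processing)
}

toyRawMatrix <- function(x, conditions, roles = "oxidation", batch = "B1",
                         plex = batch, modality = "redox") {
  sd <- data.frame(sample_id = colnames(x), condition = conditions,
                   channel_role = rep_len(roles, ncol(x)),
                   batch = rep_len(batch, ncol(x)),
                   plex_id = rep_len(plex, ncol(x)),
                   stringsAsFactors = FALSE)
  rownames(sd) <- colnames(x)
  abundanceMatrix(x, sd, scale = "raw", modality = modality,
                  processing = "rollup")
}

## brute-force roll-up oracle: plain loops over (key, sample)
bruteForceRollup <- function(psm_frame, design_frame, keys) {
  keep <- !is.na(keys)
  psm_frame <- psm_frame[keep, , drop = FALSE]
  keys <- keys[keep]
  dns <- design_frame[design_frame$channel_role != "empty", , drop = FALSE]
  features <- sort(unique(keys))
  out <- matrix(NA_real_, length(features), nrow(dns),
                dimnames = list(features, dns$sample_id))
  for (f in features) {
    for (j in seq_len(nrow(dns))) {
      rows <- which(keys == f & psm_frame$plex_id == dns$plex_id[j])
      col <- paste0("intensity_", dns$channel_id[j])
      if (!col %in% colnames(psm_frame)) next
      v <- psm_frame[rows, col]
      v <- v[!is.na(v) & v > 0]
      if (length(v) > 0) out[f, dns$sample_id[j]] <- sum(v)
    }
  }
  out
}

## brute-force BH step-up oracle, straight from the definition
bruteForceBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## hypergeometric upper tail by exhaustive enumeration of hit configurations
enumHyperP <- function(N, K, n, k) {
  ## P[X >= k] by summing the point probabilities from the definition
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
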