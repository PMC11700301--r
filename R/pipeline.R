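#' Run the full multi-PTM analysis pipeline from a configuration
#'
#' Executes ingest (read + filter PSMs) -> quantification (global protein
#' and peptide roll-up, normalization; each PTM modality rolled up to
#' sites, global-scaled, batch corrected, protein corrected, NA filtered)
#' -> redox stoichiometry -> differential statistics (two-sample contrasts
#' and one-way ANOVA vs the reference condition) -> over-representation
#' analysis -> structure distance mapping, writing tab-separated outputs
#' plus a YAML run manifest (thresholds, seed, per-stage feature counts) to
#' the output directory. Optional stages (ORA without a GMT file,
#' structures without structure files) are skipped with a logged notice.
#' Given the same configuration the run is deterministic.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `psm_tables` (named list modality -> TSV path; must include `global`),
#'   `design` (plex-design TSV), `fasta`, optional `gmt`, optional
#'   `structures` (named list accession -> file with `residues` vector),
#'   `output_dir`, and optional `thresholds` overriding `max_ppm` (10),
#'   `max_pepq` (0.01), `max_na_per_condition` (2), `de_max_adj_p` (0.05),
#'   `de_min_abs_log2fc` (0.8), `ora_max_q` (0.2), `ora_max_adj_p` (0.05),
#'   `anova_min_abs_log2fc` (1), `plddt_threshold` (70), plus `reference`
#'   (ANOVA reference condition) and `contrasts` (list of 2-vectors).
#' @param seed integer seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config must set output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- utils::modifyList(list(
    max_ppm = 10, max_pepq = 0.01, max_na_per_condition = 2,
    de_max_adj_p = 0.05, de_min_abs_log2fc = 0.8,
    ora_max_q = 0.2, ora_max_adj_p = 0.05,
    anova_min_abs_log2fc = 1, plddt_threshold = 70),
    if (is.null(config$thresholds)) list() else config$thresholds)
  set.seed(seed)
  manifest <- list(package_version = as.character(
    utils::packageVersion("ptmplex")),
    seed = seed, thresholds = thr, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(sprintf("%s=%s", names(list(...)), list(...)),
                          collapse = " ")))
  }
  fail <- function(stage, e) {
    writeLines(sprintf("FAILED at stage %s: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  ## ingest ------------------------------------------------------------------
  stage <- "ingest"
  res <- tryCatch({
    design <- readPlexDesign(config$design)
    psms <- lapply(names(config$psm_tables), function(mod)
      filterPsms(readPsmTable(config$psm_tables[[mod]], mod),
                 maxPpm = thr$max_ppm, maxPepQ = thr$max_pepq))
    names(psms) <- names(config$psm_tables)
    for (mod in names(psms))
      log_stage(paste0("ingest_", mod), n_psms = nrow(psmData(psms[[mod]])),
                n_filtered = nFiltered(psms[[mod]]))
    list(design = design, psms = psms)
  }, error = function(e) fail(stage, e))
  design <- res$design; psms <- res$psms
  if (!"global" %in% names(psms))
    stop("config$psm_tables must include a 'global' table")
  fasta <- fastaSequences(config$fasta)

  ## quant -------------------------------------------------------------------
  stage <- "quant"
  q <- tryCatch({
    prot_raw <- rollupProtein(psms$global, design)
    pep_raw <- rollupPeptide(psms$global, design)
    prot <- medianCenter(batchCorrect(log2Transform(prot_raw)))
    pep_log2 <- log2Transform(pep_raw)
    writeAbundanceMatrix(prot, file.path(out_dir, "protein_normalized.tsv"))
    log_stage("quant_global", n_proteins = nrow(prot),
              n_peptides = nrow(pep_log2))
    site_mods <- c(redox = "nem", phospho = "phospho", acetyl = "acetyl")
    sites <- list()
    for (mod in intersect(names(psms), names(site_mods))) {
      raw <- rollupSite(psms[[mod]], design, site_mods[[mod]], fasta)
      if (mod == "redox")
        writeStoichiometry(percentOxidation(raw, global = pep_log2),
                           file.path(out_dir, "redox_stoichiometry.tsv"))
      m <- correctForProtein(
        batchCorrect(scaleToGlobal(log2Transform(raw), pep_log2)), prot)
      ## the NA rule counts biological replicates, not total-thiol singlets
      m <- suppressWarnings(filterMissing(
        subsetByRole(m), maxNAPerCondition = thr$max_na_per_condition))
      writeAbundanceMatrix(m, file.path(out_dir,
                                        sprintf("%s_sites_corrected.tsv", mod)))
      log_stage(paste0("quant_", mod), n_sites = nrow(raw),
                n_after_na_filter = nrow(m))
      sites[[mod]] <- m
    }
    list(protein = prot, sites = sites)
  }, error = function(e) fail(stage, e))

  ## stats -------------------------------------------------------------------
  stage <- "stats"
  matrices <- c(list(global = q$protein), q$sites)
  de_tables <- list()
  anova_tables <- list()
  tryCatch({
    contrasts <- config$contrasts
    if (is.null(contrasts)) {
      conds <- unique(designTable(design)$condition)
      conds <- conds[nzchar(conds)]
      tp <- sub("^.*_", "", conds)
      contrasts <- lapply(unique(tp), function(t) {
        cs <- conds[tp == t]
        trt <- grep("^Control", cs, invert = TRUE, value = TRUE)
        ctl <- grep("^Control", cs, value = TRUE)
        if (length(trt) == 1 && length(ctl) == 1) c(trt, ctl) else NULL
      })
      contrasts <- Filter(Negate(is.null), contrasts)
    }
    reference <- if (is.null(config$reference)) "Control_4h" else
      config$reference
    for (mod in names(matrices)) {
      m <- matrices[[mod]]
      if (!"na-filtered" %in% processingLog(m))
        m <- suppressWarnings(filterMissing(
          subsetByRole(m), maxNAPerCondition = thr$max_na_per_condition))
      de <- do.call(rbind, lapply(contrasts, function(ct)
        twoSampleTest(m, ct[1], ct[2])))
      utils::write.table(de, file.path(out_dir,
                                       sprintf("%s_de.tsv", mod)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      de_tables[[mod]] <- de
      an <- oneWayAnova(m, reference = reference)
      utils::write.table(an, file.path(out_dir,
                                       sprintf("%s_anova.tsv", mod)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      anova_tables[[mod]] <- an
      log_stage(paste0("stats_", mod),
                n_tested = sum(!is.na(de$adj_p)),
                n_de = length(deSignificant(de, thr$de_max_adj_p,
                                            thr$de_min_abs_log2fc)),
                n_anova = length(anovaSignificant(
                  an, thr$de_max_adj_p, thr$anova_min_abs_log2fc)))
    }
  }, error = function(e) fail(stage, e))

  ## enrichment --------------------------------------------------------------
  ora_tables <- list()
  if (!is.null(config$gmt)) {
    stage <- "enrichment"
    tryCatch({
      sets <- readGmt(config$gmt)
      for (mod in names(de_tables)) {
        de <- de_tables[[mod]]
        tested <- de$feature[!is.na(de$adj_p)]
        hits <- deSignificant(de, thr$de_max_adj_p, thr$de_min_abs_log2fc)
        if (mod != "global") {
          tested <- sitesToGenes(tested)
          hits <- sitesToGenes(hits)
        }
        if (length(hits) == 0) next
        res <- ora(hits, unique(tested), sets)
        utils::write.table(res, file.path(out_dir,
                                          sprintf("%s_ora.tsv", mod)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ora_tables[[mod]] <- res
        log_stage(paste0("ora_", mod), n_sets = nrow(res),
                  n_significant = nrow(oraSignificant(res, thr$ora_max_q,
                                                      thr$ora_max_adj_p)))
      }
    }, error = function(e) fail(stage, e))
  } else {
    message("[enrichment] skipped: no GMT file configured")
    manifest$stages$enrichment <- list(skipped = TRUE)
  }

  ## structure ---------------------------------------------------------------
  dist_results <- list()
  if (!is.null(config$structures)) {
    stage <- "structure"
    tryCatch({
      for (acc in names(config$structures)) {
        sc <- config$structures[[acc]]
        model <- readStructure(sc$path, accession = acc)
        dm <- siteDistanceMatrix(model, unlist(sc$residues),
                                 plddtThreshold = thr$plddt_threshold)
        utils::write.table(
          data.frame(site = rownames(distances(dm)), distances(dm),
                     plddt = dm@plddt, low_confidence = dm@lowConfidence,
                     check.names = FALSE),
          file.path(out_dir, sprintf("%s_distances.tsv", acc)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        dist_results[[acc]] <- dm
        log_stage(paste0("structure_", acc),
                  n_sites = nrow(distances(dm)),
                  n_low_confidence = sum(dm@lowConfidence))
      }
    }, error = function(e) fail(stage, e))
  } else {
    message("[structure] skipped: no structure files configured")
    manifest$stages$structure <- list(skipped = TRUE)
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results <- list(manifest = manifest, design = design,
                  protein = q$protein, sites = q$sites,
                  de = de_tables, anova = anova_tables, ora = ora_tables,
                  distances = dist_results, matrices = matrices,
                  thresholds = thr, out_dir = out_dir)
  invisible(results)
}

placeholderFigure <- function(path, text) {
  grDevices::png(path, width = 600, height = 400)
  graphics::plot.new()
  graphics::text(0.5, 0.5, text)
  grDevices::dev.off()
}

#' Render standard figures from pipeline results
#'
#' Writes, per modality where inputs exist: a volcano plot per contrast
#' (cutoff lines at the DE thresholds), a heatmap of ANOVA-significant
#' features (rows scaled to mean 0, SD 1), an ORA dot plot (gene ratio vs
#' set, point size = hit count, colour = adjusted p), and a CA-CA distance
#' heatmap annotated with the distances to one decimal. Empty result
#' tables produce a placeholder figure with a notice.
#'
#' @param results the list returned by [runPipeline()].
#' @param out_dir output directory; defaults to the pipeline's.
#' @return character vector of written figure paths, invisibly.
#' @export
renderFigures <- function(results, out_dir = results$out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- results$thresholds
  written <- character()
  add <- function(p) written <<- c(written, p)

  for (mod in names(results$de)) {
    de <- results$de[[mod]]
    for (ct in unique(de$contrast)) {
      path <- file.path(out_dir, sprintf("volcano_%s_%s.png", mod,
                                         gsub("[^A-Za-z0-9]+", "_", ct)))
      sub <- de[de$contrast == ct & !is.na(de$adj_p), , drop = FALSE]
      if (nrow(sub) == 0) {
        placeholderFigure(path, sprintf("no tested features: %s", ct))
      } else {
        sub$significant <- sub$adj_p <= thr$de_max_adj_p &
          abs(sub$log2fc) >= thr$de_min_abs_log2fc
        g <- ggplot2::ggplot(sub, ggplot2::aes(
          x = .data$log2fc, y = -log10(.data$adj_p),
          colour = .data$significant)) +
          ggplot2::geom_point(size = 0.8) +
          ggplot2::geom_vline(xintercept = c(-1, 1) * thr$de_min_abs_log2fc,
                              linetype = "dashed") +
          ggplot2::geom_hline(yintercept = -log10(thr$de_max_adj_p),
                              linetype = "dashed") +
          ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                                  `TRUE` = "firebrick")) +
          ggplot2::labs(title = sprintf("%s: %s", mod, ct),
                        x = "log2 fold change", y = "-log10 adjusted p") +
          ggplot2::theme_bw()
        ggplot2::ggsave(path, g, width = 5, height = 4, dpi = 100)
      }
      add(path)
    }
  }

  for (mod in names(results$anova)) {
    an <- results$anova[[mod]]
    path <- file.path(out_dir, sprintf("heatmap_%s.png", mod))
    sig <- anovaSignificant(an, thr$de_max_adj_p, thr$anova_min_abs_log2fc)
    m <- results$matrices[[mod]]
    sig <- intersect(sig, rownames(m))
    x <- abundances(m)[sig, , drop = FALSE]
    x <- x[rowSums(is.na(x)) == 0, , drop = FALSE]
    if (nrow(x) < 2) {
      placeholderFigure(path, sprintf("no significant features: %s", mod))
    } else {
      xs <- t(scale(t(x)))   # per-feature mean 0, SD 1
      grDevices::png(path, width = 800, height = 600)
      pheatmap::pheatmap(xs, show_rownames = nrow(xs) <= 50,
                         main = sprintf("%s ANOVA (row-scaled)", mod))
      grDevices::dev.off()
    }
    add(path)
  }

  for (mod in names(results$ora)) {
    res <- results$ora[[mod]]
    path <- file.path(out_dir, sprintf("ora_dotplot_%s.png", mod))
    if (is.null(res) || nrow(res) == 0) {
      placeholderFigure(path, "no over-represented sets")
    } else {
      res$gene_ratio <- res$k / res$n
      g <- ggplot2::ggplot(res, ggplot2::aes(
        x = .data$gene_ratio, y = stats::reorder(.data$set, .data$gene_ratio),
        size = .data$k, colour = .data$adj_p)) +
        ggplot2::geom_point() +
        ggplot2::labs(title = sprintf("%s over-representation", mod),
                      x = "gene ratio", y = NULL) +
        ggplot2::theme_bw()
      ggplot2::ggsave(path, g, width = 6, height = 4, dpi = 100)
    }
    add(path)
  }

  for (acc in names(results$distances)) {
    dm <- results$distances[[acc]]
    path <- file.path(out_dir, sprintf("distance_heatmap_%s.png", acc))
    d <- distances(dm)
    labs <- rownames(d)
    labs[dm@lowConfidence] <- paste0(labs[dm@lowConfidence], " *")
    grDevices::png(path, width = 600, height = 500)
    pheatmap::pheatmap(d, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = matrix(sprintf("%.1f", d), nrow(d)),
                       labels_row = labs, labels_col = labs,
                       main = sprintf("%s CA-CA distances (A); * low pLDDT",
                                      acc))
    grDevices::dev.off()
    add(path)
  }
  invisible(written)
}

#' @importFrom ggplot2 .data
NULL
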