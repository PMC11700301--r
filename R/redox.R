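#' Mean % cysteine thiol oxidation per site and condition
#'
#' For each cysteine site the raw reporter intensities of the thiol
#' oxidation channels (NEM-blocked samples) and, separately, of the
#' total-thiol channels are averaged; the site's mean oxidation intensity
#' is then divided by its mean total-thiol intensity and expressed in
#' percent.
#'
#' For each condition the oxidation channels are that condition's samples;
#' the respective total-thiol channels are those annotated with the same
#' condition when the design provides them, and otherwise all total-thiol
#' channels of the plex(es) containing the condition's samples.
#'
#' Channel-loading normalization happens in up to two steps. If a `global`
#' peptide matrix is supplied, every shared channel is first divided by
#' 2^(its global column median), removing the per-channel loading offset
#' estimated from the unenriched data -- this is essential when a condition
#' has a single total-thiol channel, whose loading cannot be separated from
#' signal using the redox data alone. Then, within the per-condition channel
#' selection, each channel is normalized by its summed intensity over sites
#' quantified in all selected channels, rescaled to the mean column sum of
#' its role group, so residual loading differences among the oxidation
#' channels and among the total-thiol channels cancel while the
#' oxidation/total intensity scale -- the stoichiometry signal itself -- is
#' preserved; `normalize = FALSE` disables this second step. Values above
#' 100% are reported with an `over_range` flag rather than clipped
#' (over-range frequency is itself a QC signal); `clip = TRUE` caps them
#' at 100.
#'
#' @param m a raw-scale redox site-level [AbundanceMatrix-class] whose
#'   `colData` carries `channel_role`, `condition` and `plex_id`.
#' @param global optional log2-scale global *peptide*
#'   [AbundanceMatrix-class] (not batch corrected) used to remove
#'   per-channel loading before the ratio.
#' @param normalize apply within-role column-sum normalization (default
#'   TRUE).
#' @param clip cap values at 100% (default FALSE).
#' @return a data.frame (one row per site x condition) with columns `site`,
#'   `condition`, `pct_oxidation`, `n_oxidation_channels`,
#'   `n_total_channels`, `over_range`. Sites with no total-thiol signal are
#'   excluded; their count is in `attr(, "n_skipped")`.
#' @export
percentOxidation <- function(m, global = NULL, normalize = TRUE,
                             clip = FALSE) {
  requireScale(m, "raw", "percentOxidation")
  cd <- as.data.frame(colData(m))
  if (!any(cd$channel_role == "oxidation") ||
      !any(cd$channel_role == "total_thiol"))
    stop("design must declare at least one oxidation and one total_thiol channel")
  x0 <- abundances(m)
  if (!is.null(global)) {
    requireScale(global, "log2", "percentOxidation")
    if (hasStep(global, "batch-corrected"))
      stop("state error in percentOxidation: global matrix must not be batch corrected")
    shared <- intersect(colnames(m), colnames(global))
    used_roles <- cd$channel_role %in% c("oxidation", "total_thiol")
    missing_glob <- setdiff(colnames(m)[used_roles], shared)
    if (length(missing_glob) > 0)
      warning(sprintf("no global column for sample(s) %s; left unscaled",
                      paste(missing_glob, collapse = ", ")))
    med <- apply(abundances(global)[, shared, drop = FALSE], 2,
                 stats::median, na.rm = TRUE)
    x0[, shared] <- sweep(x0[, shared, drop = FALSE], 2, 2^med, "/")
  }
  conds <- unique(cd$condition[cd$channel_role == "oxidation"])
  out <- list()
  n_skipped <- 0L
  for (cc in conds) {
    ox_cols <- which(cd$channel_role == "oxidation" & cd$condition == cc)
    tt_cols <- which(cd$channel_role == "total_thiol" & cd$condition == cc)
    if (length(tt_cols) == 0) {
      plexes <- unique(cd$plex_id[ox_cols])
      tt_cols <- which(cd$channel_role == "total_thiol" &
                         cd$plex_id %in% plexes)
    }
    x <- x0
    if (normalize) {
      sel <- c(ox_cols, tt_cols)
      xu <- x0[, sel, drop = FALSE]
      complete <- rowSums(is.na(xu)) == 0
      if (!any(complete)) {
        warning("no sites quantified in all selected channels; normalizing by per-column sums over non-missing values")
        csum <- colSums(xu, na.rm = TRUE)
      } else {
        csum <- colSums(xu[complete, , drop = FALSE])
      }
      role <- cd$channel_role[sel]
      group_mean <- tapply(csum, role, mean)
      x[, sel] <- sweep(xu, 2, csum / group_mean[role], "/")
    }
    mo <- rowMeans(x[, ox_cols, drop = FALSE], na.rm = TRUE)
    mt <- rowMeans(x[, tt_cols, drop = FALSE], na.rm = TRUE)
    ok <- !is.nan(mt) & mt > 0 & !is.nan(mo)
    n_skipped <- n_skipped + sum(!ok)
    pct <- 100 * mo[ok] / mt[ok]
    over <- pct > 100
    if (clip) pct <- pmin(pct, 100)
    out[[cc]] <- data.frame(
      site = rownames(x)[ok], condition = cc, pct_oxidation = pct,
      n_oxidation_channels = rowSums(!is.na(x[ok, ox_cols, drop = FALSE])),
      n_total_channels = rowSums(!is.na(x[ok, tt_cols, drop = FALSE])),
      over_range = over, row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Summarize a % oxidation distribution
#'
#' @param st data.frame from [percentOxidation()].
#' @param binWidth histogram bin width in percentage points; default 5.
#' @return list with `deciles` (0%..100% quantiles in steps of 10%),
#'   `breaks`, `counts` (fixed-width bins over \[0, 100\] plus a terminal
#'   over-range bin labelled `">100"`), and `n`.
#' @export
oxidationDistribution <- function(st, binWidth = 5) {
  if (is.null(st) || nrow(st) == 0)
    stop("oxidation distribution undefined: empty stoichiometry table")
  v <- st$pct_oxidation
  breaks <- seq(0, 100, by = binWidth)
  counts <- as.vector(table(cut(pmin(v, 100 - 1e-9)[v <= 100], breaks,
                                right = FALSE, include.lowest = TRUE)))
  counts <- c(counts, sum(v > 100))
  names(counts) <- c(paste0("[", utils::head(breaks, -1), ",",
                            utils::tail(breaks, -1), ")"), ">100")
  list(deciles = stats::quantile(v, probs = seq(0, 1, 0.1)),
       breaks = breaks, counts = counts, n = length(v))
}

#' Write a stoichiometry table to TSV
#' @param st data.frame from [percentOxidation()].
#' @param path output path.
#' @export
writeStoichiometry <- function(st, path) {
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
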