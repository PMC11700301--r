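#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (sort ascending, multiply by n/rank, cumulative
#' minimum from the largest rank, cap at 1, restore input order); delegates
#' to [stats::p.adjust()] after validating the inputs.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

groupColumns <- function(m, group, roles) {
  cd <- as.data.frame(colData(m))
  sel <- cd$condition == group
  if (!is.null(roles) && "channel_role" %in% colnames(cd))
    sel <- sel & cd$channel_role %in% roles
  which(sel)
}

#' Two-sample differential-abundance test
#'
#' Per feature: log2FC = mean(A) - mean(B) and a two-sided two-sample
#' t-test on the log2 values (pooled variance by default), with BH
#' adjustment over all tested features. Features with fewer than
#' `minReplicates` non-missing values in either group are skipped.
#' Zero pooled variance is floored at 1e-12 and flagged instead of
#' producing NaN. With `moderated = TRUE` the per-feature variances are
#' shrunk by limma's empirical-Bayes moderation (an approximation of a
#' moderated-t analysis, documented as such).
#'
#' @param m a log2-scale [AbundanceMatrix-class] with `condition` in its
#'   `colData`.
#' @param groupA,groupB condition labels to contrast (A vs B).
#' @param roles channel roles eligible as replicates; default
#'   oxidation/standard.
#' @param minReplicates minimum non-missing replicates per group; default 2.
#' @param varEqual pooled-variance t-test (default TRUE).
#' @param moderated use limma empirical-Bayes variance moderation.
#' @return data.frame with columns `feature`, `contrast`, `log2fc`, `t`,
#'   `df`, `p`, `adj_p`, `n_a`, `n_b`, `var_floored`.
#' @export
twoSampleTest <- function(m, groupA, groupB,
                          roles = c("oxidation", "standard"),
                          minReplicates = 2, varEqual = TRUE,
                          moderated = FALSE) {
  requireScale(m, "log2", "twoSampleTest")
  ca <- groupColumns(m, groupA, roles)
  cb <- groupColumns(m, groupB, roles)
  if (length(ca) < 2 || length(cb) < 2)
    stop(sprintf("each group needs >= 2 samples (found %d and %d)",
                 length(ca), length(cb)))
  x <- abundances(m)
  a <- x[, ca, drop = FALSE]
  b <- x[, cb, drop = FALSE]
  na <- rowSums(!is.na(a))
  nb <- rowSums(!is.na(b))
  testable <- na >= minReplicates & nb >= minReplicates
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  lfc <- mean_a - mean_b
  res <- data.frame(feature = rownames(x),
                    contrast = paste(groupA, "vs", groupB),
                    log2fc = ifelse(testable, lfc, NA),
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    adj_p = NA_real_, n_a = na, n_b = nb,
                    var_floored = FALSE, stringsAsFactors = FALSE)
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("moderated = TRUE requires the limma package")
    sub <- cbind(a, b)[testable, , drop = FALSE]
    grp <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))), levels = c("B", "A"))
    fit <- limma::eBayes(limma::lmFit(sub, stats::model.matrix(~grp)))
    res$t[testable] <- fit$t[, 2]
    res$df[testable] <- fit$df.total
    res$p[testable] <- fit$p.value[, 2]
  } else {
    var_a <- apply(a, 1, stats::var, na.rm = TRUE)
    var_b <- apply(b, 1, stats::var, na.rm = TRUE)
    if (varEqual) {
      df <- na + nb - 2
      sp2 <- ((na - 1) * var_a + (nb - 1) * var_b) / df
      floored <- testable & sp2 < 1e-12
      sp2 <- pmax(sp2, 1e-12)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
    } else {
      se2a <- var_a / na
      se2b <- var_b / nb
      floored <- testable & (se2a + se2b) < 1e-12
      se <- sqrt(pmax(se2a + se2b, 1e-12))
      df <- (se2a + se2b)^2 /
        (se2a^2 / pmax(na - 1, 1) + se2b^2 / pmax(nb - 1, 1))
    }
    tt <- lfc / se
    res$t[testable] <- tt[testable]
    res$df[testable] <- df[testable]
    res$p[testable] <- 2 * stats::pt(-abs(tt[testable]), df[testable])
    res$var_floored <- floored
  }
  res$adj_p[testable] <- bhAdjust(res$p[testable])
  res
}

#' Features passing the differential-expression cutoffs
#'
#' Default cutoffs follow the reporting convention used throughout the
#' package: BH-adjusted p <= 0.05 and |log2FC| >= 0.8.
#'
#' @param res data.frame from [twoSampleTest()].
#' @param maxAdjP adjusted-p cutoff; default 0.05.
#' @param minAbsLog2FC absolute log2FC cutoff; default 0.8.
#' @return character vector of feature ids.
#' @export
deSignificant <- function(res, maxAdjP = 0.05, minAbsLog2FC = 0.8) {
  ok <- !is.na(res$adj_p) & res$adj_p <= maxAdjP &
    abs(res$log2fc) >= minAbsLog2FC
  res$feature[ok]
}

#' One-way ANOVA across conditions with a reference condition
#'
#' Classic one-way ANOVA (equal-variance F test via
#' [stats::oneway.test()]) per feature over all conditions with at least
#' `minReplicates` non-missing replicates, BH adjustment over tested
#' features, and per-condition log2FC versus the reference condition
#' (the reference's own log2FC is 0).
#'
#' @param m a log2-scale [AbundanceMatrix-class].
#' @param reference reference condition label, e.g. `"Control_4h"`
#'   (the 4 h control).
#' @param roles channel roles eligible as replicates.
#' @param minReplicates minimum non-missing replicates per condition.
#' @return data.frame with `feature`, `f`, `p`, `adj_p`, one
#'   `log2fc_<condition>` column per non-reference condition, and
#'   `max_abs_log2fc`.
#' @export
oneWayAnova <- function(m, reference = "Control_4h",
                        roles = c("oxidation", "standard"),
                        minReplicates = 2) {
  requireScale(m, "log2", "oneWayAnova")
  cd <- as.data.frame(colData(m))
  keep <- if ("channel_role" %in% colnames(cd))
    cd$channel_role %in% roles else rep(TRUE, nrow(cd))
  x <- abundances(m)[, keep, drop = FALSE]
  cond <- as.character(cd$condition[keep])
  conds <- unique(cond)
  if (!reference %in% conds)
    stop(sprintf("reference condition '%s' absent from design", reference))
  others <- setdiff(conds, reference)
  res <- data.frame(feature = rownames(x), f = NA_real_, p = NA_real_,
                    adj_p = NA_real_, stringsAsFactors = FALSE)
  for (cc in others) res[[paste0("log2fc_", cc)]] <- NA_real_
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    ok <- !is.na(v)
    tab <- table(cond[ok])
    use <- names(tab)[tab >= minReplicates]
    if (length(use) < 2 || !reference %in% use) next
    sel <- ok & cond %in% use
    if (all(tapply(v[sel], cond[sel], stats::var) < 1e-24)) {
      res$f[i] <- 0; res$p[i] <- 1
    } else {
      ft <- stats::oneway.test(v[sel] ~ factor(cond[sel]), var.equal = TRUE)
      res$f[i] <- unname(ft$statistic)
      res$p[i] <- ft$p.value
    }
    mu <- tapply(v[ok], cond[ok], mean)
    for (cc in intersect(others, names(mu)))
      res[[paste0("log2fc_", cc)]][i] <- unname(mu[cc] - mu[reference])
  }
  tested <- !is.na(res$p)
  res$adj_p[tested] <- bhAdjust(res$p[tested])
  fc_cols <- grep("^log2fc_", colnames(res))
  res$max_abs_log2fc <- apply(abs(as.matrix(res[, fc_cols, drop = FALSE])),
                              1, function(r) if (all(is.na(r))) NA
                              else max(r, na.rm = TRUE))
  res
}

#' Features passing the ANOVA reporting filter
#'
#' Default: adjusted p <= 0.05 and absolute log2FC >= 1 versus the
#' reference in at least one condition.
#'
#' @param res data.frame from [oneWayAnova()].
#' @param maxAdjP adjusted-p cutoff; default 0.05.
#' @param minAbsLog2FC cutoff on the maximum |log2FC|; default 1.
#' @return character vector of feature ids.
#' @export
anovaSignificant <- function(res, maxAdjP = 0.05, minAbsLog2FC = 1) {
  ok <- !is.na(res$adj_p) & res$adj_p <= maxAdjP &
    !is.na(res$max_abs_log2fc) & res$max_abs_log2fc >= minAbsLog2FC
  res$feature[ok]
}

#' Percent coefficient of variation on raw intensities
#'
#' 100 * sd / mean over the non-missing raw intensities of each replicate
#' group, per feature. Features with zero mean in a group are skipped and
#' counted in `attr(, "n_skipped")`.
#'
#' @param m a raw-scale [AbundanceMatrix-class].
#' @param groupBy `colData` column defining replicate groups; default
#'   `"condition"`.
#' @param roles channel roles to include.
#' @return long data.frame with `feature`, `group`, `cv`, `n`.
#' @export
percentCV <- function(m, groupBy = "condition",
                      roles = c("oxidation", "standard")) {
  requireScale(m, "raw", "percentCV")
  cd <- as.data.frame(colData(m))
  keep <- if ("channel_role" %in% colnames(cd))
    cd$channel_role %in% roles else rep(TRUE, nrow(cd))
  x <- abundances(m)[, keep, drop = FALSE]
  grp <- as.character(cd[[groupBy]][keep])
  out <- list()
  n_skipped <- 0L
  for (g in unique(grp)) {
    sub <- x[, grp == g, drop = FALSE]
    if (ncol(sub) < 2) next
    n_ok <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    sd_ <- apply(sub, 1, stats::sd, na.rm = TRUE)
    usable <- n_ok >= 2 & !is.na(mu) & mu != 0
    n_skipped <- n_skipped + sum(n_ok >= 2 & (is.na(mu) | mu == 0))
    out[[g]] <- data.frame(feature = rownames(sub)[usable], group = g,
                           cv = 100 * sd_[usable] / mu[usable],
                           n = n_ok[usable], row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Median %CV per replicate group
#' @param cvs data.frame from [percentCV()].
#' @return named numeric vector of per-group median %CV.
#' @export
medianCV <- function(cvs) {
  vapply(split(cvs$cv, cvs$group), stats::median, numeric(1))
}

#' Pairwise-complete Pearson correlation between samples
#'
#' Cells computed from fewer than 3 shared non-missing features are set to
#' missing and their count reported in `attr(, "n_flagged")`.
#'
#' @param m a log2-scale [AbundanceMatrix-class].
#' @return symmetric sample x sample correlation matrix with unit diagonal.
#' @export
sampleCorrelation <- function(m) {
  requireScale(m, "log2", "sampleCorrelation")
  x <- abundances(m)
  r <- stats::cor(x, use = "pairwise.complete.obs")
  obs <- !is.na(x)
  shared <- crossprod(obs * 1)
  flag <- shared < 3
  r[flag] <- NA
  diag(r) <- 1
  attr(r, "n_flagged") <- sum(flag[upper.tri(flag)])
  r
}

#' PCA sample scores on complete-case features
#'
#' Centers features (no scaling) and computes a principal component
#' analysis of the samples over features observed in every sample.
#'
#' @param m a log2-scale [AbundanceMatrix-class] with >= 3 samples.
#' @param nComponents number of components to return; default 2.
#' @return list with `scores` (samples x components) and `var_explained`
#'   (percent of variance per component).
#' @export
pcaScores <- function(m, nComponents = 2) {
  requireScale(m, "log2", "pcaScores")
  x <- abundances(m)
  if (ncol(x) < 3) stop("PCA requires at least 3 samples")
  complete <- rowSums(is.na(x)) == 0
  if (sum(complete) < 3)
    stop("PCA requires at least 3 complete-case features")
  pr <- stats::prcomp(t(x[complete, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  k <- min(nComponents, ncol(pr$x))
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)])
}
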