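#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `set id`,
#' `description`, then member gene ids. Duplicate members within a set are
#' removed.
#'
#' @param path path to a GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   member ids with a `description` attribute.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("GMT format error at line %d: empty member list", i))
    attr(members, "description") <- f[2]
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list as returned by [readGmt()].
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    desc <- attr(sets[[id]], "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse PTM site ids to their parent protein/gene ids
#'
#' For ORA, site-level hit lists are collapsed so that each parent protein
#' counts once.
#'
#' @param siteIds character vector of ids like `"P12345-C171"`.
#' @return unique accessions.
#' @export
sitesToGenes <- function(siteIds) {
  unique(sub("-[^-]*$", "", siteIds))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set (intersected with the universe first; empty sets are
#' dropped) tests whether the hit list contains more members than expected
#' by chance: p = P\[X >= k\] with X ~ Hypergeometric(N, K, n), where N is
#' the universe size, K the in-universe set size, n the hit-list size and
#' k the observed overlap. P-values are BH-adjusted over the tested sets.
#' The reported q-value equals the BH-adjusted p by default; with
#' `qvalueMethod = "storey"` it is scaled by the Storey pi0 estimate
#' (lambda = 0.5), an approximation of a full q-value computation.
#'
#' @param hits character vector of differential gene ids (must be a subset
#'   of `universe`).
#' @param universe character vector of all tested gene ids.
#' @param sets named list of gene sets (see [readGmt()]).
#' @param qvalueMethod `"bh"` (default) or `"storey"`.
#' @return data.frame with `set`, `description`, `k`, `K`, `n`, `N`, `p`,
#'   `adj_p`, `q`, sorted by p.
#' @export
ora <- function(hits, universe, sets, qvalueMethod = c("bh", "storey")) {
  qvalueMethod <- match.arg(qvalueMethod)
  hits <- unique(hits)
  universe <- unique(universe)
  extra <- setdiff(hits, universe)
  if (length(extra) > 0)
    stop(sprintf("hits not in universe: %s",
                 paste(utils::head(extra, 5), collapse = ", ")))
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    desc <- attr(sets[[id]], "description")
    data.frame(set = id, description = if (is.null(desc)) id else desc,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$adj_p <- bhAdjust(res$p)
  if (qvalueMethod == "storey") {
    pi0 <- min(1, mean(res$p > 0.5) / 0.5)
    res$q <- pmin(1, pi0 * res$adj_p)
  } else {
    res$q <- res$adj_p
  }
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}

#' Gene sets passing the ORA reporting cutoffs
#'
#' Default cutoffs: q <= 0.2 and BH-adjusted p <= 0.05.
#'
#' @param res data.frame from [ora()].
#' @param maxQ q-value cutoff; default 0.2.
#' @param maxAdjP adjusted-p cutoff; default 0.05.
#' @return the filtered rows of `res`.
#' @export
oraSignificant <- function(res, maxQ = 0.2, maxAdjP = 0.05) {
  res[res$q <= maxQ & res$adj_p <= maxAdjP, , drop = FALSE]
}
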