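#' Accessors for ptmplex classes
#'
#' Small accessor generics: `designTable()` returns the underlying
#' data.frame of a [PlexDesign-class]; `psmData()` the PSM records of a
#' [PsmTable-class]; `psmModality()` its modality; `abundances()` the assay
#' matrix of an [AbundanceMatrix-class]; `assayScale()`, `assayModality()`
#' and `processingLog()` its scale/modality/processing metadata;
#' `residueTable()` the residue table of a [StructureModel-class];
#' `distances()` the distance matrix of a [SiteDistanceMatrix-class].
#'
#' @param x an object of the documented class.
#' @return the accessed component.
#' @name accessors
#' @aliases designTable psmData psmModality abundances assayScale
#'   assayModality processingLog residueTable distances
NULL

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setGeneric("psmData", function(x) standardGeneric("psmData"))
#' @rdname accessors
#' @export
setGeneric("psmModality", function(x) standardGeneric("psmModality"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("assayScale", function(x) standardGeneric("assayScale"))
#' @rdname accessors
#' @export
setGeneric("assayModality", function(x) standardGeneric("assayModality"))
#' @rdname accessors
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))
#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname accessors
setMethod("designTable", "PlexDesign", function(x) x@design)
#' @rdname accessors
setMethod("psmData", "PsmTable", function(x) x@psms)
#' @rdname accessors
setMethod("psmModality", "PsmTable", function(x) x@modality)
#' @rdname accessors
setMethod("abundances", "AbundanceMatrix",
          function(x) SummarizedExperiment::assay(x))
#' @rdname accessors
setMethod("assayScale", "AbundanceMatrix", function(x) metadata(x)$scale)
#' @rdname accessors
setMethod("assayModality", "AbundanceMatrix", function(x) metadata(x)$modality)
#' @rdname accessors
setMethod("processingLog", "AbundanceMatrix", function(x) metadata(x)$processing)
#' @rdname accessors
setMethod("residueTable", "StructureModel", function(x) x@residues)
#' @rdname accessors
setMethod("distances", "SiteDistanceMatrix", function(x) x@distances)

setMethod("show", "PlexDesign", function(object) {
  d <- object@design
  n_empty <- sum(d$channel_role == "empty")
  cat(sprintf(
    "PlexDesign: %d channels in %d plex(es), %d samples (%d empty channels)\n",
    nrow(d), length(unique(d$plex_id)), nrow(d) - n_empty, n_empty))
  roles <- table(d$channel_role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "),
      "\n")
  invisible(NULL)
})

setMethod("show", "ModRegistry", function(object) {
  cat(sprintf("ModRegistry with %d entries:\n", nrow(object@entries)))
  print(object@entries, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "PsmTable", function(object) {
  d <- object@psms
  nch <- length(grep("^intensity_", colnames(d)))
  cat(sprintf("PsmTable (%s): %d PSMs, %d proteins, %d reporter channels\n",
              object@modality, nrow(d),
              length(unique(d$protein_accession)), nch))
  invisible(NULL)
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix (%s, %s): %d features x %d samples\n",
              assayModality(object), assayScale(object),
              nrow(object), ncol(object)))
  steps <- processingLog(object)
  cat("  processing:",
      if (length(steps)) paste(steps, collapse = " -> ") else "(none)", "\n")
  invisible(NULL)
})

setMethod("show", "StructureModel", function(object) {
  r <- object@residues
  cat(sprintf("StructureModel %s: %d residues, pLDDT %.1f-%.1f\n",
              object@accession, nrow(r), min(r$plddt), max(r$plddt)))
  invisible(NULL)
})

setMethod("show", "SiteDistanceMatrix", function(object) {
  cat(sprintf("SiteDistanceMatrix %s: %d sites (%d low-confidence at pLDDT < %g)\n",
              object@accession, nrow(object@distances),
              sum(object@lowConfidence), object@threshold))
  print(round(object@distances, 1))
  invisible(NULL)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d proteins; sites: %s; seed %s\n",
              nrow(object@proteins),
              paste(sprintf("%s=%d", names(object@sites),
                            vapply(object@sites, nrow, 0L)), collapse = ", "),
              object@params$seed))
  invisible(NULL)
})
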