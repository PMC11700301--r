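#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @import SummarizedExperiment
NULL

PLEX_DESIGN_COLUMNS <- c("plex_id", "channel_id", "sample_id", "condition",
                         "timepoint", "replicate", "channel_role", "batch")

CHANNEL_ROLES <- c("oxidation", "total_thiol", "standard", "empty")

PSM_REQUIRED_COLUMNS <- c("psm_id", "plex_id", "peptide", "mods",
                          "protein_accession", "peptide_start",
                          "mass_error_ppm", "pepq")

#' PlexDesign: sample layout of a multiplexed (TMT) experiment
#'
#' Maps each (plex, channel) pair to a sample with its condition, timepoint,
#' replicate number, channel role (`oxidation`, `total_thiol`, `standard` or
#' `empty`) and batch. Channel roles distinguish NEM-blocked thiol-oxidation
#' samples from unblocked total-thiol samples in redox designs; `empty`
#' channels are skipped TMT channels that carry no sample.
#'
#' @slot design data.frame with columns `plex_id`, `channel_id`, `sample_id`,
#'   `condition`, `timepoint`, `replicate`, `channel_role`, `batch`.
#' @export
setClass("PlexDesign", slots = c(design = "data.frame"))

setValidity("PlexDesign", function(object) {
  d <- object@design
  missing_cols <- setdiff(PLEX_DESIGN_COLUMNS, colnames(d))
  if (length(missing_cols) > 0)
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  key <- paste(d$plex_id, d$channel_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    return(sprintf("duplicate (plex, channel) pair(s): %s",
                   paste(gsub("\r", ":", dup), collapse = ", ")))
  }
  if (!all(d$channel_role %in% CHANNEL_ROLES))
    return(sprintf("channel_role must be one of %s",
                   paste(CHANNEL_ROLES, collapse = ", ")))
  empty <- d$channel_role == "empty"
  has_sample <- !is.na(d$sample_id) & nzchar(d$sample_id)
  if (any(empty & has_sample))
    return("empty channels must not carry a sample_id")
  if (any(!empty & !has_sample))
    return("non-empty channels must carry a sample_id")
  if (anyDuplicated(d$sample_id[has_sample]))
    return("sample_id values must be unique across non-empty channels")
  bpp <- unique(d[, c("plex_id", "batch")])
  if (anyDuplicated(bpp$plex_id))
    return("each plex_id must map to exactly one batch")
  TRUE
})

#' ModRegistry: modification mass registry
#'
#' Monoisotopic delta masses (Da), target residues and fixed/dynamic status
#' of the modifications handled by the pipeline.
#'
#' @slot entries data.frame with columns `name`, `delta_mass`, `targets`
#'   (comma-separated residue letters, `N-term` allowed) and `type`
#'   (`"fixed"` or `"dynamic"`).
#' @export
setClass("ModRegistry", slots = c(entries = "data.frame"))

setValidity("ModRegistry", function(object) {
  e <- object@entries
  need <- c("name", "delta_mass", "targets", "type")
  if (!all(need %in% colnames(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(e$name)) return("modification names must be unique")
  if (!all(is.finite(e$delta_mass))) return("delta masses must be finite")
  if (any(!nzchar(e$targets)))
    return("each entry must name at least one target residue or N-term")
  if (!all(e$type %in% c("fixed", "dynamic")))
    return("type must be 'fixed' or 'dynamic'")
  TRUE
})

#' PsmTable: peptide-spectrum matches with reporter intensities
#'
#' One table per data modality (global / redox / phospho / acetyl). Each row
#' is a PSM carrying the bare peptide sequence, its modifications encoded as
#' `"name@pos"` (zero-based position within the peptide, `nt` for the
#' N-terminus; multiple mods separated by `;`), the protein accession and
#' 1-based start of the peptide in the protein, search-quality fields
#' (`mass_error_ppm`, `pepq`) and one raw reporter-ion intensity column per
#' channel, named `intensity_<channel_id>`.
#'
#' @slot psms data.frame of PSM records.
#' @slot modality character scalar: `"global"`, `"redox"`, `"phospho"` or
#'   `"acetyl"`.
#' @slot meta list of bookkeeping values (e.g. `n_filtered`).
#' @export
setClass("PsmTable",
         slots = c(psms = "data.frame", modality = "character", meta = "list"),
         prototype = prototype(modality = "global", meta = list()))

setValidity("PsmTable", function(object) {
  d <- object@psms
  missing_cols <- setdiff(PSM_REQUIRED_COLUMNS, colnames(d))
  if (length(missing_cols) > 0)
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (length(object@modality) != 1L)
    return("modality must be a single string")
  if (nrow(d) > 0 && !all(is.finite(d$mass_error_ppm)))
    return("mass_error_ppm must be finite")
  if (nrow(d) > 0 && (any(d$pepq < 0) || any(d$pepq > 1)))
    return("pepq must lie in [0, 1]")
  ic <- grep("^intensity_", colnames(d), value = TRUE)
  if (length(ic) > 0) {
    v <- unlist(d[ic], use.names = FALSE)
    if (any(v < 0, na.rm = TRUE))
      return("raw reporter intensities must be >= 0")
  }
  TRUE
})

#' AbundanceMatrix: features-by-samples abundance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' of raw or log2 abundances for proteins, peptides or PTM sites. Sample
#' metadata (condition, timepoint, replicate, plex, batch, channel role)
#' lives in `colData`; feature metadata (accession, site positions) in
#' `rowData`. The scale (`"raw"`/`"log2"`), data modality and the ordered
#' log of processing steps applied so far are kept in `metadata()` and are
#' used to enforce the order of the normalization chain.
#'
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  md <- metadata(object)
  if (is.null(md$scale) || !md$scale %in% c("raw", "log2"))
    return("metadata scale must be 'raw' or 'log2'")
  if (is.null(md$modality))
    return("metadata modality must be set")
  if (is.null(md$processing) || !is.character(md$processing))
    return("metadata processing must be a character vector")
  if (anyDuplicated(rownames(object)))
    return("duplicate feature ids")
  if (anyDuplicated(colnames(object)))
    return("duplicate sample ids")
  x <- SummarizedExperiment::assay(object)
  if (md$scale == "raw" && any(x < 0, na.rm = TRUE))
    return("raw abundances must be >= 0")
  if (md$scale == "log2" && any(!is.finite(x[!is.na(x)])))
    return("log2 abundances must be finite where not missing")
  TRUE
})

#' StructureModel: alpha-carbon trace of a predicted protein structure
#'
#' Per-residue CA coordinates (Angstrom) and per-residue confidence (pLDDT,
#' 0-100, read from the B-factor field by AlphaFold2 convention).
#'
#' @slot accession character scalar identifying the protein.
#' @slot residues data.frame with columns `pos` (1-based), `aa` (one-letter
#'   residue code), `x`, `y`, `z`, `plddt`.
#' @export
setClass("StructureModel",
         slots = c(accession = "character", residues = "data.frame"))

setValidity("StructureModel", function(object) {
  r <- object@residues
  need <- c("pos", "aa", "x", "y", "z", "plddt")
  if (!all(need %in% colnames(r)))
    return(sprintf("residues must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r) == 0) return("structure has no residues with CA atoms")
  if (anyDuplicated(r$pos)) return("residue positions must be unique")
  if (is.unsorted(r$pos)) return("residue positions must be ascending")
  if (!all(is.finite(c(r$x, r$y, r$z)))) return("coordinates must be finite")
  if (any(r$plddt < 0 | r$plddt > 100)) return("pLDDT must lie in [0, 100]")
  TRUE
})

#' SiteDistanceMatrix: pairwise CA-CA distances among modified residues
#'
#' Symmetric matrix of 3D Euclidean distances (Angstrom) between the alpha
#' carbons of selected residues, with per-site pLDDT and low-confidence
#' flags (sites under the pLDDT threshold should be interpreted cautiously).
#'
#' @slot distances symmetric numeric matrix with zero diagonal, dimnames are
#'   site labels such as `"C42"`.
#' @slot plddt named numeric vector of per-site confidence.
#' @slot lowConfidence named logical vector of flags.
#' @slot threshold pLDDT threshold used for flagging.
#' @slot accession protein identifier.
#' @export
setClass("SiteDistanceMatrix",
         slots = c(distances = "matrix", plddt = "numeric",
                   lowConfidence = "logical", threshold = "numeric",
                   accession = "character"))

setValidity("SiteDistanceMatrix", function(object) {
  d <- object@distances
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (any(d < 0)) return("distances must be >= 0")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (any(abs(d - t(d)) > 1e-9)) return("distance matrix must be symmetric")
  if (length(object@plddt) != nrow(d) ||
      length(object@lowConfidence) != nrow(d))
    return("per-site annotations must match matrix dimension")
  TRUE
})

#' SyntheticTruth: ground-truth parameters of a simulated experiment
#'
#' Holds everything the synthetic-data generator drew: per-protein baselines
#' and condition effects, per-site occupancy effects or oxidation
#' stoichiometries, per-channel loading factors, per-plex batch offsets,
#' protein sequences, the plex design, and the generator parameters
#' (noise sd, dropout, seed).
#'
#' @slot proteins data.frame of protein-level truth.
#' @slot sites named list of per-modality site-level truth data.frames.
#' @slot channels data.frame of per-(plex, channel) loading factors (log2).
#' @slot plexes data.frame of per-plex batch offsets (log2).
#' @slot design [PlexDesign-class] used for simulation.
#' @slot sequences named character vector of protein sequences.
#' @slot params list of generator parameters (includes `seed`).
#' @export
setClass("SyntheticTruth",
         slots = c(proteins = "data.frame", sites = "list",
                   channels = "data.frame", plexes = "data.frame",
                   design = "PlexDesign", sequences = "character",
                   params = "list"))

setValidity("SyntheticTruth", function(object) {
  p <- object@params
  if (!is.null(p$dropout) && (p$dropout < 0 || p$dropout >= 1))
    return("dropout must lie in [0, 1)")
  for (mod in names(object@sites)) {
    s <- object@sites[[mod]]
    if (mod == "redox" && !is.null(s$stoichiometry)) {
      if (any(s$stoichiometry <= 0 | s$stoichiometry > 100))
        return("oxidation stoichiometries must lie in (0, 100]")
    }
  }
  TRUE
})
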