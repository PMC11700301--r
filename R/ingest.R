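#' Default modification registry
#'
#' Returns the registry of modification delta masses the pipeline was
#' configured with: methionine oxidation (+15.9949 Da), NEM blocking of
#' cysteine (+125.047679 Da), phosphorylation of S/T/Y (+79.9663 Da), TMT on
#' lysine and the peptide N-terminus (+304.207146 Da, fixed) and lysine
#' acetylation (+42.01056 Da). Under a fixed-TMT search, acetyl-lysine is
#' searched as a dynamic modification whose mass is the difference between
#' the acetyl and TMT masses (see [acetylDeltaVsFixedTMT()]).
#'
#' @return a [ModRegistry-class].
#' @export
#' @examples
#' reg <- defaultModRegistry()
#' modMass(reg, "phospho")
defaultModRegistry <- function() {
  new("ModRegistry", entries = data.frame(
    name = c("oxidation", "nem", "phospho", "tmt", "acetyl"),
    delta_mass = c(15.9949, 125.047679, 79.9663, 304.207146, 42.01056),
    targets = c("M", "C", "S,T,Y", "K,N-term", "K"),
    type = c("dynamic", "dynamic", "dynamic", "fixed", "dynamic"),
    stringsAsFactors = FALSE))
}

#' Look up a modification's monoisotopic delta mass
#'
#' @param registry a [ModRegistry-class].
#' @param name modification name.
#' @return delta mass in Da.
#' @export
modMass <- function(registry, name) {
  stopifnot(is(registry, "ModRegistry"))
  i <- match(name, registry@entries$name)
  if (is.na(i))
    stop(sprintf("modification '%s' not found in registry", name))
  registry@entries$delta_mass[i]
}

#' Dynamic-modification mass for acetyl-lysine under fixed TMT
#'
#' When TMT is searched as a fixed modification on lysine, an acetylated
#' lysine cannot carry the label, so acetylation is searched as a dynamic
#' modification whose delta mass is the acetyl mass minus the TMT mass
#' (a signed value, -262.196586 Da with the default registry).
#'
#' @param registry a [ModRegistry-class] containing `acetyl` and `tmt`.
#' @param acetyl,tmt registry entry names.
#' @return signed delta mass in Da.
#' @export
acetylDeltaVsFixedTMT <- function(registry = defaultModRegistry(),
                                  acetyl = "acetyl", tmt = "tmt") {
  modMass(registry, acetyl) - modMass(registry, tmt)
}

## ---- plex design -----------------------------------------------------------

#' Construct and validate a PlexDesign
#'
#' @param design data.frame with the columns listed under
#'   [PlexDesign-class]. `sample_id` may be `NA`/empty only for channels with
#'   role `"empty"`.
#' @return a validated [PlexDesign-class].
#' @export
plexDesign <- function(design) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(design)) {
    design$sample_id <- as.character(design$sample_id)
    design$sample_id[is.na(design$sample_id)] <- ""
  }
  new("PlexDesign", design = design)
}

#' Read a plex design from a tab-separated file
#'
#' The file must carry a header row naming the [PlexDesign-class] columns.
#'
#' @param path path to a TSV file.
#' @return a validated [PlexDesign-class].
#' @export
readPlexDesign <- function(path) {
  if (!file.exists(path)) stop(sprintf("plex design file not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(PLEX_DESIGN_COLUMNS, colnames(d))
  if (length(missing_cols) > 0)
    stop(sprintf("plex design is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  d$replicate <- as.integer(d$replicate)
  plexDesign(d)
}

#' Write a plex design to a tab-separated file
#' @param design a [PlexDesign-class].
#' @param path output path.
#' @export
writePlexDesign <- function(design, path) {
  stopifnot(is(design, "PlexDesign"))
  utils::write.table(design@design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## sample annotation of the non-empty channels, one row per sample
sampleAnnotation <- function(design) {
  d <- designTable(design)
  d <- d[d$channel_role != "empty", , drop = FALSE]
  rownames(d) <- d$sample_id
  d
}

## ---- PSM tables ------------------------------------------------------------

#' Construct and validate a PsmTable
#'
#' @param psms data.frame of PSM records (see [PsmTable-class] for the
#'   required columns and the `"name@pos"` modification encoding).
#' @param modality data modality: `"global"`, `"redox"`, `"phospho"` or
#'   `"acetyl"`.
#' @return a [PsmTable-class].
#' @export
psmTable <- function(psms, modality = "global") {
  new("PsmTable", psms = as.data.frame(psms, stringsAsFactors = FALSE),
      modality = modality)
}

#' Read a PSM table from a tab-separated file
#'
#' @inheritParams psmTable
#' @param path path to a TSV file with a header row.
#' @return a [PsmTable-class].
#' @export
readPsmTable <- function(path, modality = "global") {
  if (!file.exists(path)) stop(sprintf("PSM table not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(PSM_REQUIRED_COLUMNS, colnames(d))
  if (length(missing_cols) > 0)
    stop(sprintf("PSM table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  d$mods[is.na(d$mods)] <- ""
  psmTable(d, modality)
}

#' Write a PsmTable to a tab-separated file
#' @param psms a [PsmTable-class].
#' @param path output path.
#' @export
writePsmTable <- function(psms, path) {
  stopifnot(is(psms, "PsmTable"))
  utils::write.table(psmData(psms), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse "name@pos" modification strings
#'
#' @param mods character vector of `;`-separated `"name@pos"` entries
#'   (`pos` zero-based within the peptide, `"nt"` for the N-terminus).
#' @return list of data.frames with columns `name` and `pos` (`NA` for the
#'   N-terminus).
#' @export
parseMods <- function(mods) {
  mods[is.na(mods)] <- ""
  lapply(strsplit(mods, ";", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0)
      return(data.frame(name = character(), pos = integer()))
    nm <- sub("@.*$", "", parts)
    ps <- sub("^.*@", "", parts)
    data.frame(name = nm,
               pos = ifelse(ps == "nt", NA_integer_,
                            suppressWarnings(as.integer(ps))),
               stringsAsFactors = FALSE)
  })
}

#' Filter PSMs on mass accuracy and PepQ
#'
#' Retains PSMs with `|mass_error_ppm| <= maxPpm` (inclusive) and
#' `pepq < maxPepQ` (strict). Row order is preserved; the number of removed
#' records is stored in the returned table's `meta$n_filtered` and also
#' reported via [nFiltered()].
#'
#' @param psms a [PsmTable-class].
#' @param maxPpm maximum absolute reporter mass error (ppm); default 10.
#' @param maxPepQ PepQ must be strictly below this; default 0.01.
#' @return the filtered [PsmTable-class].
#' @export
filterPsms <- function(psms, maxPpm = 10, maxPepQ = 0.01) {
  stopifnot(is(psms, "PsmTable"))
  d <- psmData(psms)
  keep <- abs(d$mass_error_ppm) <= maxPpm & d$pepq < maxPepQ
  out <- psms
  out@psms <- d[keep, , drop = FALSE]
  out@meta$n_filtered <- sum(!keep)
  out
}

#' Number of PSMs removed by the last filter
#' @param psms a [PsmTable-class] returned by [filterPsms()].
#' @return integer count (0 if never filtered).
#' @export
nFiltered <- function(psms) {
  n <- psms@meta$n_filtered
  if (is.null(n)) 0L else n
}

## ---- site mapping ----------------------------------------------------------

fastaSequences <- function(fasta) {
  if (is(fasta, "AAStringSet")) {
    seqs <- as.character(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    fastaSequences(Biostrings::readAAStringSet(fasta))
  } else {
    stop("fasta must be an AAStringSet, a named character vector, or a file path")
  }
}

#' Map modified peptides to protein site identifiers
#'
#' Converts within-peptide modification positions to 1-based protein
#' coordinates (`peptide_start + pos`) and builds one site identifier per
#' PSM: `"<accession>-<residue><position>"` for single sites, with all
#' target-mod positions concatenated in ascending order for multi-site
#' peptides (e.g. `"P1-S10S14"`). The peptide sequence is checked against
#' the protein sequence and each mapped residue letter against the FASTA
#' letter at that position.
#'
#' @param psms a [PsmTable-class].
#' @param fasta protein sequences: an `AAStringSet`, a named character
#'   vector, or a FASTA file path. Names must match `protein_accession`.
#' @param targetMod name of the modification defining the sites (e.g.
#'   `"nem"`, `"phospho"`, `"acetyl"`).
#' @return character vector of site ids, one per PSM (`NA` for PSMs without
#'   the target modification).
#' @export
mapToSites <- function(psms, fasta, targetMod) {
  stopifnot(is(psms, "PsmTable"))
  d <- psmData(psms)
  seqs <- fastaSequences(fasta)
  unknown <- setdiff(unique(d$protein_accession), names(seqs))
  if (length(unknown) > 0)
    stop(sprintf("accession(s) absent from FASTA: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  modlist <- parseMods(d$mods)
  out <- rep(NA_character_, nrow(d))
  for (i in seq_len(nrow(d))) {
    m <- modlist[[i]]
    m <- m[m$name == targetMod & !is.na(m$pos), , drop = FALSE]
    if (nrow(m) == 0) next
    pep <- d$peptide[i]
    if (any(m$pos < 0 | m$pos >= nchar(pep)))
      stop(sprintf("PSM %s: modification position outside peptide", d$psm_id[i]))
    acc <- d$protein_accession[i]
    prot <- seqs[[acc]]
    start <- d$peptide_start[i]
    sub <- substr(prot, start, start + nchar(pep) - 1L)
    if (!identical(sub, pep))
      stop(sprintf(
        "PSM %s: peptide does not match %s at position %d (found '%s')",
        d$psm_id[i], acc, start, sub))
    prot_pos <- sort(start + m$pos)
    letters_at <- substring(prot, prot_pos, prot_pos)
    pep_letters <- substring(pep, prot_pos - start + 1L, prot_pos - start + 1L)
    if (!all(letters_at == pep_letters))
      stop(sprintf("PSM %s: residue letter mismatch against FASTA for %s",
                   d$psm_id[i], acc))
    out[i] <- paste0(acc, "-", paste0(letters_at, prot_pos, collapse = ""))
  }
  out
}

#' Split site ids into accession and position components
#'
#' @param siteIds character vector of ids produced by [mapToSites()].
#' @return data.frame with columns `site`, `accession`, `positions` (list
#'   column of integer vectors) and `residues` (list column of letters).
#' @export
parseSiteIds <- function(siteIds) {
  acc <- sub("-[^-]*$", "", siteIds)
  tail <- sub("^.*-", "", siteIds)
  pieces <- regmatches(tail, gregexpr("[A-Z][0-9]+", tail))
  data.frame(site = siteIds, accession = acc,
             positions = I(lapply(pieces, function(p)
               as.integer(sub("^[A-Z]", "", p)))),
             residues = I(lapply(pieces, function(p) substr(p, 1, 1))),
             stringsAsFactors = FALSE)
}

## ---- search-level QC -------------------------------------------------------

#' TMT labeling efficiency from a dynamic-label search
#'
#' For PSM tables searched with the TMT label as a *dynamic* modification,
#' computes the fraction of labelable positions (lysines plus the peptide
#' N-terminus) that actually carry the label.
#'
#' @param psms a [PsmTable-class] whose `mods` include `tmt@...` entries.
#' @param tmtMod registry name of the label; default `"tmt"`.
#' @return fraction in \[0, 1\].
#' @export
labelingEfficiency <- function(psms, tmtMod = "tmt") {
  stopifnot(is(psms, "PsmTable"))
  d <- psmData(psms)
  if (nrow(d) == 0) stop("labeling efficiency undefined: empty PSM table")
  n_k <- vapply(gregexpr("K", d$peptide, fixed = TRUE),
                function(x) sum(x > 0), 0L)
  labelable <- sum(n_k) + nrow(d)   # every peptide has one N-terminus
  if (labelable == 0) stop("labeling efficiency undefined: no labelable positions")
  modlist <- parseMods(d$mods)
  labeled <- sum(vapply(modlist, function(m) sum(m$name == tmtMod), 0L))
  labeled / labelable
}

#' Enrichment selectivity of a PTM-enriched PSM table
#'
#' Fraction of identifications bearing the enrichment target: a cysteine
#' residue for redox (thiol-affinity) enrichment, a phosphosite for IMAC, an
#' acetyl-lysine for acetyl immunoaffinity enrichment. By default the
#' fraction is computed over unique peptides; set `unit = "psms"` to count
#' PSMs instead.
#'
#' @param psms a [PsmTable-class].
#' @param target `"cysteine"`, `"phospho"` or `"acetyl"`.
#' @param unit `"peptides"` (default) or `"psms"`.
#' @return fraction in \[0, 1\].
#' @export
enrichmentSelectivity <- function(psms,
                                  target = c("cysteine", "phospho", "acetyl"),
                                  unit = c("peptides", "psms")) {
  stopifnot(is(psms, "PsmTable"))
  target <- match.arg(target)
  unit <- match.arg(unit)
  d <- psmData(psms)
  if (nrow(d) == 0) stop("selectivity undefined: empty PSM table")
  has_target <- switch(target,
    cysteine = grepl("C", d$peptide, fixed = TRUE),
    phospho  = grepl("phospho@", d$mods, fixed = TRUE),
    acetyl   = grepl("acetyl@", d$mods, fixed = TRUE))
  if (unit == "peptides") {
    hit <- tapply(has_target, d$peptide, any)
    mean(hit)
  } else {
    mean(has_target)
  }
}
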