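#' Read a predicted protein structure (PDB or mmCIF)
#'
#' Extracts the alpha-carbon trace of a single-chain model (the AlphaFold2
#' convention). Per-residue confidence (pLDDT, 0-100) is read from the
#' B-factor column, again by AlphaFold2 convention. Residues without a CA
#' atom are skipped with a warning; multi-chain files are rejected with a
#' request to extract one chain.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param accession protein identifier; defaults to the file name.
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, accession = NULL) {
  if (!file.exists(path)) stop(sprintf("structure file not found: %s", path))
  if (is.null(accession))
    accession <- sub("\\.(pdb|cif|mmcif)$", "", basename(path),
                     ignore.case = TRUE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    ## bio3d's mmCIF reader emits advisory warnings (beta status, secondary
    ## structure records) that are irrelevant to the CA trace
    withCallingHandlers(bio3d::read.cif(path), warning = function(w) {
      if (grepl("beta version|helix/sheet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  } else {
    bio3d::read.pdb(path)
  }
  atoms <- pdb$atom
  chains <- unique(atoms$chain[!is.na(atoms$chain)])
  if (length(chains) > 1)
    stop(sprintf(
      "structure has %d chains (%s); extract a single chain before loading",
      length(chains), paste(chains, collapse = ", ")))
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  all_res <- unique(atoms$resno)
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0)
    warning(sprintf("residue(s) without CA atom skipped: %s",
                    paste(missing_ca, collapse = ", ")))
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(ca$resid))
  new("StructureModel", accession = accession,
      residues = data.frame(pos = ca$resno, aa = aa1,
                            x = ca$x, y = ca$y, z = ca$z,
                            plddt = ca$b, stringsAsFactors = FALSE))
}

parseResidueLabels <- function(residues) {
  if (is.data.frame(residues)) {
    data.frame(label = paste0(residues$aa, residues$pos),
               aa = residues$aa, pos = as.integer(residues$pos),
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = residues,
               aa = substr(residues, 1, 1),
               pos = as.integer(sub("^[A-Za-z]", "", residues)),
               stringsAsFactors = FALSE)
  }
}

matchResidues <- function(model, req) {
  r <- residueTable(model)
  idx <- match(req$pos, r$pos)
  if (any(is.na(idx)))
    stop(sprintf("residue position(s) absent from %s: %s", model@accession,
                 paste(req$pos[is.na(idx)], collapse = ", ")))
  bad <- r$aa[idx] != req$aa
  if (any(bad))
    stop(sprintf(
      "residue letter mismatch in %s at position(s) %s (structure has %s)",
      model@accession,
      paste(req$pos[bad], collapse = ", "),
      paste(r$aa[idx][bad], collapse = ", ")))
  idx
}

#' Pairwise CA-CA Euclidean distances among selected residues
#'
#' Builds the symmetric matrix of 3D Euclidean distances (in Angstrom)
#' between the alpha carbons of the requested residues, annotated with each
#' residue's pLDDT and a low-confidence flag (pLDDT below `plddtThreshold`,
#' default 70, the conventional AlphaFold2 "low" boundary). Distances
#' involving flagged residues should be interpreted cautiously: low pLDDT
#' marks disordered or unreliable regions.
#'
#' @param model a [StructureModel-class].
#' @param residues residues of interest: character labels like
#'   `c("C42", "K26")` or a data.frame with `aa` and `pos`. Each residue
#'   letter is validated against the structure.
#' @param plddtThreshold flagging threshold; default 70.
#' @return a [SiteDistanceMatrix-class].
#' @export
siteDistanceMatrix <- function(model, residues, plddtThreshold = 70) {
  stopifnot(is(model, "StructureModel"))
  req <- parseResidueLabels(residues)
  idx <- matchResidues(model, req)
  r <- residueTable(model)
  xyz <- as.matrix(r[idx, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(req$label, req$label)
  plddt <- stats::setNames(r$plddt[idx], req$label)
  new("SiteDistanceMatrix", distances = d, plddt = plddt,
      lowConfidence = plddt < plddtThreshold,
      threshold = plddtThreshold, accession = model@accession)
}

#' Flag low-confidence residues
#'
#' @inheritParams siteDistanceMatrix
#' @param threshold pLDDT threshold; residues with pLDDT strictly below it
#'   are flagged. Default 70.
#' @return named logical vector, one flag per requested residue.
#' @export
flagLowConfidence <- function(model, residues, threshold = 70) {
  stopifnot(is(model, "StructureModel"))
  req <- parseResidueLabels(residues)
  idx <- matchResidues(model, req)
  stats::setNames(residueTable(model)$plddt[idx] < threshold, req$label)
}
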