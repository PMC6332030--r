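#' @include chem-utils.R
NULL

# Assemble a Molecule from a V2000 molblock: hypervalent normalization, ring
# perception, benzenoid aromaticity.
.moleculeFromMolblock <- function(molblock, name = NULL,
                                  properties = stats::setNames(numeric(), character())) {
  raw <- .parseMolblock(molblock, name)
  nh <- .normalizeHypervalent(raw$atoms, raw$bonds)
  rings <- .findRings(nh$atoms, nh$bonds)
  arom <- .perceiveAromaticity(nh$atoms, nh$bonds, rings)
  atoms <- nh$atoms
  atoms$aromatic <- arom$atoms
  atoms <- atoms[, c("element", "charge", "aromatic", "x", "y", "z")]
  bonds <- nh$bonds
  bonds$aromatic <- arom$bonds
  methods::new("Molecule", name = raw$name, atoms = atoms, bonds = bonds,
               rings = rings, properties = properties, is3d = raw$is3d)
}

#' Parse a SMILES string into a Molecule
#'
#' Aromaticity is perceived on the kekule structure with the benzenoid model
#' used by the parameter vocabulary (six-membered C/N rings only); implicit
#' hydrogens are expanded to explicit atoms. With \code{embed3d = TRUE} a
#' deterministic seeded 3D conformer is embedded (RDKit ETKDGv3 + force-field
#' cleanup), which the geometry-dependent special groups require.
#'
#' @param smiles SMILES string (use explicit charges for zwitterions).
#' @param name Molecule name; defaults to the SMILES string.
#' @param embed3d Embed a 3D conformer.
#' @param seed Integer seed for the conformer embedding.
#' @return A \linkS4class{Molecule}.
#' @examples
#' \dontrun{
#' phenol <- parseSmiles("c1ccccc1O", "phenol")
#' }
#' @export
parseSmiles <- function(smiles, name = smiles, embed3d = FALSE, seed = 1L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  molblock <- if (embed3d) .rdkitEmbed(smiles, seed) else .smilesToMolblock(smiles)
  .moleculeFromMolblock(molblock, name = name)
}

#' Read molecules from an SDF/MOL file
#'
#' Reads a V2000 SD file (or single molfile), expanding hydrogens and
#' perceiving aromaticity as in \code{\link{parseSmiles}}. SD data fields
#' whose tags match the configured descriptor tags populate the molecules'
#' \code{properties}. Records that cannot be parsed (or contain unsupported
#' elements) are skipped and reported in the \code{"errors"} attribute of the
#' result, a \code{data.frame} with the failing entry index and message.
#'
#' @param path Path to an SDF or MOL file.
#' @param propertyTags Named character vector mapping descriptor ids to SD
#'   tags; default from \code{\link{gaDefaultConfig}}.
#' @return List of \linkS4class{Molecule} (possibly empty), with an
#'   \code{"errors"} attribute.
#' @export
readSDF <- function(path, propertyTags = gaDefaultConfig()$property_tags) {
  stopifnot(file.exists(path))
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || all(!nzchar(trimws(txt))))
    return(structure(list(), errors = data.frame(index = integer(),
                                                 message = character())))
  sstr <- ChemmineR::read.SDFstr(path)
  recs <- methods::as(sstr, "list")
  mols <- list()
  errs <- data.frame(index = integer(), message = character(),
                     stringsAsFactors = FALSE)
  for (idx in seq_along(recs)) {
    rec <- recs[[idx]]
    res <- tryCatch({
      endl <- grep("^M  END", rec)
      if (!length(endl)) stop("no 'M  END' terminator")
      molblock <- paste(rec[seq_len(endl[1])], collapse = "\n")
      props <- .sdfDataFields(rec[-seq_len(endl[1])], propertyTags)
      mb <- .molblockAddH(molblock)
      .moleculeFromMolblock(mb, properties = props)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(index = idx, message = conditionMessage(res),
                                     stringsAsFactors = FALSE))
    } else {
      if (!nzchar(res@name) || res@name == "unnamed")
        res@name <- trimws(rec[1])
      mols[[length(mols) + 1L]] <- res
    }
  }
  if (nrow(errs))
    warning(sprintf("%d SDF record(s) rejected (see attr(, 'errors'))", nrow(errs)))
  structure(mols, errors = errs)
}

.sdfDataFields <- function(lines, propertyTags) {
  props <- stats::setNames(numeric(), character())
  tagAt <- grep("^>\\s*<", lines)
  for (t in tagAt) {
    tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", lines[t])
    hit <- names(propertyTags)[match(tag, propertyTags)]
    if (!is.na(hit) && t < length(lines)) {
      val <- suppressWarnings(as.numeric(trimws(lines[t + 1L])))
      if (!is.na(val)) props[hit] <- val
    }
  }
  props
}

# V2000 writer (ChemmineR's writer does not emit M CHG formal charges, which
# the zwitterion conventions here depend on).
.molblockFromMolecule <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  hdr <- c(mol@name, sprintf("  GroupAdditivity%s", if (mol@is3d) " 3D" else " 2D"), "")
  cnt <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                a$x, a$y, a$z, a$element)
  bd <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order) else character()
  chg <- which(a$charge != 0)
  chgl <- character()
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      chgl <- c(chgl, paste0("M  CHG", sprintf("%3d", length(grp)),
                             paste(sprintf("%4d%4d", grp, a$charge[grp]),
                                   collapse = "")))
    }
  }
  paste(c(hdr, cnt, at, bd, chgl, "M  END"), collapse = "\n")
}

#' Write a Molecule as SMILES
#'
#' @param mol A \linkS4class{Molecule}.
#' @return A SMILES string.
#' @export
asSmiles <- function(mol) {
  stopifnot(methods::is(mol, "Molecule"))
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "SMI", source = .molblockFromMolecule(mol)))
  smi <- strsplit(trimws(out), "[ \t]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("SMILES export failed")
  smi
}

#' Embed a deterministic 3D conformer for a Molecule
#'
#' Round-trips the connectivity through SMILES into the seeded RDKit
#' embedding; experimental properties and the name are preserved.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param seed Integer seed.
#' @return A \linkS4class{Molecule} with 3D coordinates.
#' @export
embedConformer <- function(mol, seed = 1L) {
  out <- parseSmiles(asSmiles(mol), name = mol@name, embed3d = TRUE, seed = seed)
  out@properties <- mol@properties
  out
}

#' Molecular formula as element counts
#'
#' Counts include explicit hydrogens (all molecules in this package carry
#' explicit H).
#'
#' @param mol A \linkS4class{Molecule}.
#' @return Named integer vector in Hill order (C, H, then alphabetical).
#' @examples
#' \dontrun{
#' molecularFormula(parseSmiles("CC(=O)C"))  # C3 H6 O1
#' }
#' @export
molecularFormula <- function(mol) {
  stopifnot(methods::is(mol, "Molecule"))
  tab <- table(mol@atoms$element)
  cnt <- stats::setNames(as.integer(tab), names(tab))
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  cnt[ord]
}

#' Net formal charge of a molecule
#'
#' @param mol A \linkS4class{Molecule}.
#' @return Integer net charge.
#' @export
netCharge <- function(mol) {
  stopifnot(methods::is(mol, "Molecule"))
  as.integer(sum(mol@atoms$charge))
}
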