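#' @include specials.R
NULL

# Structural strong-acid detectors (fully ionized in water; excluded from
# partition/solubility training per the method's scope).
.isStrongAcid <- function(mol) {
  a <- mol@atoms
  b <- mol@bonds
  adj <- .adjacency(nrow(a), b)
  dblO <- function(i) {
    inc <- b[(b$i == i | b$j == i) & b$order == 2L, , drop = FALSE]
    part <- ifelse(inc$i == i, inc$j, inc$i)
    sum(a$element[part] == "O")
  }
  for (o in which(a$element == "O")) {
    nbr <- adj[[o]]
    if (!any(a$element[nbr] == "H")) next
    hv <- nbr[a$element[nbr] != "H"]
    for (x in hv) {
      el <- a$element[x]
      if (el == "S" && dblO(x) >= 1L) return(TRUE)      # sulfonic/sulfinic
      if (el == "P" && dblO(x) >= 1L) return(TRUE)      # phosphonic/phosphoric
      if (el == "N" && dblO(x) >= 1L &&
          sum(a$element[adj[[x]]] == "O") >= 2L) return(TRUE)  # nitric ester acid
    }
  }
  # bare hydrogen halides
  if (nrow(a) == 2L && any(a$element %in% .GA_HALOGENS) &&
      any(a$element == "H")) return(TRUE)
  FALSE
}

#' Eligibility of a molecule for a descriptor model
#'
#' Applies the method's scope rules: only elements H, B, C, N, O, P, S, Si
#' and the halogens are supported; net-charged species (zwitterions are
#' fine) are excluded; and for the partition/solubility-type descriptors
#' strong acids are excluded. Which rules apply per descriptor is
#' configurable.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param descriptor Descriptor id.
#' @param config Configuration list.
#' @return List with \code{pass} (logical) and \code{reason} (character,
#'   empty when passing).
#' @export
eligibilityFilter <- function(mol, descriptor, config = gaDefaultConfig()) {
  stopifnot(methods::is(mol, "Molecule"))
  descriptor <- .canonDescriptor(descriptor)
  rules <- config$eligibility
  unk <- setdiff(unique(mol@atoms$element), .GA_ELEMENTS)
  if (length(unk))
    return(list(pass = FALSE,
                reason = paste("unsupported element(s):",
                               paste(unk, collapse = ", "))))
  if (isTRUE(rules$net_charge) && netCharge(mol) != 0L)
    return(list(pass = FALSE,
                reason = sprintf("net charge %+d (only neutral molecules and zwitterions)",
                                 netCharge(mol))))
  if (descriptor %in% rules$strong_acid_descriptors && .isStrongAcid(mol))
    return(list(pass = FALSE, reason = "strong acid"))
  list(pass = TRUE, reason = character())
}
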