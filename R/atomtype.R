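#' @include molecule.R
NULL

#' Backbone atom-type label
#'
#' Renders the backbone-atom label of the additivity vocabulary for one atom:
#' element, charge mark and subtype. Carbon and nitrogen are subtyped by
#' aromaticity or bond pattern (\code{aromatic}; \code{sp} for one triple or
#' two cumulated double bonds; \code{sp2} for one double bond; else
#' \code{sp3}); sulfur by its connection count (\code{S2} for two
#' connections, else \code{S4}); phosphorus likewise (\code{P3}/\code{P4});
#' oxygen, boron and silicon carry the bare element symbol. A nonzero formal
#' charge renders as \code{(+)}/\code{(-)} directly after the element, e.g.
#' \code{"N(+) sp2"}. Hydrogen and the halogens are never backbone atoms.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param atom Atom index.
#' @return Label string, e.g. \code{"C sp3"}, \code{"N(+) sp2"}, \code{"S4"}.
#' @examples
#' \dontrun{
#' m <- parseSmiles("C=C=C")            # allene
#' backboneLabel(m, 2)                  # "C sp"
#' }
#' @export
backboneLabel <- function(mol, atom) {
  stopifnot(methods::is(mol, "Molecule"))
  el <- mol@atoms$element[atom]
  if (!el %in% .GA_BACKBONE_ELEMENTS)
    stop(sprintf("atom %d (%s) cannot be a backbone atom", atom, el),
         call. = FALSE)
  chg <- mol@atoms$charge[atom]
  mark <- if (chg > 0) "(+)" else if (chg < 0) "(-)" else ""
  b <- mol@bonds
  inc <- b[b$i == atom | b$j == atom, , drop = FALSE]
  ndbl <- sum(inc$order == 2L & !inc$aromatic)
  ntrp <- sum(inc$order == 3L)
  ncon <- nrow(inc)
  sub <- switch(el,
    C = , N = {
      if (mol@atoms$aromatic[atom]) "aromatic"
      else if (ntrp >= 1L || ndbl >= 2L) "sp"
      else if (ndbl == 1L) "sp2"
      else "sp3"
    },
    S = if (ncon == 2L) "2" else "4",
    P = if (ncon == 3L) "3" else "4",
    "")
  if (el %in% c("C", "N")) paste0(el, mark, " ", sub)
  else if (el %in% c("S", "P")) paste0(el, mark, sub)
  else paste0(el, mark)
}
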