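#' @include atomtype.R
NULL

.PREFIXES <- c("", "=", "#", ":")  # single, double, triple, aromatic

#' Render a canonical neighbour term
#'
#' Neighbour atoms are listed element-major in the fixed rank order
#' H > B > C > N > O > S > P > Si > F > Cl > Br > J (iodine is written
#' \code{J}), and within one element by bond type (single, double
#' \code{=}, triple \code{#}, aromatic \code{:}); counts are appended when
#' greater than one. A nonzero net charge of the neighbour atoms appends
#' \code{(+)}/\code{(-)}, and a positive pi-conjugation count appends
#' \code{(pi)}, \code{(2pi)} or \code{(3pi)}.
#'
#' @param tokens \code{data.frame} with columns \code{prefix} (one of
#'   \code{""}, \code{"="}, \code{"#"}, \code{":"}), \code{element} and
#'   \code{count}.
#' @param charge Net formal charge of the neighbour atoms.
#' @param pi Pi-conjugation count (0--3); only meaningful for backbones
#'   \code{N sp3}, \code{O} and \code{S2}.
#' @return Canonical term string, e.g. \code{"H2CN(+)"} or \code{"CO=O"}.
#' @export
neighborTerm <- function(tokens, charge = 0L, pi = 0L) {
  stopifnot(is.data.frame(tokens),
            all(c("prefix", "element", "count") %in% names(tokens)))
  if (nrow(tokens)) {
    bad <- setdiff(tokens$element, c(.GA_ELEMENTS, "J"))
    if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
    if (any(tokens$count < 1)) stop("token counts must be >= 1")
    el <- ifelse(tokens$element == "I", "J", tokens$element)
    rank <- .GA_RANK[ifelse(el == "J", "I", el)]
    agg <- stats::aggregate(tokens$count,
                            by = list(prefix = tokens$prefix, element = el,
                                      rank = rank),
                            FUN = sum)
    agg <- agg[order(agg$rank, match(agg$prefix, .PREFIXES)), , drop = FALSE]
    body <- paste0(agg$prefix, agg$element,
                   ifelse(agg$x > 1L, agg$x, ""), collapse = "")
  } else body <- ""
  suffix <- ""
  if (charge > 0) suffix <- "(+)" else if (charge < 0) suffix <- "(-)"
  if (pi > 0) suffix <- paste0(suffix, if (pi == 1L) "(pi)" else
                               sprintf("(%dpi)", min(pi, 3L)))
  paste0(body, suffix)
}

#' Parse a neighbour term
#'
#' Inverse of \code{\link{neighborTerm}}; \code{neighborTerm} applied to the
#' result reproduces the canonical string (canonical form is a fixed point).
#'
#' @param term Neighbour term string.
#' @return List with \code{tokens} (\code{data.frame}), \code{charge} and
#'   \code{pi}.
#' @export
parseNeighborTerm <- function(term) {
  stopifnot(is.character(term), length(term) == 1L)
  s <- term
  pi <- 0L
  m <- regmatches(s, regexec("\\((([123])?)pi\\)$", s))[[1]]
  if (length(m)) {
    pi <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    s <- sub("\\(([123])?pi\\)$", "", s)
  }
  charge <- 0L
  if (grepl("\\(\\+\\)$", s)) { charge <- 1L; s <- sub("\\(\\+\\)$", "", s) }
  else if (grepl("\\(-\\)$", s)) { charge <- -1L; s <- sub("\\(-\\)$", "", s) }
  pat <- "([=#:]?)(Cl|Br|Si|[HBCNOSPFJ])([0-9]*)"
  toks <- data.frame(prefix = character(), element = character(),
                     count = integer(), stringsAsFactors = FALSE)
  while (nzchar(s)) {
    m <- regmatches(s, regexec(paste0("^", pat), s))[[1]]
    if (!length(m)) stop("unparsable neighbour term: '", term, "'", call. = FALSE)
    toks <- rbind(toks, data.frame(
      prefix = m[2], element = if (m[3] == "J") "I" else m[3],
      count = if (nzchar(m[4])) as.integer(m[4]) else 1L,
      stringsAsFactors = FALSE))
    s <- substr(s, nchar(m[1]) + 1L, nchar(s))
  }
  list(tokens = toks, charge = charge, pi = pi)
}

# Pi-suffix eligibility: neutral N sp3, O and S2 backbones with only single
# bonds (lone-pair conjugation annotation).
.piEligible <- function(mol, atom, label) {
  if (!label %in% c("N sp3", "O", "S2")) return(FALSE)
  b <- mol@bonds
  inc <- b[b$i == atom | b$j == atom, , drop = FALSE]
  all(inc$order == 1L) && !any(inc$aromatic)
}

# A neighbour is conjugated if it is aromatic or carries a double/triple
# bond to a third atom.
.isConjugated <- function(mol, atom) {
  if (mol@atoms$aromatic[atom]) return(TRUE)
  b <- mol@bonds
  inc <- b[b$i == atom | b$j == atom, , drop = FALSE]
  any(inc$order >= 2L)
}

#' Atom-group key of one backbone atom
#'
#' Builds the canonical (backbone label, neighbour term) pair for an atom.
#' Atoms bound to fewer than two other atoms (counting hydrogen) and atoms
#' that cannot be backbones (H, halogens) return \code{NULL}; they appear
#' only inside the neighbour terms of their partners. Backbones of type
#' \code{N sp3}, \code{O} and \code{S2} receive a pi suffix counting
#' neighbours that belong to conjugated moieties.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param atom Atom index.
#' @return Character vector \code{c(backbone, neighbors)} or \code{NULL}.
#' @examples
#' \dontrun{
#' m <- parseSmiles("c1ccccc1O")
#' groupKey(m, 7)   # c("O", "HC(pi)")
#' }
#' @export
groupKey <- function(mol, atom) {
  stopifnot(methods::is(mol, "Molecule"))
  el <- mol@atoms$element[atom]
  if (!el %in% .GA_BACKBONE_ELEMENTS) return(NULL)
  b <- mol@bonds
  inc <- b[b$i == atom | b$j == atom, , drop = FALSE]
  if (nrow(inc) < 2L) return(NULL)
  nbr <- ifelse(inc$i == atom, inc$j, inc$i)
  prefix <- ifelse(inc$aromatic, ":",
                   ifelse(inc$order == 2L, "=",
                          ifelse(inc$order == 3L, "#", "")))
  tokens <- data.frame(prefix = prefix, element = mol@atoms$element[nbr],
                       count = 1L, stringsAsFactors = FALSE)
  charge <- sum(mol@atoms$charge[nbr])
  label <- backboneLabel(mol, atom)
  pi <- 0L
  if (.piEligible(mol, atom, label))
    pi <- sum(vapply(nbr, function(n) .isConjugated(mol, n), logical(1)))
  c(label, neighborTerm(tokens, charge = charge, pi = min(pi, 3L)))
}

#' @describeIn fragmentMolecule Fragment a molecule into its atom groups.
#'
#' Every backbone atom contributes exactly one atom-group key; the result is
#' invariant under atom and bond reordering. Special-group counts are not
#' part of the fragmentation step (see \code{\link{detectSpecialGroups}}).
#' @export
setMethod("fragmentMolecule", "Molecule", function(mol, ...) {
  keys <- character()
  for (a in seq_len(nrow(mol@atoms))) {
    gk <- groupKey(mol, a)
    if (!is.null(gk)) keys <- c(keys, paste(gk[1], gk[2], sep = "|"))
  }
  cnt <- if (length(keys)) table(keys) else table(character())
  methods::new("FragmentProfile",
               groupCounts = stats::setNames(as.numeric(cnt), names(cnt)),
               specialCounts = stats::setNames(numeric(), character()),
               name = mol@name)
})

#' Complete fragment profile (atom groups plus selected special groups)
#'
#' @param mol A \linkS4class{Molecule}.
#' @param specialIds Character vector of special-group ids to detect
#'   (subset of \code{c("HBridge", "HH_lt2", "HH_2to2.3", "Angle60",
#'   "Angle90", "Angle102", "Alkane", "UnsatHC", "XCH2n")}).
#' @param config Configuration list, see \code{\link{gaDefaultConfig}}.
#' @return A \linkS4class{FragmentProfile}.
#' @export
moleculeProfile <- function(mol, specialIds = character(),
                            config = gaDefaultConfig()) {
  prof <- fragmentMolecule(mol)
  if (length(specialIds))
    prof@specialCounts <- detectSpecialGroups(mol, specialIds, config)
  prof
}
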