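#' @include fragment.R
NULL

.GEOMETRY_SPECIALS <- c("HBridge", "HH_lt2", "HH_2to2.3",
                        "Angle60", "Angle90", "Angle102")

#' Detect special-group counts
#'
#' Computes the requested non-atom-group correction terms:
#' \describe{
#'   \item{HBridge}{Number of acidic hydrogens (on neutral O/N/S) within the
#'     hydrogen-bond distance window of a neutral basic acceptor (O/N/F)
#'     closing a 5--7-membered pseudo-ring. Charged donors/acceptors are
#'     excluded (those contacts are salt bridges, not hydrogen bridges).}
#'   \item{HH_lt2, HH_2to2.3}{Nonbonded intramolecular H--H pairs binned by
#'     distance (< 2 Angstrom; 2--2.3 Angstrom). Pairs on the same or on
#'     adjacent heavy atoms are excluded; each unordered pair counts once.}
#'   \item{Angle60, Angle90, Angle102}{Ring-internal heavy-atom bond angles
#'     binned at (<= 60.5], (60.5, 90] and (90, 102] degrees (ring strain).}
#'   \item{Alkane, UnsatHC}{Per-carbon correction for pure hydrocarbons:
#'     the carbon count is emitted under \code{Alkane} for saturated and
#'     under \code{UnsatHC} for aromatic/olefinic/alkyne hydrocarbons
#'     (mutually exclusive; zero for heteroatom-containing molecules).}
#'   \item{XCH2n}{Number of CH2 groups in unbranched CH2 chains (length
#'     > 1) ending in CH3, NH2, OH, SH or halogen; by default only chains
#'     attached to an aromatic ring qualify (config
#'     \code{specials$xch2n_policy = "unrestricted"} lifts the
#'     restriction).}
#' }
#' Geometry-dependent detectors require 3D coordinates and raise an error
#' without them; request only composition detectors for 2D input.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param specialIds Ids to detect.
#' @param config Configuration list, see \code{\link{gaDefaultConfig}}.
#' @return Named numeric vector over \code{specialIds}.
#' @export
detectSpecialGroups <- function(mol, specialIds = .GA_SPECIAL_IDS,
                                config = gaDefaultConfig()) {
  stopifnot(methods::is(mol, "Molecule"))
  bad <- setdiff(specialIds, .GA_SPECIAL_IDS)
  if (length(bad)) stop("unknown special ids: ", paste(bad, collapse = ", "))
  geo <- intersect(specialIds, .GEOMETRY_SPECIALS)
  if (length(geo) && !mol@is3d)
    stop("special group(s) ", paste(geo, collapse = ", "),
         " require 3D coordinates ('", mol@name,
         "' has none); embed a conformer or exclude the detector",
         call. = FALSE)
  out <- stats::setNames(numeric(length(specialIds)), specialIds)
  sc <- config$specials
  if (any(c("HH_lt2", "HH_2to2.3") %in% specialIds)) {
    hh <- .hhContacts(mol, minPath = sc$hh_min_path)
    if ("HH_lt2" %in% specialIds) out["HH_lt2"] <- hh["lt2"]
    if ("HH_2to2.3" %in% specialIds) out["HH_2to2.3"] <- hh["w2to2.3"]
  }
  if ("HBridge" %in% specialIds)
    out["HBridge"] <- .hBridges(mol, maxDist = sc$hbridge_max_dist,
                                ringSizes = sc$hbridge_ring)
  if (any(c("Angle60", "Angle90", "Angle102") %in% specialIds)) {
    ang <- .ringAngles(mol, bins = sc$angle_bins)
    for (id in intersect(specialIds, c("Angle60", "Angle90", "Angle102")))
      out[id] <- ang[[id]]
  }
  if (any(c("Alkane", "UnsatHC") %in% specialIds)) {
    hc <- .hydrocarbonCorrection(mol)
    if ("Alkane" %in% specialIds) out["Alkane"] <- hc["Alkane"]
    if ("UnsatHC" %in% specialIds) out["UnsatHC"] <- hc["UnsatHC"]
  }
  if ("XCH2n" %in% specialIds)
    out["XCH2n"] <- .xch2nCount(mol, policy = sc$xch2n_policy,
                                countMode = sc$xch2n_count)
  out
}

.coords <- function(mol) as.matrix(mol@atoms[, c("x", "y", "z")])

.dist <- function(xyz, a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))

# Nonbonded H-H pairs binned by distance; pairs whose carrier heavy atoms
# are identical or adjacent (bond path < minPath between the H atoms) are
# excluded, so geminal/vicinal contacts never count.
.hhContacts <- function(mol, minPath = 4L) {
  a <- mol@atoms
  hs <- which(a$element == "H")
  res <- c(lt2 = 0, w2to2.3 = 0)
  if (length(hs) < 2L) return(res)
  D <- .bondDistances(nrow(a), mol@bonds)
  xyz <- .coords(mol)
  for (p in seq_along(hs)) for (q in seq_len(p - 1L)) {
    h1 <- hs[p]; h2 <- hs[q]
    path <- D[h1, h2]
    if (is.na(path) || path >= minPath) {
      d <- .dist(xyz, h1, h2)
      if (d < 2) res["lt2"] <- res["lt2"] + 1
      else if (d <= 2.3) res["w2to2.3"] <- res["w2to2.3"] + 1
    }
  }
  res
}

.hBridges <- function(mol, maxDist = 2.5, ringSizes = c(5L, 7L)) {
  a <- mol@atoms
  b <- mol@bonds
  adj <- .adjacency(nrow(a), b)
  D <- .bondDistances(nrow(a), b)
  xyz <- .coords(mol)
  hs <- which(a$element == "H")
  acceptors <- which(a$element %in% c("O", "N", "F") & a$charge == 0)
  n <- 0
  for (h in hs) {
    don <- adj[[h]]
    if (length(don) != 1L) next
    d <- don[1]
    if (!a$element[d] %in% c("O", "N", "S") || a$charge[d] != 0) next
    for (acc in acceptors) {
      if (acc == d || acc %in% adj[[h]]) next
      path <- D[d, acc]
      if (is.na(path)) next
      ring <- path + 2L  # D, chain atoms, A, H close the pseudo-ring
      if (ring < ringSizes[1] || ring > ringSizes[2]) next
      if (.dist(xyz, h, acc) <= maxDist) { n <- n + 1; break }
    }
  }
  n
}

.ringAngles <- function(mol, bins = c(60.5, 90, 102)) {
  out <- c(Angle60 = 0, Angle90 = 0, Angle102 = 0)
  if (!length(mol@rings)) return(out)
  xyz <- .coords(mol)
  seen <- character()
  for (r in mol@rings) {
    nr <- length(r)
    for (k in seq_len(nr)) {
      j <- r[k]
      i <- r[if (k == 1L) nr else k - 1L]
      l <- r[if (k == nr) 1L else k + 1L]
      id <- paste(j, min(i, l), max(i, l))
      if (id %in% seen) next
      seen <- c(seen, id)
      v1 <- xyz[i, ] - xyz[j, ]
      v2 <- xyz[l, ] - xyz[j, ]
      cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cs))) * 180 / pi
      if (ang <= bins[1]) out["Angle60"] <- out["Angle60"] + 1
      else if (ang <= bins[2]) out["Angle90"] <- out["Angle90"] + 1
      else if (ang <= bins[3]) out["Angle102"] <- out["Angle102"] + 1
    }
  }
  out
}

.hydrocarbonCorrection <- function(mol) {
  a <- mol@atoms
  out <- c(Alkane = 0, UnsatHC = 0)
  if (!all(a$element %in% c("C", "H"))) return(out)
  nC <- sum(a$element == "C")
  b <- mol@bonds
  cc <- a$element[b$i] == "C" & a$element[b$j] == "C"
  unsat <- any(cc & (b$order >= 2L | b$aromatic))
  if (unsat) out["UnsatHC"] <- nC else out["Alkane"] <- nC
  out
}

# Unbranched CH2 chains with a polar/terminal end group X.
.xch2nCount <- function(mol, policy = c("aromatic", "unrestricted"),
                        countMode = c("n", "n-1")) {
  policy <- match.arg(policy)
  countMode <- match.arg(countMode)
  a <- mol@atoms
  b <- mol@bonds
  adj <- .adjacency(nrow(a), b)
  heavy <- function(i) adj[[i]][a$element[adj[[i]]] != "H"]
  nH <- function(i) sum(a$element[adj[[i]]] == "H")
  allSingle <- function(i) {
    inc <- b[b$i == i | b$j == i, , drop = FALSE]
    all(inc$order == 1L) && !any(inc$aromatic)
  }
  isCH2 <- vapply(seq_len(nrow(a)), function(i)
    a$element[i] == "C" && !a$aromatic[i] && nH(i) == 2L &&
      length(heavy(i)) == 2L && allSingle(i), logical(1))
  isX <- function(i) {
    el <- a$element[i]
    (el == "C" && nH(i) == 3L) ||                       # CH3
      (el == "N" && nH(i) == 2L && length(heavy(i)) == 1L) ||
      (el == "O" && nH(i) == 1L) ||
      (el == "S" && nH(i) == 1L) ||
      el %in% .GA_HALOGENS
  }
  total <- 0
  visited <- logical(nrow(a))
  for (s in which(isCH2)) {
    if (visited[s]) next
    hv <- heavy(s)
    ext <- hv[!isCH2[hv]]
    if (length(ext) != 1L && !(length(ext) == 2L)) next
    if (length(ext) == 0L) next           # interior of a longer run
    # walk the run starting from a terminal CH2
    run <- s; prev <- ext[1]
    cur <- s
    repeat {
      nxt <- setdiff(heavy(cur), prev)
      if (length(nxt) != 1L || !isCH2[nxt]) break
      prev <- cur; cur <- nxt; run <- c(run, cur)
    }
    visited[run] <- TRUE
    endA <- setdiff(heavy(run[1]), run)          # attachment side
    endB <- setdiff(heavy(run[length(run)]), run)
    if (!length(endA) || !length(endB)) next     # ring-closed chain
    n <- length(run)
    if (n <= 1L) next
    qualifies <- function(att, term) {
      okX <- isX(term)
      okAtt <- if (policy == "aromatic") a$aromatic[att] else TRUE
      okX && okAtt
    }
    if (qualifies(endA, endB) || qualifies(endB, endA))
      total <- total + if (countMode == "n") n else n - 1L
  }
  total
}
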