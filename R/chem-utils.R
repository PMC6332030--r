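#' @include AllClasses.R
NULL

# Elements supported by the additivity scheme. Iodine is rendered "J" inside
# neighbour terms for readability, following the table vocabulary.
.GA_ELEMENTS <- c("H", "B", "C", "N", "O", "S", "P", "Si", "F", "Cl", "Br", "I")
.GA_RANK <- stats::setNames(seq_along(.GA_ELEMENTS), .GA_ELEMENTS)
.GA_HALOGENS <- c("F", "Cl", "Br", "I")
.GA_BACKBONE_ELEMENTS <- c("B", "C", "N", "O", "S", "P", "Si")

.GA_SPECIAL_IDS <- c("HBridge", "HH_lt2", "HH_2to2.3", "Angle60", "Angle90",
                     "Angle102", "Alkane", "UnsatHC", "XCH2n")

# Printed table vocabulary <-> internal special ids
.GA_SPECIAL_TSV <- data.frame(
  id = .GA_SPECIAL_IDS,
  backbone = c("H", "H", "H", "Angle60", "Angle90", "Angle102",
               "Alkane", "Unsaturated HC", "X(CH2)n"),
  neighbors = c("H Acceptor", ".H", "..H", "", "", "",
                "No of C atoms", "No of C atoms", "No of CH2 groups"),
  stringsAsFactors = FALSE)

.isSpecialId <- function(key) key %in% .GA_SPECIAL_IDS

.gaCache <- new.env(parent = emptyenv())

.obOptions <- function(...) {
  nm <- c(...)
  if (!length(nm)) return(NULL)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

# SMILES -> V2000 molfile text with explicit hydrogens (no coordinates).
.smilesToMolblock <- function(smiles) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = smiles,
                                               options = .obOptions("h"))),
    error = function(e) "")
  if (!nzchar(txt) || !grepl("V2000", txt, fixed = TRUE))
    stop("SMILES parse error in '", smiles, "'", call. = FALSE)
  txt
}

# Molfile -> molfile with explicit hydrogens added (idempotent); normalizes
# charge bookkeeping through Open Babel.
.molblockAddH <- function(molblock) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "SDF", source = molblock,
                                               options = .obOptions("h"))),
    error = function(e) "")
  if (!nzchar(txt) || !grepl("V2000", txt, fixed = TRUE))
    stop("unparsable molfile entry", call. = FALSE)
  txt
}

# Deterministic seeded 3D embedding for a vector of SMILES via RDKit
# (ETKDGv3 + MMFF/UFF cleanup). Returns molblock strings.
.rdkitEmbed <- function(smiles, seed = 1L) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for conformer embedding")
  script <- system.file("python", "embed_conformers.py",
                        package = "GroupAdditivity", mustWork = TRUE)
  inp <- jsonlite::toJSON(list(smiles = as.list(smiles), seed = as.integer(seed)),
                          auto_unbox = TRUE)
  out <- suppressWarnings(system2(py, shQuote(script), input = inp,
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("conformer embedding subprocess failed")
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
  bad <- vapply(res, is.null, logical(1))
  if (any(bad))
    stop("conformer embedding failed for: ",
         paste(smiles[bad], collapse = ", "))
  vapply(res, identity, character(1))
}

# Parse one V2000 molfile (text) into raw atom/bond tables. Formal charges
# are taken from "M  CHG" lines (authoritative), falling back to the legacy
# atom-block charge codes.
.parseMolblock <- function(molblock, name = NULL) {
  ln <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  ln <- sub("\r$", "", ln)
  if (length(ln) < 4) stop("unparsable molfile entry")
  counts <- ln[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("unparsable molfile counts line")
  if (na == 0) stop("empty molfile entry")
  at <- ln[4 + seq_len(na)]
  bd <- if (nb > 0) ln[4 + na + seq_len(nb)] else character()
  element <- trimws(substr(at, 32, 34))
  x <- as.numeric(substr(at, 1, 10))
  y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  ccode <- suppressWarnings(as.integer(substr(at, 37, 39)))
  charge <- integer(na)
  known <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  hit <- !is.na(ccode) & ccode %in% as.integer(names(known))
  charge[hit] <- known[as.character(ccode[hit])]
  chg <- grep("^M  CHG", ln, value = TRUE)
  if (length(chg)) {
    charge <- integer(na)  # M CHG supersedes all legacy codes
    for (l in chg) {
      v <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))),
                                                "\\s+")[[1]]))
      n <- v[1]
      for (k in seq_len(n)) charge[v[2 * k]] <- v[2 * k + 1]
    }
  }
  i <- as.integer(substr(bd, 1, 3))
  j <- as.integer(substr(bd, 4, 6))
  ord <- as.integer(substr(bd, 7, 9))
  dim3 <- grepl("3D", substr(ln[2], 21, 22), fixed = TRUE) ||
    (any(is.finite(z)) && stats::sd(c(z, 0)) > 1e-3 && stats::sd(c(y, 0)) > 1e-3 &&
       stats::sd(c(x, 0)) > 1e-3)
  unk <- setdiff(unique(element), .GA_ELEMENTS)
  if (length(unk))
    stop("unsupported element(s): ", paste(unk, collapse = ", "), call. = FALSE)
  if (is.null(name)) {
    name <- trimws(ln[1])
    if (!nzchar(name)) name <- "unnamed"
  }
  list(name = name,
       atoms = data.frame(element = element, charge = charge,
                          x = x, y = y, z = z, stringsAsFactors = FALSE),
       bonds = data.frame(i = i, j = j, order = ord),
       is3d = isTRUE(dim3))
}

# Adjacency list over a bond table.
.adjacency <- function(natoms, bonds) {
  adj <- vector("list", natoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# All-pairs topological (bond-count) distances by BFS; molecules are small.
.bondDistances <- function(natoms, bonds) {
  adj <- .adjacency(natoms, bonds)
  D <- matrix(NA_integer_, natoms, natoms)
  for (s in seq_len(natoms)) {
    d <- rep(NA_integer_, natoms); d[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    D[s, ] <- d
  }
  D
}

# Smallest rings (atom index vectors) via ChemmineR ring perception.
.findRings <- function(atoms, bonds, upper = 8) {
  if (!nrow(bonds)) return(list())
  sdf <- .toSDF(atoms, bonds)
  r <- tryCatch(ChemmineR::rings(sdf, upper = upper, type = "all", arom = FALSE),
                error = function(e) list())
  lapply(unname(r), function(v) as.integer(sub("^.*_", "", v)))
}

# Minimal SDF object for ChemmineR graph utilities.
.toSDF <- function(atoms, bonds) {
  na <- nrow(atoms)
  ab <- cbind(C1 = atoms$x, C2 = atoms$y, C3 = atoms$z)
  rownames(ab) <- paste(atoms$element, seq_len(na), sep = "_")
  bb <- cbind(C1 = bonds$i, C2 = bonds$j, C3 = bonds$order)
  rownames(bb) <- seq_len(nrow(bonds))
  header <- c(Molecule_Name = "mol", Source = "", Comment = "", Counts_Line =
                sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nrow(bonds)))
  new("SDF", header = header, atomblock = ab, bondblock = bb,
      datablock = character())
}

# Benzenoid aromaticity: six-membered rings of C/N in which every ring atom
# carries a double bond to an atom of the candidate ring system (handles
# fused kekule structures iteratively). Five-membered heteroaromatics stay
# in their kekule forms, which is the form the parameter vocabulary types.
.perceiveAromaticity <- function(atoms, bonds, rings) {
  na <- nrow(atoms)
  aromAtoms <- logical(na)
  aromBonds <- logical(nrow(bonds))
  cand <- Filter(function(r) length(r) == 6 &&
                   all(atoms$element[r] %in% c("C", "N")), rings)
  if (!length(cand)) return(list(atoms = aromAtoms, bonds = aromBonds))
  dpart <- vector("list", na)  # double-bond partners
  for (k in seq_len(nrow(bonds))) if (bonds$order[k] == 2L) {
    dpart[[bonds$i[k]]] <- c(dpart[[bonds$i[k]]], bonds$j[k])
    dpart[[bonds$j[k]]] <- c(dpart[[bonds$j[k]]], bonds$i[k])
  }
  alive <- rep(TRUE, length(cand))
  repeat {
    pool <- unique(unlist(cand[alive]))
    drop <- FALSE
    for (q in which(alive)) {
      ok <- all(vapply(cand[[q]], function(a)
        length(intersect(dpart[[a]], pool)) > 0, logical(1)))
      if (!ok) { alive[q] <- FALSE; drop <- TRUE }
    }
    if (!drop || !any(alive)) break
  }
  for (q in which(alive)) {
    r <- cand[[q]]
    aromAtoms[r] <- TRUE
    for (k in seq_len(nrow(bonds)))
      if (bonds$i[k] %in% r && bonds$j[k] %in% r) aromBonds[k] <- TRUE
  }
  list(atoms = aromAtoms, bonds = aromBonds)
}

# Normalize charge-separated sulfoxide/sulfone and phosphorus ylide oxygen
# representations ([S+]-[O-]) to the hypervalent S=O form the vocabulary uses.
.normalizeHypervalent <- function(atoms, bonds) {
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    ei <- atoms$element[i]; ej <- atoms$element[j]
    swap <- ej %in% c("S", "P") && ei == "O"
    if (swap) { tmp <- i; i <- j; j <- tmp; ei <- atoms$element[i]; ej <- atoms$element[j] }
    if (ei %in% c("S", "P") && ej == "O" && bonds$order[k] == 1L &&
        atoms$charge[i] > 0 && atoms$charge[j] < 0) {
      bonds$order[k] <- 2L
      atoms$charge[i] <- atoms$charge[i] - 1L
      atoms$charge[j] <- atoms$charge[j] + 1L
    }
  }
  list(atoms = atoms, bonds = bonds)
}
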