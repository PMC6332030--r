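#' @include eligibility.R
NULL

.GA_DESCRIPTORS <- c("heat_of_combustion", "logP", "logS", "refractivity",
                     "polarizability", "toxicity")

.GA_UNITS <- c(heat_of_combustion = "kJ/mol", logP = "log10 units",
               logS = "log10 mol/L", refractivity = "cm3/mol",
               polarizability = "1e-24 cm3", toxicity = "-log10 mmol/L",
               logBB = "log10 units", heat_of_formation = "kJ/mol")

.canonDescriptor <- function(x) {
  alias <- c(hc = "heat_of_combustion", dhc = "heat_of_combustion",
             heat_of_combustion = "heat_of_combustion",
             hf = "heat_of_formation", heat_of_formation = "heat_of_formation",
             logp = "logP", logs = "logS", mr = "refractivity",
             refractivity = "refractivity", polarizability = "polarizability",
             alpha = "polarizability", toxicity = "toxicity",
             tox = "toxicity", pigc50 = "toxicity", logbb = "logBB")
  hit <- alias[tolower(x)]
  if (is.na(hit)) stop("unknown descriptor id: ", x, call. = FALSE)
  unname(hit)
}

#' Packaged descriptor ids
#'
#' @return Character vector of the six descriptor ids with packaged
#'   contribution tables.
#' @export
availableDescriptors <- function() .GA_DESCRIPTORS

.BACKBONE_RE <- paste0(
  "^(C(\\(\\+\\)|\\(-\\))? (sp3|sp2|sp|aromatic)",
  "|N(\\(\\+\\)|\\(-\\))? (sp3|sp2|sp|aromatic)",
  "|S(\\(\\+\\)|\\(-\\))?[24]|P(\\(\\+\\)|\\(-\\))?[34]",
  "|[OB](\\(\\+\\)|\\(-\\))?|Si(\\(\\+\\)|\\(-\\))?|H)$")

# Validate one atom-group key; returns canonical "backbone|neighbors".
.validateGroupKey <- function(backbone, neighbors) {
  if (!grepl(.BACKBONE_RE, backbone))
    stop("invalid backbone label: '", backbone, "'", call. = FALSE)
  p <- parseNeighborTerm(neighbors)
  canon <- neighborTerm(p$tokens, p$charge, p$pi)
  if (!identical(canon, neighbors))
    stop("non-canonical neighbour term: '", neighbors, "' (canonical: '",
         canon, "')", call. = FALSE)
  paste(backbone, neighbors, sep = "|")
}

#' Load a parameter table
#'
#' Reads a tab-separated parameter table: header comments (\code{# descriptor:},
#' \code{# units:}), a \code{backbone / neighbors / contribution /
#' occurrences / molecules} body (special groups appear under their printed
#' vocabulary, e.g. \code{"Alkane" / "No of C atoms"}; an optional
#' \code{Const} row holds the additive constant) and \code{#stat} footer
#' rows keyed A--H with the fit and cross-validation statistics.
#'
#' @param source Packaged descriptor id (one of
#'   \code{availableDescriptors()}) or path to a TSV file.
#' @return A \linkS4class{ParameterTable}.
#' @examples
#' \dontrun{
#' tab <- loadParameterTable("logP")
#' tableConstant(tab)  # 0.25
#' }
#' @export
loadParameterTable <- function(source) {
  path <- source
  if (!file.exists(source)) {
    id <- tryCatch(.canonDescriptor(source), error = function(e) NA_character_)
    if (!is.na(id) && id %in% .GA_DESCRIPTORS)
      path <- system.file("extdata", "tables", paste0(id, ".tsv"),
                          package = "GroupAdditivity", mustWork = TRUE)
    else stop("no such file or packaged table: ", source, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  descriptor <- sub("^# descriptor:\\s*", "",
                    grep("^# descriptor:", lines, value = TRUE)[1])
  units <- sub("^# units:\\s*", "", grep("^# units:", lines, value = TRUE)[1])
  if (is.na(descriptor)) descriptor <- "custom"
  if (is.na(units)) units <- ""
  constant <- NA_real_
  ent <- list()
  stats <- list(); cvs <- list()
  for (k in seq_along(lines)) {
    l <- lines[k]
    if (!nzchar(trimws(l))) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (startsWith(l, "#stat")) {
      key <- f[2]; label <- f[3]
      val <- suppressWarnings(as.numeric(f[4]))
      n <- suppressWarnings(as.numeric(f[5]))
      switch(key,
             A = { stats$based_on <- n },
             B = { stats$R2 <- val; stats$N <- n },
             C = { stats$MAE <- val },
             D = { stats$SD <- val },
             E = { cvs$k <- val; cvs$N_cv <- n },
             F = { cvs$Q2 <- val },
             G = { cvs$MAE_cv <- val },
             H = { cvs$SD_cv <- val })
      next
    }
    if (startsWith(l, "#")) next
    if (identical(f[1], "backbone")) next
    if (length(f) < 5) f <- c(f, rep("", 5 - length(f)))
    backbone <- f[1]; neighbors <- f[2]
    contribution <- suppressWarnings(as.numeric(f[3]))
    occurrences <- suppressWarnings(as.integer(f[4]))
    molecules <- suppressWarnings(as.integer(f[5]))
    if (is.na(contribution))
      stop(sprintf("%s line %d: malformed contribution", path, k), call. = FALSE)
    if (backbone == "Const") { constant <- contribution; next }
    sp <- .GA_SPECIAL_TSV$id[.GA_SPECIAL_TSV$backbone == backbone &
                             .GA_SPECIAL_TSV$neighbors == neighbors]
    key <- if (length(sp) == 1L) sp else
      tryCatch(.validateGroupKey(backbone, neighbors), error = function(e)
        stop(sprintf("%s line %d: %s", path, k, conditionMessage(e)),
             call. = FALSE))
    if (is.na(occurrences) || is.na(molecules))
      stop(sprintf("%s line %d: malformed counts", path, k), call. = FALSE)
    if (key %in% vapply(ent, `[[`, "", "key"))
      stop(sprintf("%s line %d: duplicate key '%s'", path, k, key),
           call. = FALSE)
    ent[[length(ent) + 1L]] <- list(key = key, backbone = backbone,
                                    neighbors = neighbors,
                                    contribution = contribution,
                                    occurrences = occurrences,
                                    molecules = molecules)
  }
  entries <- if (length(ent)) do.call(rbind, lapply(ent, function(e)
    data.frame(e, stringsAsFactors = FALSE))) else
    data.frame(key = character(), backbone = character(),
               neighbors = character(), contribution = numeric(),
               occurrences = integer(), molecules = integer())
  methods::new("ParameterTable", descriptor = descriptor, units = units,
               constant = constant, entries = entries, stats = stats,
               cvStats = cvs)
}

#' Save a parameter table
#'
#' Writes the TSV format read by \code{\link{loadParameterTable}}; reloading
#' reproduces the table exactly. Output is ASCII (the unicode minus of the
#' printed tables is normalized to \code{-} on transcription already).
#'
#' @param table A \linkS4class{ParameterTable}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
saveParameterTable <- function(table, path) {
  stopifnot(methods::is(table, "ParameterTable"))
  e <- table@entries
  out <- c(sprintf("# descriptor: %s", table@descriptor),
           sprintf("# units: %s", table@units),
           "backbone\tneighbors\tcontribution\toccurrences\tmolecules")
  if (!is.na(table@constant))
    out <- c(out, sprintf("Const\t\t%s\t\t", as.character(table@constant)))
  if (nrow(e))
    out <- c(out, sprintf("%s\t%s\t%s\t%d\t%d", e$backbone, e$neighbors,
                          as.character(e$contribution), e$occurrences,
                          e$molecules))
  s <- table@stats; cv <- table@cvStats
  fmt <- function(key, label, val, n)
    sprintf("#stat\t%s\t%s\t%s\t%s", key, label,
            if (is.null(val)) "" else as.character(val),
            if (is.null(n)) "" else as.character(n))
  if (length(s)) {
    out <- c(out, fmt("A", "based_on", NULL, s$based_on),
             fmt("B", "R2", s$R2, s$N), fmt("C", "MAE", s$MAE, s$N),
             fmt("D", "SD", s$SD, s$N))
  }
  if (length(cv)) {
    out <- c(out, fmt("E", "k", cv$k, cv$N_cv), fmt("F", "Q2", cv$Q2, cv$N_cv),
             fmt("G", "MAE_cv", cv$MAE_cv, cv$N_cv),
             fmt("H", "SD_cv", cv$SD_cv, cv$N_cv))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Packaged parameter table for a descriptor (cached)
#'
#' @param descriptor Descriptor id or alias (e.g. \code{"logP"}, \code{"mr"}).
#' @return A \linkS4class{ParameterTable}.
#' @export
packagedTable <- function(descriptor) {
  id <- .canonDescriptor(descriptor)
  if (!id %in% .GA_DESCRIPTORS)
    stop("no packaged table for descriptor: ", id,
         if (id == "logBB") " (the printed table is an excerpt only; fit your own)",
         call. = FALSE)
  key <- paste0("table_", id)
  if (is.null(.gaCache[[key]])) .gaCache[[key]] <- loadParameterTable(id)
  .gaCache[[key]]
}

# Special-group ids present in a table (these drive which detectors run).
.tableSpecials <- function(table) {
  intersect(table@entries$key, .GA_SPECIAL_IDS)
}

#' Applicability gate: the three-molecule confirmation rule
#'
#' A molecule's descriptor can be evaluated only if each of its atom groups
#' is present in the parameter table and represented by at least three
#' independent training molecules. Special groups never block a prediction.
#'
#' @param profile A \linkS4class{FragmentProfile}.
#' @param table A \linkS4class{ParameterTable}.
#' @param minMolecules Confirmation threshold (default 3).
#' @return An \linkS4class{Applicability}.
#' @export
checkApplicability <- function(profile, table, minMolecules = 3L) {
  stopifnot(methods::is(profile, "FragmentProfile"),
            methods::is(table, "ParameterTable"))
  keys <- names(profile@groupCounts)
  keys <- keys[!.isSpecialId(keys)]
  e <- table@entries
  miss <- keys[!keys %in% e$key]
  present <- setdiff(keys, miss)
  unc <- present[e$molecules[match(present, e$key)] < minMolecules]
  methods::new("Applicability",
               applicable = length(miss) == 0L && length(unc) == 0L,
               missing = miss, unconfirmed = unc)
}
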