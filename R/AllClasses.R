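#' @include AllGenerics.R
NULL

#' Molecule: an attributed molecular graph
#'
#' Explicit-hydrogen molecular graph with elements, formal charges, kekule
#' bond orders, benzenoid aromaticity flags, optional 3D coordinates and a
#' named vector of experimental descriptor values.
#'
#' @slot name Molecule title.
#' @slot atoms \code{data.frame} with columns \code{element}, \code{charge},
#'   \code{aromatic}, \code{x}, \code{y}, \code{z}.
#' @slot bonds \code{data.frame} with columns \code{i}, \code{j},
#'   \code{order} (1, 2, 3; kekule order for aromatic bonds) and
#'   \code{aromatic} (bond belongs to an aromatic ring).
#' @slot rings List of integer vectors: smallest rings (atom indices).
#' @slot properties Named numeric vector of experimental descriptor values.
#' @slot is3d Whether coordinates are a 3D conformer.
#'
#' @aliases atoms bonds molName properties has3d
#' @name Molecule-class
#' @exportClass Molecule
setClass("Molecule",
  representation(name = "character", atoms = "data.frame", bonds = "data.frame",
                 rings = "list", properties = "numeric", is3d = "logical"))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msg <- character()
  need <- c("element", "charge", "aromatic", "x", "y", "z")
  if (!all(need %in% names(a))) msg <- c(msg, "atoms lacks required columns")
  if (nrow(b)) {
    if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a)))
      msg <- c(msg, "bond endpoints index valid atoms")
    if (any(b$i == b$j)) msg <- c(msg, "self-bonds are not allowed")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) msg <- c(msg, "at most one bond per atom pair")
    if (any(b$aromatic & !(a$aromatic[b$i] & a$aromatic[b$j])))
      msg <- c(msg, "aromatic bonds must connect aromatic atoms")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentProfile: atom-group and special-group counts of one molecule
#'
#' Multiset of canonical atom-group keys (the \eqn{A_i} of the additivity
#' equation) plus special-group counts (the \eqn{B_j}).
#'
#' @slot groupCounts Named integer vector; names are canonical
#'   \code{"backbone|neighbors"} key strings.
#' @slot specialCounts Named numeric vector over special-group ids.
#' @slot name Molecule name the profile was computed from.
#'
#' @aliases groupCounts specialCounts
#' @name FragmentProfile-class
#' @exportClass FragmentProfile
setClass("FragmentProfile",
  representation(groupCounts = "numeric", specialCounts = "numeric",
                 name = "character"))

setValidity("FragmentProfile", function(object) {
  msg <- character()
  if (length(object@groupCounts) && (is.null(names(object@groupCounts)) ||
      any(!nzchar(names(object@groupCounts)))))
    msg <- c(msg, "groupCounts must be named")
  if (any(object@groupCounts <= 0)) msg <- c(msg, "group counts must be positive")
  if (any(object@specialCounts < 0)) msg <- c(msg, "special counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ParameterTable: fitted group contributions for one descriptor
#'
#' @slot descriptor Descriptor id (e.g. \code{"logP"}).
#' @slot units Descriptor units.
#' @slot constant The additive constant C (\code{NA} when the table has none).
#' @slot entries \code{data.frame}: \code{key}, \code{backbone},
#'   \code{neighbors}, \code{contribution}, \code{occurrences},
#'   \code{molecules}.
#' @slot stats Named list with fit statistics (\code{R2}, \code{MAE},
#'   \code{SD}, \code{N}, \code{based_on}), possibly empty.
#' @slot cvStats Named list with cross-validation statistics (\code{k},
#'   \code{Q2}, \code{MAE_cv}, \code{SD_cv}, \code{N_cv}), possibly empty.
#'
#' @aliases descriptorId tableEntries tableConstant tableUnits fitStats cvStats
#' @name ParameterTable-class
#' @exportClass ParameterTable
setClass("ParameterTable",
  representation(descriptor = "character", units = "character",
                 constant = "numeric", entries = "data.frame",
                 stats = "list", cvStats = "list"))

setValidity("ParameterTable", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("key", "backbone", "neighbors", "contribution", "occurrences", "molecules")
  if (!all(need %in% names(e))) return("entries lacks required columns")
  if (nrow(e)) {
    if (anyDuplicated(e$key)) msg <- c(msg, "duplicate keys")
    bad <- e$occurrences < e$molecules | e$molecules < 1
    if (any(bad)) msg <- c(msg, paste("occurrences >= molecules >= 1 violated for",
                                      paste(e$key[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Applicability: result of the three-molecule confirmation gate
#'
#' A molecule is evaluable only when every atom group it contains is present
#' in the parameter table and confirmed by at least three independent
#' training molecules. Special groups never block.
#'
#' @slot applicable Logical verdict.
#' @slot missing Atom-group keys absent from the table.
#' @slot unconfirmed Keys present but backed by fewer than three molecules.
#'
#' @name Applicability-class
#' @exportClass Applicability
setClass("Applicability",
  representation(applicable = "logical", missing = "character",
                 unconfirmed = "character"))

setValidity("Applicability", function(object) {
  ok <- length(object@missing) == 0 && length(object@unconfirmed) == 0
  if (identical(object@applicable, ok)) TRUE else
    "verdict must be applicable iff missing and unconfirmed are empty"
})

#' Prediction: a descriptor value with its contribution breakdown
#'
#' @slot descriptor Descriptor id.
#' @slot value Predicted value (\code{NA} on rejection).
#' @slot applicability \linkS4class{Applicability} gate result.
#' @slot breakdown \code{data.frame}: \code{key}, \code{count},
#'   \code{contribution}, \code{subtotal} (includes the constant row).
#' @slot units Descriptor units.
#'
#' @aliases predictedValue breakdown isApplicable
#' @name Prediction-class
#' @exportClass Prediction
setClass("Prediction",
  representation(descriptor = "character", value = "numeric",
                 applicability = "Applicability", breakdown = "data.frame",
                 units = "character"))

#' CVReport: pooled shifted k-fold cross-validation results
#'
#' @slot k Number of folds.
#' @slot runs \code{data.frame} per run: \code{run}, \code{train},
#'   \code{test}, \code{evaluable}.
#' @slot predictions \code{data.frame}: \code{id}, \code{experimental},
#'   \code{predicted} pooled over all runs (evaluable test molecules only).
#' @slot Q2 Cross-validated coefficient of determination.
#' @slot MAE Mean absolute deviation of pooled predictions.
#' @slot SD Sample standard deviation of pooled residuals.
#' @slot N Number of pooled (evaluable) test molecules.
#'
#' @name CVReport-class
#' @exportClass CVReport
setClass("CVReport",
  representation(k = "integer", runs = "data.frame", predictions = "data.frame",
                 Q2 = "numeric", MAE = "numeric", SD = "numeric", N = "integer"))

setValidity("CVReport", function(object) {
  if (object@N != nrow(object@predictions)) "N must equal pooled prediction count"
  else if (anyDuplicated(object@predictions$id)) "each molecule tested at most once"
  else TRUE
})

#' SyntheticSet: profiles generated from known ground-truth contributions
#'
#' @slot profiles List of \linkS4class{FragmentProfile}.
#' @slot truth Named numeric vector of generating contributions.
#' @slot constant Generating additive constant.
#' @slot sigma Gaussian noise standard deviation.
#' @slot seed RNG seed used.
#' @slot values Numeric response vector (counts x truth + constant + noise).
#'
#' @name SyntheticSet-class
#' @exportClass SyntheticSet
setClass("SyntheticSet",
  representation(profiles = "list", truth = "numeric", constant = "numeric",
                 sigma = "numeric", seed = "integer", values = "numeric"))

setMethod("show", "Molecule", function(object) {
  nel <- table(object@atoms$element)
  cat(sprintf("Molecule '%s': %d atoms (%s), %d bonds%s\n", object@name,
              nrow(object@atoms),
              paste(names(nel), as.integer(nel), sep = "", collapse = " "),
              nrow(object@bonds),
              if (object@is3d) ", 3D" else ""))
  if (length(object@properties))
    cat("  properties:", paste(names(object@properties),
        signif(object@properties, 5), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FragmentProfile", function(object) {
  cat(sprintf("FragmentProfile '%s': %d atom groups, %d special groups\n",
              object@name, length(object@groupCounts),
              sum(object@specialCounts != 0)))
  if (length(object@groupCounts)) {
    df <- data.frame(key = names(object@groupCounts),
                     count = as.integer(object@groupCounts))
    print(df, row.names = FALSE)
  }
  sp <- object@specialCounts[object@specialCounts != 0]
  if (length(sp))
    cat("  specials:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ParameterTable", function(object) {
  cat(sprintf("ParameterTable '%s' (%s): %d entries%s\n", object@descriptor,
              object@units, nrow(object@entries),
              if (!is.na(object@constant))
                sprintf(", constant C = %.4g", object@constant) else ""))
  if (length(object@stats))
    cat("  fit:", paste(names(object@stats), unlist(object@stats),
        sep = "=", collapse = ", "), "\n")
  if (length(object@cvStats))
    cat("  cv: ", paste(names(object@cvStats), unlist(object@cvStats),
        sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Applicability", function(object) {
  if (object@applicable) cat("applicable\n")
  else cat("inapplicable; missing:", paste(object@missing, collapse = ", "),
           "; unconfirmed:", paste(object@unconfirmed, collapse = ", "), "\n")
})

setMethod("show", "Prediction", function(object) {
  if (is.na(object@value)) {
    cat(sprintf("Prediction (%s): rejected\n", object@descriptor))
    show(object@applicability)
  } else {
    cat(sprintf("Prediction (%s): %.4g %s\n", object@descriptor, object@value,
                object@units))
  }
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: k = %d, N = %d, Q2 = %.4f, MAE = %.4g, SD = %.4g\n",
              object@k, object@N, object@Q2, object@MAE, object@SD))
})

setMethod("atoms", "Molecule", function(x) x@atoms)
setMethod("bonds", "Molecule", function(x) x@bonds)
setMethod("molName", "Molecule", function(x) x@name)
setMethod("properties", "Molecule", function(x) x@properties)
setMethod("has3d", "Molecule", function(x) x@is3d)
setMethod("groupCounts", "FragmentProfile", function(x) x@groupCounts)
setMethod("specialCounts", "FragmentProfile", function(x) x@specialCounts)
setMethod("descriptorId", "ParameterTable", function(x) x@descriptor)
setMethod("tableEntries", "ParameterTable", function(x) x@entries)
setMethod("tableConstant", "ParameterTable", function(x) x@constant)
setMethod("tableUnits", "ParameterTable", function(x) x@units)
setMethod("fitStats", "ParameterTable", function(x) x@stats)
setMethod("cvStats", "ParameterTable", function(x) x@cvStats)
setMethod("predictedValue", "Prediction", function(x) x@value)
setMethod("breakdown", "Prediction", function(x) x@breakdown)
setMethod("isApplicable", "Prediction", function(x) x@applicability@applicable)
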