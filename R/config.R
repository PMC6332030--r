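#' @include synthdata.R
NULL

#' Default configuration
#'
#' Nested configuration list controlling descriptor tags, eligibility
#' rules, special-group detector thresholds, solver settings,
#' cross-validation, conformer embedding and the combustion-product
#' constants. Defaults reproduce the documented reference behaviour of the
#' packaged tables.
#'
#' @section Fields:
#' \describe{
#'   \item{property_tags}{SD-file tag per descriptor id.}
#'   \item{eligibility}{\code{net_charge} (exclude net-charged species);
#'     \code{strong_acid_descriptors} (descriptors with the strong-acid
#'     exclusion).}
#'   \item{specials}{\code{hbridge_max_dist} (Angstrom),
#'     \code{hbridge_ring} (pseudo-ring size window), \code{hh_min_path}
#'     (minimum H-H bond path counted), \code{angle_bins} (degree bin
#'     edges), \code{xch2n_policy} (\code{"aromatic"} or
#'     \code{"unrestricted"}), \code{xch2n_count} (\code{"n"} or
#'     \code{"n-1"}).}
#'   \item{solver}{\code{tol}, \code{max_iter}, \code{ridge} for the
#'     Gauss-Seidel solve.}
#'   \item{fit}{\code{constant_for}: descriptors fitted with a constant
#'     column; \code{specials}: special-group ids per descriptor;
#'     \code{rmse}: report RMSE instead of residual SD.}
#'   \item{cv}{\code{k}; \code{shuffle_seed} (\code{NULL} keeps the
#'     deterministic input order).}
#'   \item{embed}{\code{auto} (embed a conformer when geometry specials are
#'     needed and coordinates are absent); \code{seed}.}
#'   \item{combustion_products}{Formation enthalpies, kJ/mol.}
#' }
#'
#' @return Configuration list.
#' @export
gaDefaultConfig <- function() {
  list(
    property_tags = c(heat_of_combustion = "HC_EXP",
                      heat_of_formation = "HF_EXP", logP = "LOGP_EXP",
                      logS = "LOGS_EXP", refractivity = "MR_EXP",
                      polarizability = "POLARIZABILITY_EXP",
                      toxicity = "TOX_PIGC50_EXP", logBB = "LOGBB_EXP"),
    eligibility = list(net_charge = TRUE,
                       strong_acid_descriptors = c("logP", "logS",
                                                   "refractivity")),
    specials = list(hbridge_max_dist = 2.5, hbridge_ring = c(5L, 7L),
                    hh_min_path = 4L, angle_bins = c(60.5, 90, 102),
                    xch2n_policy = "aromatic", xch2n_count = "n"),
    solver = list(tol = 1e-8, max_iter = 100000L, ridge = 0),
    fit = list(constant = TRUE, rmse = FALSE,
               constant_for = c("logP", "logS", "polarizability",
                                "toxicity", "logBB"),
               specials = list(
                 heat_of_combustion = c("HBridge", "HH_lt2", "HH_2to2.3",
                                        "Angle60", "Angle90", "Angle102"),
                 logP = c("HBridge", "Alkane", "UnsatHC", "XCH2n"),
                 logS = c("HBridge", "Alkane", "UnsatHC", "XCH2n"),
                 refractivity = character(),
                 polarizability = character(),
                 toxicity = character(),
                 logBB = character())),
    cv = list(k = 10L, shuffle_seed = NULL),
    embed = list(auto = TRUE, seed = 1L),
    combustion_products = combustionProducts(),
    output = list(format = "text"))
}

.mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- paste0(path, "$", nm)
    if (!nm %in% names(base))
      stop("unknown configuration key at ", here, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]], here)
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a JSON configuration file
#'
#' Values are merged over \code{\link{gaDefaultConfig}}; unknown keys raise
#' a validation error naming the JSON path.
#'
#' @param path Path to a JSON file (or \code{NULL} for the defaults).
#' @return Configuration list.
#' @export
readGaConfig <- function(path = NULL) {
  cfg <- gaDefaultConfig()
  if (is.null(path)) return(cfg)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .mergeConfig(cfg, user)
}
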