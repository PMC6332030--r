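#' @include crossval.R
NULL

#' Predict a descriptor value by contribution summation
#'
#' Applies the additivity equation \eqn{Y = \sum_i a_i A_i + \sum_j b_j B_j
#' + C}: the molecule is fragmented, the applicability gate is checked
#' (every atom group present in the table and confirmed by at least three
#' training molecules; special groups never block), the special groups
#' present in the table are detected, and the contributions are summed.
#' Which special groups apply is dictated by the table itself: the
#' enthalpy table carries H-bridge/H-H-contact/ring-strain terms, the
#' logP/logS tables H-bridge and hydrocarbon/chain corrections, and the
#' refractivity/polarizability/toxicity tables none (no 3D geometry is
#' required for those).
#'
#' When the table contains geometry-dependent specials and the molecule has
#' no 3D coordinates, a deterministic seeded conformer is embedded if
#' \code{config$embed$auto} is \code{TRUE} (the default), otherwise an error
#' is raised.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param table A \linkS4class{ParameterTable} (or descriptor id, resolved
#'   via \code{\link{packagedTable}}).
#' @param config Configuration list.
#' @return A \linkS4class{Prediction}; on gate failure the value is
#'   \code{NA} and the applicability slot lists the missing/unconfirmed
#'   keys.
#' @examples
#' \dontrun{
#' glycine <- parseSmiles("C(C(=O)[O-])[NH3+]", "glycine")
#' predictDescriptor(glycine, "logP")  # -3.22
#' }
#' @export
predictDescriptor <- function(mol, table, config = gaDefaultConfig()) {
  stopifnot(methods::is(mol, "Molecule"))
  if (is.character(table)) table <- packagedTable(table)
  stopifnot(methods::is(table, "ParameterTable"))
  elig <- eligibilityFilter(mol, table@descriptor, config)
  if (!elig$pass)
    stop("molecule '", mol@name, "' not eligible for ", table@descriptor,
         ": ", elig$reason, call. = FALSE)
  prof <- fragmentMolecule(mol)
  app <- checkApplicability(prof, table)
  if (!app@applicable)
    return(methods::new("Prediction", descriptor = table@descriptor,
                        value = NA_real_, applicability = app,
                        breakdown = data.frame(), units = table@units))
  specialIds <- .tableSpecials(table)
  if (length(intersect(specialIds, .GEOMETRY_SPECIALS)) && !mol@is3d) {
    if (isTRUE(config$embed$auto))
      mol <- embedConformer(mol, seed = config$embed$seed)
    # else: detectSpecialGroups raises the explicit no-coordinates error
  }
  sp <- if (length(specialIds))
    detectSpecialGroups(mol, specialIds, config) else
    stats::setNames(numeric(), character())
  cnt <- c(prof@groupCounts, sp[sp != 0])
  e <- table@entries
  hit <- match(names(cnt), e$key)
  contrib <- e$contribution[hit]
  bd <- data.frame(key = names(cnt), count = as.numeric(cnt),
                   contribution = contrib,
                   subtotal = as.numeric(cnt) * contrib,
                   stringsAsFactors = FALSE)
  if (!is.na(table@constant))
    bd <- rbind(data.frame(key = "Const", count = 1,
                           contribution = table@constant,
                           subtotal = table@constant), bd)
  value <- sum(bd$subtotal)
  methods::new("Prediction", descriptor = table@descriptor, value = value,
               applicability = app, breakdown = bd, units = table@units)
}

#' Default formation enthalpies of the combustion products
#'
#' Standard-state formation enthalpies (kJ/mol) of the oxidation products
#' used for the indirect heat-of-formation calculation: CO2(g), H2O(l),
#' H3BO3(c), H2SO4 in 115 H2O, H3PO4(c), SiO2(quartz) and the aqueous
#' hydrogen halides; N2 is the reference state (0). The CO2 and H2O values
#' are the classic thermochemical-calorie constants (-94.051 and -68.315
#' kcal/mol) converted with the 4.1868 J/cal factor; all values can be
#' overridden through the configuration.
#'
#' @return Named numeric vector (kJ/mol).
#' @export
combustionProducts <- function() {
  c(CO2 = -94.051 * 4.1868, H2O = -68.315 * 4.1868,
    H3BO3 = -1094.3, H2SO4aq = -887.8, H3PO4 = -1284.4, SiO2 = -910.7,
    HF = -332.6, HCl = -166.6, HBr = -121.6, HI = -55.2, N2 = 0)
}

#' Combustion stoichiometry of a molecular formula
#'
#' Element-balanced complete-combustion products under the standard
#' calorimetric convention: carbon to CO2, halogens to aqueous HX, sulfur
#' to hydrated H2SO4 (consuming 2 H per S), phosphorus to H3PO4 (3 H),
#' boron to H3BO3 (3 H), silicon to SiO2, remaining hydrogen to liquid
#' water and nitrogen to N2; O2 consumption closes the oxygen balance
#' (negative when the molecule releases oxygen).
#'
#' @param counts Named element counts as returned by
#'   \code{\link{molecularFormula}}.
#' @return List with \code{products} (named numeric, possibly fractional)
#'   and \code{O2} consumed.
#' @examples
#' combustionStoichiometry(c(C = 3, H = 6, O = 1))  # acetone: 3 CO2 + 3 H2O, O2 = 4
#' @export
combustionStoichiometry <- function(counts) {
  n <- function(el) if (el %in% names(counts)) as.numeric(counts[[el]]) else 0
  unk <- setdiff(names(counts), .GA_ELEMENTS)
  if (length(unk))
    stop("unsupported element(s): ", paste(unk, collapse = ", "), call. = FALSE)
  hx <- c(HF = n("F"), HCl = n("Cl"), HBr = n("Br"), HI = n("I"))
  hUsed <- sum(hx) + 2 * n("S") + 3 * n("P") + 3 * n("B")
  hFree <- n("H") - hUsed
  if (hFree < 0)
    stop("not enough hydrogen to form HX/oxyacid products; ",
         "configure the free-halogen variant for perhalogenated compounds",
         call. = FALSE)
  prod <- c(CO2 = n("C"), H2O = hFree / 2, N2 = n("N") / 2,
            H2SO4aq = n("S"), H3PO4 = n("P"), H3BO3 = n("B"), SiO2 = n("Si"),
            hx)
  prod <- prod[prod != 0]
  oProd <- sum(prod * c(CO2 = 2, H2O = 1, N2 = 0, H2SO4aq = 4, H3PO4 = 4,
                        H3BO3 = 3, SiO2 = 2, HF = 0, HCl = 0, HBr = 0,
                        HI = 0)[names(prod)])
  o2 <- (oProd - n("O")) / 2
  list(products = prod, O2 = o2)
}

#' Indirect heat of formation from the predicted heat of combustion
#'
#' \eqn{\Delta H_f = \sum_p n_p \Delta H_f(p) - \Delta H_c}: the predicted
#' heat of combustion is combined with the formation enthalpies of the
#' combustion products obtained from \code{\link{combustionStoichiometry}}.
#'
#' @param mol A \linkS4class{Molecule}.
#' @param hcTable Heat-of-combustion \linkS4class{ParameterTable} (default:
#'   the packaged one).
#' @param products Named product formation enthalpies (kJ/mol).
#' @param config Configuration list.
#' @return List with \code{value} (kJ/mol), \code{hc} (the predicted heat of
#'   combustion \linkS4class{Prediction}) and \code{productSum}.
#' @export
heatOfFormation <- function(mol, hcTable = packagedTable("heat_of_combustion"),
                            products = NULL, config = gaDefaultConfig()) {
  if (is.null(products)) products <- config$combustion_products
  hc <- predictDescriptor(mol, hcTable, config)
  if (is.na(hc@value))
    stop("heat-of-combustion prediction rejected for '", mol@name, "': ",
         paste(c(hc@applicability@missing, hc@applicability@unconfirmed),
               collapse = ", "), call. = FALSE)
  st <- combustionStoichiometry(molecularFormula(mol))
  missing <- setdiff(names(st$products), names(products))
  if (length(missing))
    stop("no formation enthalpy configured for product(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  productSum <- sum(st$products * products[names(st$products)])
  list(value = productSum - hc@value, hc = hc, productSum = productSum,
       products = st$products, O2 = st$O2)
}

#' Molar refractivity from refractive index, molecular weight and density
#'
#' Lorentz-Lorenz relation
#' \eqn{MR = (n_D^2 - 1)/(n_D^2 + 2) \times M/d}.
#'
#' @param nD Refractive index (>= 1).
#' @param M Molecular weight (g/mol).
#' @param d Density (g/cm3, > 0).
#' @return Molar refractivity (cm3/mol).
#' @examples
#' mrFromRefractiveIndex(1.5, 100, 1)  # 29.41
#' @export
mrFromRefractiveIndex <- function(nD, M, d) {
  stopifnot(nD >= 1)
  if (any(d <= 0)) stop("density must be positive", call. = FALSE)
  (nD^2 - 1) / (nD^2 + 2) * M / d
}
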