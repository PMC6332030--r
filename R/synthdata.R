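#' @include predict.R
NULL

#' Generate a synthetic training set with known contributions
#'
#' Random sparse count profiles over an artificial group alphabet with
#' ground-truth contributions; responses are \code{counts x truth +
#' constant + Gaussian noise}. Deterministic under the seed and independent
#' of the caller's RNG state. Used for parameter-recovery and
#' cross-validation checks.
#'
#' @param nMol Number of molecules (profiles).
#' @param nGroups Alphabet size.
#' @param countRange Inclusive integer range for group counts.
#' @param truthRange Range the ground-truth contributions are drawn from.
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param constant Ground-truth additive constant.
#' @return A \linkS4class{SyntheticSet}.
#' @export
generateSyntheticSet <- function(nMol, nGroups = 8L, countRange = c(0L, 4L),
                                 truthRange = c(-2, 2), sigma = 0, seed = 1L,
                                 constant = 0) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(nMol >= 1L, nGroups >= 1L)
  if (nMol < nGroups)
    warning("fewer molecules than groups: contributions not identifiable")
  rs <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = .GlobalEnv))
  set.seed(as.integer(seed))
  keys <- sprintf("G%02d", seq_len(nGroups))
  truth <- stats::setNames(stats::runif(nGroups, truthRange[1], truthRange[2]),
                           keys)
  counts <- matrix(sample(seq(countRange[1], countRange[2]),
                          nMol * nGroups, replace = TRUE),
                   nrow = nMol, dimnames = list(NULL, keys))
  empty <- rowSums(counts) == 0
  if (any(empty))
    counts[empty, 1L] <- 1L
  profiles <- lapply(seq_len(nMol), function(m) {
    cnt <- counts[m, ]
    cnt <- cnt[cnt > 0]
    methods::new("FragmentProfile", groupCounts = cnt,
                 specialCounts = stats::setNames(numeric(), character()),
                 name = sprintf("synth%04d", m))
  })
  values <- as.numeric(counts %*% truth) + constant +
    stats::rnorm(nMol, 0, sigma)
  methods::new("SyntheticSet", profiles = profiles, truth = truth,
               constant = constant, sigma = sigma, seed = as.integer(seed),
               values = values)
}

#' Worked-example fixtures
#'
#' Reference molecules with expected descriptor values for the packaged
#' contribution tables. Expectations marked \code{source = "printed"} are
#' published reference calculations for these exact structures; those
#' marked \code{"derived-sum"} are hand-computed sums of the packaged
#' contributions (used for the two descriptors without published
#' per-molecule reference values). Zwitterions are written with explicit charges;
#' tolerances reflect contribution rounding (two printed decimals) and, for
#' the enthalpies, conformer-dependent H-H contact counts.
#'
#' @return \code{data.frame} with columns \code{name}, \code{smiles},
#'   \code{descriptor}, \code{expected}, \code{tolerance}, \code{needs3d},
#'   \code{source}.
#' @export
workedExampleFixtures <- function() {
  fx <- function(name, smiles, descriptor, expected, tolerance, needs3d, source)
    data.frame(name = name, smiles = smiles, descriptor = descriptor,
               expected = expected, tolerance = tolerance, needs3d = needs3d,
               source = source, stringsAsFactors = FALSE)
  rbind(
    fx("glycine-zwitterion", "C(C(=O)[O-])[NH3+]", "logP", -3.22, 0.05, FALSE, "printed"),
    fx("alanine-zwitterion", "CC(C(=O)[O-])[NH3+]", "logP", -2.75, 0.05, FALSE, "printed"),
    fx("valine-zwitterion", "CC(C)C(C(=O)[O-])[NH3+]", "logP", -2.08, 0.05, FALSE, "printed"),
    fx("ornithine-zwitterion", "NCCCC(C(=O)[O-])[NH3+]", "logP", -3.54, 0.05, FALSE, "printed"),
    fx("tetracosane", paste0("C", strrep("C", 23)), "logP", 12.75, 0.05, FALSE, "printed"),
    fx("phenol-enol", "Oc1ccccc1", "logP", 1.76, 0.05, FALSE, "printed"),
    fx("acetone-keto", "CC(=O)C", "logP", 0.60, 0.05, FALSE, "printed"),
    fx("eicosane", strrep("C", 20), "logS", -12.54, 0.05, FALSE, "printed"),
    fx("hexacosane", strrep("C", 26), "logS", -16.44, 0.05, FALSE, "printed"),
    fx("1-hexadecanol", paste0("OC", strrep("C", 15)), "logS", -4.04, 0.05, FALSE, "printed"),
    fx("1-octadecanol", paste0("OC", strrep("C", 17)), "logS", -4.68, 0.05, FALSE, "printed"),
    fx("methanol", "CO", "refractivity", 8.09, 0.05, FALSE, "printed"),
    fx("tripalmitin",
       "CCCCCCCCCCCCCCCC(=O)OCC(OC(=O)CCCCCCCCCCCCCCC)COC(=O)CCCCCCCCCCCCCCC",
       "refractivity", 243.12, 0.10, FALSE, "printed"),
    fx("valine-zwitterion", "CC(C)C(C(=O)[O-])[NH3+]", "heat_of_combustion",
       -2932.9, 6, TRUE, "printed"),
    fx("threonine-zwitterion", "CC(O)C(C(=O)[O-])[NH3+]", "heat_of_combustion",
       -2090.5, 6, TRUE, "printed"),
    fx("serine-zwitterion", "OCC(C(=O)[O-])[NH3+]", "heat_of_combustion",
       -1441.4, 6, TRUE, "printed"),
    fx("acetone", "CC(=O)C", "heat_of_formation", -243.18, 5, TRUE, "printed"),
    fx("phenol", "Oc1ccccc1", "heat_of_formation", -166.90, 5, TRUE, "printed"),
    fx("4-phenylazophenol-azo", "Oc1ccc(cc1)/N=N/c1ccccc1",
       "heat_of_formation", 141.92, 5, TRUE, "printed"),
    fx("methanol", "CO", "polarizability", 3.35, 0.05, FALSE, "derived-sum"),
    fx("benzene", "c1ccccc1", "polarizability", 10.70, 0.05, FALSE, "derived-sum"),
    fx("phenol", "Oc1ccccc1", "toxicity", -0.10, 0.05, FALSE, "derived-sum"),
    fx("ethanol", "CCO", "toxicity", -1.89, 0.05, FALSE, "derived-sum"))
}

#' Azo/hydrazone tautomer pairs
#'
#' The eight azo-dye tautomer pairs used to probe whether the indirect
#' heat-of-formation calculation identifies the experimentally dominant
#' form (the lower-enthalpy member should match the known equilibrium
#' side).
#'
#' @return \code{data.frame} with columns \code{name}, \code{azo},
#'   \code{hydrazone} (SMILES) and \code{lower} (\code{"azo"} or
#'   \code{"hydrazone"}, the experimentally dominant form).
#' @export
azoTautomerPairs <- function() {
  data.frame(
    name = c("4-phenylazophenol", "2-phenylazophenol", "4-aminoazobenzene",
             "2-aminoazobenzene", "1-phenylazo-2-naphthol",
             "4-phenylazo-1-naphthol", "1-phenylazo-2-naphthylamine",
             "4-phenylazo-1-naphthylamine"),
    azo = c("Oc1ccc(cc1)N=Nc1ccccc1", "Oc1ccccc1N=Nc1ccccc1",
            "Nc1ccc(cc1)N=Nc1ccccc1", "Nc1ccccc1N=Nc1ccccc1",
            "Oc1ccc2ccccc2c1N=Nc1ccccc1", "Oc1ccc(N=Nc2ccccc2)c2ccccc12",
            "Nc1ccc2ccccc2c1N=Nc1ccccc1", "Nc1ccc(N=Nc2ccccc2)c2ccccc12"),
    hydrazone = c("O=C1C=CC(C=C1)=NNc1ccccc1", "O=C1C=CC=CC1=NNc1ccccc1",
                  "N=C1C=CC(C=C1)=NNc1ccccc1", "N=C1C=CC=CC1=NNc1ccccc1",
                  "O=C1C=Cc2ccccc2C1=NNc1ccccc1",
                  "O=C1C=CC(=NNc2ccccc2)c2ccccc12",
                  "N=C1C=Cc2ccccc2C1=NNc1ccccc1",
                  "N=C1C=CC(=NNc2ccccc2)c2ccccc12"),
    lower = c("azo", "azo", "azo", "azo", "hydrazone", "hydrazone",
              "azo", "azo"),
    stringsAsFactors = FALSE)
}
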