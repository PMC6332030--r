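#' @include fitting.R
NULL

#' Shifted k-fold split
#'
#' Deterministic extraction scheme: run \code{r} (0-based) takes every k-th
#' element starting at position \code{r + 1} as the test set, so over the k
#' runs every element is used exactly once as a test item and no structural
#' clusters are extracted together.
#'
#' @param ids Ordered vector of identifiers.
#' @param k Number of folds (>= 2, <= length(ids)).
#' @param run Run index, 0 to k - 1.
#' @return List with \code{train} and \code{test}.
#' @examples
#' kfoldSplit(0:9, k = 5, run = 1)$test  # 1, 6
#' @export
kfoldSplit <- function(ids, k, run) {
  stopifnot(k >= 2L, run >= 0L, run < k)
  if (k > length(ids)) stop("k exceeds the number of items", call. = FALSE)
  pos <- seq_along(ids) - 1L
  test <- pos %% k == run
  list(train = ids[!test], test = ids[test])
}

# Profile-level cross-validation core shared by the molecule interface and
# the synthetic-data tests.
.crossValidateProfiles <- function(profiles, values, k = 10L,
                                   config = gaDefaultConfig(),
                                   descriptor = "custom") {
  n <- length(profiles)
  stopifnot(length(values) == n)
  ids <- seq_len(n)
  runs <- data.frame(run = integer(), train = integer(), test = integer(),
                     evaluable = integer())
  pooled <- data.frame(id = character(), experimental = numeric(),
                       predicted = numeric(), stringsAsFactors = FALSE)
  for (r in 0:(k - 1L)) {
    sp <- kfoldSplit(ids, k, r)
    tab <- tryCatch(.fitProfiles(profiles[sp$train], values[sp$train],
                                 descriptor = descriptor, config = config),
                    error = function(e) NULL)
    nev <- 0L
    if (!is.null(tab)) {
      for (m in sp$test) {
        app <- checkApplicability(profiles[[m]], tab)
        if (!app@applicable) next
        pr <- .evaluateProfile(profiles[[m]], tab)
        nev <- nev + 1L
        pooled <- rbind(pooled, data.frame(
          id = profiles[[m]]@name, experimental = values[m], predicted = pr,
          stringsAsFactors = FALSE))
      }
    }
    runs <- rbind(runs, data.frame(run = r, train = length(sp$train),
                                   test = length(sp$test), evaluable = nev))
  }
  res <- pooled$experimental - pooled$predicted
  sstot <- sum((pooled$experimental - mean(pooled$experimental))^2)
  q2 <- if (nrow(pooled) < 2L || sstot == 0) NA_real_ else 1 - sum(res^2) / sstot
  methods::new("CVReport", k = as.integer(k), runs = runs,
               predictions = pooled, Q2 = q2,
               MAE = if (nrow(pooled)) mean(abs(res)) else NA_real_,
               SD = if (nrow(pooled) >= 2L) stats::sd(res) else NA_real_,
               N = nrow(pooled))
}

# Plain additive evaluation of a profile against a table (no gating).
.evaluateProfile <- function(profile, table) {
  e <- table@entries
  cnt <- c(profile@groupCounts, profile@specialCounts)
  cnt <- cnt[cnt != 0]
  hit <- match(names(cnt), e$key)
  contrib <- ifelse(is.na(hit), 0, e$contribution[hit])
  base <- if (is.na(table@constant)) 0 else table@constant
  base + sum(cnt * contrib)
}

#' Shifted k-fold cross-validation of a descriptor model
#'
#' For each of the k runs the contribution table is refitted on the reduced
#' training set and the held-out molecules are predicted with it. Test
#' molecules whose atom groups lose their three-molecule confirmation in the
#' reduced set are excluded from the pooling (N decrements accordingly).
#' \eqn{Q^2} is computed over the pooled out-of-fold predictions.
#'
#' @param molecules List of \linkS4class{Molecule} with experimental values.
#' @param descriptor Descriptor id.
#' @param k Number of folds (default 10; use \code{k = length(molecules)}
#'   for leave-one-out).
#' @param config Configuration list. \code{config$cv$shuffle_seed}, when not
#'   \code{NULL}, applies a seeded shuffle to the input order first; the
#'   default keeps the deterministic file order.
#' @return A \linkS4class{CVReport}.
#' @export
crossValidate <- function(molecules, descriptor, k = 10L,
                          config = gaDefaultConfig()) {
  descriptor <- .canonDescriptor(descriptor)
  keep <- vapply(molecules, function(m)
    eligibilityFilter(m, descriptor, config)$pass, logical(1))
  molecules <- molecules[keep]
  if (!is.null(config$cv$shuffle_seed)) {
    rs <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(as.integer(config$cv$shuffle_seed))
    molecules <- molecules[sample(seq_along(molecules))]
    if (!is.null(rs)) assign(".Random.seed", rs, envir = .GlobalEnv)
  }
  specials <- config$fit$specials[[descriptor]]
  if (is.null(specials)) specials <- character()
  profiles <- lapply(molecules, moleculeProfile, specialIds = specials,
                     config = config)
  values <- vapply(molecules, function(m) unname(m@properties[descriptor]),
                   numeric(1))
  cfg <- config
  cfg$fit$constant <- !is.null(config$fit$constant_for) &&
    descriptor %in% config$fit$constant_for
  .crossValidateProfiles(profiles, values, k = k, config = cfg,
                         descriptor = descriptor)
}

#' Serialize a CVReport as JSON
#'
#' Summary fields mirror the parameter-table footer rows (k, Q2, average
#' and standard deviation of the cross-validated predictions).
#'
#' @param report A \linkS4class{CVReport}.
#' @param path Optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to \code{path}).
#' @export
cvReportJSON <- function(report, path = NULL) {
  stopifnot(methods::is(report, "CVReport"))
  obj <- list(k = report@k, Q2 = report@Q2, MAE_cv = report@MAE,
              SD_cv = report@SD, N_cv = report@N,
              runs = report@runs, predictions = report@predictions)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
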