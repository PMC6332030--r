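#' @include params.R
NULL

#' Build the M x (N + 1) design matrix of a training set
#'
#' One row per molecule, one column per atom/special group (cell value: the
#' occurrence count of that group in the molecule) plus an all-ones constant
#' column when requested. Columns that are zero for every molecule are
#' dropped and reported in the \code{"dropped"} attribute.
#'
#' @param profiles List of \linkS4class{FragmentProfile}.
#' @param values Numeric vector of experimental values, one per profile.
#' @param schema Optional column (key) order; defaults to the sorted union
#'   of keys present in the profiles (atom groups, then special groups).
#' @param constant Include a constant column (named \code{"Const"}).
#' @return List with \code{X} (matrix; rownames are molecule names,
#'   colnames keys), \code{y}, and attribute \code{"dropped"}.
#' @export
buildDesignMatrix <- function(profiles, values, schema = NULL, constant = TRUE) {
  stopifnot(length(profiles) == length(values))
  if (anyNA(values)) {
    bad <- vapply(profiles[is.na(values)], function(p) p@name, character(1))
    stop("missing experimental value for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  allCounts <- lapply(profiles, function(p) c(p@groupCounts, p@specialCounts))
  if (is.null(schema)) {
    keys <- unique(unlist(lapply(allCounts, names)))
    grp <- sort(keys[!.isSpecialId(keys)])
    schema <- c(grp, intersect(.GA_SPECIAL_IDS, keys))
  }
  X <- matrix(0, nrow = length(profiles), ncol = length(schema),
              dimnames = list(vapply(profiles, function(p) p@name, character(1)),
                              schema))
  for (m in seq_along(profiles)) {
    cnt <- allCounts[[m]]
    cnt <- cnt[names(cnt) %in% schema]
    if (length(cnt)) X[m, names(cnt)] <- cnt
  }
  dropped <- colnames(X)[colSums(X != 0) == 0L]
  if (length(dropped)) X <- X[, !colnames(X) %in% dropped, drop = FALSE]
  if (constant) X <- cbind(X, Const = 1)
  structure(list(X = X, y = as.numeric(values)), dropped = dropped)
}

#' Solve the least-squares problem by Gauss-Seidel iteration
#'
#' Iterates Gauss-Seidel sweeps on the normal equations
#' \eqn{X^T X \beta = X^T y} from a zero start until the largest coordinate
#' update of a sweep falls below \code{tol} (scaled by the current iterate
#' magnitude). The normal matrix is symmetric positive (semi-)definite, for
#' which Gauss-Seidel is convergent; a tiny ridge can be added for
#' rank-deficient instances.
#'
#' @param X Design matrix (no all-zero columns).
#' @param y Response vector.
#' @param tol Convergence tolerance on the per-sweep update (default 1e-8).
#' @param maxIter Maximum number of sweeps.
#' @param ridge Optional ridge term added to the normal-equation diagonal.
#' @return Named numeric vector of contributions in column order.
#' @examples
#' X <- cbind(a = c(1, 0), b = c(0, 2))
#' gaussSeidelSolve(X, c(3, 4))  # a = 3, b = 2
#' @export
gaussSeidelSolve <- function(X, y, tol = 1e-8, maxIter = 100000L, ridge = 0) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) > 0L)
  A <- crossprod(X)
  if (ridge > 0) diag(A) <- diag(A) + ridge
  if (any(diag(A) == 0))
    stop("design matrix has an all-zero column; drop it before solving")
  b <- as.numeric(crossprod(X, y))
  n <- ncol(A)
  beta <- numeric(n)
  for (it in seq_len(maxIter)) {
    delta <- 0
    for (j in seq_len(n)) {
      new <- (b[j] - sum(A[j, -j] * beta[-j])) / A[j, j]
      delta <- max(delta, abs(new - beta[j]))
      beta[j] <- new
    }
    if (delta < tol * max(1, max(abs(beta)))) {
      return(stats::setNames(beta, colnames(X)))
    }
  }
  res <- sqrt(sum((y - as.numeric(X %*% beta))^2))
  cond <- simpleError(sprintf(
    "Gauss-Seidel did not converge in %d sweeps (last update %.3g, residual norm %.3g)",
    maxIter, delta, res))
  cond$beta <- stats::setNames(beta, colnames(X))
  cond$residual <- res
  stop(cond)
}

#' Fit statistics of predicted versus experimental values
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}; MAE is the mean
#' absolute residual; SD the sample standard deviation of the signed
#' residuals (set \code{rmse = TRUE} for the root-mean-square variant).
#'
#' @param predicted,experimental Equal-length numeric vectors (length >= 2).
#' @param rmse Report RMSE instead of the residual standard deviation.
#' @return List with \code{R2}, \code{MAE}, \code{SD}, \code{N}.
#' @export
fitStatistics <- function(predicted, experimental, rmse = FALSE) {
  stopifnot(length(predicted) == length(experimental),
            length(predicted) >= 2L)
  res <- experimental - predicted
  sstot <- sum((experimental - mean(experimental))^2)
  r2 <- if (sstot == 0) {
    warning("constant experimental values: R2 undefined")
    NA_real_
  } else 1 - sum(res^2) / sstot
  list(R2 = r2, MAE = mean(abs(res)),
       SD = if (rmse) sqrt(mean(res^2)) else stats::sd(res),
       N = length(res))
}

# Core fitting on profiles (no chemistry): returns a ParameterTable.
.fitProfiles <- function(profiles, values, descriptor = "custom",
                         units = "", config = gaDefaultConfig()) {
  if (!length(profiles)) stop("empty training set", call. = FALSE)
  useConst <- isTRUE(config$fit$constant)
  dm <- buildDesignMatrix(profiles, values, constant = useConst)
  sol <- gaussSeidelSolve(dm$X, dm$y, tol = config$solver$tol,
                          maxIter = config$solver$max_iter,
                          ridge = config$solver$ridge)
  keys <- setdiff(colnames(dm$X), "Const")
  occurrences <- vapply(keys, function(k) sum(dm$X[, k]), numeric(1))
  molecules <- vapply(keys, function(k) sum(dm$X[, k] != 0), numeric(1))
  tsv <- .GA_SPECIAL_TSV
  spIdx <- match(keys, tsv$id)
  backbone <- ifelse(!is.na(spIdx), tsv$backbone[spIdx],
                     vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1))
  neighbors <- ifelse(!is.na(spIdx), tsv$neighbors[spIdx],
                      vapply(strsplit(keys, "|", fixed = TRUE), function(x)
                        if (length(x) > 1) x[2] else "", ""))
  entries <- data.frame(key = keys, backbone = backbone, neighbors = neighbors,
                        contribution = as.numeric(sol[keys]),
                        occurrences = as.integer(occurrences),
                        molecules = as.integer(molecules),
                        stringsAsFactors = FALSE)
  tab <- methods::new("ParameterTable", descriptor = descriptor, units = units,
                      constant = if (useConst) unname(sol["Const"]) else NA_real_,
                      entries = entries, stats = list(), cvStats = list())
  # statistics over the molecules whose every atom group passes the
  # three-molecule gate (evaluable subset; smaller than the basis set)
  pred <- as.numeric(dm$X %*% sol[colnames(dm$X)])
  grpKeys <- keys[is.na(spIdx)]
  confirmed <- grpKeys[entries$molecules[match(grpKeys, entries$key)] >= 3L]
  evaluable <- vapply(seq_along(profiles), function(m) {
    mk <- names(profiles[[m]]@groupCounts)
    all(mk %in% confirmed)
  }, logical(1))
  st <- list(based_on = length(profiles))
  if (sum(evaluable) >= 2L) {
    fs <- fitStatistics(pred[evaluable], dm$y[evaluable],
                        rmse = isTRUE(config$fit$rmse))
    st <- c(st, fs)
  }
  tab@stats <- st
  tab
}

#' Fit a contribution table from training molecules
#'
#' End-to-end pipeline: eligibility filter, fragmentation (plus the
#' special-group detectors configured for the descriptor), design matrix,
#' Gauss-Seidel solve, and assembly of a \linkS4class{ParameterTable} with
#' per-group occurrence/molecule counts and fit statistics. The statistics
#' are computed over the molecules whose every atom group is confirmed by
#' at least three training molecules, which is why their N is generally
#' smaller than the basis set.
#'
#' @param molecules List of \linkS4class{Molecule} carrying the descriptor's
#'   experimental value in \code{properties}.
#' @param descriptor Descriptor id.
#' @param config Configuration list.
#' @return A \linkS4class{ParameterTable}.
#' @export
fitTable <- function(molecules, descriptor, config = gaDefaultConfig()) {
  descriptor <- .canonDescriptor(descriptor)
  if (!length(molecules)) stop("empty training set", call. = FALSE)
  keep <- vapply(molecules, function(m)
    eligibilityFilter(m, descriptor, config)$pass, logical(1))
  if (!any(keep)) stop("no eligible training molecules", call. = FALSE)
  molecules <- molecules[keep]
  specials <- config$fit$specials[[descriptor]]
  if (is.null(specials)) specials <- character()
  profiles <- lapply(molecules, moleculeProfile, specialIds = specials,
                     config = config)
  values <- vapply(molecules, function(m) {
    v <- m@properties[descriptor]
    if (is.na(v)) NA_real_ else unname(v)
  }, numeric(1))
  if (anyNA(values))
    stop("missing experimental ", descriptor, " value for: ",
         paste(vapply(molecules[is.na(values)], function(m) m@name,
                      character(1)), collapse = ", "), call. = FALSE)
  useConst <- !is.null(config$fit$constant_for) &&
    descriptor %in% config$fit$constant_for
  cfg <- config
  cfg$fit$constant <- useConst
  .fitProfiles(profiles, values, descriptor = descriptor,
               units = unname(.GA_UNITS[descriptor]), config = cfg)
}
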