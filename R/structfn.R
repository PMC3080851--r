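# Karhunen-Loeve reduction of the moment time series and the plane fit
# estimating the decline in bulk modulus from structure.

# Coerce trajectories / data frames / matrices to a moment matrix with the
# four moment columns, plus the K/K0 response when present.
.moment_matrix <- function(x, moments = c("mu", "m2", "m3", "m4")) {
  if (inherits(x, "destruction_trajectory")) x <- x$steps
  if (is.data.frame(x)) {
    if (!all(moments %in% names(x)))
      stop("missing moment columns: ",
           paste(setdiff(moments, names(x)), collapse = ", "))
    K <- if ("K_over_K0" %in% names(x)) x$K_over_K0 else NULL
    M <- as.matrix(x[moments])
  } else {
    M <- as.matrix(x)
    if (ncol(M) != length(moments))
      stop("expected ", length(moments), " moment columns")
    colnames(M) <- moments
    K <- NULL
  }
  if (anyNA(M) || any(!is.finite(M))) stop("moment matrix contains missing values")
  list(M = M, K = K)
}

.pool_moments <- function(trajectories, moments) {
  if (inherits(trajectories, c("destruction_trajectory", "data.frame")) ||
      is.matrix(trajectories))
    trajectories <- list(trajectories)
  parts <- lapply(trajectories, .moment_matrix, moments = moments)
  M <- do.call(rbind, lapply(parts, `[[`, "M"))
  Ks <- lapply(parts, `[[`, "K")
  K <- if (any(vapply(Ks, is.null, TRUE))) NULL else unlist(Ks)
  run <- rep.int(seq_along(parts),
                 vapply(parts, function(p) nrow(p$M), 1L))
  list(M = M, K = K, run = run)
}

#' Karhunen-Loeve (principal component) basis of the moment matrix
#'
#' Column-centers the moment matrix, forms its covariance matrix and
#' eigendecomposes it. Eigenpairs are sorted by descending eigenvalue and
#' each eigenvector's sign is fixed so that its largest-magnitude component
#' is positive, making projections reproducible. Rank-deficient input is
#' allowed (zero eigenvalues are retained).
#'
#' @param M a moment matrix (rows = destruction steps), a trajectory, a data
#'   frame with moment columns, or a list of these (rows are pooled).
#' @param moments the moment column names.
#' @return An object of class `kl_basis`: `vectors` (columns are
#'   eigenvectors), `values`, `center` (column means used for centering) and
#'   `explained` (fraction of total variance per component).
#' @export
kl_basis <- function(M, moments = c("mu", "m2", "m3", "m4")) {
  pm <- .pool_moments(M, moments)
  if (nrow(pm$M) < 3L) stop("at least 3 rows are needed to estimate the covariance")
  ctr <- colMeans(pm$M)
  C <- cov(pm$M)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- moments
  structure(list(vectors = vecs, values = vals, center = ctr,
                 explained = if (sum(vals) > 0) vals / sum(vals)
                             else rep(0, length(vals)),
                 moments = moments),
            class = "kl_basis")
}

#' @export
print.kl_basis <- function(x, ...) {
  cat("Karhunen-Loeve basis of the moment covariance\n")
  cat("  explained variance:",
      paste(sprintf("%.3f%%", 100 * x$explained), collapse = ", "), "\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' Project moment rows onto a Karhunen-Loeve basis
#'
#' Rows are centered with the basis's own column means (essential when
#' projecting new simulations onto a fixed basis) and dotted with the
#' eigenvectors. The first two columns are the structure variables P1 and P2.
#'
#' @param M as in [kl_basis()].
#' @param basis a [kl_basis()].
#' @return Numeric matrix of scores with columns `P1, P2, ...`.
#' @export
kl_project <- function(M, basis) {
  stopifnot(inherits(basis, "kl_basis"))
  pm <- .pool_moments(M, basis$moments)
  P <- sweep(pm$M, 2, basis$center) %*% basis$vectors
  colnames(P) <- paste0("P", seq_len(ncol(P)))
  P
}

#' Fit the structure-function model
#'
#' The core estimator: pooled destruction trajectories (by default one
#' spatially random and one force-based run) supply a moment matrix whose
#' Karhunen-Loeve basis reduces the four airspace-volume moments to two
#' structure variables `P1`, `P2`; the decline in normalized bulk modulus is
#' then fit by the minimum-mean-square-error plane
#' `K/K0 = a * P1 + b * P2 + c`.
#'
#' @param trajectories a `destruction_trajectory`, a data frame with moment
#'   and `K_over_K0` columns, or a list of these (pooled).
#' @param moments moment columns to use.
#' @param K optional response vector overriding the `K_over_K0` column.
#' @return An object of class `structfn`: the fitted basis, plane
#'   coefficients and residuals, with the usual [coef()], [predict()],
#'   [residuals()], [fitted()], `summary()` and `plot()` methods.
#' @examples
#' # toy trajectories lying exactly on a plane in moment space
#' m <- seq(0, 1, length.out = 20)
#' df <- data.frame(mu = 1 + m, m2 = 2 * m, m3 = m^2, m4 = 3 * m^2,
#'                  K_over_K0 = 1 - 0.5 * m)
#' fit <- structfn(df)
#' coef(fit)
#' max(abs(residuals(fit)))
#' @export
structfn <- function(trajectories, moments = c("mu", "m2", "m3", "m4"),
                     K = NULL) {
  pm <- .pool_moments(trajectories, moments)
  if (is.null(K)) K <- pm$K
  if (is.null(K))
    stop("no K_over_K0 response found; supply trajectories or the 'K' argument")
  if (length(K) != nrow(pm$M)) stop("response length does not match moment rows")
  basis <- kl_basis(pm$M, moments)
  P <- kl_project(pm$M, basis)
  df <- data.frame(K = K, P1 = P[, 1], P2 = P[, 2])
  if (basis$values[2] <= 1e-14 * basis$values[1] ||
      qr(cbind(1, P[, 1:2]))$rank < 3)
    stop("degenerate fit: (P1, P2) scores are collinear")
  lmfit <- lm(K ~ P1 + P2, data = df)
  cf <- coef(lmfit)
  res <- structure(list(
    basis = basis,
    coefficients = c(a = unname(cf["P1"]), b = unname(cf["P2"]),
                     c = unname(cf["(Intercept)"])),
    fitted.values = unname(stats::fitted(lmfit)),
    residuals = unname(stats::residuals(lmfit)),
    rms = sqrt(mean(stats::residuals(lmfit)^2)),
    K = K, scores = P[, 1:2, drop = FALSE], run = pm$run,
    n_runs = length(unique(pm$run)),
    moments = moments, call = match.call()),
    class = "structfn")
  res
}

#' @export
print.structfn <- function(x, ...) {
  cf <- x$coefficients
  cat("Structure-function model: K/K0 = a*P1 + b*P2 + c\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g  (rms residual %.4g)\n",
              cf["a"], cf["b"], cf["c"], x$rms))
  cat(sprintf("  first two components explain %.3f%% of moment variability\n",
              100 * sum(x$basis$explained[1:2])))
  cat(sprintf("  fitted on %d steps from %d run(s)\n", length(x$K), x$n_runs))
  invisible(x)
}

#' @export
coef.structfn <- function(object, ...) object$coefficients

#' @export
residuals.structfn <- function(object, ...) object$residuals

#' @export
fitted.structfn <- function(object, ...) object$fitted.values

#' @export
summary.structfn <- function(object, ...) {
  err <- estimation_error(object$fitted.values, object$K)
  structure(list(object = object,
                 explained = object$basis$explained,
                 coefficients = object$coefficients,
                 rms = object$rms,
                 error_summary = summary(err)),
            class = "summary.structfn")
}

#' @export
print.summary.structfn <- function(x, ...) {
  print(x$object)
  cat("  explained variance per component:",
      paste(sprintf("%.4f%%", 100 * x$explained), collapse = ", "), "\n")
  cat("  in-sample relative error (%):\n")
  print(x$error_summary)
  invisible(x)
}

#' Predict the decline in bulk modulus from structure
#'
#' Projects new moment rows onto the fitted Karhunen-Loeve basis (using the
#' basis's centering means) and evaluates the fitted plane.
#'
#' @param object a [structfn()] fit.
#' @param newdata a trajectory, data frame, moment matrix, or list of these;
#'   defaults to the training data.
#' @param ... unused.
#' @return Numeric vector of estimated `K/K0`.
#' @export
predict.structfn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  P <- kl_project(newdata, object$basis)
  cf <- object$coefficients
  as.numeric(cf["a"] * P[, 1] + cf["b"] * P[, 2] + cf["c"])
}

#' @export
plot.structfn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(100 * x$basis$explained,
                    names.arg = paste0("e", seq_along(x$basis$explained)),
                    ylab = "% variability explained", main = "KL spectrum")
  plot(x$fitted.values, x$K, col = x$run, xlab = "plane estimate of K/K0",
       ylab = "measured K/K0", main = "plane fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Relative estimation error of the stiffness estimate
#'
#' Per-step error `100 * |K_hat - K| / K` in percent of the measured value.
#'
#' @param K_hat estimated `K/K0` series.
#' @param K measured `K/K0` series (strictly positive).
#' @return Numeric vector of percent errors.
#' @export
estimation_error <- function(K_hat, K) {
  if (length(K_hat) != length(K)) stop("series lengths differ")
  if (any(!is.finite(K)) || any(K <= 0)) stop("'K' must be positive and finite")
  100 * abs(K_hat - K) / K
}

#' Cross-fit generalization evaluation
#'
#' Fixes the Karhunen-Loeve basis and the plane on a subset of runs (the
#' base random + force pair in the original design), projects every other
#' run - different lattice, pre-strain, constitutive law or mixed fraction -
#' onto that same basis, and summarizes the per-run relative estimation
#' error, reproducing the generalization experiment behind the estimator.
#'
#' @param trajectories named list of `destruction_trajectory` objects (or
#'   data frames with moment and `K_over_K0` columns).
#' @param fit_source names (or indices) of the runs used to fit the model.
#' @param eval_source runs to evaluate; default: all runs (the fit runs give
#'   in-sample errors).
#' @param moments moment columns to use.
#' @return An object of class `structfn_crossfit`: the fit, per-run error
#'   series, and a `summary` data frame with per-run max, median and
#'   quartiles of the percent error.
#' @export
crossfit_evaluation <- function(trajectories, fit_source,
                                eval_source = NULL,
                                moments = c("mu", "m2", "m3", "m4")) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  if (is.null(names(trajectories)))
    names(trajectories) <- paste0("run", seq_along(trajectories))
  fit_runs <- trajectories[fit_source]
  if (length(fit_runs) == 0L) stop("'fit_source' selects no runs")
  if (is.null(eval_source)) eval_source <- names(trajectories)
  fit <- structfn(fit_runs, moments = moments)
  errors <- list()
  rows <- list()
  for (nm in eval_source) {
    tr <- trajectories[[nm]]
    pm <- .pool_moments(tr, moments)
    if (is.null(pm$K)) stop("run '", nm, "' has no K_over_K0 response")
    e <- estimation_error(predict(fit, tr), pm$K)
    errors[[nm]] <- e
    q <- quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
    rows[[nm]] <- data.frame(run = nm, n_steps = length(e), max = max(e),
                             median = q[2], q1 = q[1], q3 = q[3],
                             in_sample = nm %in% names(fit_runs))
  }
  structure(list(fit = fit, errors = errors,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "structfn_crossfit")
}

#' @export
print.structfn_crossfit <- function(x, ...) {
  print(x$fit)
  cat("Per-run relative estimation error (% of measured K/K0):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.structfn_crossfit <- function(x, ...) {
  graphics::boxplot(x$errors, ylab = "relative error (%)",
                    las = 2, main = "stiffness estimation error by run", ...)
  invisible(x)
}
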