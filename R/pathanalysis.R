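## Path-coefficient analysis: partition of trait correlations with a
## dependent variable into direct effects (path coefficients) and indirect
## effects routed through correlated predictors.

#' Solve for direct path coefficients
#'
#' Direct effects are the standardized regression coefficients solving the
#' normal equations `R_x P = r_xy`, where `R_x` is the correlation matrix
#' among the explanatory traits and `r_xy` their correlations with the
#' dependent variable. Solved via QR; the condition number of `R_x` is
#' reported, with a warning above 1e3 (near-collinear predictor sets make the
#' coefficients extremely sensitive to rounding of the input correlations).
#'
#' @param R_x symmetric predictor correlation matrix (unit diagonal).
#' @param r_xy correlations of each predictor with the dependent variable.
#' @return list `P` (direct effects), `kappa` (condition number), `residual`
#'   (max abs residual of the solved system).
#' @export
solve_path <- function(R_x, r_xy) {
  R_x <- as.matrix(R_x)
  k <- nrow(R_x)
  if (ncol(R_x) != k || length(r_xy) != k) stop("dimension mismatch")
  if (max(abs(R_x - t(R_x))) > 1e-8) stop("R_x must be symmetric")
  if (max(abs(diag(R_x) - 1)) > 1e-8) stop("R_x must have unit diagonal")
  if (max(abs(R_x)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  kap <- kappa(R_x, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    off <- abs(R_x); diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1L, ]
    stop(sprintf("R_x is singular or numerically so; most collinear pair: %s, %s (r = %.3f)",
                 rownames(R_x)[ij[1L]] %||% ij[1L], colnames(R_x)[ij[2L]] %||% ij[2L],
                 R_x[ij[1L], ij[2L]]))
  }
  if (kap > 1e3)
    warning(sprintf("ill-conditioned predictor correlation matrix (condition number %.3g); direct effects are sensitive to rounding of the inputs", kap))
  P <- solve(qr(R_x, LAPACK = TRUE), as.numeric(r_xy))
  names(P) <- rownames(R_x)
  list(P = P, kappa = kap, residual = max(abs(R_x %*% P - r_xy)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indirect effects routed through correlated predictors
#'
#' `I[i, i'] = r_ii' * P_i'`: the indirect effect of predictor `i` on the
#' dependent variable mediated by predictor `i'`. The diagonal is `NA` (a
#' predictor's effect through itself is its direct effect).
#'
#' @param P direct effects.
#' @param R_x predictor correlation matrix.
#' @return k x k matrix with `NA` diagonal.
#' @export
indirect_effects <- function(P, R_x) {
  R_x <- as.matrix(R_x)
  if (length(P) != nrow(R_x)) stop("dimension mismatch")
  I <- R_x * rep(P, each = length(P))  # I[i, j] = R_x[i, j] * P[j]
  diag(I) <- NA_real_
  dimnames(I) <- dimnames(R_x)
  I
}

#' Reconstructed correlation of predictor i with the dependent variable
#'
#' `P_i + sum_{i' != i} I[i, i']`, identically row `i` of `R_x P`.
#'
#' @param P direct effects.
#' @param I indirect-effect matrix from [indirect_effects()].
#' @param i predictor index (or name).
#' @export
reconstruct_correlation <- function(P, I, i) {
  if (is.character(i)) i <- match(i, names(P))
  P[i] + sum(I[i, ], na.rm = TRUE)
}

#' Path coefficient of determination
#'
#' `R^2 = sum_i P_i r_iy`, the variance of the dependent variable explained
#' by the predictor set. Equals the squared multiple correlation when `P`
#' solves the exact normal equations; with rounded published coefficients it
#' may stray outside `[0, 1]`, in which case a warning is raised.
#'
#' @param P direct effects.
#' @param r_xy predictor-dependent correlations.
#' @export
path_r2 <- function(P, r_xy) {
  if (length(P) != length(r_xy)) stop("dimension mismatch")
  r2 <- sum(P * r_xy)
  if (r2 < 0 || r2 > 1)
    warning(sprintf("path R^2 = %.4f outside [0, 1]; inputs are not an exact correlation structure", r2))
  r2
}

#' Full path-coefficient decomposition
#'
#' Convenience wrapper running [solve_path()], [indirect_effects()],
#' correlation reconstruction and [path_r2()] for one dependent variable.
#'
#' @param cor_matrix full trait correlation matrix (e.g. `correlations(x)$r`
#'   or [lowp_trait_correlations()]).
#' @param predictors names of the explanatory traits.
#' @param dependent name of the dependent trait.
#' @return object of class `"path_decomposition"`: `direct`, `indirect`,
#'   `reconstructed`, `r_xy`, `r2`, `kappa`, `predictors`, `dependent`.
#' @export
path_analysis <- function(cor_matrix, predictors, dependent) {
  stopifnot(all(predictors %in% rownames(cor_matrix)),
            dependent %in% rownames(cor_matrix),
            !(dependent %in% predictors))
  R_x <- cor_matrix[predictors, predictors, drop = FALSE]
  r_xy <- cor_matrix[predictors, dependent]
  sol <- solve_path(R_x, r_xy)
  I <- indirect_effects(sol$P, R_x)
  recon <- vapply(seq_along(predictors), function(i)
    reconstruct_correlation(sol$P, I, i), numeric(1))
  names(recon) <- predictors
  structure(list(direct = sol$P, indirect = I, reconstructed = recon,
                 r_xy = r_xy, r2 = path_r2(sol$P, r_xy), kappa = sol$kappa,
                 predictors = predictors, dependent = dependent),
            class = "path_decomposition")
}

#' @export
print.path_decomposition <- function(x, digits = 3, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f", width = digits + 4)
  cat(sprintf("Path analysis: %s ~ %s\n", x$dependent,
              paste(x$predictors, collapse = " + ")))
  for (i in seq_along(x$predictors)) {
    p <- x$predictors[i]
    cat(sprintf("%s\n  Direct effect %s\n", p, fmt(x$direct[i])))
    for (j in seq_along(x$predictors)) {
      if (j == i) next
      cat(sprintf("  Indirect effect via %s %s\n", x$predictors[j],
                  fmt(x$indirect[i, j])))
    }
    cat(sprintf("  Correlation (r) %s\n", fmt(x$reconstructed[i])))
  }
  cat(sprintf("Coefficient of determination %s (condition number %.1f)\n",
              fmt(x$r2), x$kappa))
  invisible(x)
}

#' Table-shaped export of a path decomposition
#'
#' @param x a `"path_decomposition"`.
#' @return data frame with one row per (predictor, component) in the layout
#'   direct / indirect-via-each / reconstructed correlation, plus an R^2 row.
#' @export
path_table <- function(x) {
  stopifnot(inherits(x, "path_decomposition"))
  rows <- list()
  for (i in seq_along(x$predictors)) {
    p <- x$predictors[i]
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = p, component = "direct", value = unname(x$direct[i]))
    for (j in seq_along(x$predictors)) {
      if (j == i) next
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, component = paste0("indirect_via_", x$predictors[j]),
        value = x$indirect[i, j])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = p, component = "correlation", value = unname(x$reconstructed[i]))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    predictor = "", component = "r_squared", value = x$r2)
  out <- do.call(rbind, rows)
  out$dependent <- x$dependent
  out[, c("dependent", "predictor", "component", "value")]
}
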