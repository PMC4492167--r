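## Multiple interval mapping engine: Haley-Knott design construction,
## multivariate least-squares fits, determinant-ratio LOD, genome scans,
## resampled score-statistic thresholds, forward model search, epistasis,
## effect tests, variance explained and drop-LOD support intervals.
## Single-trait MIM is the T = 1 case of every routine.

empty_terms <- function() data.frame(chrom = character(0), pos = numeric(0),
                                     stringsAsFactors = FALSE)

## grid column index of each term; error if a term is off-grid
term_grid_index <- function(probs, terms) {
  if (nrow(terms) == 0L) return(integer(0))
  vapply(seq_len(nrow(terms)), function(i) {
    idx <- which(probs$grid$chrom == as.character(terms$chrom[i]) &
                   abs(probs$grid$pos - terms$pos[i]) < 1e-8)
    if (length(idx) != 1L)
      stop(sprintf("term %d (chrom %s, %.3f cM) is not a grid position",
                   i, terms$chrom[i], terms$pos[i]))
    idx[1L]
  }, integer(1))
}

#' Haley-Knott design matrix for a QTL model
#'
#' Additive column `r` holds the expected Cockerham code `xhat = 2q - 1` at
#' QTL position `r`; an epistasis column for pair `(r, l)` is the elementwise
#' product of the two additive columns (products of expectations, the
#' standard Haley-Knott convention).
#'
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param terms data frame `chrom`, `pos` of QTL positions (grid positions).
#' @param pairs integer matrix with two columns indexing rows of `terms`, or NULL.
#' @return lines x (terms + pairs) matrix with columns `Q1, Q2, ...` and `Qr:Ql`.
#' @export
design_matrix <- function(probs, terms, pairs = NULL) {
  gidx <- term_grid_index(probs, terms)
  X <- probs$xhat[, gidx, drop = FALSE]
  colnames(X) <- if (length(gidx)) paste0("Q", seq_along(gidx)) else character(0)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    if (any(pairs > nrow(terms)) || any(pairs < 1L))
      stop("epistatic pair indices must reference included terms")
    P <- sapply(seq_len(nrow(pairs)), function(k)
      X[, pairs[k, 1L]] * X[, pairs[k, 2L]])
    colnames(P) <- paste0("Q", pairs[, 1L], ":Q", pairs[, 2L])
    X <- cbind(X, P)
  }
  rownames(X) <- probs$lines
  X
}

## multivariate least squares with intercept; raw and ML residual covariance
## and the multivariate-normal log-likelihood
fit_mvreg <- function(Z, X) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  Tn <- ncol(Z)
  X1 <- cbind("(Intercept)" = rep(1, n), X)
  if (n <= ncol(X1)) stop("more coefficients than lines")
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) {
    drop <- setdiff(seq_len(ncol(X1)), qx$pivot[seq_len(qx$rank)])
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X1)[drop], collapse = ", "))
  }
  coef <- qr.coef(qx, Z)
  E <- qr.resid(qx, Z)
  SigmaRaw <- crossprod(E)
  Sigma <- SigmaRaw / n
  ld <- determinant(Sigma, logarithm = TRUE)
  logdet <- if (ld$sign > 0) as.numeric(ld$modulus) else -Inf
  ll <- -n / 2 * (Tn * log(2 * pi) + logdet + Tn)
  list(coef = coef, E = E, Sigma = Sigma, SigmaRaw = SigmaRaw,
       logdet = logdet, logLik = ll, n = n, T = Tn, qr = qx)
}

#' Fit a QTL model by Haley-Knott regression
#'
#' Per-trait least squares with the shared design of [design_matrix()]
#' (intercept included); the residual covariance is the maximum-likelihood
#' `E'E / n` and the reported log-likelihood is multivariate normal. With one
#' trait this is exactly single-trait MIM.
#'
#' @param Z standardized line x trait matrix (or a `"trait_matrix"`).
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param terms data frame `chrom`, `pos`; may be empty.
#' @param pairs integer matrix of epistatic pairs (2 columns), or NULL.
#' @return object of class `"qtl_model"` with elements `terms`, `pairs`,
#'   `mu`, `beta` (terms x traits), `w` (pairs x traits), `Sigma`, `logLik`,
#'   `n`, `traits`, plus the design `X`, residuals `E` and trait matrix `Z`.
#' @export
fit_qtl_model <- function(Z, probs, terms = empty_terms(), pairs = NULL) {
  Z <- as_trait_z(Z)
  if (nrow(Z) != nrow(probs$q)) stop("trait matrix / probabilities line mismatch")
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (nrow(pairs) == 0L) pairs <- NULL
  }
  X <- design_matrix(probs, terms, pairs)
  fit <- fit_mvreg(Z, X)
  m <- nrow(terms)
  npair <- if (is.null(pairs)) 0L else nrow(pairs)
  beta <- fit$coef[seq_len(m) + 1L, , drop = FALSE]
  w <- if (npair) fit$coef[m + 1L + seq_len(npair), , drop = FALSE] else NULL
  structure(list(terms = terms, pairs = pairs,
                 mu = fit$coef[1L, ], beta = beta, w = w,
                 Sigma = fit$Sigma, SigmaRaw = fit$SigmaRaw,
                 logdet = fit$logdet, logLik = fit$logLik,
                 n = fit$n, traits = colnames(Z), X = X, E = fit$E, Z = Z),
            class = "qtl_model")
}

as_trait_z <- function(Z) {
  if (inherits(Z, "trait_matrix")) Z <- Z$z
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("trait", seq_len(ncol(Z)))
  Z
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("QTL model: %d term(s), %d epistatic pair(s), %d trait(s), n = %d, logLik = %.3f\n",
              nrow(x$terms), if (is.null(x$pairs)) 0L else nrow(x$pairs),
              length(x$traits), x$n, x$logLik))
  if (nrow(x$terms)) {
    df <- x$terms
    df$effects <- apply(round(x$beta, 3), 1, paste, collapse = "/")
    print(df)
  }
  invisible(x)
}

#' LOD score between two nested model fits
#'
#' `LOD = (n/2) log10(|Sigma_0| / |Sigma_1|)`, the multivariate determinant
#' ratio; for one trait this reduces to `(n/2) log10(RSS_0 / RSS_1)`. The
#' reduced model must be nested in the full one (checked via the
#' log-likelihoods up to numerical tolerance).
#'
#' @param fit0 reduced `"qtl_model"`.
#' @param fit1 full `"qtl_model"` on the same data.
#' @return nonnegative LOD score.
#' @export
lod_compare <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "qtl_model"), inherits(fit1, "qtl_model"))
  if (fit0$n != fit1$n || length(fit0$traits) != length(fit1$traits))
    stop("fits are not on the same data")
  lod <- fit0$n / 2 * (fit0$logdet - fit1$logdet) / log(10)
  if (lod < -1e-6) stop("models are not nested (reduced model fits better)")
  max(lod, 0)
}

## ---- score machinery -------------------------------------------------------
## For each candidate column c (a grid position's xhat, or an epistasis
## product), residualized against the current design: per-line score
## contributions u_i = c~_i * e_i (T-vector). Observed statistic
## s' V^{-1} s with s = colSums(U), V = U'U (the conditional covariance of a
## wild-bootstrap resample g'U with iid standard-normal weights g shared
## across candidates and traits). Ustack holds the whitened U blocks so a
## resampled genome-wide maximum is a single matrix product away.
score_machinery <- function(model, C) {
  E0 <- model$E
  n <- nrow(E0)
  Tn <- ncol(E0)
  X1 <- cbind(1, model$X)
  qx <- qr(X1)
  Ct <- qr.resid(qx, C)
  P <- ncol(Ct)
  a <- colSums(Ct^2)
  active <- a > 1e-10 * n
  stat <- numeric(P)
  Ustack <- matrix(0, n, Tn * P)
  for (p in which(active)) {
    U <- E0 * Ct[, p]
    V <- crossprod(U)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R))
      R <- chol(V + diag(1e-10 * max(diag(V), 1e-300), Tn))
    Ut <- U %*% backsolve(R, diag(Tn))
    stat[p] <- sum(colSums(Ut)^2)
    Ustack[, (p - 1L) * Tn + seq_len(Tn)] <- Ut
  }
  ## determinant-lemma LOD for adding each candidate to the model
  S <- crossprod(E0, Ct)
  M <- tryCatch(solve(model$SigmaRaw), error = function(e) NULL)
  lod <- rep(0, P)
  if (!is.null(M)) {
    qf <- colSums(S * (M %*% S))
    ratio <- pmax(1 - qf / pmax(a, 1e-300), 1e-300)
    lod <- ifelse(active, -model$n / 2 * log10(ratio), 0)
    lod <- pmax(lod, 0)
  }
  list(stat = stat, lod = lod, Ustack = Ustack, active = active,
       n = n, T = Tn, P = P)
}

## candidate additive columns: all grid positions not already in the model
candidate_grid <- function(probs, model) {
  gidx <- term_grid_index(probs, model$terms)
  keep <- setdiff(seq_len(nrow(probs$grid)), gidx)
  list(cols = probs$xhat[, keep, drop = FALSE], grid = probs$grid[keep, , drop = FALSE])
}

#' Genome scan for adding one QTL
#'
#' At every grid position not already in the model, the LOD score and the
#' score statistic for adding one additive term jointly across all traits
#' (single-trait MIM when the trait matrix has one column).
#'
#' @param Z standardized trait matrix (or `"trait_matrix"`).
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model current `"qtl_model"` (default: empty model).
#' @return data frame of class `"scan_profile"`: `chrom`, `pos`, `lod`, `score`.
#' @export
scan_add_qtl <- function(Z, probs, model = NULL) {
  if (is.null(model)) model <- fit_qtl_model(Z, probs)
  cand <- candidate_grid(probs, model)
  mach <- score_machinery(model, cand$cols)
  out <- data.frame(chrom = cand$grid$chrom, pos = cand$grid$pos,
                    lod = mach$lod, score = mach$stat,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_profile", "data.frame")
  out
}

## resampled genome-wide maxima of the score statistic: one standard-normal
## weight per line, shared across candidates and traits within a resample
resample_maxima <- function(mach, K, seed, chunk = 250L) {
  set.seed(seed)
  Tn <- mach$T
  P <- mach$P
  maxima <- numeric(0)
  done <- 0L
  while (done < K) {
    k <- min(chunk, K - done)
    G <- matrix(stats::rnorm(k * mach$n), k, mach$n)
    M2 <- (G %*% mach$Ustack)^2
    stats <- matrix(0, k, P)
    for (t in seq_len(Tn))
      stats <- stats + M2[, (seq_len(P) - 1L) * Tn + t, drop = FALSE]
    maxima <- c(maxima, apply(stats, 1L, max))
    done <- done + k
  }
  maxima
}

#' Resampled score-statistic genome-wide threshold
#'
#' Builds the per-line score contributions of every candidate position given
#' the current model, perturbs them with standard-normal wild-bootstrap
#' weights shared across positions and traits within a resample (preserving
#' genome-wide and cross-trait dependence), and takes the empirical
#' `(1 - alpha)` quantile of the `K` resampled genome-wide maxima as the
#' threshold on the score-statistic scale. No model refitting is involved,
#' which is what makes the scheme cheap enough to recompute at every forward
#' round.
#'
#' @param Z standardized trait matrix.
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model current `"qtl_model"` (default: empty model).
#' @param alpha genome-wide level (e.g. 0.15 for main effects, 0.05 for epistasis).
#' @param K number of resamples (>= 100).
#' @param seed integer seed.
#' @param candidates optional matrix of candidate columns (defaults to all
#'   grid positions not in the model); used by the epistasis search to
#'   restrict the maximum to the candidate pairs.
#' @return object of class `"score_threshold"`: `alpha`, `K`, `seed`,
#'   `threshold`, `maxima`, `observed` (per-candidate observed statistics),
#'   `observed_max`, `lod` (per-candidate LOD), `exceeds` (observed max >
#'   threshold), and the candidate `grid` when applicable.
#' @export
resampled_score_threshold <- function(Z, probs, model = NULL, alpha = 0.15,
                                      K = 1000L, seed = 1L, candidates = NULL) {
  if (K < 100L) stop("K must be >= 100 for a stable quantile")
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(model)) model <- fit_qtl_model(Z, probs)
  grid <- NULL
  if (is.null(candidates)) {
    cand <- candidate_grid(probs, model)
    candidates <- cand$cols
    grid <- cand$grid
  }
  mach <- score_machinery(model, candidates)
  maxima <- resample_maxima(mach, K, seed)
  thr <- sort(maxima)[ceiling((1 - alpha) * K)]
  structure(list(alpha = alpha, K = K, seed = seed, threshold = thr,
                 maxima = maxima, observed = mach$stat,
                 observed_max = max(mach$stat), lod = mach$lod,
                 exceeds = max(mach$stat) > thr, grid = grid),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("Resampled score threshold: %.3f at alpha = %.2f (K = %d); observed max %.3f (%s)\n",
              x$threshold, x$alpha, x$K, x$observed_max,
              if (x$exceeds) "exceeds" else "below"))
  invisible(x)
}

#' Forward search for main-effect QTL
#'
#' Up to `rounds` iterations, each adding the single best grid position (ties
#' broken toward the lowest chromosome, then the lowest cM) if its score
#' statistic exceeds the genome-wide threshold freshly recomputed against the
#' current model; stops early otherwise. Included positions are then refined
#' by [refine_positions()].
#'
#' @param Z standardized trait matrix (or `"trait_matrix"`).
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param alpha_main genome-wide level for main effects (default 0.15).
#' @param rounds maximum number of additions (default 3).
#' @param K resamples per threshold.
#' @param seed integer seed (round `k` uses `seed + k`).
#' @return fitted `"qtl_model"`.
#' @export
forward_search <- function(Z, probs, alpha_main = 0.15, rounds = 3L,
                           K = 1000L, seed = 1L) {
  model <- fit_qtl_model(Z, probs)
  if (rounds < 1L) return(model)
  for (k in seq_len(rounds)) {
    thr <- resampled_score_threshold(Z, probs, model, alpha = alpha_main,
                                     K = K, seed = seed + k)
    if (!thr$exceeds) break
    best <- which.max(thr$observed)  # grid order = lowest chrom, lowest cM first
    new_terms <- rbind(model$terms,
                       data.frame(chrom = thr$grid$chrom[best],
                                  pos = thr$grid$pos[best],
                                  stringsAsFactors = FALSE))
    model <- fit_qtl_model(Z, probs, terms = new_terms)
  }
  if (nrow(model$terms) > 0L) model <- refine_positions(Z, probs, model)
  model
}

## full-model refit with term i moved to pos (pairs recomputed automatically)
move_term <- function(Z, probs, model, i, pos) {
  terms <- model$terms
  terms$pos[i] <- pos
  fit_qtl_model(Z, probs, terms = terms, pairs = model$pairs)
}

#' Re-estimate QTL positions coordinate-wise
#'
#' Each term is re-scanned over its own chromosome's grid holding all other
#' terms (and any epistatic pairs, recomputed as the term moves) fixed, and
#' moved to the position maximizing the full-model likelihood; sweeps repeat
#' until no term moves or `max_sweeps` is reached. The full-model LOD never
#' decreases (each move is an argmax that includes the current position).
#'
#' @param Z standardized trait matrix.
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model fitted `"qtl_model"` with at least one term.
#' @param max_sweeps sweep limit (default 10).
#' @return refitted `"qtl_model"`.
#' @export
refine_positions <- function(Z, probs, model, max_sweeps = 10L) {
  stopifnot(inherits(model, "qtl_model"))
  if (nrow(model$terms) == 0L) stop("model has no terms to refine")
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(nrow(model$terms))) {
      cc <- model$terms$chrom[i]
      cand_pos <- probs$grid$pos[probs$grid$chrom == cc]
      other <- model$terms$pos[-i][model$terms$chrom[-i] == cc]
      cand_pos <- setdiff(cand_pos, other)
      ll <- vapply(cand_pos, function(p)
        move_term(Z, probs, model, i, p)$logLik, numeric(1))
      best <- cand_pos[which.max(ll)]
      if (abs(best - model$terms$pos[i]) > 1e-9) {
        model <- move_term(Z, probs, model, i, best)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  model
}

#' Forward search for epistatic interactions among included QTL
#'
#' Candidate set: all unordered pairs of included terms not yet in the model.
#' Pairs are added one at a time while the best candidate's score statistic
#' exceeds the resampled threshold at `alpha_epi` (maxima taken over the
#' candidate pairs). After the search, a pair is retained only if at least
#' one of its per-trait epistatic effects is significant at `p < 0.05` by
#' [effect_pvalues()]; all per-trait effects of retained pairs are reported.
#'
#' @param Z standardized trait matrix.
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model fitted `"qtl_model"` with main-effect terms.
#' @param alpha_epi genome-wide level for the epistasis search (default 0.05).
#' @param K resamples per threshold and for the retention p-values.
#' @param seed integer seed.
#' @return refitted `"qtl_model"` (unchanged, with a message, if < 2 terms).
#' @export
epistasis_search <- function(Z, probs, model, alpha_epi = 0.05,
                             K = 1000L, seed = 1L) {
  stopifnot(inherits(model, "qtl_model"))
  m <- nrow(model$terms)
  if (m < 2L) {
    message("epistasis_search: fewer than 2 terms in the model; nothing to test")
    return(model)
  }
  all_pairs <- t(utils::combn(m, 2L))
  round_k <- 0L
  repeat {
    round_k <- round_k + 1L
    have <- model$pairs
    remaining <- all_pairs[!apply(all_pairs, 1L, function(pr)
      !is.null(have) && any(have[, 1L] == pr[1L] & have[, 2L] == pr[2L])), ,
      drop = FALSE]
    if (nrow(remaining) == 0L) break
    Xadd <- design_matrix(probs, model$terms, remaining)
    Xadd <- Xadd[, m + seq_len(nrow(remaining)), drop = FALSE]
    thr <- resampled_score_threshold(Z, probs, model, alpha = alpha_epi,
                                     K = K, seed = seed + 100L + round_k,
                                     candidates = Xadd)
    if (!thr$exceeds) break
    best <- remaining[which.max(thr$observed), , drop = FALSE]
    model <- fit_qtl_model(Z, probs, terms = model$terms,
                           pairs = rbind(model$pairs, best))
  }
  if (!is.null(model$pairs) && nrow(model$pairs) > 0L) {
    tests <- effect_pvalues(Z, probs, model, K = K, seed = seed + 500L)
    keep <- vapply(seq_len(nrow(model$pairs)), function(k) {
      nm <- paste0("Q", model$pairs[k, 1L], ":Q", model$pairs[k, 2L])
      any(tests$p[tests$effect == nm] < 0.05)
    }, logical(1))
    if (!all(keep))
      model <- fit_qtl_model(Z, probs, terms = model$terms,
                             pairs = model$pairs[keep, , drop = FALSE])
  }
  model
}

#' Per-effect significance by score-statistic resampling
#'
#' For every effect (additive term x trait and epistatic pair x trait), the
#' effect's score statistic is computed under the model excluding that
#' column, and its p-value is the upper tail of the wild-bootstrap resampled
#' null distribution of the same statistic. Star codes: `+` p < 0.1,
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param Z standardized trait matrix.
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model fitted `"qtl_model"`.
#' @param K number of resamples.
#' @param seed integer seed.
#' @return data frame `effect`, `trait`, `estimate`, `p`, `stars`.
#' @export
effect_pvalues <- function(Z, probs, model, K = 1000L, seed = 1L) {
  stopifnot(inherits(model, "qtl_model"))
  X <- model$X
  if (ncol(X) == 0L) stop("model has no effects to test")
  Zm <- model$Z
  n <- nrow(Zm)
  Tn <- ncol(Zm)
  set.seed(seed)
  B <- rbind(model$beta, model$w)
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    X1m <- cbind(1, X[, -j, drop = FALSE])
    qx <- qr(X1m)
    Em <- qr.resid(qx, Zm)
    ct <- qr.resid(qx, X[, j])
    U <- Em * ct
    s <- colSums(U)
    v <- pmax(colSums(U^2), 1e-300)
    stat <- s^2 / v
    G <- matrix(stats::rnorm(K * n), K, n)
    M2 <- (G %*% U)^2  # K x T
    p <- vapply(seq_len(Tn), function(t)
      (1 + sum(M2[, t] / v[t] >= stat[t])) / (K + 1), numeric(1))
    out[[j]] <- data.frame(effect = colnames(X)[j], trait = colnames(Zm),
                           estimate = B[j, ], p = p, stars = star_code(p),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Star codes for p-values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `+` p < 0.1, `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @export
star_code <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.1, "+", ""))))
}

#' Variance explained per effect and per trait
#'
#' For each effect column `j` and trait `t`,
#' `R^2 = 100 * Var_lines(b_jt x_j) / Var_lines(z_t)`; per trait,
#' `R^2_T = 100 * Var_lines(full fitted genetic value) / Var_lines(z_t)`,
#' computed from the full fitted model including non-significant effects.
#'
#' @param model fitted `"qtl_model"`.
#' @return list `per_effect` (effects x traits matrix, percent) and `total`
#'   (per-trait percent).
#' @export
qtl_r2 <- function(model) {
  stopifnot(inherits(model, "qtl_model"))
  X <- model$X
  Zm <- model$Z
  vz <- apply(Zm, 2, stats::var)
  B <- rbind(model$beta, model$w)
  if (ncol(X) == 0L)
    return(list(per_effect = matrix(0, 0, ncol(Zm),
                                    dimnames = list(NULL, colnames(Zm))),
                total = stats::setNames(rep(0, ncol(Zm)), colnames(Zm))))
  per <- matrix(0, ncol(X), ncol(Zm), dimnames = list(colnames(X), colnames(Zm)))
  for (j in seq_len(ncol(X)))
    per[j, ] <- 100 * B[j, ]^2 * stats::var(X[, j]) / vz
  Ghat <- X %*% B
  total <- 100 * apply(Ghat, 2, stats::var) / vz
  list(per_effect = per, total = total)
}

#' Drop-LOD support interval for one QTL
#'
#' Profiles the term's position over its chromosome's grid (all other terms
#' and epistatic pairs held fixed, pairs involving the term recomputed as it
#' moves), against the reduced model with the term (and its pairs) removed.
#' The interval is the contiguous grid run around the peak where
#' `LOD >= peak - drop`; flanking markers are the nearest map markers at or
#' outside each bound. If the whole profile varies by less than `drop`, the
#' interval spans the chromosome and is flagged flat.
#'
#' @param Z standardized trait matrix.
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model fitted `"qtl_model"`.
#' @param term_index which term to profile.
#' @param drop LOD drop (default 1.5, an approximate 95% interval).
#' @return object of class `"support_interval"`: `term`, `chrom`, `peak_pos`,
#'   `peak_lod`, `left`, `right`, `flank_left`, `flank_right`, `flat`,
#'   `profile` (data frame `pos`, `lod`).
#' @export
support_interval <- function(Z, probs, model, term_index, drop = 1.5) {
  stopifnot(inherits(model, "qtl_model"),
            term_index >= 1L, term_index <= nrow(model$terms))
  cc <- model$terms$chrom[term_index]
  cand_pos <- probs$grid$pos[probs$grid$chrom == cc]
  other <- model$terms$pos[-term_index][model$terms$chrom[-term_index] == cc]
  cand_pos <- setdiff(cand_pos, other)
  red_terms <- model$terms[-term_index, , drop = FALSE]
  red_pairs <- NULL
  if (!is.null(model$pairs)) {
    keep <- model$pairs[, 1L] != term_index & model$pairs[, 2L] != term_index
    rp <- model$pairs[keep, , drop = FALSE]
    if (nrow(rp)) {
      rp[rp > term_index] <- rp[rp > term_index] - 1L
      red_pairs <- rp
    }
  }
  fit0 <- fit_qtl_model(Z, probs, terms = red_terms, pairs = red_pairs)
  lod <- vapply(cand_pos, function(p)
    lod_compare(fit0, move_term(Z, probs, model, term_index, p)), numeric(1))
  peak <- which.max(lod)
  flat <- (max(lod) - min(lod)) < drop
  if (flat) {
    li <- 1L
    ri <- length(cand_pos)
    warning(sprintf("flat LOD profile for term %d on chromosome %s; interval spans the chromosome",
                    term_index, cc))
  } else {
    keep <- lod >= lod[peak] - drop
    li <- peak
    while (li > 1L && keep[li - 1L]) li <- li - 1L
    ri <- peak
    while (ri < length(cand_pos) && keep[ri + 1L]) ri <- ri + 1L
  }
  mpos <- probs$map$pos[probs$map$chrom == cc]
  mnames <- probs$map$marker[probs$map$chrom == cc]
  fl <- mnames[max(c(which(mpos <= cand_pos[li] + 1e-9), 1L))]
  fr <- mnames[min(c(which(mpos >= cand_pos[ri] - 1e-9), length(mpos)))]
  structure(list(term = term_index, chrom = cc,
                 peak_pos = cand_pos[peak], peak_lod = lod[peak],
                 left = cand_pos[li], right = cand_pos[ri],
                 flank_left = fl, flank_right = fr, flat = flat,
                 profile = data.frame(pos = cand_pos, lod = lod)),
            class = "support_interval")
}

#' @export
print.support_interval <- function(x, ...) {
  cat(sprintf("Term %d (chrom %s): peak %.1f cM, LOD %.2f, interval [%.1f, %.1f] cM (%s - %s)%s\n",
              x$term, x$chrom, x$peak_pos, x$peak_lod, x$left, x$right,
              x$flank_left, x$flank_right, if (x$flat) " [flat]" else ""))
  invisible(x)
}

#' Complete MIM / MT-MIM analysis
#'
#' Forward main-effect search ([forward_search()]), then the epistasis search
#' among included QTL ([epistasis_search()]). With a one-column trait matrix
#' this is single-trait MIM; with several columns, MT-MIM.
#'
#' @param Z standardized trait matrix (or `"trait_matrix"`).
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param alpha_main genome-wide level for main effects (default 0.15).
#' @param alpha_epi genome-wide level for epistasis (default 0.05).
#' @param rounds maximum main-effect additions (default 3).
#' @param K resamples per threshold.
#' @param seed integer seed.
#' @return fitted `"qtl_model"`.
#' @export
map_qtl <- function(Z, probs, alpha_main = 0.15, alpha_epi = 0.05,
                    rounds = 3L, K = 1000L, seed = 1L) {
  model <- forward_search(Z, probs, alpha_main = alpha_main, rounds = rounds,
                          K = K, seed = seed)
  if (nrow(model$terms) >= 2L)
    model <- epistasis_search(Z, probs, model, alpha_epi = alpha_epi,
                              K = K, seed = seed)
  model
}
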