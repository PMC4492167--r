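## Phenotype preparation: per-trait two-way fixed-effects model with
## homoscedastic or per-genotype residual variances, fitted genotype values,
## standardization, heritability and trait correlations.

check_records <- function(records) {
  need <- c("line", "block", "trait", "value")
  if (!all(need %in% names(records)))
    stop("phenotype records need columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(records$value))) stop("non-finite phenotype values")
  key <- paste(records$line, records$block, records$trait)
  if (anyDuplicated(key))
    stop("duplicated (line, block, trait) cells: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  invisible(records)
}

#' Fit the per-trait phenotypic model
#'
#' Fits `y_ij = mu + B_i + G_j + e_ij` for one trait by maximum likelihood,
#' with blocks and genotypes as fixed, sum-to-zero effects. Residuals are
#' either homoscedastic, `e ~ N(0, sigma^2)`, or heteroscedastic by genotype,
#' `e_ij ~ N(0, sigma_j^2)`; the latter is maximized by coordinate ascent
#' (generalized least squares for the mean given the variances, closed-form
#' per-genotype variances given the mean), so its log-likelihood never falls
#' below the homoscedastic one. Because the unconstrained by-genotype
#' likelihood is unbounded (block parameters can chase a single genotype),
#' the per-genotype variances are constrained to at least 1e-3 of the
#' homoscedastic variance.
#'
#' @param records long data frame `line`, `block`, `trait`, `value`.
#' @param trait trait name to fit.
#' @param variance_model `"homoscedastic"` or `"by_genotype"`.
#' @param tol,max_iter convergence controls for the heteroscedastic fit.
#' @return object of class `"trait_fit"`: intercept `mu`, sum-to-zero `block_effects`
#'   and `genotype_effects`, `sigma2` (scalar or per-genotype), ML `logLik`,
#'   `variance_model`, and bookkeeping (`n`, `J`, `r`).
#' @export
fit_trait_model <- function(records, trait,
                            variance_model = c("homoscedastic", "by_genotype"),
                            tol = 1e-10, max_iter = 200L) {
  variance_model <- match.arg(variance_model)
  check_records(records)
  d <- records[records$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for trait ", trait)
  line <- factor(d$line)
  block <- factor(d$block)
  if (nlevels(block) < 2L) stop("need at least 2 blocks")
  X <- stats::model.matrix(~ block + line,
                           data = data.frame(block = block, line = line),
                           contrasts.arg = list(block = "contr.sum", line = "contr.sum"))
  if (qr(X)$rank < ncol(X)) {
    tab <- table(line, block)
    bad <- rownames(tab)[rowSums(tab > 0) < 2L]
    stop("singular design; genotypes observed in < 2 blocks: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  y <- d$value
  n <- length(y)
  J <- nlevels(line)
  fit0 <- stats::lm.fit(X, y)
  s2 <- sum(fit0$residuals^2) / n
  ll_hom <- -n / 2 * (log(2 * pi * s2) + 1)
  if (variance_model == "homoscedastic") {
    beta <- fit0$coefficients
    sigma2 <- s2
    ll <- ll_hom
  } else {
    beta <- fit0$coefficients
    res <- fit0$residuals
    jidx <- as.integer(line)
    # The unconstrained by-genotype ML is unbounded: the shared block
    # parameters can chase one genotype's few observations and send its
    # variance to zero. Variances are floored at 1e-3 of the homoscedastic
    # estimate (a sd ratio of ~0.03), far below any plausible real
    # heterogeneity, making this a constrained ML fit.
    floor_j <- 1e-3 * s2
    sig_j <- pmax(as.numeric(tapply(res^2, jidx, mean)), floor_j)
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      w <- 1 / sig_j[jidx]
      fitw <- stats::lm.wfit(X, y, w)
      res <- y - X %*% fitw$coefficients
      sig_j <- pmax(as.numeric(tapply(res^2, jidx, mean)), floor_j)
      ll_new <- -n / 2 * log(2 * pi) -
        0.5 * sum(tabulate(jidx, J) * log(sig_j)) -
        0.5 * sum(res^2 / sig_j[jidx])
      if (is.finite(ll) && abs(ll_new - ll) < tol) { ll <- ll_new; beta <- fitw$coefficients; break }
      ll <- ll_new
      beta <- fitw$coefficients
    }
    sigma2 <- stats::setNames(sig_j, levels(line))
  }
  nb <- nlevels(block)
  bcoef <- beta[seq(2, nb)]
  gcoef <- beta[seq(nb + 1, nb + J - 1)]
  block_effects <- stats::setNames(c(bcoef, -sum(bcoef)), levels(block))
  genotype_effects <- stats::setNames(c(gcoef, -sum(gcoef)), levels(line))
  structure(list(trait = trait, mu = unname(beta[1L]),
                 block_effects = block_effects,
                 genotype_effects = genotype_effects,
                 sigma2 = sigma2, logLik = ll,
                 variance_model = variance_model, n = n, J = J,
                 r = nlevels(block),
                 residuals = as.numeric(y - X %*% beta),
                 genotype_index = as.integer(line), rank = ncol(X)),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Trait model '%s' (%s): %d lines, %d blocks, logLik %.3f\n",
              x$trait, x$variance_model, x$J, x$r, x$logLik))
  invisible(x)
}

#' Compare the two residual-variance models
#'
#' Tests homogeneity of the per-genotype residual variances against the
#' chi-square reference with `J - 1` degrees of freedom. The raw likelihood
#' ratio `2 (llhet - llhom)` is severely anti-conservative when each genotype
#' contributes only a few replicates (at four blocks the per-genotype
#' variances carry about three residual degrees of freedom each, and the raw
#' statistic rejects a true homoscedastic model almost always), so the
#' selection statistic is the Bartlett-corrected form of the same likelihood
#' ratio: residual sums of squares of the shared mean structure grouped by
#' genotype, weighted by their residual degrees of freedom and divided by the
#' Bartlett scale factor. Its size is close to nominal at the designs this
#' package targets. The heteroscedastic model is selected when `p < level`;
#' the raw log-likelihood ratio is also reported as `lrt_raw`.
#'
#' @param fit_homo,fit_het [fit_trait_model()] fits of the same data.
#' @param level selection level (default 0.05).
#' @return list `statistic` (Bartlett-corrected), `lrt_raw`, `df`, `p`,
#'   `selected` (one of the two fits), `variance_model`.
#' @export
select_variance_model <- function(fit_homo, fit_het, level = 0.05) {
  stopifnot(inherits(fit_homo, "trait_fit"), inherits(fit_het, "trait_fit"))
  if (fit_homo$variance_model != "homoscedastic" ||
      fit_het$variance_model != "by_genotype")
    stop("arguments must be the homoscedastic and by_genotype fits, in that order")
  if (fit_homo$trait != fit_het$trait || fit_homo$n != fit_het$n ||
      fit_homo$J != fit_het$J)
    stop("fits are not nested versions of the same model")
  J <- fit_homo$J
  n <- fit_homo$n
  jidx <- fit_homo$genotype_index
  nj <- tabulate(jidx, J)
  nu <- n - fit_homo$rank
  nuj <- nj * nu / n  # residual df allocated proportionally to group size
  rssj <- as.numeric(tapply(fit_homo$residuals^2, jidx, sum))
  sj <- pmax(rssj / nuj, 1e-300)
  sp <- sum(rssj) / nu
  B <- nu * log(sp) - sum(nuj * log(sj))
  C <- 1 + (sum(1 / nuj) - 1 / nu) / (3 * (J - 1))
  stat <- max(0, B / C)
  df <- J - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  het <- p < level
  list(statistic = stat, lrt_raw = max(0, 2 * (fit_het$logLik - fit_homo$logLik)),
       df = df, p = p,
       selected = if (het) fit_het else fit_homo,
       variance_model = if (het) "by_genotype" else "homoscedastic")
}

#' Fitted genotype values from a trait model
#'
#' One value per line: `mu + G_j`, the least-squares genotype mean adjusted
#' for block effects.
#'
#' @param fit a [fit_trait_model()] fit.
#' @return named numeric vector over lines.
#' @export
genotype_fitted_values <- function(fit) {
  stopifnot(inherits(fit, "trait_fit"))
  fit$mu + fit$genotype_effects
}

#' Standardize a numeric vector to zero mean and unit sd
#'
#' Uses the sample standard deviation (n - 1 denominator). The centering and
#' scale are attached as attributes `"center"` and `"scale"` for
#' back-transformation.
#'
#' @param x numeric vector with positive sd.
#' @export
standardize <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) stop("cannot standardize a constant trait")
  structure((x - m) / s, center = m, scale = s)
}

#' Prepare the standardized trait matrix for QTL mapping
#'
#' For each trait: fit both residual-variance models, keep the better one by
#' the likelihood-ratio test ([select_variance_model()]), extract fitted
#' genotype values and standardize them across lines. The standardized
#' line x trait matrix is the input to MIM/MT-MIM.
#'
#' @param records long phenotype data frame `line`, `block`, `trait`, `value`.
#' @param traits traits to include (default: all present, in order of appearance).
#' @param select_variance if FALSE, always use the homoscedastic model.
#' @return object of class `"trait_matrix"`: list with `z` (line x trait
#'   standardized matrix), `fitted` (unstandardized), `center`, `scale`,
#'   `variance_model` and `lrt_p` per trait.
#' @export
prep_traits <- function(records, traits = NULL, select_variance = TRUE) {
  check_records(records)
  if (is.null(traits)) traits <- unique(records$trait)
  fits <- vector("list", length(traits))
  lrt_p <- vmod <- stats::setNames(rep(NA, length(traits)), traits)
  for (k in seq_along(traits)) {
    fh <- fit_trait_model(records, traits[k], "homoscedastic")
    if (select_variance) {
      fg <- fit_trait_model(records, traits[k], "by_genotype")
      sel <- select_variance_model(fh, fg)
      fits[[k]] <- sel$selected
      lrt_p[k] <- sel$p
      vmod[k] <- sel$variance_model
    } else {
      fits[[k]] <- fh
      vmod[k] <- "homoscedastic"
    }
  }
  fitted <- sapply(fits, genotype_fitted_values)
  colnames(fitted) <- traits
  zl <- apply(fitted, 2, standardize, simplify = FALSE)
  z <- sapply(zl, as.numeric)
  dimnames(z) <- dimnames(fitted)
  structure(list(z = z, fitted = fitted,
                 center = sapply(zl, attr, "center"),
                 scale = sapply(zl, attr, "scale"),
                 variance_model = vmod, lrt_p = lrt_p),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("Standardized trait matrix: %d lines x %d traits (%s)\n",
              nrow(x$z), ncol(x$z), paste(colnames(x$z), collapse = ", ")))
  invisible(x)
}

#' Broad-sense heritability from ANOVA mean squares
#'
#' `h2 = sigma_G^2 / (sigma_G^2 + sigma_E^2)` with
#' `sigma_G^2 = (MS_G - MS_E) / r` (truncated at 0) and `sigma_E^2 = MS_E`,
#' from the two-way ANOVA of `value ~ block + line`; `r` is the number of
#' replications (blocks).
#'
#' @param records long phenotype data frame.
#' @param trait trait name.
#' @return list `trait`, `MS_G`, `MS_E`, `r`, `sigma2_G`, `sigma2_E`, `h2`.
#' @export
heritability <- function(records, trait) {
  check_records(records)
  d <- records[records$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for trait ", trait)
  d$line <- factor(d$line)
  d$block <- factor(d$block)
  r <- nlevels(d$block)
  if (r < 2L) stop("heritability needs r >= 2 replications")
  an <- stats::anova(stats::lm(value ~ block + line, data = d))
  MS_G <- an["line", "Mean Sq"]
  MS_E <- an["Residuals", "Mean Sq"]
  sigma2_G <- max(0, (MS_G - MS_E) / r)
  h2 <- sigma2_G / (sigma2_G + MS_E)
  list(trait = trait, MS_G = MS_G, MS_E = MS_E, r = r,
       sigma2_G = sigma2_G, sigma2_E = MS_E, h2 = h2)
}

#' Pairwise trait correlations on per-line values
#'
#' Pearson correlations across lines with two-sided t-test p-values and a
#' significance flag at `p < 0.01` (the convention used when reporting
#' trait-correlation tables).
#'
#' @param x a `"trait_matrix"` from [prep_traits()] or a numeric line x trait
#'   matrix of per-line values.
#' @return object of class `"trait_cor"`: list `r`, `p`, `sig` (logical,
#'   `p < 0.01`), `n`.
#' @export
correlations <- function(x) {
  m <- if (inherits(x, "trait_matrix")) x$fitted else as.matrix(x)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 lines")
  if (any(apply(m, 2, stats::sd) <= 0)) stop("zero-variance trait")
  r <- stats::cor(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, sig = p < 0.01, n = n), class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  out <- matrix(paste0(format(round(x$r, digits)), ifelse(x$sig, "**", "")),
                nrow(x$r), dimnames = dimnames(x$r))
  diag(out) <- "1"
  print(out, quote = FALSE)
  invisible(x)
}
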