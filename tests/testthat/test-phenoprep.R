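test_that("noiseless two-way data recover mu, blocks and genotype effects exactly", {
  mu <- 10
  be <- c(-1, 0.4, 0.6)
  ge <- c(2, -1, -0.5, -0.5)
  d <- make_records(mu, be, ge)
  fit <- fit_trait_model(d, "y")
  expect_equal(fit$mu, mu, tolerance = 1e-9)
  expect_equal(unname(fit$block_effects), be, tolerance = 1e-9)
  expect_equal(unname(fit$genotype_effects), ge, tolerance = 1e-9)
  expect_equal(unname(genotype_fitted_values(fit)), mu + ge, tolerance = 1e-9)
  # adding a constant shifts fitted values by that constant
  d2 <- d; d2$value <- d2$value + 3
  expect_equal(unname(genotype_fitted_values(fit_trait_model(d2, "y"))),
               mu + ge + 3, tolerance = 1e-9)
  # balanced blocks: fitted genotype values independent of the block shift
  d3 <- make_records(mu, be * 10, ge)
  expect_equal(genotype_fitted_values(fit_trait_model(d3, "y")),
               genotype_fitted_values(fit), tolerance = 1e-9)
  # residuals orthogonal to the design
  set.seed(1)
  d4 <- d; d4$value <- d4$value + rnorm(nrow(d))
  f4 <- fit_trait_model(d4, "y")
  res <- d4$value - f4$mu - f4$block_effects[d4$block] - f4$genotype_effects[d4$line]
  expect_lt(abs(sum(res)), 1e-9)
  expect_lt(max(abs(tapply(res, d4$block, sum))), 1e-9)
  expect_lt(max(abs(tapply(res, d4$line, sum))), 1e-9)
})

test_that("heteroscedastic ML fit matches a profile-likelihood oracle and dominates", {
  set.seed(42)
  J <- 10
  r <- 4
  ge <- rnorm(J)
  mult <- rep(c(0.7, 1.6), each = J / 2)
  d <- make_records(5, seq(-0.7, 0.7, length.out = r), ge - mean(ge))
  d$value <- d$value + rnorm(nrow(d)) * mult[match(d$line, sort(unique(d$line)))]
  fh <- fit_trait_model(d, "y", "homoscedastic")
  fg <- fit_trait_model(d, "y", "by_genotype")
  expect_gte(fg$logLik, fh$logLik)
  # homoscedastic ML log-likelihood equals lm's
  f_lm <- lm(value ~ factor(block) + factor(line), data = d)
  expect_equal(fh$logLik, as.numeric(logLik(f_lm)), tolerance = 1e-8)
  # oracle: maximize the profile log-likelihood over the per-genotype
  # log-variances with a generic optimizer (beta profiled out by GLS)
  line_f <- factor(d$line)
  X <- model.matrix(~ factor(block) + line_f, data = d)
  jidx <- as.integer(line_f)
  n <- nrow(d)
  prof_ll <- function(logs2) {
    w <- 1 / exp(logs2)[jidx]
    res <- d$value - X %*% stats::lm.wfit(X, d$value, w)$coefficients
    -n / 2 * log(2 * pi) - 0.5 * sum(log(exp(logs2))[jidx]) - 0.5 * sum(res^2 * w)
  }
  # the profile likelihood evaluated at the fitted variances reproduces the
  # reported log-likelihood
  expect_equal(prof_ll(log(fg$sigma2)), fg$logLik, tolerance = 1e-8)
  # the fit is a (constrained) local maximum: a bounded quasi-Newton
  # optimizer started at the fitted variances cannot improve it (the surface
  # is multimodal, so global comparisons are not meaningful here)
  floor_j <- 1e-3 * fh$sigma2
  opt <- optim(log(fg$sigma2), prof_ll, method = "L-BFGS-B",
               lower = log(floor_j), upper = log(1e4),
               control = list(fnscale = -1, maxit = 1000, factr = 10))
  expect_lt(opt$value - fg$logLik, 1e-4)
})

test_that("variance-model LRT has J-1 df, correct size, and power", {
  d <- make_records(0, c(-1, 1), rnorm(12), resid = rnorm(24))
  fh <- fit_trait_model(d, "y", "homoscedastic")
  fg <- fit_trait_model(d, "y", "by_genotype")
  sel <- select_variance_model(fh, fg)
  expect_equal(sel$df, 11L)
  expect_error(select_variance_model(fg, fh), "that order")
  # under homoscedastic truth the homoscedastic model is kept almost always
  set.seed(7)
  n_het <- 0L
  for (k in 1:40) {
    dk <- make_records(0, c(-1, 0, 1), rnorm(10), resid = rnorm(30))
    s <- select_variance_model(fit_trait_model(dk, "y", "homoscedastic"),
                               fit_trait_model(dk, "y", "by_genotype"))
    n_het <- n_het + (s$variance_model == "by_genotype")
  }
  expect_lte(n_het, 6L)  # nominal 5 % selection rate
  # strong heteroscedasticity is detected
  set.seed(8)
  mult <- rep(c(0.3, 3), each = 6)
  dh <- make_records(0, c(-1, 0, 0.5, 0.5), rnorm(12))
  dh$value <- dh$value + rnorm(nrow(dh)) * mult[match(dh$line, sort(unique(dh$line)))]
  s <- select_variance_model(fit_trait_model(dh, "y", "homoscedastic"),
                             fit_trait_model(dh, "y", "by_genotype"))
  expect_equal(s$variance_model, "by_genotype")
})

test_that("standardize centers and scales with the sample sd and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  set.seed(1)
  x <- rnorm(50, 7, 3)
  z1 <- as.numeric(standardize(x))
  expect_lt(abs(mean(z1)), 1e-9)
  expect_lt(abs(sd(z1) - 1), 1e-9)
  expect_equal(as.numeric(standardize(z1)), z1, tolerance = 1e-12)
  expect_equal(as.numeric(standardize(2.5 * x - 4)), z1, tolerance = 1e-9)
  expect_error(standardize(rep(1, 5)), "constant")
})

test_that("heritability follows the ANOVA mean-square estimator", {
  set.seed(11)
  ge <- rnorm(60, sd = 1)
  d <- make_records(3, c(-1, -0.5, 0.5, 1), ge, resid = rnorm(240, sd = 1))
  h <- heritability(d, "y")
  # independent computation from aov mean squares
  an <- anova(lm(value ~ block + line, data = transform(d, block = factor(block), line = factor(line))))
  sg <- max(0, (an["line", "Mean Sq"] - an["Residuals", "Mean Sq"]) / 4)
  expect_equal(h$h2, sg / (sg + an["Residuals", "Mean Sq"]), tolerance = 1e-12)
  expect_equal(h$r, 4L)
  expect_gte(h$h2, 0)
  expect_lte(h$h2, 1)
  # affine invariance
  d2 <- d; d2$value <- 100 * d2$value - 7
  expect_equal(heritability(d2, "y")$h2, h$h2, tolerance = 1e-9)
  # near the analytic expectation sigma_G^2 / (sigma_G^2 + sigma_E^2) = 0.5
  expect_lt(abs(h$h2 - 0.5), 0.15)
  # r = 1 is rejected
  expect_error(heritability(make_records(0, 0, rnorm(5)), "y"), "r >= 2")
})

test_that("trait correlations carry t-test p-values and the p < 0.01 flag", {
  set.seed(5)
  n <- 145
  x <- rnorm(n)
  m <- cbind(a = x, b = x + rnorm(n, sd = 0.5), c = rnorm(n))
  ct <- correlations(m)
  expect_equal(diag(ct$r), c(a = 1, b = 1, c = 1))
  expect_equal(ct$r, t(ct$r))
  expect_equal(ct$p["a", "b"],
               cor.test(m[, "a"], m[, "b"])$p.value, tolerance = 1e-9)
  expect_true(ct$sig["a", "b"])
  # independent traits at n = 145 rarely reach |r| >= 0.22
  set.seed(6)
  exceed <- 0L
  for (k in 1:50) {
    r <- cor(rnorm(n), rnorm(n))
    exceed <- exceed + (abs(r) >= 0.22)
  }
  expect_lte(exceed, 2L)
  expect_error(correlations(cbind(a = rep(1, 10), b = rnorm(10))), "zero-variance")
})

test_that("prep_traits returns standardized fitted values with bookkeeping", {
  arch <- sim_architecture(qtl_loci = data.frame(chrom = c("1", "2"), pos = c(94, 48)),
                           additive_effects = default_additive_effects()[1:2, ],
                           epistatic_terms = NULL)
  sim <- simulate_study(arch, map = simulate_map(n_chrom = 2), n_lines = 60, seed = 21)
  tm <- prep_traits(sim$phenotypes, select_variance = FALSE)
  expect_equal(dim(tm$z), c(60L, 7L))
  expect_lt(max(abs(colMeans(tm$z))), 1e-9)
  expect_lt(max(abs(apply(tm$z, 2, sd) - 1)), 1e-9)
  expect_equal(tm$z * rep(tm$scale, each = 60) + rep(tm$center, each = 60),
               tm$fitted, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(tm$variance_model == "homoscedastic"))
})
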