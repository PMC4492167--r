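test_that("design matrix carries expected codes and exact epistasis products", {
  sim <- small_qtl_sim(seed = 2)
  # marker-coincident term on fully observed data: columns equal observed codes
  mpos <- sim$map[sim$map$chrom == "1", ][3, ]
  X <- design_matrix(sim$probs, data.frame(chrom = "1", pos = mpos$pos))
  expect_equal(unname(X[, 1]), unname(sim$geno[, mpos$marker]))
  # epistasis column is the elementwise product of the additive columns
  terms <- data.frame(chrom = c("1", "2"), pos = c(30, 40))
  X2 <- design_matrix(sim$probs, terms, pairs = cbind(1L, 2L))
  expect_equal(X2[, "Q1:Q2"], X2[, "Q1"] * X2[, "Q2"], tolerance = 1e-15)
  # off-grid term errors
  expect_error(design_matrix(sim$probs, data.frame(chrom = "1", pos = 30.5)),
               "not a grid position")
  # all flanks missing: expected code is 0
  map1 <- genetic_map(c("a", "b"), c(1, 1), c(0, 20))
  gna <- matrix(NA_real_, 1, 2, dimnames = list("L1", c("a", "b")))
  pna <- suppressWarnings(qtl_genotype_probabilities(map1, gna))
  Xna <- design_matrix(pna, data.frame(chrom = "1", pos = 10))
  expect_identical(unname(Xna[1, 1]), 0)
})

test_that("model fitting reduces to least squares and interpolates noiseless data", {
  sim <- small_qtl_sim(seed = 3)
  # empty model: Sigma is the ML (n denominator) covariance of Z
  m0 <- fit_qtl_model(sim$z, sim$probs)
  n <- nrow(sim$z)
  expect_equal(m0$Sigma, cov(sim$z) * (n - 1) / n, tolerance = 1e-12)
  # T = 1 estimates equal ordinary least squares
  m1 <- fit_qtl_model(sim$z, sim$probs, terms = data.frame(chrom = "1", pos = 30))
  f <- lm(sim$z ~ m1$X)
  expect_equal(unname(m1$beta[1, 1]), unname(coef(f)[2]), tolerance = 1e-12)
  expect_equal(unname(m1$mu), unname(coef(f)[1]), tolerance = 1e-12)
  # noiseless Z = XB is recovered exactly
  X <- design_matrix(sim$probs, data.frame(chrom = c("1", "2"), pos = c(30, 40)))
  Zn <- X %*% c(0.7, -0.4)
  colnames(Zn) <- "y"
  mn <- fit_qtl_model(Zn, sim$probs, terms = data.frame(chrom = c("1", "2"), pos = c(30, 40)))
  expect_equal(unname(mn$beta[, 1]), c(0.7, -0.4), tolerance = 1e-9)
  expect_lt(mn$Sigma[1, 1], 1e-18)
  # rank-deficient designs are refused with the offending column named
  expect_error(fit_qtl_model(sim$z, sim$probs,
                             terms = data.frame(chrom = c("1", "1"), pos = c(30, 30))),
               "collinear")
})

test_that("LOD is the determinant ratio, zero for identical fits, and transform-invariant", {
  set.seed(9)
  sim <- small_qtl_sim(seed = 4)
  Z3 <- cbind(y1 = as.numeric(sim$z),
              y2 = as.numeric(standardize(0.3 * sim$qtl_codes[, 1] + rnorm(120))),
              y3 = as.numeric(standardize(rnorm(120))))
  rownames(Z3) <- rownames(sim$geno)
  t1 <- data.frame(chrom = "1", pos = 30)
  m0 <- fit_qtl_model(Z3, sim$probs)
  m1 <- fit_qtl_model(Z3, sim$probs, terms = t1)
  expect_equal(lod_compare(m0, m0), 0)
  lod <- lod_compare(m0, m1)
  expect_gte(lod, 0)
  # T = 1: (n/2) log10(RSS0/RSS1) from lm
  z1 <- Z3[, 1, drop = FALSE]
  s0 <- fit_qtl_model(z1, sim$probs)
  s1 <- fit_qtl_model(z1, sim$probs, terms = t1)
  orc <- oracle_scan1(as.numeric(z1), design_matrix(sim$probs, t1)[, 1])
  expect_equal(lod_compare(s0, s1), orc$lod, tolerance = 1e-9)
  # invariance under invertible trait transformations
  A <- matrix(c(1, 0.5, -0.2, 0, 1.3, 0.7, 0, 0, 0.6), 3, 3)
  ZA <- Z3 %*% A
  expect_equal(lod_compare(fit_qtl_model(ZA, sim$probs),
                           fit_qtl_model(ZA, sim$probs, terms = t1)),
               lod, tolerance = 1e-9)
  # non-nested comparison (better reduced model) is refused
  expect_error(lod_compare(m1, m0), "not nested")
})

test_that("genome scan matches the lm oracle and excludes included positions", {
  sim <- small_qtl_sim(seed = 5)
  model <- fit_qtl_model(sim$z, sim$probs, terms = data.frame(chrom = "2", pos = 40))
  sc <- scan_add_qtl(sim$z, sim$probs, model)
  expect_false(any(sc$chrom == "2" & abs(sc$pos - 40) < 1e-9))
  X0 <- design_matrix(sim$probs, model$terms)[, 1]
  for (k in c(2L, 37L, 90L, nrow(sc))) {
    gi <- which(sim$probs$grid$chrom == sc$chrom[k] &
                  abs(sim$probs$grid$pos - sc$pos[k]) < 1e-9)
    orc <- oracle_scan1(as.numeric(sim$z), sim$probs$xhat[, gi], X0)
    expect_equal(sc$lod[k], orc$lod, tolerance = 1e-9)
    expect_equal(sc$score[k], orc$score, tolerance = 1e-9)
  }
  expect_true(all(sc$lod >= 0))
  # a planted 0.4-sd QTL at 30 cM peaks nearby
  peak <- sc[which.max(sc$lod), ]
  expect_equal(peak$chrom, "1")
  expect_lt(abs(peak$pos - 30), 15)
})

test_that("resampled thresholds are seeded, monotone in alpha, and guard K", {
  sim <- small_qtl_sim(seed = 6)
  t15 <- resampled_score_threshold(sim$z, sim$probs, alpha = 0.15, K = 200, seed = 3)
  t15b <- resampled_score_threshold(sim$z, sim$probs, alpha = 0.15, K = 200, seed = 3)
  expect_identical(t15$threshold, t15b$threshold)
  expect_identical(t15$maxima, t15b$maxima)
  t05 <- resampled_score_threshold(sim$z, sim$probs, alpha = 0.05, K = 200, seed = 3)
  expect_gte(t05$threshold, t15$threshold)
  expect_error(resampled_score_threshold(sim$z, sim$probs, K = 50), "K must be")
  # the planted QTL's observed maximum clears the 15 % threshold
  expect_true(t15$exceeds)
})

test_that("forward search recovers a planted QTL and respects rounds = 0", {
  sim <- small_qtl_sim(seed = 7)
  m0 <- forward_search(sim$z, sim$probs, rounds = 0)
  expect_equal(nrow(m0$terms), 0L)
  m <- forward_search(sim$z, sim$probs, rounds = 3, K = 200, seed = 2)
  expect_gte(nrow(m$terms), 1L)
  expect_equal(m$terms$chrom[1], "1")
  expect_lt(abs(m$terms$pos[1] - 30), 15)
})

test_that("position refinement is monotone in likelihood and repairs displaced terms", {
  sim <- small_qtl_sim(seed = 8, beta = 0.8)
  displaced <- fit_qtl_model(sim$z, sim$probs, terms = data.frame(chrom = "1", pos = 35))
  ref <- refine_positions(sim$z, sim$probs, displaced)
  expect_gte(ref$logLik, displaced$logLik)
  expect_lt(abs(ref$terms$pos[1] - 30), 6)
  # already-optimal model is a fixed point
  ref2 <- refine_positions(sim$z, sim$probs, ref)
  expect_identical(ref2$terms, ref$terms)
})

test_that("epistasis search tests pairs of included terms and applies retention", {
  set.seed(31)
  map <- simulate_map(n_chrom = 2, chrom_lengths = 80, markers_per_chrom = 9)
  g <- simulate_ril_genotypes(map, qtl_loci = data.frame(chrom = c("1", "2"), pos = c(30, 40)),
                              n_lines = 150, seed = 31)
  q <- g$qtl_codes
  zs <- standardize(0.4 * q[, 1] - 0.35 * q[, 2] + 0.5 * q[, 1] * q[, 2] + rnorm(150))
  z <- matrix(as.numeric(zs), dimnames = list(rownames(g$geno), "y"))
  probs <- qtl_genotype_probabilities(map, g$geno)
  model <- fit_qtl_model(z, probs, terms = data.frame(chrom = c("1", "2"), pos = c(30, 40)))
  me <- epistasis_search(z, probs, model, K = 200, seed = 4)
  expect_equal(nrow(me$pairs), 1L)
  expect_equal(unname(me$pairs[1, ]), c(1L, 2L))
  expect_lt(abs(me$w[1, 1] - 0.5 / attr(zs, "scale")), 0.2)
  # single-term models are returned unchanged with a message
  m1 <- fit_qtl_model(z, probs, terms = data.frame(chrom = "1", pos = 30))
  expect_message(out <- epistasis_search(z, probs, m1), "fewer than 2")
  expect_identical(out$terms, m1$terms)
})

test_that("effect p-values are seeded and star codes follow the four thresholds", {
  expect_identical(star_code(c(0.04, 0.0009, 0.2, 0.009, 0.07)),
                   c("*", "***", "", "**", "+"))
  sim <- small_qtl_sim(seed = 10)
  model <- fit_qtl_model(sim$z, sim$probs, terms = data.frame(chrom = "1", pos = 30))
  e1 <- effect_pvalues(sim$z, sim$probs, model, K = 200, seed = 5)
  e2 <- effect_pvalues(sim$z, sim$probs, model, K = 200, seed = 5)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 1L)  # one term x one trait
  expect_lt(e1$p, 0.05)       # the planted effect is significant
  expect_equal(e1$estimate, unname(model$beta[1, 1]))
})

test_that("variance explained decomposes exactly for orthogonal designs", {
  # handcrafted orthogonal two-QTL design on two chromosomes
  map <- genetic_map(c("a1", "a2", "b1", "b2"), c(1, 1, 2, 2), c(0, 10, 0, 10))
  codes1 <- rep(c(1, 1, -1, -1), 5)
  codes2 <- rep(c(1, -1, 1, -1), 5)
  g <- cbind(a1 = codes1, a2 = codes1, b1 = codes2, b2 = codes2)
  rownames(g) <- sprintf("L%02d", 1:20)
  probs <- qtl_genotype_probabilities(map, g)
  terms <- data.frame(chrom = c("1", "2"), pos = c(0, 0))
  z <- matrix(0.5 * codes1 - 0.25 * codes2 + rep(c(0.1, -0.1), 10),
              dimnames = list(rownames(g), "y"))
  model <- fit_qtl_model(z, probs, terms = terms)
  r2 <- qtl_r2(model)
  expect_equal(sum(r2$per_effect[, "y"]), unname(r2$total["y"]), tolerance = 1e-9)
  # zero-effect term contributes zero
  z0 <- matrix(0.5 * codes1 + 0.001 * rnorm(20), dimnames = list(rownames(g), "y"))
  m0 <- fit_qtl_model(z0, probs, terms = terms)
  expect_lt(qtl_r2(m0)$per_effect["Q2", "y"], 0.5)
  # a 0.3-sd effect on a unit-variance trait explains about 9 %
  set.seed(12)
  simb <- small_qtl_sim(seed = 13, beta = 0.3, n_lines = 2000)
  mb <- fit_qtl_model(simb$z, simb$probs, terms = data.frame(chrom = "1", pos = 30))
  expect_lt(abs(qtl_r2(mb)$total["y"] - 100 * 0.09 / 1.09), 2.5)
})

test_that("support intervals satisfy the drop definition and flag flat profiles", {
  sim <- small_qtl_sim(seed = 14, beta = 0.6)
  model <- forward_search(sim$z, sim$probs, rounds = 1, K = 200, seed = 6)
  iv <- support_interval(sim$z, sim$probs, model, 1, drop = 1.5)
  expect_lte(iv$left, iv$peak_pos)
  expect_gte(iv$right, iv$peak_pos)
  prof <- iv$profile
  inside <- prof$pos >= iv$left & prof$pos <= iv$right
  expect_true(all(prof$lod[inside] >= iv$peak_lod - 1.5))
  just_out <- (prof$pos == max(c(-Inf, prof$pos[prof$pos < iv$left]))) |
    (prof$pos == min(c(Inf, prof$pos[prof$pos > iv$right])))
  if (any(just_out)) expect_true(all(prof$lod[just_out] < iv$peak_lod - 1.5))
  # endpoints lie on the chromosome's grid
  gpos <- sim$probs$grid$pos[sim$probs$grid$chrom == iv$chrom]
  expect_true(iv$left %in% gpos && iv$right %in% gpos)
  # flanking markers bracket the interval
  mpos <- sim$map$pos[sim$map$chrom == iv$chrom]
  expect_lte(mpos[match(iv$flank_left, sim$map$marker[sim$map$chrom == iv$chrom])],
             iv$left + 1e-9)
  # a trait with no QTL on the profiled chromosome yields a flat, flagged interval
  set.seed(15)
  znull <- matrix(as.numeric(standardize(rnorm(120))),
                  dimnames = list(rownames(sim$geno), "y"))
  mflat <- fit_qtl_model(znull, sim$probs, terms = data.frame(chrom = "2", pos = 40))
  expect_warning(ivf <- support_interval(znull, sim$probs, mflat, 1), "flat")
  expect_true(ivf$flat)
  gpos2 <- sim$probs$grid$pos[sim$probs$grid$chrom == "2"]
  expect_equal(c(ivf$left, ivf$right), range(gpos2))
})
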