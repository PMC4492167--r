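# Independent oracles and small fixture builders shared across test files.

# Exhaustive three-locus enumeration under the two-state RIL chain:
# P(middle locus = +1 | flanks a, b at distances d1, d2 cM).
oracle_q3 <- function(a, b, d1, d2) {
  R1 <- ril_collapse(kosambi_to_recfrac(d1))
  R2 <- ril_collapse(kosambi_to_recfrac(d2))
  states <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
  T1 <- ifelse(states$s1 == states$s2, 1 - R1, R1)
  T2 <- ifelse(states$s2 == states$s3, 1 - R2, R2)
  p <- 0.5 * T1 * T2
  sel <- states$s1 == a & states$s3 == b
  sum(p[sel & states$s2 == 1]) / sum(p[sel])
}

# Single-trait interval-mapping oracle via lm: LOD and robust score statistic
# for adding covariate x to a model that already contains columns X0.
oracle_scan1 <- function(z, x, X0 = NULL) {
  f0 <- if (is.null(X0)) lm(z ~ 1) else lm(z ~ X0)
  f1 <- if (is.null(X0)) lm(z ~ x) else lm(z ~ X0 + x)
  n <- length(z)
  lod <- n / 2 * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
  ct <- if (is.null(X0)) x - mean(x) else resid(lm(x ~ X0))
  e0 <- resid(f0)
  u <- ct * e0
  list(lod = lod, score = sum(u)^2 / sum(u^2), beta = unname(coef(f1)[length(coef(f1))]))
}

# Balanced two-way phenotype records from explicit parameters.
make_records <- function(mu, block_eff, geno_eff, resid = NULL, trait = "y") {
  J <- length(geno_eff)
  r <- length(block_eff)
  lines <- sprintf("L%02d", seq_len(J))
  blocks <- sprintf("B%d", seq_len(r))
  d <- expand.grid(line = lines, block = blocks, stringsAsFactors = FALSE)
  d$trait <- trait
  d$value <- mu + block_eff[match(d$block, blocks)] + geno_eff[match(d$line, lines)]
  if (!is.null(resid)) d$value <- d$value + resid
  d
}

# Small mapped RIL dataset with one planted QTL; returns everything needed
# for scan-level tests.
small_qtl_sim <- function(seed = 1, beta = 0.4, n_lines = 120,
                          qtl = data.frame(chrom = "1", pos = 30)) {
  map <- simulate_map(n_chrom = 2, chrom_lengths = 80, markers_per_chrom = 9)
  g <- simulate_ril_genotypes(map, qtl_loci = qtl, n_lines = n_lines, seed = seed)
  set.seed(seed + 5000)
  z <- beta * g$qtl_codes[, 1] + rnorm(n_lines)
  z <- matrix(as.numeric(standardize(z)), dimnames = list(rownames(g$geno), "y"))
  probs <- qtl_genotype_probabilities(map, g$geno)
  list(map = map, geno = g$geno, qtl_codes = g$qtl_codes, z = z, probs = probs)
}

# Trait correlation matrix and printed path-analysis coefficients of the
# low-P maize worked example (2-3 dp published precision).
published_path_example <- function() {
  R <- lowp_trait_correlations()
  list(
    R = R,
    predictors = c("SA", "RL", "SA2", "RD"),
    direct = list(
      TDW = c(SA = 5.935, RL = -4.831, SA2 = -0.681, RD = -0.424),
      Pcont = c(SA = 1.597, RL = -0.997, SA2 = -0.117, RD = 0.281)),
    indirect_RL_via_SA = c(TDW = 5.816, Pcont = 1.565),
    recon_SA = c(TDW = 0.86, Pcont = 0.39),
    r2 = c(TDW = 0.869, Pcont = 0.295))
}
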