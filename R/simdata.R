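#' Simulate a genetic map
#'
#' Generates a marker map for a given number of chromosomes. Defaults emulate
#' a dense biparental maize map: 10 chromosomes of 178.75 cM carrying 292
#' markers in total (1787.5 cM, mean spacing ~6.1 cM).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_lengths chromosome lengths in cM (recycled to `n_chrom`).
#' @param markers_per_chrom integer vector (recycled), each >= 2.
#' @param spacing `"uniform"` (equidistant, default) or `"random"` (uniform
#'   order statistics between the chromosome ends).
#' @param seed integer seed, used only when `spacing = "random"`.
#' @return a [genetic_map()].
#' @export
simulate_map <- function(n_chrom = 10,
                         chrom_lengths = rep(178.75, n_chrom),
                         markers_per_chrom = rep(c(30L, 29L), c(2, 8))[seq_len(n_chrom)],
                         spacing = c("uniform", "random"),
                         seed = 1L) {
  spacing <- match.arg(spacing)
  chrom_lengths <- rep_len(chrom_lengths, n_chrom)
  markers_per_chrom <- rep_len(as.integer(markers_per_chrom), n_chrom)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (any(markers_per_chrom < 2L)) stop("need at least 2 markers per chromosome")
  if (spacing == "random") set.seed(seed)
  pieces <- lapply(seq_len(n_chrom), function(cc) {
    m <- markers_per_chrom[cc]
    L <- chrom_lengths[cc]
    p <- if (spacing == "uniform") seq(0, L, length.out = m)
         else c(0, sort(stats::runif(m - 2L, 0, L)), L)
    data.frame(marker = sprintf("m%d_%02d", cc, seq_len(m)),
               chrom = as.character(cc), pos = p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  genetic_map(df$marker, df$chrom, df$pos)
}

#' Simulate selfed-RIL genotypes on a map
#'
#' Each line's genome per chromosome is a realization of a two-state (+1/-1)
#' Markov chain over the ordered loci (map markers plus any QTL pseudo-loci):
#' the first locus is +1 or -1 with probability 1/2 and each subsequent locus
#' switches with the RIL-collapsed recombination probability of the interval
#' ([ril_collapse()] of [kosambi_to_recfrac()]). QTL codes are returned
#' separately and never appear in the marker output.
#'
#' @param map a [genetic_map()].
#' @param qtl_loci optional data frame with columns `chrom`, `pos` giving QTL
#'   pseudo-locus positions (must lie within the map extent of their chromosome).
#' @param n_lines number of lines.
#' @param seed integer seed.
#' @return list with `geno` (lines x markers matrix, +1/-1) and `qtl_codes`
#'   (lines x QTL matrix, +1/-1; NULL when no `qtl_loci`).
#' @export
simulate_ril_genotypes <- function(map, qtl_loci = NULL, n_lines = 145, seed = 1L) {
  stopifnot(n_lines >= 1)
  set.seed(seed)
  if (!is.null(qtl_loci)) {
    qtl_loci <- data.frame(chrom = as.character(qtl_loci$chrom),
                           pos = as.numeric(qtl_loci$pos))
    for (k in seq_len(nrow(qtl_loci))) {
      p <- map$pos[map$chrom == qtl_loci$chrom[k]]
      if (length(p) == 0L || qtl_loci$pos[k] < min(p) || qtl_loci$pos[k] > max(p))
        stop("QTL locus ", k, " outside map extent of chromosome ", qtl_loci$chrom[k])
    }
  }
  lines <- sprintf("RIL%03d", seq_len(n_lines))
  geno <- matrix(NA_real_, n_lines, nrow(map),
                 dimnames = list(lines, map$marker))
  n_qtl <- if (is.null(qtl_loci)) 0L else nrow(qtl_loci)
  qtl_codes <- if (n_qtl) matrix(NA_real_, n_lines, n_qtl,
                                 dimnames = list(lines, sprintf("Q%d", seq_len(n_qtl))))
               else NULL
  for (cc in chromosomes(map)) {
    midx <- which(map$chrom == cc)
    loci <- data.frame(pos = map$pos[midx], type = "m", id = midx)
    if (n_qtl) {
      qk <- which(qtl_loci$chrom == cc)
      if (length(qk))
        loci <- rbind(loci, data.frame(pos = qtl_loci$pos[qk], type = "q", id = qk))
    }
    loci <- loci[order(loci$pos, loci$type), , drop = FALSE]
    K <- nrow(loci)
    states <- matrix(NA_real_, n_lines, K)
    states[, 1L] <- sample(c(-1, 1), n_lines, replace = TRUE)
    if (K > 1L) {
      Rs <- ril_switch_prob(diff(loci$pos))
      for (k in 2:K) {
        flip <- stats::rbinom(n_lines, 1L, Rs[k - 1L])
        states[, k] <- states[, k - 1L] * (1 - 2 * flip)
      }
    }
    is_m <- loci$type == "m"
    geno[, loci$id[is_m]] <- states[, is_m, drop = FALSE]
    if (any(!is_m))
      qtl_codes[, loci$id[!is_m]] <- states[, !is_m, drop = FALSE]
  }
  list(geno = geno, qtl_codes = qtl_codes)
}

#' Multi-trait QTL architecture for phenotype simulation
#'
#' Bundles everything the phenotype simulator needs: QTL positions, additive
#' effects per trait (in phenotype-sd units), optional epistatic terms,
#' residual trait covariance, block design and optional per-line residual-sd
#' heterogeneity. The defaults describe a seven-trait maize seedling study
#' under low phosphorus: 145 lines, four randomized complete blocks with
#' fixed shifts (-0.3, -0.1, 0.1, 0.3) sd, a residual covariance equal to the
#' observed trait correlation matrix among root-morphology, biomass and
#' P-content traits, three QTL with additive effects of 0.25-0.40 sd, and one
#' epistatic pair acting on dry weight and P content.
#'
#' @param qtl_loci data frame `chrom`, `pos` of QTL positions.
#' @param additive_effects QTL x trait numeric matrix (sd units).
#' @param epistatic_terms list of `list(pair = c(r, l), effects = <per-trait>)`,
#'   pairs indexing rows of `qtl_loci`; or NULL.
#' @param residual_covariance trait x trait positive-definite matrix.
#' @param block_effects replicate x trait matrix of fixed shifts (or a vector,
#'   applied to every trait); rows define `n_replicates`.
#' @param trait_means per-trait intercepts (default 0).
#' @param het_sd_multipliers optional per-line positive residual-sd factors.
#' @param missing_rate marker missingness rate in `[0, 1)` used by
#'   [simulate_study()].
#' @return object of class `"sim_architecture"`.
#' @export
sim_architecture <- function(qtl_loci = default_qtl_loci(),
                             additive_effects = default_additive_effects(),
                             epistatic_terms = default_epistatic_terms(),
                             residual_covariance = lowp_trait_correlations(),
                             block_effects = c(-0.3, -0.1, 0.1, 0.3),
                             trait_means = NULL,
                             het_sd_multipliers = NULL,
                             missing_rate = 0) {
  additive_effects <- as.matrix(additive_effects)
  Tn <- ncol(additive_effects)
  traits <- colnames(additive_effects)
  if (is.null(traits)) traits <- paste0("trait", seq_len(Tn))
  Sigma <- as.matrix(residual_covariance)
  if (nrow(Sigma) != Tn || ncol(Sigma) != Tn)
    stop("residual_covariance dimension does not match trait count")
  if (max(abs(Sigma - t(Sigma))) > 1e-8) stop("residual_covariance must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("residual_covariance must be positive definite")
  if (!is.matrix(block_effects))
    block_effects <- matrix(block_effects, length(block_effects), Tn)
  if (ncol(block_effects) != Tn) stop("block_effects column count != trait count")
  if (is.null(trait_means)) trait_means <- rep(0, Tn)
  if (!is.null(qtl_loci) && nrow(additive_effects) != nrow(qtl_loci))
    stop("additive_effects rows must match qtl_loci rows")
  if (!is.null(epistatic_terms)) {
    for (term in epistatic_terms) {
      if (length(term$pair) != 2L || any(term$pair > nrow(qtl_loci)))
        stop("epistatic pair indices must reference qtl_loci rows")
      if (length(term$effects) != Tn) stop("epistatic effects length != trait count")
    }
  }
  if (!is.null(het_sd_multipliers) && any(het_sd_multipliers <= 0))
    stop("het_sd_multipliers must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(qtl_loci = qtl_loci, additive_effects = additive_effects,
                 epistatic_terms = epistatic_terms, residual_covariance = Sigma,
                 block_effects = block_effects, n_replicates = nrow(block_effects),
                 trait_means = trait_means, traits = traits,
                 het_sd_multipliers = het_sd_multipliers,
                 missing_rate = missing_rate),
            class = "sim_architecture")
}

#' Observed trait correlation matrix of the low-P maize seedling example
#'
#' Pearson correlations among root surface area (SA), root length (RL),
#' surface area of fine roots (SA2), root diameter (RD), root:shoot dry
#' weight ratio (R:S), total seedling dry weight (TDW) and total P content
#' (Pcont) measured on 145 maize RILs grown under low phosphorus. The matrix
#' is positive definite and serves both as the default residual covariance of
#' the simulator and as the worked example for path analysis.
#'
#' @return 7 x 7 named correlation matrix.
#' @export
lowp_trait_correlations <- function() {
  traits <- c("SA", "RL", "SA2", "RD", "RS", "TDW", "Pcont")
  R <- diag(7)
  dimnames(R) <- list(traits, traits)
  vals <- c(0.98, 0.80, -0.48, -0.38, 0.86, 0.39,
            0.69, -0.62, -0.38, 0.79, 0.31,
            0.03, -0.29, 0.77, 0.48,
            0.26, -0.25, 0.14,
            -0.43, -0.02,
            0.58)
  k <- 1L
  for (i in 1:6) for (j in (i + 1):7) {
    R[i, j] <- R[j, i] <- vals[k]
    k <- k + 1L
  }
  R
}

#' Default QTL architecture pieces of the low-P seedling emulation
#'
#' Three QTL near commonly reported maize root-trait regions (chromosomes 1,
#' 8 and 10), additive effects of 0.25-0.40 phenotype-sd spread over the
#' seven traits, and one epistatic pair (QTL 2 x QTL 3) acting on total dry
#' weight (0.307 sd) and P content (0.265 sd).
#'
#' @return `default_qtl_loci()`: data frame `chrom`, `pos`;
#'   `default_additive_effects()`: 3 x 7 matrix;
#'   `default_epistatic_terms()`: list of pair/effect terms.
#' @export
default_qtl_loci <- function() {
  data.frame(chrom = c("1", "8", "10"), pos = c(94, 48, 38),
             stringsAsFactors = FALSE)
}

#' @rdname default_qtl_loci
#' @export
default_additive_effects <- function() {
  traits <- c("SA", "RL", "SA2", "RD", "RS", "TDW", "Pcont")
  B <- matrix(0, 3, 7, dimnames = list(NULL, traits))
  B[1, c("RD", "RS", "TDW")] <- c(0.31, -0.27, -0.25)
  B[2, c("SA", "RL", "Pcont")] <- c(-0.25, -0.26, -0.30)
  B[3, c("SA", "RL", "SA2")] <- c(-0.28, -0.27, -0.40)
  B
}

#' @rdname default_qtl_loci
#' @export
default_epistatic_terms <- function() {
  traits <- c("SA", "RL", "SA2", "RD", "RS", "TDW", "Pcont")
  eff <- stats::setNames(rep(0, 7), traits)
  eff[c("TDW", "Pcont")] <- c(0.307, 0.265)
  list(list(pair = c(2L, 3L), effects = eff))
}

#' Simulate multi-trait phenotypes from true QTL codes
#'
#' For line `j`, trait `t`, replicate `i`:
#' `y = mu_t + block_it + sum_r beta_tr x_jr + sum_(r<l) w_trl x_jr x_jl + eps`,
#' with the per-replicate trait vector `eps` multivariate normal with the
#' architecture's residual covariance, optionally scaled by a per-line sd
#' multiplier.
#'
#' @param qtl_codes lines x QTL matrix of true +1/-1 codes (as returned by
#'   [simulate_ril_genotypes()]).
#' @param arch a [sim_architecture()].
#' @param seed integer seed.
#' @return long-format data frame `line`, `block`, `trait`, `value`
#'   (a `PhenotypeRecords` table).
#' @export
simulate_phenotypes <- function(qtl_codes, arch, seed = 1L) {
  stopifnot(inherits(arch, "sim_architecture"))
  set.seed(seed)
  n <- nrow(qtl_codes)
  Tn <- length(arch$traits)
  lines <- rownames(qtl_codes)
  if (is.null(lines)) lines <- sprintf("RIL%03d", seq_len(n))
  G <- matrix(rep(arch$trait_means, each = n), n, Tn)  # genetic value + intercept
  if (!is.null(arch$qtl_loci) && nrow(arch$additive_effects) > 0)
    G <- G + qtl_codes %*% arch$additive_effects
  for (term in arch$epistatic_terms)
    G <- G + (qtl_codes[, term$pair[1L]] * qtl_codes[, term$pair[2L]]) %o%
      as.numeric(term$effects)
  mult <- arch$het_sd_multipliers
  if (is.null(mult)) mult <- rep(1, n)
  if (length(mult) != n) stop("het_sd_multipliers length != number of lines")
  out <- vector("list", arch$n_replicates)
  for (b in seq_len(arch$n_replicates)) {
    eps <- MASS::mvrnorm(n, mu = rep(0, Tn), Sigma = arch$residual_covariance)
    Y <- G + matrix(rep(arch$block_effects[b, ], each = n), n, Tn) + eps * mult
    out[[b]] <- data.frame(line = rep(lines, Tn),
                           block = sprintf("B%d", b),
                           trait = rep(arch$traits, each = n),
                           value = as.vector(Y),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Draw per-line lognormal residual-sd multipliers
#'
#' Heteroscedasticity model: per-line residual-sd factors drawn lognormal
#' with median 1 and geometric sd `gsd` (default 1.5).
#'
#' @param n_lines number of lines.
#' @param gsd geometric standard deviation (> 1 gives heterogeneity).
#' @param seed integer seed.
#' @export
het_sd_multipliers <- function(n_lines, gsd = 1.5, seed = 1L) {
  stopifnot(gsd >= 1)
  set.seed(seed)
  exp(stats::rnorm(n_lines, 0, log(gsd)))
}

#' Inject missing marker calls
#'
#' Each observed cell is independently set missing with probability `rate`.
#'
#' @param geno lines x markers matrix.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @export
inject_missing <- function(geno, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(geno)
  set.seed(seed)
  mask <- matrix(stats::runif(length(geno)) < rate, nrow(geno), ncol(geno))
  geno[mask & !is.na(geno)] <- NA
  geno
}

#' Simulate a complete RIL QTL study
#'
#' Convenience wrapper: map, genotypes (with optional missingness), true QTL
#' codes and phenotypes in one call, with sub-seeds derived from `seed`.
#'
#' @param arch a [sim_architecture()].
#' @param map a [genetic_map()] (default: [simulate_map()] with its defaults).
#' @param n_lines number of RILs.
#' @param seed integer seed (< 2^21 recommended; sub-seeds are `seed * 7 + k`).
#' @return list `map`, `geno`, `qtl_codes`, `phenotypes`, `arch`.
#' @export
simulate_study <- function(arch = sim_architecture(), map = simulate_map(),
                           n_lines = 145, seed = 1L) {
  g <- simulate_ril_genotypes(map, qtl_loci = arch$qtl_loci,
                              n_lines = n_lines, seed = seed * 7L + 1L)
  geno <- g$geno
  if (arch$missing_rate > 0)
    geno <- inject_missing(geno, arch$missing_rate, seed = seed * 7L + 2L)
  ph <- simulate_phenotypes(g$qtl_codes, arch, seed = seed * 7L + 3L)
  list(map = map, geno = geno, qtl_codes = g$qtl_codes, phenotypes = ph,
       arch = arch)
}
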