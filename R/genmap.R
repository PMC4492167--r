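#' Construct a genetic map
#'
#' A genetic map is an ordered set of markers with centiMorgan (cM) positions
#' on one or more chromosomes. It defines the coordinate system for genome
#' scans and genotype-probability computations.
#'
#' Markers sharing an identical position on a chromosome are jittered by
#' +1e-6 cM in input order so that positions are strictly increasing, which
#' keeps interval arithmetic well defined without affecting any result at
#' working precision. Each chromosome must carry at least two markers.
#'
#' @param markers character vector of genome-wide unique marker names.
#' @param chrom chromosome identifier per marker (coerced to character).
#' @param pos position in cM per marker, non-negative.
#' @return An object of class `"genetic_map"`: a data frame with columns
#'   `marker`, `chrom`, `pos`, sorted by chromosome (input order of first
#'   appearance) and position.
#' @examples
#' gm <- genetic_map(c("m1", "m2", "m3"), c(1, 1, 1), c(0, 12.5, 30))
#' @export
genetic_map <- function(markers, chrom, pos) {
  markers <- as.character(markers)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(markers) != length(chrom) || length(markers) != length(pos))
    stop("markers, chrom and pos must have equal length")
  if (anyDuplicated(markers))
    stop("duplicated marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  if (any(!is.finite(pos)) || any(pos < 0))
    stop("positions must be finite and >= 0")
  chrom_levels <- unique(chrom)
  ord <- order(match(chrom, chrom_levels), pos)
  df <- data.frame(marker = markers[ord], chrom = chrom[ord], pos = pos[ord],
                   stringsAsFactors = FALSE)
  n_jit <- 0L
  for (cc in chrom_levels) {
    idx <- which(df$chrom == cc)
    if (length(idx) < 2L)
      stop("chromosome ", cc, " has fewer than 2 markers")
    p <- df$pos[idx]
    # tie-jitter: strictly increasing positions within each chromosome
    for (k in seq_along(p)[-1L]) {
      if (p[k] <= p[k - 1L]) {
        p[k] <- p[k - 1L] + 1e-6
        n_jit <- n_jit + 1L
      }
    }
    df$pos[idx] <- p
  }
  if (n_jit > 0L)
    message("genetic_map: jittered ", n_jit, " co-located marker position(s) by +1e-6 cM")
  structure(df, class = c("genetic_map", "data.frame"),
            chrom_levels = chrom_levels)
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  cat(sprintf("Genetic map: %d markers on %d chromosome(s), %.1f cM\n",
              s$n_markers, s$n_chrom, s$total_length))
  invisible(x)
}

chromosomes <- function(map) attr(map, "chrom_levels")

#' Map distance to recombination fraction (Kosambi)
#'
#' Converts a Kosambi map distance in cM to a meiotic recombination fraction.
#'
#' @param d map distance in cM, `d >= 0` (vectorized).
#' @return recombination fraction `r = 0.5 * tanh(2 d / 100)`, in `[0, 0.5)`.
#' @seealso [recfrac_to_kosambi()], [ril_collapse()]
#' @export
kosambi_to_recfrac <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("map distance must be finite and >= 0")
  0.5 * tanh(2 * d / 100)
}

#' Recombination fraction to map distance (Kosambi)
#'
#' @param r recombination fraction in `[0, 0.5)` (vectorized).
#' @return map distance in cM, `d = 25 * log((1 + 2r) / (1 - 2r))`.
#' @export
recfrac_to_kosambi <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Meiotic to RIL-by-selfing recombination fraction
#'
#' In a recombinant inbred line population derived by repeated selfing, the
#' observable recombination fraction between two loci is inflated relative to
#' the single-meiosis fraction because recombinants accumulate over
#' generations. At the infinite-selfing limit the two-locus collapse is
#' `R = 2r / (1 + 2r)` (Haldane-Waddington). Residual heterozygosity is
#' ignored: the genotype space has the two parental homozygotes only.
#'
#' @param r meiotic recombination fraction in `[0, 0.5]` (vectorized).
#' @return RIL recombination fraction `R <= 0.5`.
#' @export
ril_collapse <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("recombination fraction must lie in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

## per-interval switch probability of the two-state RIL chain over d cM
ril_switch_prob <- function(d) ril_collapse(kosambi_to_recfrac(d))

#' Validate a line-by-marker genotype matrix against a map
#'
#' Genotypes are coded +1 for the parent-A homozygote and -1 for the
#' parent-B homozygote; anything else is coerced to `NA` (missing) with a
#' message, because a selfed RIL model space has two states.
#'
#' @param geno numeric matrix, lines in rows (rownames = line ids), markers in
#'   columns (colnames = marker names).
#' @param map a [genetic_map()].
#' @return the validated (possibly coerced) matrix, columns ordered as in the map.
#' @export
validate_genotypes <- function(geno, map) {
  if (is.null(colnames(geno))) stop("genotype matrix must have marker column names")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("L", seq_len(nrow(geno)))
  missing_cols <- setdiff(map$marker, colnames(geno))
  extra_cols <- setdiff(colnames(geno), map$marker)
  if (length(missing_cols) || length(extra_cols))
    stop("genotype/map marker mismatch; absent from genotypes: ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         if (length(extra_cols)) paste0("; not on map: ",
                                        paste(utils::head(extra_cols, 5), collapse = ", ")))
  geno <- geno[, map$marker, drop = FALSE]
  bad <- !(geno %in% c(-1, 1)) & !is.na(geno)
  if (any(bad)) {
    message("validate_genotypes: coerced ", sum(bad),
            " non-parental call(s) to missing")
    geno[bad] <- NA
  }
  storage.mode(geno) <- "double"
  geno
}

#' Scan grid of a genetic map
#'
#' The grid is the union of all marker positions and `step`-spaced points
#' between the first and last marker of each chromosome, anchored at the
#' first marker (the map's own cM coordinates are kept).
#'
#' @param map a [genetic_map()].
#' @param step grid step in cM (default 1).
#' @return data frame with columns `chrom`, `pos`.
#' @export
scan_grid <- function(map, step = 1.0) {
  stopifnot(step > 0)
  out <- lapply(chromosomes(map), function(cc) {
    p <- map$pos[map$chrom == cc]
    g <- sort(unique(c(p, seq(p[1L], p[length(p)], by = step))))
    data.frame(chrom = cc, pos = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Conditional QTL genotype probabilities on a scan grid
#'
#' For every line and grid position, computes `q = P(genotype = +1 | marker
#' data)` under a two-state Markov chain over the ordered loci of each
#' chromosome, with per-interval switch probability equal to the RIL-collapsed
#' recombination fraction of the interval length ([ril_collapse()] of
#' [kosambi_to_recfrac()]). Conditioning uses the nearest informative
#' (non-missing) flanking marker on each side, which for a Markov chain equals
#' the full-chromosome forward-backward result; one-sided conditioning applies
#' beyond the outermost informative markers, and `q = 0.5` when a line has no
#' informative marker on a chromosome (with a warning).
#'
#' The derived expected Cockerham code is `xhat = 2q - 1`; at a grid position
#' coinciding with an observed marker, `xhat` equals the observed code.
#'
#' @param map a [genetic_map()].
#' @param geno line x marker matrix coded +1/-1/NA (see [validate_genotypes()]).
#' @param step grid step in cM.
#' @return An object of class `"geno_probs"`: a list with elements `map`,
#'   `grid` (data frame `chrom`, `pos`), `q` and `xhat` (line x grid-position
#'   matrices), and `lines`.
#' @export
qtl_genotype_probabilities <- function(map, geno, step = 1.0) {
  geno <- validate_genotypes(geno, map)
  grid <- scan_grid(map, step = step)
  n <- nrow(geno)
  q <- matrix(0.5, n, nrow(grid), dimnames = list(rownames(geno), NULL))
  empty_lines <- character(0)
  for (cc in chromosomes(map)) {
    midx <- which(map$chrom == cc)
    gidx <- which(grid$chrom == cc)
    mpos <- map$pos[midx]
    gpos <- grid$pos[gidx]
    gcodes <- geno[, midx, drop = FALSE]
    for (i in seq_len(n)) {
      inf <- which(!is.na(gcodes[i, ]))
      if (length(inf) == 0L) {
        empty_lines <- c(empty_lines, paste0(rownames(geno)[i], "/", cc))
        next  # q stays 0.5
      }
      ip <- mpos[inf]
      iv <- gcodes[i, inf]
      li <- findInterval(gpos, ip)              # nearest informative at pos <= g (0 if none)
      ri <- length(ip) - findInterval(-gpos, rev(-ip)) + 1L  # nearest at pos >= g
      has_l <- li >= 1L
      has_r <- ri <= length(ip)
      # P(+1 | left state a over distance dl): (1-Rl) if a == +1 else Rl
      pl <- rep(NA_real_, length(gpos))
      Rl <- rep(NA_real_, length(gpos))
      if (any(has_l)) {
        Rl[has_l] <- ril_switch_prob(gpos[has_l] - ip[li[has_l]])
        al <- iv[li[has_l]]
        pl[has_l] <- ifelse(al > 0, 1 - Rl[has_l], Rl[has_l])
      }
      pr <- rep(NA_real_, length(gpos))
      if (any(has_r)) {
        Rr <- ril_switch_prob(ip[ri[has_r]] - gpos[has_r])
        ar <- iv[ri[has_r]]
        pr[has_r] <- ifelse(ar > 0, 1 - Rr, Rr)  # P(right = b | state +1)
      }
      qi <- rep(0.5, length(gpos))
      both <- has_l & has_r
      # P(+1|a,b) = P(+1|a) P(b|+1) / [P(+1|a) P(b|+1) + P(-1|a) P(b|-1)]
      wplus <- pl[both] * pr[both]
      wminus <- (1 - pl[both]) * (1 - pr[both])
      qi[both] <- wplus / (wplus + wminus)
      lonly <- has_l & !has_r
      qi[lonly] <- pl[lonly]
      ronly <- !has_l & has_r
      qi[ronly] <- pr[ronly]
      q[i, gidx] <- qi
    }
  }
  if (length(empty_lines))
    warning("no informative markers for ", length(empty_lines),
            " line/chromosome combination(s); q = 0.5 there (e.g. ",
            paste(utils::head(empty_lines, 3), collapse = ", "), ")")
  structure(list(map = map, grid = grid, q = q, xhat = 2 * q - 1,
                 lines = rownames(geno)),
            class = "geno_probs")
}

#' @export
print.geno_probs <- function(x, ...) {
  cat(sprintf("Genotype probabilities: %d lines x %d grid positions (%d chromosomes)\n",
              nrow(x$q), ncol(x$q), length(unique(x$grid$chrom))))
  invisible(x)
}

#' Marker segregation-distortion test
#'
#' Tests every marker for the 1:1 segregation expected of a biparental RIL
#' population with a 1-df chi-square on the counts of the two homozygote
#' classes (missing calls excluded), with a Bonferroni-corrected rejection
#' flag at level `alpha / M`, `M` the number of testable markers.
#'
#' @param geno line x marker matrix coded +1/-1/NA.
#' @param alpha nominal familywise level (default 0.05).
#' @return data frame with columns `marker`, `n_plus`, `n_minus`, `chisq`,
#'   `p`, `distorted` (Bonferroni flag), `testable`.
#' @export
segregation_test <- function(geno, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  n_plus <- colSums(geno == 1, na.rm = TRUE)
  n_minus <- colSums(geno == -1, na.rm = TRUE)
  ntot <- n_plus + n_minus
  testable <- ntot > 0
  chisq <- ifelse(testable, (n_plus - n_minus)^2 / ntot, NA_real_)
  p <- ifelse(testable, stats::pchisq(chisq, df = 1, lower.tail = FALSE), NA_real_)
  M <- sum(testable)
  if (M == 0L) stop("no testable markers (all calls missing)")
  data.frame(marker = colnames(geno), n_plus = n_plus, n_minus = n_minus,
             chisq = chisq, p = p,
             distorted = testable & !is.na(p) & p < alpha / M,
             testable = testable,
             row.names = NULL, stringsAsFactors = FALSE)
}
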