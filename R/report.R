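## File I/O for the standard inputs/outputs, map summary statistics and
## QTL report tables (with optional bin annotation for QTL naming).

#' Read a genetic map from TSV
#'
#' Expected header: `marker`, `chrom`, `pos_cM` (tab-separated).
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos_cM")
  if (!all(need %in% names(df)))
    stop("map file needs columns: ", paste(need, collapse = ", "))
  genetic_map(df$marker, df$chrom, df$pos_cM)
}

#' Write a genetic map to TSV
#'
#' @param map a [genetic_map()].
#' @param path file path.
#' @export
write_genetic_map <- function(map, path) {
  df <- data.frame(marker = map$marker, chrom = map$chrom, pos_cM = map$pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from CSV
#'
#' First column `line`; remaining columns are marker names; cells are decoded
#' by `codes` (default `A` -> +1, `B` -> -1); empty cells and `NA` are
#' missing, and any other value is coerced to missing with a logged count.
#'
#' @param path file path.
#' @param map a [genetic_map()] to validate against.
#' @param codes named vector mapping cell values to +1/-1.
#' @return validated lines x markers matrix.
#' @export
read_genotypes <- function(path, map, codes = c(A = 1, B = -1)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "line") stop("first genotype column must be 'line'")
  if (anyDuplicated(df$line))
    stop("duplicated line ids: ",
         paste(utils::head(unique(df$line[duplicated(df$line)]), 5), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$line
  g <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (k in seq_along(codes)) g[m == names(codes)[k]] <- codes[k]
  n_bad <- sum(!is.na(m) & m != "" & !(m %in% names(codes)))
  if (n_bad > 0)
    message("read_genotypes: coerced ", n_bad, " unrecognized call(s) to missing")
  validate_genotypes(g, map)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [read_genotypes()] under the same code mapping.
#'
#' @param geno lines x markers matrix coded +1/-1/NA.
#' @param path file path.
#' @param codes named vector mapping cell values to +1/-1.
#' @export
write_genotypes <- function(geno, path, codes = c(A = 1, B = -1)) {
  chars <- matrix(NA_character_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  for (k in seq_along(codes)) chars[!is.na(geno) & geno == codes[k]] <- names(codes)[k]
  df <- data.frame(line = rownames(geno), chars, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read long-format phenotype records from CSV
#'
#' Expected columns `line`, `block`, `trait`, `value`.
#'
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_records(df)
}

#' Write long-format phenotype records to CSV
#'
#' @param records phenotype data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(records, path) {
  check_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Map summary statistics
#'
#' Total length is the sum over chromosomes of (last - first marker
#' position). Mean marker spacing is reported under two conventions:
#' `spacing_per_marker = total / n_markers` (the convention behind the usual
#' "average interval" figure quoted for dense maize maps) and
#' `spacing_per_interval = total / (n_markers - n_chrom)`, the mean length of
#' the actual inter-marker intervals.
#'
#' @param map a [genetic_map()].
#' @return list `total_length`, `n_markers`, `n_chrom`, `spacing_per_marker`,
#'   `spacing_per_interval`.
#' @export
map_summary <- function(map) {
  ccs <- chromosomes(map)
  lens <- vapply(ccs, function(cc) {
    p <- map$pos[map$chrom == cc]
    max(p) - min(p)
  }, numeric(1))
  total <- sum(lens)
  M <- nrow(map)
  list(total_length = total, n_markers = M, n_chrom = length(ccs),
       spacing_per_marker = total / M,
       spacing_per_interval = total / (M - length(ccs)))
}

#' Assign bins to positions
#'
#' @param bin_table data frame `bin`, `chrom`, `start_cM`, `end_cM`
#'   (half-open intervals `[start, end)`, non-overlapping per chromosome).
#' @param chrom,pos position to annotate (vectorized).
#' @return bin labels; `NA` where a position falls in no bin.
#' @export
assign_bins <- function(bin_table, chrom, pos) {
  need <- c("bin", "chrom", "start_cM", "end_cM")
  if (!all(need %in% names(bin_table)))
    stop("bin table needs columns: ", paste(need, collapse = ", "))
  vapply(seq_along(chrom), function(i) {
    hit <- which(bin_table$chrom == as.character(chrom[i]) &
                   bin_table$start_cM <= pos[i] & pos[i] < bin_table$end_cM)
    if (length(hit)) as.character(bin_table$bin[hit[1L]]) else NA_character_
  }, character(1))
}

#' QTL report table
#'
#' One row per QTL and per epistatic pair, in the layout of published
#' multi-trait QTL tables: name, bin (when a bin table is supplied),
#' chromosome, peak position, LOD, flanking markers of the drop-LOD support
#' interval, and per-trait effect, significance stars and variance explained.
#' QTL are named `q<Label><bin>` when a bin table is given (label `Multi`
#' for multi-trait models, the trait name for single-trait models), falling
#' back to `q<Label><chrom>@<cM>` with a warning for positions outside all
#' bins; epistasis rows join the two parent QTL names with `" X "`.
#'
#' @param Z standardized trait matrix used to fit the model.
#' @param probs a [qtl_genotype_probabilities()] object.
#' @param model fitted `"qtl_model"`.
#' @param tests optional precomputed [effect_pvalues()] table.
#' @param bin_table optional bin annotation (see [assign_bins()]).
#' @param label QTL-name label; default `"Multi"` for multi-trait models,
#'   the trait name for single-trait models.
#' @param drop LOD drop for support intervals.
#' @param K,seed resampling controls forwarded to [effect_pvalues()] when
#'   `tests` is not supplied.
#' @return data frame of class `"qtl_report"` with per-trait effect/star/R2
#'   columns and attributes `r2_total` (per-trait R^2_T) and `intervals`.
#' @export
generate_qtl_report <- function(Z, probs, model, tests = NULL, bin_table = NULL,
                                label = NULL, drop = 1.5, K = 1000L, seed = 1L) {
  stopifnot(inherits(model, "qtl_model"))
  m <- nrow(model$terms)
  if (m == 0L) stop("empty model: nothing to report")
  if (is.null(label))
    label <- if (length(model$traits) > 1L) "Multi" else model$traits[1L]
  if (is.null(tests))
    tests <- effect_pvalues(Z, probs, model, K = K, seed = seed)
  r2 <- qtl_r2(model)
  ivs <- lapply(seq_len(m), function(i)
    support_interval(Z, probs, model, i, drop = drop))
  name_of <- function(i) {
    cc <- model$terms$chrom[i]
    pp <- model$terms$pos[i]
    if (!is.null(bin_table)) {
      b <- assign_bins(bin_table, cc, pp)
      if (!is.na(b)) return(paste0("q", label, b))
      warning(sprintf("position %s@%.1f outside all bins; fallback name used", cc, pp))
    }
    sprintf("q%s%s@%.1f", label, cc, pp)
  }
  qnames <- vapply(seq_len(m), name_of, character(1))
  bins <- if (!is.null(bin_table))
    assign_bins(bin_table, model$terms$chrom, model$terms$pos) else NA_character_
  per_trait <- function(effect_name, est_row, r2_row) {
    cols <- list()
    for (t in model$traits) {
      tt <- tests[tests$effect == effect_name & tests$trait == t, ]
      cols[[paste0("effect_", t)]] <- est_row[t]
      cols[[paste0("stars_", t)]] <- if (nrow(tt)) tt$stars else ""
      cols[[paste0("r2_", t)]] <- r2_row[t]
    }
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(m), function(i) {
    cbind(data.frame(name = qnames[i], type = "additive",
                     bin = bins[i], chrom = model$terms$chrom[i],
                     pos_cM = model$terms$pos[i],
                     lod = ivs[[i]]$peak_lod,
                     flank_left = ivs[[i]]$flank_left,
                     flank_right = ivs[[i]]$flank_right,
                     stringsAsFactors = FALSE),
          per_trait(paste0("Q", i), model$beta[i, ], r2$per_effect[paste0("Q", i), ]))
  })
  if (!is.null(model$pairs) && nrow(model$pairs) > 0L) {
    rows <- c(rows, lapply(seq_len(nrow(model$pairs)), function(k) {
      i <- model$pairs[k, 1L]
      j <- model$pairs[k, 2L]
      en <- paste0("Q", i, ":Q", j)
      cbind(data.frame(name = paste(qnames[i], "X", qnames[j]),
                       type = "epistasis", bin = NA_character_,
                       chrom = NA_character_, pos_cM = NA_real_, lod = NA_real_,
                       flank_left = NA_character_, flank_right = NA_character_,
                       stringsAsFactors = FALSE),
            per_trait(en, model$w[k, ], r2$per_effect[en, ]))
    }))
  }
  out <- do.call(rbind, rows)
  attr(out, "r2_total") <- r2$total
  attr(out, "intervals") <- ivs
  class(out) <- c("qtl_report", "data.frame")
  out
}

#' Export scan profiles to TSV
#'
#' One tab-separated file per profile with columns
#' `chrom`, `pos_cM`, `lod`, `score`; reading the file back reproduces the
#' values exactly (full precision).
#'
#' @param profiles a `"scan_profile"` data frame or a named list of them.
#' @param dir output directory (created if needed).
#' @return invisible character vector of file paths.
#' @export
export_scan_profiles <- function(profiles, dir) {
  if (inherits(profiles, "scan_profile")) profiles <- list(scan = profiles)
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- paste0("scan", seq_along(profiles))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(profiles)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- profiles[[nm]]
    out <- data.frame(chrom = df$chrom, pos_cM = sprintf("%.17g", df$pos),
                      lod = sprintf("%.17g", df$lod),
                      score = sprintf("%.17g", df$score))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
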