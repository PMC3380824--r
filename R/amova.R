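# One-factor analysis of molecular variance (Excoffier-style decomposition
# of squared molecular distances) with whole-haplotype label permutation for
# significance. Raw pairwise nucleotide differences serve as the squared
# Euclidean distances, the standard haplotypic-AMOVA convention.

#' Pairwise nucleotide difference matrix
#'
#' `d_ij` is the number of aligned columns at which haplotypes `i` and `j`
#' carry different bases, ignoring columns where either carries a gap or `N`.
#'
#' @param aln A `haplotype_alignment`.
#' @return Symmetric integer matrix with zero diagonal, dimnames the
#'   haplotype ids.
#' @export
pairwise_difference_matrix <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  m <- aln$mat
  n <- nrow(m)
  valid <- !(m %in% c("-", "N"))
  dim(valid) <- dim(m)
  d <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  d
}

# Phi_ST and variance components from a squared-distance matrix and a group
# factor. dist2: matrix of squared distances (for nucleotide differences the
# counts themselves). Returns the decomposition used by both the observed
# fit and the permutation loop.
.amova_components <- function(dist2, groups) {
  groups <- as.factor(groups)
  N <- length(groups)
  G <- nlevels(droplevels(groups))
  idx_by_group <- split(seq_len(N), droplevels(groups))
  n_g <- lengths(idx_by_group)
  ssd_total <- sum(dist2[upper.tri(dist2)]) / N
  ssd_within <- sum(vapply(idx_by_group, function(idx) {
    sub <- dist2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  df_among <- G - 1L
  df_within <- N - G
  sigma2_within <- ssd_within / df_within
  n_c <- (N - sum(n_g^2) / N) / df_among
  sigma2_among <- (ssd_among / df_among - sigma2_within) / n_c
  phi_st <- sigma2_among / (sigma2_among + sigma2_within)
  list(ssd_total = ssd_total, ssd_among = ssd_among, ssd_within = ssd_within,
       df_among = df_among, df_within = df_within,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       n_c = n_c, phi_st = phi_st,
       pct_among = 100 * sigma2_among / (sigma2_among + sigma2_within))
}

.as_group_vector <- function(dist, groups) {
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(rownames(dist), names(groups))
    if (length(missing_ids) > 0L) {
      stop("no group assignment for haplotype(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    groups <- groups[rownames(dist)]
  } else if (length(groups) != nrow(dist)) {
    stop("groups must be named by haplotype id or match the distance matrix",
         call. = FALSE)
  }
  as.character(groups)
}

#' One-factor AMOVA variance components
#'
#' Decomposes molecular variance among and within groups from a matrix of
#' pairwise nucleotide differences (used as squared Euclidean distances):
#' `SSD_within = sum_g SS_g / n_g`, `sigma2_within = SSD_within / (N - G)`,
#' `sigma2_among = (SSD_among/(G-1) - sigma2_within) / n_c` with
#' `n_c = (N - sum n_g^2 / N) / (G - 1)`. Negative among-group components are
#' reported as computed (standard AMOVA behaviour, no truncation).
#'
#' @param dist Symmetric pairwise-difference matrix (see
#'   [pairwise_difference_matrix()]).
#' @param groups Group labels, either named by haplotype id or aligned with
#'   the rows of `dist`.
#' @param exclude Optional group label(s) to drop before the analysis (e.g.
#'   an outgroup).
#' @param factor_name Label recorded in the result (`phenotype`, `species`,
#'   `geography`, ...).
#' @return An object of class `amova_result` with the variance components,
#'   `pct_among`, `phi_st` and (before permutation) `p_perm = NA`.
#' @export
amova_oneway <- function(dist, groups, exclude = NULL,
                         factor_name = "group") {
  dist <- as.matrix(dist)
  grp <- .as_group_vector(dist, groups)
  keep <- !grp %in% exclude
  dist <- dist[keep, keep, drop = FALSE]
  grp <- grp[keep]
  if (length(unique(grp)) < 2L) {
    stop("AMOVA needs at least 2 groups with members", call. = FALSE)
  }
  comp <- .amova_components(dist, grp)
  structure(c(list(factor = factor_name, n = length(grp),
                   groups = table(grp)), comp,
              list(p_perm = NA_real_, n_perm = 0L)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result> factor ", x$factor, " (", x$n, " haplotypes, ",
      length(x$groups), " groups)\n", sep = "")
  cat(sprintf("  sigma2 among = %.4f, within = %.4f; %% among = %.2f; Phi_ST = %.4f\n",
              x$sigma2_among, x$sigma2_within, x$pct_among, x$phi_st))
  if (x$n_perm > 0L) {
    cat(sprintf("  permutation p = %s (%d permutations)\n",
                format(x$p_perm), x$n_perm))
  }
  invisible(x)
}

#' AMOVA with permutation significance
#'
#' Permutes whole-haplotype group labels, recomputes `Phi_ST` for each
#' permutation, and reports `p = (1 + #\{Phi_perm >= Phi_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams amova_oneway
#' @param n_perm Number of label permutations (1000 for production runs).
#' @param seed Optional seed.
#' @return An `amova_result` with `p_perm` and `n_perm` filled in.
#' @export
amova_permutation_test <- function(dist, groups, n_perm = 1000, seed = NULL,
                                   exclude = NULL, factor_name = "group") {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- amova_oneway(dist, groups, exclude = exclude,
                      factor_name = factor_name)
  dist <- as.matrix(dist)
  grp <- .as_group_vector(dist, groups)
  keep <- !grp %in% exclude
  dist <- dist[keep, keep, drop = FALSE]
  grp <- grp[keep]
  phi_perm <- vapply(seq_len(n_perm), function(i) {
    .amova_components(dist, sample(grp))$phi_st
  }, numeric(1))
  res$p_perm <- (1 + sum(phi_perm >= res$phi_st)) / (n_perm + 1)
  res$n_perm <- as.integer(n_perm)
  res$phi_perm <- phi_perm
  res
}

#' Per-locus AMOVA report across grouping factors
#'
#' Runs one-factor AMOVAs for each requested metadata factor on each locus
#' and assembles the standard report: rows are loci, with percentage of
#' variation explained, permutation p, and significance tier per factor.
#' The outgroup species is excluded.
#'
#' @param alignments Named list of `haplotype_alignment` objects.
#' @param metadata A `specimen_metadata` data frame.
#' @param factors Metadata columns to analyse; `region` is reported as
#'   `geography`.
#' @param n_perm Permutations per test.
#' @param seed Optional seed.
#' @return A data frame report.
#' @export
amova_report <- function(alignments, metadata,
                         factors = c("phenotype", "species", "region"),
                         n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  outgroup_ids <- metadata$haplotype_id[metadata$species == "numata_outgroup"]
  rows <- lapply(alignments, function(aln) {
    d <- pairwise_difference_matrix(aln)
    keep <- setdiff(aln$ids, outgroup_ids)
    d <- d[keep, keep, drop = FALSE]
    row <- list(locus = aln$locus_name)
    for (f in factors) {
      grp <- stats::setNames(metadata[[f]], metadata$haplotype_id)[keep]
      fac_label <- if (f == "region") "geography" else f
      res <- amova_permutation_test(d, grp, n_perm = n_perm,
                                    factor_name = fac_label)
      row[[paste0("pct_", fac_label)]] <- res$pct_among
      row[[paste0("p_", fac_label)]] <- res$p_perm
      row[[paste0("tier_", fac_label)]] <- table_significance_tiers(res$p_perm)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
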