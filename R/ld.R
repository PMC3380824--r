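# Pairwise linkage disequilibrium (D, D') and the shared/exclusive
# polymorphism gene-flow statistic x = Dss - Dsx, with its coalescent
# simulation null. Shared polymorphisms that entered a population by recent
# gene flow are younger than retained ancestral polymorphisms and so carry
# stronger LD with each other than with the population's exclusive
# polymorphisms; a positive x flags gene flow, and the recipient population
# shows the larger positive value.

#' Gametic disequilibrium D and normalised D' for two biallelic sites
#'
#' `D = p_AB - p_A p_B`, with `A` and `B` the minor alleles at the two sites
#' (ties broken alphabetically). `D' = D / D_max`, where
#' `D_max = min(p_A (1 - p_B), (1 - p_A) p_B)` when `D > 0` and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` when `D < 0`; `D' = 0` when `D = 0`.
#'
#' @param a,b Character (or other atomic) vectors of alleles at the two
#'   sites, one entry per haplotype, no missing values.
#' @return Named numeric vector `c(D = ..., D_prime = ...)`.
#' @export
#' @examples
#' ld_D_and_Dprime(c("A", "A", "a", "a"), c("B", "B", "b", "b"))
ld_D_and_Dprime <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) stop("allele vectors differ in length", call. = FALSE)
  ta <- sort(table(a))
  tb <- sort(table(b))
  if (length(ta) != 2L || length(tb) != 2L) {
    stop("both sites must be biallelic among the supplied haplotypes",
         call. = FALSE)
  }
  # minor allele; on a 50/50 tie take the alphabetically first
  minor_of <- function(tab) {
    if (tab[[1]] == tab[[2]]) sort(names(tab))[1] else names(tab)[1]
  }
  A <- minor_of(ta)
  B <- minor_of(tb)
  n <- length(a)
  pA <- sum(a == A) / n
  pB <- sum(b == B) / n
  pAB <- sum(a == A & b == B) / n
  D <- pAB - pA * pB
  if (D > 0) {
    Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    Dmax <- min(pA * pB, (1 - pA) * (1 - pB))
  } else {
    Dmax <- 1
  }
  c(D = D, D_prime = if (D == 0) 0 else D / Dmax)
}

# |D'| for every column pair of a 0/1 haplotype matrix (columns already
# biallelic within the supplied rows). Fully vectorised via crossprod.
.abs_dprime_matrix <- function(X) {
  n <- nrow(X)
  p <- colMeans(X)
  P <- crossprod(X) / n
  D <- P - tcrossprod(p)
  pos <- pmin(outer(p, 1 - p), outer(1 - p, p))
  neg <- pmin(outer(p, p), outer(1 - p, 1 - p))
  Dmax <- ifelse(D > 0, pos, neg)
  Dp <- ifelse(D == 0, 0, D / Dmax)
  diag(Dp) <- 1
  list(abs = abs(Dp), signed = Dp)
}

# Mean |D'| (and signed D') over the site pairs (i in set1) x (j in set2),
# excluding i == j; for set1 == set2 averages over unordered distinct pairs.
.pair_mean <- function(M, S, set1, set2) {
  if (length(set1) == 0L || length(set2) == 0L) {
    return(list(n = 0L, mean_abs = NA_real_, mean_signed = NA_real_))
  }
  same <- identical(sort(set1), sort(set2))
  if (same) {
    if (length(set1) < 2L) {
      return(list(n = 0L, mean_abs = NA_real_, mean_signed = NA_real_))
    }
    sub <- M[set1, set1, drop = FALSE]
    ssub <- S[set1, set1, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    svals <- ssub[upper.tri(ssub)]
  } else {
    vals <- as.vector(M[set1, set2, drop = FALSE])
    svals <- as.vector(S[set1, set2, drop = FALSE])
  }
  list(n = length(vals), mean_abs = mean(vals), mean_signed = mean(svals))
}

# Observed x statistic from a 0/1 matrix.
# X: haplotypes x sites binary matrix; idx1/idx2 row indices of the two pops.
# For each population, sites with within-population minor-allele count below
# min_count are dropped from that population's pair sets (D' is degenerate,
# +-1, for singletons). The default measure is signed D' with each site
# oriented to its within-population minor allele, so complete coupling
# scores +1 and complete repulsion -1; "magnitude" averages |D'| instead.
# orient = "minor" re-orients every column to its within-population minor
# allele; "as_coded" keeps the incoming 0/1 coding (used when 1 already
# means the derived allele, the unbiased orientation).
# Returns per-population x, class means (both measures) and pair counts.
.xstat_binary <- function(X, idx1, idx2, measure = "signed", min_count = 2,
                          orient = "minor") {
  X1 <- X[idx1, , drop = FALSE]
  X2 <- X[idx2, , drop = FALSE]
  cs1 <- colSums(X1)
  cs2 <- colSums(X2)
  poly1 <- cs1 > 0L & cs1 < nrow(X1)
  poly2 <- cs2 > 0L & cs2 < nrow(X2)
  ok1 <- pmin(cs1, nrow(X1) - cs1) >= min_count
  ok2 <- pmin(cs2, nrow(X2) - cs2) >= min_count
  res <- list()
  for (p in 1:2) {
    Xp <- if (p == 1L) X1 else X2
    okp <- if (p == 1L) ok1 else ok2
    shared <- which(poly1 & poly2 & okp)
    excl <- if (p == 1L) which(poly1 & !poly2 & okp) else
                         which(poly2 & !poly1 & okp)
    focal <- c(shared, excl)
    if (length(shared) >= 1L && length(focal) >= 2L) {
      sub <- Xp[, focal, drop = FALSE]
      if (orient == "minor") {
        flip <- colMeans(sub) > 0.5
        sub[, flip] <- 1L - sub[, flip]
      }
      dm <- .abs_dprime_matrix(sub)
      is_shared <- seq_along(focal) <= length(shared)
      ss <- .pair_mean(dm$abs, dm$signed, which(is_shared), which(is_shared))
      sx <- if (length(excl) >= 1L) {
        .pair_mean(dm$abs, dm$signed, which(is_shared), which(!is_shared))
      } else {
        list(n = 0L, mean_abs = NA_real_, mean_signed = NA_real_)
      }
    } else {
      ss <- list(n = 0L, mean_abs = NA_real_, mean_signed = NA_real_)
      sx <- list(n = 0L, mean_abs = NA_real_, mean_signed = NA_real_)
    }
    x <- if (ss$n > 0L && sx$n > 0L) {
      if (measure == "signed") ss$mean_signed - sx$mean_signed
      else ss$mean_abs - sx$mean_abs
    } else {
      NA_real_
    }
    res[[p]] <- list(x = x,
                     D_SS_mean = if (measure == "signed") ss$mean_signed else ss$mean_abs,
                     D_SX_mean = if (measure == "signed") sx$mean_signed else sx$mean_abs,
                     D_SS_mean_abs = ss$mean_abs, D_SX_mean_abs = sx$mean_abs,
                     D_SS_mean_signed = ss$mean_signed,
                     D_SX_mean_signed = sx$mean_signed,
                     n_SS_pairs = ss$n, n_SX_pairs = sx$n,
                     n_shared = length(shared),
                     n_exclusive = length(excl))
  }
  res
}

# Recode the usable (non-excluded, biallelic) columns of an alignment as a
# 0/1 matrix over the two populations' haplotypes. With `ancestral` (a
# per-site vector of ancestral bases), columns are polarised so 1 = derived
# allele wherever the ancestral base is observed at the column; other
# columns keep the default coding. Returns NULL if no usable columns.
.binary_recode <- function(aln, pop1, pop2, sites = NULL, ancestral = NULL) {
  ids <- c(pop1, pop2)
  m <- aln$mat[ids, , drop = FALSE]
  if (is.null(sites)) {
    cls <- classify_sites(aln, pop1, pop2)
    sites <- which(cls$klass %in% c("shared", "exclusive_pop1",
                                    "exclusive_pop2", "fixed_difference"))
  }
  if (length(sites) == 0L) return(NULL)
  X <- matrix(0L, nrow = length(ids), ncol = length(sites))
  for (k in seq_along(sites)) {
    col <- m[, sites[k]]
    anc <- if (is.null(ancestral)) NA_character_ else ancestral[sites[k]]
    if (!is.na(anc) && anc %in% col) {
      X[, k] <- as.integer(col != anc)
    } else {
      X[, k] <- as.integer(col == sort(unique(col))[1])
    }
  }
  rownames(X) <- ids
  X
}

# Resolve the `ancestral` argument of x_statistic/geneflow_test to a
# per-site character vector (or NULL): a single base recycles; a haplotype
# id present in the alignment contributes its sequence (gap/N -> NA).
.resolve_ancestral <- function(aln, ancestral) {
  if (is.null(ancestral)) return(NULL)
  L <- alignment_length(aln)
  if (length(ancestral) == 1L && ancestral %in% aln$ids) {
    anc <- aln$mat[ancestral, ]
    anc[anc %in% c("-", "N")] <- NA_character_
    return(anc)
  }
  if (length(ancestral) == 1L) return(rep(toupper(ancestral), L))
  if (length(ancestral) != L) {
    stop("ancestral must be a single base, an outgroup haplotype id, or a ",
         "per-site vector of length ", L, call. = FALSE)
  }
  toupper(ancestral)
}

.empty_geneflow_pop <- function() {
  list(x = NA_real_, D_SS_mean = NA_real_, D_SX_mean = NA_real_,
       D_SS_mean_abs = NA_real_, D_SX_mean_abs = NA_real_,
       D_SS_mean_signed = NA_real_, D_SX_mean_signed = NA_real_,
       n_SS_pairs = 0L, n_SX_pairs = 0L, n_shared = 0L, n_exclusive = 0L)
}

#' Observed gene-flow statistic x = Dss - Dsx per population
#'
#' For each population, Dss is the mean D' over all pairs of shared
#' polymorphisms and Dsx the mean D' over all pairs of one shared and one
#' population-exclusive polymorphism, both computed within that population's
#' haplotypes only. Recent gene flow leaves shared polymorphisms in strong
#' mutual coupling, so a positive x flags gene flow and the recipient
#' population carries the larger positive value. `x` is `NA` when a locus
#' lacks shared or usable exclusive polymorphisms (a valid outcome, reported
#' as such, as for loci fixed between the species).
#'
#' By default D' is signed. With `ancestral` supplied (an outgroup
#' haplotype, a per-site vector of ancestral bases, or a single base for
#' simulator output), sites are polarised so that D' measures coupling
#' between derived alleles -- the unbiased orientation, with expectation
#' near 0 under neutrality; derived alleles that crossed the species
#' boundary together stay coupled, driving x positive. Without `ancestral`,
#' each site is oriented to its within-population minor allele (a positive
#' bias that the simulation null reproduces, so p-values remain valid). The
#' `"magnitude"` option averages |D'| instead, but |D'| equals 1 for any
#' pair not yet broken up by recombination whatever the phase, which leaves
#' the magnitude version without discriminating power. Sites whose
#' minor-allele count within the focal population is below `min_count` are
#' excluded from that population's pairs (D' is degenerate for singletons).
#'
#' @param aln A `haplotype_alignment`.
#' @param pop1,pop2 Disjoint haplotype id sets.
#' @param labels Labels used for the two populations in reports.
#' @param ld_measure `"signed"` (default) or `"magnitude"`.
#' @param min_count Minimum within-population minor-allele count for a site
#'   to enter the pair sets (default 2, i.e. singletons excluded).
#' @param ancestral Ancestral-state specification for derived-allele
#'   polarisation: an outgroup haplotype id present in the alignment, a
#'   per-site character vector, or a single base (infinite-sites simulator
#'   output uses `"A"`). `NULL` (default) falls back to minor-allele
#'   orientation.
#' @return An object of class `gene_flow_result` (observed component only):
#'   per-population `x`, class means (signed and absolute), pair and site
#'   counts.
#' @export
x_statistic <- function(aln, pop1, pop2, labels = c("pop1", "pop2"),
                        ld_measure = c("signed", "magnitude"),
                        min_count = 2, ancestral = NULL) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  ld_measure <- match.arg(ld_measure)
  pops <- .check_pops(aln, pop1, pop2)
  anc <- .resolve_ancestral(aln, ancestral)
  X <- .binary_recode(aln, pops$pop1, pops$pop2, ancestral = anc)
  if (is.null(X)) {
    per_pop <- list(.empty_geneflow_pop(), .empty_geneflow_pop())
  } else {
    per_pop <- .xstat_binary(X, seq_along(pops$pop1),
                             length(pops$pop1) + seq_along(pops$pop2),
                             measure = ld_measure, min_count = min_count,
                             orient = if (is.null(anc)) "minor" else "as_coded")
  }
  structure(list(locus = aln$locus_name, labels = labels,
                 pop1 = per_pop[[1]], pop2 = per_pop[[2]],
                 n1 = length(pops$pop1), n2 = length(pops$pop2),
                 ld_measure = ld_measure, min_count = min_count,
                 orientation = if (is.null(anc)) "minor" else "derived",
                 null_x = NULL, p = c(NA_real_, NA_real_),
                 null_mean = c(NA_real_, NA_real_), n_sims = 0L),
            class = "gene_flow_result")
}

#' @export
print.gene_flow_result <- function(x, ...) {
  cat("<gene_flow_result> locus ", x$locus, "\n", sep = "")
  for (i in 1:2) {
    pp <- x[[c("pop1", "pop2")[i]]]
    cat(sprintf("  %-12s x = %s (Dss = %s over %d pairs, Dsx = %s over %d pairs)",
                x$labels[i], format(round(pp$x, 4)),
                format(round(pp$D_SS_mean, 4)), pp$n_SS_pairs,
                format(round(pp$D_SX_mean, 4)), pp$n_SX_pairs))
    if (x$n_sims > 0L) {
      cat(sprintf("  simulated mean = %s, p = %s",
                  format(round(x$null_mean[i], 4)), format(x$p[i])))
    }
    cat("\n")
  }
  invisible(x)
}

# Watterson's theta from a count of segregating sites.
.watterson <- function(S, n) {
  if (n < 2L) return(NA_real_)
  S / sum(1 / seq_len(n - 1L))
}

# Null model parameters estimated from the data: per-population Watterson
# theta, ancestral theta = mean of the two, split time from net divergence
# d_a = d_xy - (pi1 + pi2)/2 (per locus, mutation-scaled t = d_a / 2).
.null_im_parameters <- function(aln, pop1, pop2, rho = 2, n_blocks = 20) {
  cls <- classify_sites(aln, pop1, pop2)
  usable <- which(cls$klass != "excluded")
  m1 <- aln$mat[pop1, usable, drop = FALSE]
  m2 <- aln$mat[pop2, usable, drop = FALSE]
  seg <- function(m) {
    sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  }
  n1 <- length(pop1)
  n2 <- length(pop2)
  theta1 <- max(.watterson(seg(m1), n1), 0.1)
  theta2 <- max(.watterson(seg(m2), n2), 0.1)
  mean_pair_diff <- function(ma, mb) {
    tot <- 0
    for (i in seq_len(nrow(ma))) {
      tot <- tot + sum(t(mb) != ma[i, ])
    }
    tot / (nrow(ma) * nrow(mb))
  }
  within <- function(m) {
    n <- nrow(m)
    if (n < 2L) return(0)
    tot <- 0
    for (i in seq_len(n - 1L)) {
      tot <- tot + sum(t(m[(i + 1L):n, , drop = FALSE]) != m[i, ])
    }
    tot / (n * (n - 1L) / 2)
  }
  d_xy <- mean_pair_diff(m1, m2)
  d_a <- d_xy - (within(m1) + within(m2)) / 2
  t_split <- max(d_a / 2, 0.01)
  im_parameters(theta1 = theta1, theta2 = theta2,
                thetaA = (theta1 + theta2) / 2, t_split = t_split,
                m1 = 0, m2 = 0, n1 = n1, n2 = n2,
                locus_length = alignment_length(aln), rho = rho,
                n_blocks = min(n_blocks, alignment_length(aln)))
}

#' Coalescent-simulation gene-flow test
#'
#' Computes the observed `x = Dss - Dsx` per population and its upper-tail
#' p-value under a two-population isolation null (no migration) simulated
#' with the infinite-sites coalescent. Null parameters are estimated from the
#' data: Watterson's theta per population, ancestral theta the mean of the
#' two, and split time from the net between-population divergence; migration
#' is fixed at zero. The p-value uses the add-one rule
#' `p = (1 + #\{x_sim >= x_obs\}) / (n_sims + 1)` so it is never exactly 0.
#'
#' @inheritParams x_statistic
#' @param n_sims Number of null simulations (30000 for production runs; use
#'   fewer for exploration).
#' @param seed Optional integer seed for reproducibility.
#' @param rho Mutation-scaled intra-locus recombination rate assumed by the
#'   null simulations (see [im_parameters()]); the statistic relies on
#'   recombination having had time to break ancestral associations, so the
#'   null must recombine too.
#' @param n_blocks Recombination discretisation for the null simulations.
#' @param null_params Optional [im_parameters()] overriding the estimated
#'   null (migration rates are forced to zero).
#' @return A `gene_flow_result` with simulated null values (`null_x`, a
#'   `n_sims` x 2 matrix), per-population p-values (computed over the
#'   non-`NA` simulated values with the add-one rule) and null means.
#' @export
geneflow_test <- function(aln, pop1, pop2, n_sims = 30000, seed = NULL,
                          labels = c("pop1", "pop2"), rho = 2,
                          n_blocks = 20, ld_measure = c("signed", "magnitude"),
                          min_count = 2, ancestral = NULL,
                          null_params = NULL) {
  stopifnot(n_sims >= 1)
  ld_measure <- match.arg(ld_measure)
  if (!is.null(seed)) set.seed(seed)
  obs <- x_statistic(aln, pop1, pop2, labels = labels,
                     ld_measure = ld_measure, min_count = min_count,
                     ancestral = ancestral)
  orient <- if (is.null(ancestral)) "minor" else "as_coded"
  pops <- .check_pops(aln, pop1, pop2)
  params <- if (is.null(null_params)) {
    .null_im_parameters(aln, pops$pop1, pops$pop2, rho = rho,
                        n_blocks = n_blocks)
  } else {
    np <- null_params
    np$m1 <- 0
    np$m2 <- 0
    np$n1 <- length(pops$pop1)
    np$n2 <- length(pops$pop2)
    np
  }
  null_x <- matrix(NA_real_, nrow = n_sims, ncol = 2)
  idx1 <- seq_len(params$n1)
  idx2 <- params$n1 + seq_len(params$n2)
  for (s in seq_len(n_sims)) {
    X <- .sim_binary_matrix(params)
    if (is.null(X)) next
    r <- .xstat_binary(X, idx1, idx2, measure = ld_measure,
                       min_count = min_count, orient = orient)
    null_x[s, ] <- c(r[[1]]$x, r[[2]]$x)
  }
  p <- numeric(2)
  null_mean <- numeric(2)
  n_valid <- integer(2)
  for (i in 1:2) {
    xo <- obs[[c("pop1", "pop2")[i]]]$x
    sims <- null_x[!is.na(null_x[, i]), i]
    n_valid[i] <- length(sims)
    null_mean[i] <- if (n_valid[i] > 0L) mean(sims) else NA_real_
    p[i] <- if (is.na(xo) || n_valid[i] == 0L) NA_real_ else {
      (1 + sum(sims >= xo)) / (n_valid[i] + 1)
    }
  }
  obs$null_x <- null_x
  obs$p <- p
  obs$null_mean <- null_mean
  obs$n_sims <- n_sims
  obs$n_valid_sims <- n_valid
  obs$null_params <- params
  obs
}

#' Infer the recipient population of gene flow
#'
#' The recipient is the population with the larger positive, significant
#' `x`; `"undetermined"` when neither population has a positive significant
#' value, or on an exact tie.
#'
#' @param result A `gene_flow_result` from [geneflow_test()].
#' @param alpha Significance level applied to the simulation p-values.
#' @return The recipient population's label, or `"undetermined"`.
#' @export
infer_direction <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "gene_flow_result"))
  x <- c(result$pop1$x, result$pop2$x)
  if (all(is.na(x))) {
    stop("both x values are NA; direction cannot be inferred", call. = FALSE)
  }
  p <- result$p
  candidate <- !is.na(x) & x > 0 & !is.na(p) & p < alpha
  if (!any(candidate)) return("undetermined")
  if (all(candidate) && x[1] == x[2]) return("undetermined")
  result$labels[which(candidate)[which.max(x[candidate])]]
}

#' Pairwise |D'| matrix across a locus
#'
#' Computes the symmetric matrix of |D'| over all biallelic sites whose minor
#' allele frequency strictly exceeds `maf`, across all haplotypes of the
#' alignment (the whole-locus LD panel used for heatmap rendering).
#'
#' @param aln A `haplotype_alignment`.
#' @param maf Minor-allele-frequency threshold (strict), default 0.05.
#' @return Symmetric numeric matrix with unit diagonal; dimnames are the
#'   1-based site positions.
#' @export
pairwise_ld_matrix <- function(aln, maf = 0.05) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  sites <- maf_filter(aln, maf)
  if (length(sites) < 2L) {
    stop("fewer than 2 sites pass the MAF filter", call. = FALSE)
  }
  X <- matrix(0L, nrow = n_haplotypes(aln), ncol = length(sites))
  for (k in seq_along(sites)) {
    col <- aln$mat[, sites[k]]
    X[, k] <- as.integer(col == sort(unique(col))[1])
  }
  M <- .abs_dprime_matrix(X)$abs
  dimnames(M) <- list(sites, sites)
  M
}

#' Write a gene-flow report row set as TSV
#'
#' One row per population, mirroring the standard gene-flow table layout:
#' locus, population, observed x, simulated mean x, p.
#'
#' @param results A `gene_flow_result` or list of them.
#' @param path Output path (optional; omit to just get the data frame).
#' @return The report data frame, invisibly if written.
#' @export
geneflow_report <- function(results, path = NULL) {
  if (inherits(results, "gene_flow_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(locus = r$locus,
               population = r$labels,
               observed_x = c(r$pop1$x, r$pop2$x),
               simulated_mean_x = r$null_mean,
               p = r$p,
               n_sims = r$n_sims,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
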