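# Independent brute-force oracles and fixture builders. Everything here
# re-derives quantities from first principles, without going through the
# package's computational paths.

# random nucleotide alignment, optionally with gaps/Ns
random_alignment <- function(n, L, gap_prob = 0, seed = NULL,
                             alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  if (gap_prob > 0) {
    mask <- matrix(runif(n * L) < gap_prob, nrow = n)
    mat[mask] <- sample(c("-", "N"), sum(mask), replace = TRUE)
  }
  haplotype_alignment(mat, ids = sprintf("h%02d", seq_len(n)),
                      locus_name = "random")
}

# two-population random alignment with mostly biallelic columns
random_two_pop_alignment <- function(n1 = 20, n2 = 20, L = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  mat <- matrix("A", n, L)
  for (j in seq_len(L)) {
    p <- runif(1, 0.05, 0.95)
    mat[runif(n) < p, j] <- "G"
  }
  haplotype_alignment(mat, ids = sprintf("h%02d", seq_len(n)),
                      locus_name = "twopop")
}

# scalar D and D' from the definition, independent reimplementation
oracle_dprime <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  minor <- function(tab) {
    nm <- names(sort(tab))
    if (tab[[nm[1]]] == tab[[nm[2]]]) sort(names(tab))[1] else nm[1]
  }
  A <- minor(ta)
  B <- minor(tb)
  pA <- mean(a == A)
  pB <- mean(b == B)
  D <- mean(a == A & b == B) - pA * pB
  if (D > 0) {
    Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    Dmax <- min(pA * pB, (1 - pA) * (1 - pB))
  } else {
    return(c(D = 0, D_prime = 0))
  }
  c(D = D, D_prime = D / Dmax)
}

# per-column site classification by direct rules
oracle_classify <- function(aln, pop1, pop2) {
  m1 <- aln$mat[pop1, , drop = FALSE]
  m2 <- aln$mat[pop2, , drop = FALSE]
  vapply(seq_len(ncol(m1)), function(j) {
    c1 <- m1[, j]
    c2 <- m2[, j]
    if (any(c(c1, c2) %in% c("-", "N"))) return("excluded")
    if (length(unique(c(c1, c2))) > 2) return("excluded")
    p1 <- length(unique(c1)) > 1
    p2 <- length(unique(c2)) > 1
    if (p1 && p2) "shared"
    else if (p1) "exclusive_pop1"
    else if (p2) "exclusive_pop2"
    else if (unique(c1) != unique(c2)) "fixed_difference"
    else "monomorphic"
  }, character(1))
}

# brute-force x statistic: explicit pair enumeration with scalar D',
# mirroring the definition (per-population site filter, orientation, class
# means) without the package's matrix algebra
oracle_xstat <- function(aln, pop1, pop2, measure = "signed", min_count = 2,
                         ancestral = NULL) {
  klass <- oracle_classify(aln, pop1, pop2)
  out <- c(NA_real_, NA_real_)
  for (p in 1:2) {
    rows <- if (p == 1) pop1 else pop2
    m <- aln$mat[rows, , drop = FALSE]
    usable <- vapply(seq_len(ncol(m)), function(j) {
      tab <- table(m[, j])
      length(tab) == 2 && min(tab) >= min_count
    }, logical(1))
    shared <- which(klass == "shared" & usable)
    excl <- which(klass == paste0("exclusive_pop", p) & usable)
    if (length(shared) < 2 || length(excl) < 1) next
    pair_dp <- function(i, j) {
      a <- m[, i]
      b <- m[, j]
      # orient to 1 = derived (if ancestral known) else minor allele
      code <- function(col, pos) {
        if (!is.null(ancestral)) {
          anc <- if (length(ancestral) == 1) ancestral else ancestral[pos]
          as.integer(col != anc)
        } else {
          tab <- table(col)
          minor_allele <- if (tab[[1]] == tab[[2]]) {
            sort(names(tab))[1]
          } else {
            names(tab)[which.min(tab)]
          }
          as.integer(col == minor_allele)
        }
      }
      x <- code(a, i)
      y <- code(b, j)
      pA <- mean(x)
      pB <- mean(y)
      D <- mean(x & y) - pA * pB
      if (D == 0) return(0)
      Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
              else min(pA * pB, (1 - pA) * (1 - pB))
      dp <- D / Dmax
      if (measure == "magnitude") abs(dp) else dp
    }
    ss <- c()
    for (i in seq_along(shared)) {
      for (j in seq_along(shared)) {
        if (j > i) ss <- c(ss, pair_dp(shared[i], shared[j]))
      }
    }
    sx <- c()
    for (i in shared) for (j in excl) sx <- c(sx, pair_dp(i, j))
    out[p] <- mean(ss) - mean(sx)
  }
  out
}

# definitional AMOVA decomposition from explicit sums of squares
oracle_amova <- function(d, groups) {
  groups <- as.character(groups)
  N <- length(groups)
  lv <- unique(groups)
  G <- length(lv)
  ssd_total <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) ssd_total <- ssd_total + d[i, j]
  }
  ssd_total <- ssd_total / N
  ssd_within <- 0
  for (g in lv) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (i in seq_along(idx)[-length(idx)]) {
        for (j in (i + 1):length(idx)) s <- s + d[idx[i], idx[j]]
      }
    }
    ssd_within <- ssd_within + s / length(idx)
  }
  n_g <- table(groups)
  sigma2_within <- ssd_within / (N - G)
  n_c <- (N - sum(n_g^2) / N) / (G - 1)
  sigma2_among <- ((ssd_total - ssd_within) / (G - 1) - sigma2_within) / n_c
  list(sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       phi_st = sigma2_among / (sigma2_among + sigma2_within),
       pct_among = 100 * sigma2_among / (sigma2_among + sigma2_within))
}

# exhaustive-likelihood oracle: sums over all internal-node state
# assignments (no pruning recursion). The transition matrices come either
# from the package's cached eigen decomposition (isolating the summation
# algorithm, exact agreement expected) or from an independent matrix
# exponential (pracma::expm, full independence at ~1e-6).
oracle_tree_loglik <- function(aln, tree, model,
                               pmat = c("eigen", "expm")) {
  pmat <- match.arg(pmat)
  nuc <- c("A", "C", "G", "T")
  pi <- model$base_freqs
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  P_of <- if (pmat == "expm") {
    function(t) pracma::expm(model$Q * t)
  } else {
    function(t) introgrescan:::.pmatrix(model, t)
  }
  site_ll <- numeric(alignment_length(aln))
  for (s in seq_len(alignment_length(aln))) {
    obs <- aln$mat[tree$tip.label, s]
    total <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
    for (g in seq_len(nrow(grid))) {
      states <- integer(nnode)
      states[internal] <- grid[g, ]
      states[1:ntip] <- match(obs, nuc)
      root <- tree$edge[nrow(tree$edge), 1]
      pr_mix <- 0
      for (k in seq_len(model$n_categories)) {
        pr <- pi[states[root]]
        for (e in seq_len(nrow(tree$edge))) {
          P <- P_of(model$gamma_rates[k] * tree$edge.length[e])
          a <- states[tree$edge[e, 1]]
          b <- states[tree$edge[e, 2]]
          if (is.na(b)) { pr <- pr * 1 } else pr <- pr * P[a, b]
        }
        pr_mix <- pr_mix + pr / model$n_categories
      }
      total <- total + pr_mix
    }
    total <- (1 - model$p_inv) * total
    if (model$p_inv > 0) {
      if (length(unique(obs[obs %in% nuc])) <= 1 && any(obs %in% nuc)) {
        total <- total + model$p_inv * pi[match(unique(obs[obs %in% nuc]), nuc)]
      }
    }
    site_ll[s] <- log(total)
  }
  list(loglik = sum(site_ll), site_loglik = site_ll)
}

# monophyly of a tip set in a genealogy (parent-pointer form)
genealogy_monophyletic <- function(g, tips) {
  n_nodes <- length(g$parent)
  desc <- vector("list", n_nodes)
  for (i in seq_len(g$n_tips)) desc[[i]] <- i
  for (i in seq_len(n_nodes)) {
    p <- g$parent[i]
    if (p > 0) desc[[p]] <- c(desc[[p]], desc[[i]])
  }
  any(vapply(desc, function(d) setequal(d, tips), logical(1)))
}
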