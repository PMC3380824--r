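# Fixed-topology likelihood machinery: GTR+I+Gamma substitution model,
# Felsenstein pruning with per-site log-likelihood vectors, coordinate-wise
# branch-length optimisation, and the Shimodaira-Hasegawa topology test with
# RELL resampling of per-site log-likelihoods.

NUC <- c("A", "C", "G", "T")

#' GTR+I+Gamma substitution model
#'
#' General time-reversible rate matrix with optional invariant-site
#' proportion and discrete-gamma rate variation. The rate matrix is scaled
#' to a mean substitution rate of 1 over variable sites, so branch lengths
#' are expected substitutions per variable site.
#'
#' @param rates Six GTR exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT (all positive). `c(1,1,1,1,1,1)` with equal frequencies is
#'   Jukes-Cantor.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param p_inv Proportion of invariant sites, in `[0, 1)`.
#' @param alpha Gamma shape for among-site rate variation (`> 0`); `NULL`
#'   disables rate variation (single rate class).
#' @param n_categories Number of discrete gamma categories (default 4); each
#'   category rate is the mean of its quantile slice.
#' @return An object of class `substitution_model` with a cached eigen
#'   decomposition of the scaled rate matrix.
#' @export
substitution_model <- function(rates = c(1, 1, 1, 1, 1, 1),
                               base_freqs = rep(0.25, 4),
                               p_inv = 0, alpha = NULL, n_categories = 4) {
  if (length(rates) != 6L || any(rates <= 0)) {
    stop("rates must be 6 positive exchangeabilities", call. = FALSE)
  }
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must be 4 positive values summing to 1", call. = FALSE)
  }
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)", call. = FALSE)
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  pi <- base_freqs / sum(base_freqs)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  Q[1, 2] <- Q[2, 1] <- rates[1]  # A-C
  Q[1, 3] <- Q[3, 1] <- rates[2]  # A-G
  Q[1, 4] <- Q[4, 1] <- rates[3]  # A-T
  Q[2, 3] <- Q[3, 2] <- rates[4]  # C-G
  Q[2, 4] <- Q[4, 2] <- rates[5]  # C-T
  Q[3, 4] <- Q[4, 3] <- rates[6]  # G-T
  Q <- Q %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # reversible Q: symmetrise with sqrt(pi) for a stable eigen decomposition
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  gamma_rates <- if (is.null(alpha)) 1 else discrete_gamma_rates(alpha, n_categories)
  structure(list(rates = rates, base_freqs = pi, p_inv = p_inv,
                 alpha = alpha, n_categories = length(gamma_rates),
                 gamma_rates = gamma_rates, Q = Q,
                 eig_values = eig$values,
                 eig_right = diag(1 / sp) %*% eig$vectors,
                 eig_left = t(eig$vectors) %*% diag(sp)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> GTR rates (AC,AG,AT,CG,CT,GT) = ",
      paste(signif(x$rates, 4), collapse = ", "), "\n  freqs = ",
      paste(signif(x$base_freqs, 4), collapse = ", "),
      "; p_inv = ", x$p_inv, "; alpha = ",
      if (is.null(x$alpha)) "none" else signif(x$alpha, 4),
      " (", x$n_categories, " categories)\n", sep = "")
  invisible(x)
}

#' Mean-of-quantile discrete gamma rates
#'
#' Divides a Gamma(shape = alpha, rate = alpha) distribution (mean 1) into
#' `k` equal-probability categories and returns each category's mean rate.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4) {
  if (k == 1L) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                          rate = alpha)
  upper <- stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(k + 1)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

# Transition probability matrix P(t) for the scaled GTR matrix.
.pmatrix <- function(model, t) {
  P <- model$eig_right %*% (exp(model$eig_values * t) * model$eig_left)
  P[P < 0] <- 0
  P
}

# Tip partial-likelihood encoding: A/C/G/T unit rows, gap/N all-ones.
.tip_partials <- function(chars) {
  out <- matrix(0, length(chars), 4)
  for (b in 1:4) out[chars == NUC[b], b] <- 1
  out[chars %in% c("-", "N"), ] <- 1
  out
}

# Compress alignment columns into unique site patterns.
.site_patterns <- function(mat) {
  key <- apply(mat, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  list(mat = mat[, first, drop = FALSE],
       map = match(key, key[first]))
}

# Per-site log-likelihood under the mixture
#   L(site) = p_inv * L_const(site) + (1 - p_inv) * mean_k L_gamma_k(site).
# Pruning is run per gamma category with per-pattern rescaling against
# underflow. The tree may be rooted or unrooted; any internal node serves as
# the likelihood root (reversibility makes the placement irrelevant).
.site_loglik <- function(aln_mat, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  tips <- tree$tip.label
  if (!setequal(tips, rownames(aln_mat))) {
    stop("tree tips and alignment ids differ", call. = FALSE)
  }
  pat <- .site_patterns(aln_mat[tips, , drop = FALSE])
  npat <- ncol(pat$mat)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  pi <- model$base_freqs
  tip_part <- lapply(seq_len(ntip), function(i) .tip_partials(pat$mat[i, ]))

  lik_mix <- matrix(0, npat, 1)
  w <- (1 - model$p_inv) / model$n_categories
  for (r in model$gamma_rates) {
    partial <- vector("list", nnode)
    scaler <- numeric(npat)
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      .pmatrix(model, r * tree$edge.length[e])
    })
    for (i in seq_len(ntip)) partial[[i]] <- tip_part[[i]]
    edges <- tree$edge
    e <- 1L
    while (e <= nrow(edges)) {
      node <- edges[e, 1L]
      prod_part <- matrix(1, npat, 4)
      while (e <= nrow(edges) && edges[e, 1L] == node) {
        child <- edges[e, 2L]
        prod_part <- prod_part * (partial[[child]] %*% t(Ps[[e]]))
        e <- e + 1L
      }
      mx <- pmax(apply(prod_part, 1L, max), .Machine$double.xmin)
      scaler <- scaler + log(mx)
      partial[[node]] <- prod_part / mx
      root <- node
    }
    lik_mix <- lik_mix + w * exp(log(partial[[root]] %*% pi) + scaler)
  }
  if (model$p_inv > 0) {
    # a site can be invariant only if some base is compatible with every tip
    compat <- Reduce(`*`, tip_part)
    lik_mix <- lik_mix + model$p_inv * (compat %*% pi)
  }
  log(as.vector(lik_mix))[pat$map]
}

#' Log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning under GTR+I+Gamma. Site likelihoods mix an invariant
#' class (weight `p_inv`, only sites compatible with a constant column
#' contribute) with the discrete-gamma average over variable-rate classes.
#'
#' @param aln A `haplotype_alignment` whose ids match the tree's tips.
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param model A [substitution_model()].
#' @return List with `loglik` (total) and `site_loglik` (per-site vector
#'   summing exactly to the total). Sites impossible under the model yield
#'   `-Inf` and are flagged via the `impossible_sites` attribute.
#' @export
tree_loglikelihood <- function(aln, tree, model = substitution_model()) {
  stopifnot(inherits(aln, "haplotype_alignment"),
            inherits(model, "substitution_model"))
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  site <- .site_loglik(aln$mat, tree, model)
  out <- list(loglik = sum(site), site_loglik = site)
  if (any(!is.finite(site))) {
    attr(out, "impossible_sites") <- which(!is.finite(site))
    warning("some sites have zero probability under this tree/model",
            call. = FALSE)
  }
  out
}

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate-wise optimisation with the standard two-pass conditional
#' likelihood scheme: downward (pruning) partials and upward partials are
#' maintained so each branch's likelihood profile costs a single 4x4
#' contraction per evaluation, and each branch is maximised in turn with
#' Brent's method. Cycling continues until a full sweep improves the total
#' log-likelihood by less than `tol`; the log-likelihood is non-decreasing
#' across sweeps.
#'
#' @inheritParams tree_loglikelihood
#' @param max_cycles Maximum optimisation sweeps (warns if reached without
#'   convergence).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_length Upper bound for any single branch length.
#' @return The tree with optimised `edge.length` and attributes `loglik` and
#'   `converged`.
#' @export
optimize_branch_lengths <- function(aln, tree, model = substitution_model(),
                                    max_cycles = 200, tol = 1e-6,
                                    max_length = 10) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  tree <- ape::reorder.phylo(tree, "postorder")
  tips <- tree$tip.label
  if (!setequal(tips, aln$ids)) {
    stop("tree tips and alignment ids differ", call. = FALSE)
  }
  pat <- .site_patterns(aln$mat[tips, , drop = FALSE])
  wts <- tabulate(pat$map, ncol(pat$mat))
  npat <- ncol(pat$mat)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  edges <- tree$edge
  nedge <- nrow(edges)
  pi <- model$base_freqs
  K <- model$n_categories
  tip_part <- lapply(seq_len(ntip), function(i) .tip_partials(pat$mat[i, ]))
  # invariant-class term is branch-length free
  inv_term <- if (model$p_inv > 0) {
    model$p_inv * as.vector(Reduce(`*`, tip_part) %*% pi)
  } else {
    numeric(npat)
  }
  w_var <- (1 - model$p_inv) / K
  root <- edges[nedge, 1L]
  children <- split(seq_len(nedge), edges[, 1L])  # edges below each node

  total_loglik <- function(site_var) {
    # site_var: npat vector of summed variable-class likelihoods (x w_var)
    sum(wts * log(inv_term + site_var))
  }

  refresh <- function(len) {
    P <- lapply(seq_len(K), function(k) {
      lapply(seq_len(nedge), function(e) .pmatrix(model,
                                                  model$gamma_rates[k] * len[e]))
    })
    D <- lapply(seq_len(K), function(k) {
      d <- vector("list", nnode)
      for (i in seq_len(ntip)) d[[i]] <- tip_part[[i]]
      e <- 1L
      while (e <= nedge) {
        node <- edges[e, 1L]
        prod_part <- matrix(1, npat, 4)
        while (e <= nedge && edges[e, 1L] == node) {
          child <- edges[e, 2L]
          prod_part <- prod_part * (d[[child]] %*% t(P[[k]][[e]]))
          e <- e + 1L
        }
        d[[node]] <- prod_part
      }
      d
    })
    # upward partials: U_top[[k]][[e]] is the likelihood of everything
    # above branch e, indexed by the state at the top of the branch
    U_top <- lapply(seq_len(K), function(k) vector("list", nedge))
    U_node <- lapply(seq_len(K), function(k) {
      u <- vector("list", nnode)
      u[[root]] <- matrix(pi, npat, 4, byrow = TRUE)
      u
    })
    for (e in rev(seq_len(nedge))) {  # preorder
      parent <- edges[e, 1L]
      child <- edges[e, 2L]
      sibs <- setdiff(children[[as.character(parent)]], e)
      for (k in seq_len(K)) {
        u <- U_node[[k]][[parent]]
        for (s in sibs) {
          u <- u * (D[[k]][[edges[s, 2L]]] %*% t(P[[k]][[s]]))
        }
        U_top[[k]][[e]] <- u
        if (child > ntip) {
          U_node[[k]][[child]] <- u %*% P[[k]][[e]]
        }
      }
    }
    list(D = D, U_top = U_top)
  }

  len <- tree$edge.length
  cur <- sum(.site_loglik(aln$mat, tree, model))
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    before <- cur
    state <- refresh(len)
    for (e in seq_len(nedge)) {
      child <- edges[e, 2L]
      Dc <- lapply(seq_len(K), function(k) state$D[[k]][[child]])
      Ue <- lapply(seq_len(K), function(k) state$U_top[[k]][[e]])
      f <- function(t_len) {
        site_var <- numeric(npat)
        for (k in seq_len(K)) {
          P <- .pmatrix(model, model$gamma_rates[k] * t_len)
          site_var <- site_var +
            w_var * rowSums((Ue[[k]] %*% P) * Dc[[k]])
        }
        total_loglik(site_var)
      }
      opt <- stats::optimize(f, interval = c(0, max_length), maximum = TRUE,
                             tol = 1e-9)
      if (opt$objective > f(len[e])) len[e] <- opt$maximum
      # refresh partials so later branches see this update
      state <- refresh(len)
      cur <- max(cur, opt$objective)
    }
    tree$edge.length <- len
    cur <- sum(.site_loglik(aln$mat, tree, model))
    if (cur - before < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("branch-length optimisation did not converge after ",
            max_cycles, " cycles; returning best tree so far", call. = FALSE)
  }
  tree$edge.length <- len
  attr(tree, "loglik") <- cur
  attr(tree, "converged") <- converged
  tree
}

#' Shimodaira-Hasegawa topology test
#'
#' Scores each candidate topology (branch lengths optimised unless supplied
#' trees should be used as-is), then assesses whether the best topology is
#' significantly better than each alternative by RELL resampling: per-site
#' log-likelihood vectors are resampled with replacement, each topology's
#' resampled totals are centred by that topology's own resample mean, and
#' `p_i = (1 + #\{max_j centred_j - centred_i >= delta_i\}) / (B + 1)` with
#' `delta_i = lnL_best - lnL_i`. The best topology always has `delta = 0`
#' and `p = 1`.
#'
#' @inheritParams tree_loglikelihood
#' @param topologies List of candidate `ape::phylo` trees (>= 2), including
#'   the presumed best tree.
#' @param n_resamples RELL bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @param optimize Re-optimise branch lengths on each topology first
#'   (default `TRUE`).
#' @param opt_control Named list of arguments passed on to
#'   [optimize_branch_lengths()] (e.g. a looser `tol` for large screens).
#' @return An object of class `sh_test_result`: per-topology `loglik`,
#'   `delta`, `p`, the per-site log-likelihood matrix, and `n_resamples`.
#' @export
sh_test <- function(aln, topologies, model = substitution_model(),
                    n_resamples = 1000, seed = NULL, optimize = TRUE,
                    opt_control = list()) {
  if (length(topologies) < 2L) {
    stop("need at least 2 candidate topologies", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  site_mat <- sapply(topologies, function(tr) {
    if (optimize) {
      tr <- do.call(optimize_branch_lengths,
                    c(list(aln, tr, model), opt_control))
    }
    tree_loglikelihood(aln, tr, model)$site_loglik
  })
  totals <- colSums(site_mat)
  best <- which.max(totals)
  delta <- totals[best] - totals
  nsite <- nrow(site_mat)
  ntopo <- ncol(site_mat)
  exceed <- integer(ntopo)
  # resampled totals, centred per topology by its own resample mean
  resampled <- matrix(0, n_resamples, ntopo)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(nsite, nsite, replace = TRUE)
    resampled[b, ] <- colSums(site_mat[idx, , drop = FALSE])
  }
  centred <- sweep(resampled, 2L, colMeans(resampled))
  row_max <- apply(centred, 1L, max)
  for (i in seq_len(ntopo)) {
    exceed[i] <- sum(row_max - centred[, i] >= delta[i])
  }
  p <- (1 + exceed) / (n_resamples + 1)
  p[best] <- 1
  labels <- names(topologies)
  if (is.null(labels)) labels <- paste0("topology_", seq_len(ntopo))
  structure(list(labels = labels, loglik = totals, delta = delta, p = p,
                 best = best, site_loglik = site_mat,
                 n_resamples = n_resamples),
            class = "sh_test_result")
}

#' @export
print.sh_test_result <- function(x, ...) {
  cat("<sh_test_result> ", length(x$loglik), " topologies, ",
      x$n_resamples, " RELL resamples\n", sep = "")
  df <- data.frame(topology = x$labels, lnL = round(x$loglik, 3),
                   delta = round(x$delta, 3), p = signif(x$p, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Simulate sequences on a tree under a substitution model
#'
#' Forward simulation used for fixtures and calibration: the root state is
#' drawn from the equilibrium frequencies, each site draws a rate class
#' (invariant with probability `p_inv`, otherwise a gamma category), and
#' states evolve down each branch with the model's transition matrices.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param n_sites Number of sites to simulate.
#' @param model A [substitution_model()].
#' @param seed Optional seed.
#' @param locus_name Locus label.
#' @return A `haplotype_alignment` over the tree's tips.
#' @export
simulate_gtr_alignment <- function(tree, n_sites,
                                   model = substitution_model(),
                                   seed = NULL, locus_name = "simulated") {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1L]
  pi <- model$base_freqs
  rate_class <- ifelse(stats::runif(n_sites) < model$p_inv, 0L,
                       sample.int(model$n_categories, n_sites, replace = TRUE))
  states <- matrix(0L, nnode, n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    states[child, ] <- states[parent, ]
    for (k in seq_len(model$n_categories)) {
      sel <- which(rate_class == k)
      if (length(sel) == 0L) next
      P <- .pmatrix(model, model$gamma_rates[k] * tree$edge.length[e])
      ps <- states[parent, sel]
      for (b in 1:4) {
        at <- sel[ps == b]
        if (length(at) > 0L) {
          states[child, at] <- sample.int(4L, length(at), replace = TRUE,
                                          prob = P[b, ])
        }
      }
    }
  }
  mat <- matrix(NUC[states[seq_len(ntip), ]], nrow = ntip)
  haplotype_alignment(mat, ids = tree$tip.label, locus_name = locus_name)
}

#' Estimate a GTR+I+Gamma model on a fixed tree
#'
#' Base frequencies are taken empirically from the alignment; the six
#' exchangeabilities (GT fixed at 1), gamma shape and invariant proportion
#' are fitted by maximising the pruning likelihood on the supplied tree
#' (Nelder-Mead on transformed parameters).
#'
#' @inheritParams tree_loglikelihood
#' @param fit_gamma,fit_pinv Estimate `alpha` / `p_inv` (otherwise fixed at
#'   their starting values).
#' @param n_categories Gamma categories for the fitted model.
#' @return A fitted [substitution_model()] with attribute `loglik`.
#' @export
estimate_substitution_model <- function(aln, tree, fit_gamma = TRUE,
                                        fit_pinv = TRUE, n_categories = 4) {
  base_counts <- table(factor(aln$mat[aln$mat %in% NUC], levels = NUC))
  freqs <- as.numeric(base_counts) / sum(base_counts)
  freqs[freqs == 0] <- 1e-4
  freqs <- freqs / sum(freqs)
  build <- function(par) {
    rates <- c(exp(par[1:5]), 1)
    alpha <- if (fit_gamma) exp(par[6]) else NULL
    p_inv <- if (fit_pinv) stats::plogis(par[7]) else 0
    substitution_model(rates = rates, base_freqs = freqs, p_inv = p_inv,
                       alpha = alpha, n_categories = n_categories)
  }
  objective <- function(par) {
    m <- tryCatch(build(par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- sum(.site_loglik(aln$mat, tree, m))
    if (!is.finite(ll)) 1e10 else -ll
  }
  start <- c(rep(0, 5), log(1), stats::qlogis(0.1))
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 400))
  model <- build(fit$par)
  attr(model, "loglik") <- -fit$value
  model
}
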