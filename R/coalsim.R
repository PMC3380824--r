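# Two-population isolation-with-migration structured coalescent with
# infinite-sites mutation. All parameters are mutation-scaled per locus
# (theta = 4*N*mu, t = T*mu, m = m/mu), so time inside the simulator is in
# mutation units: a lineage pair in deme i coalesces at rate 2/theta_i, a
# lineage in deme i migrates (backwards) to the other deme at rate m_i, and
# mutations fall at rate 1 per unit branch length. Under this scaling the
# effective number of migrant gene copies per generation is
# 2*N_i*m_i = theta_i * m_i / 2 exactly.

#' Isolation-with-migration model parameters
#'
#' @param theta1,theta2,thetaA Mutation-scaled diversities (`4*N*mu` per
#'   locus) of population 1, population 2 and the ancestral population; all
#'   must be positive.
#' @param t_split Mutation-scaled divergence time (`T*mu` per locus),
#'   non-negative; `Inf` is permitted for equilibrium island-model runs when
#'   both migration rates are positive.
#' @param m1 Mutation-scaled migration rate into population 1 (`m/mu`), i.e.
#'   the donor is population 2.
#' @param m2 Mutation-scaled migration rate into population 2.
#' @param n1,n2 Haplotype sample sizes (at least 1, and `n1 + n2 >= 2`).
#' @param locus_length Number of alignment columns available to the
#'   infinite-sites mutation process.
#' @param rho Mutation-scaled intra-locus recombination rate (`r/mu` per
#'   locus, like `m = m/mu`). The default 0 models a fully non-recombining
#'   locus; note that linkage disequilibrium between variable sites is then
#'   degenerate (a single genealogy under infinite sites permits at most
#'   three gametic types per site pair, so |D'| = 1 everywhere), and the
#'   `x = Dss - Dsx` statistic needs `rho > 0` to be informative.
#' @param n_blocks Discretisation of the recombination process: the locus is
#'   modelled as this many evenly spaced, internally non-recombining
#'   segments; crossovers fall between them. Ignored when `rho = 0`.
#' @param pulse_frac Admixture pulse: fraction of population 2's ancestry
#'   that derives from population 1 at `pulse_time` (a one-time episode of
#'   introgression, in addition to any continuous migration). Default 0.
#' @param pulse_time Age of the admixture pulse (mutation-scaled, must be
#'   younger than `t_split` when `pulse_frac > 0`).
#' @param pulse_founders Number of donor founder haplotypes behind the
#'   pulse. The default 1 models adaptive introgression as a hard selective
#'   sweep of a single introgressed haplotype: all pulsed lineages coalesce
#'   instantaneously at `pulse_time` before joining the donor, so the
#'   introgressed class descends from one founder. Larger values model
#'   neutral mass admixture.
#' @return An object of class `im_parameters`.
#' @export
im_parameters <- function(theta1, theta2, thetaA, t_split, m1 = 0, m2 = 0,
                          n1 = 10, n2 = 10, locus_length = 500,
                          rho = 0, n_blocks = 20, pulse_frac = 0,
                          pulse_time = 0, pulse_founders = 1) {
  if (any(c(theta1, theta2, thetaA) <= 0)) {
    stop("all theta values must be > 0", call. = FALSE)
  }
  if (t_split < 0) stop("t_split must be >= 0", call. = FALSE)
  if (m1 < 0 || m2 < 0) stop("migration rates must be >= 0", call. = FALSE)
  if (is.infinite(t_split) && (m1 == 0 || m2 == 0)) {
    stop("t_split = Inf requires positive migration in both directions",
         call. = FALSE)
  }
  if (n1 < 1 || n2 < 1 || n1 + n2 < 2) {
    stop("need n1, n2 >= 1 and at least 2 sampled haplotypes", call. = FALSE)
  }
  if (rho < 0) stop("rho must be >= 0", call. = FALSE)
  if (rho == 0) n_blocks <- 1
  if (n_blocks < 1 || n_blocks > locus_length) {
    stop("n_blocks must be in [1, locus_length]", call. = FALSE)
  }
  if (pulse_frac < 0 || pulse_frac > 1) {
    stop("pulse_frac must be in [0, 1]", call. = FALSE)
  }
  if (pulse_frac > 0 && !(pulse_time >= 0 && pulse_time < t_split)) {
    stop("pulse_time must lie in [0, t_split)", call. = FALSE)
  }
  if (pulse_founders < 1) stop("pulse_founders must be >= 1", call. = FALSE)
  structure(list(theta1 = theta1, theta2 = theta2, thetaA = thetaA,
                 t_split = t_split, m1 = m1, m2 = m2,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 locus_length = as.integer(locus_length),
                 rho = rho, n_blocks = as.integer(n_blocks),
                 pulse_frac = pulse_frac, pulse_time = pulse_time,
                 pulse_founders = as.integer(pulse_founders)),
            class = "im_parameters")
}

#' @export
print.im_parameters <- function(x, ...) {
  cat(sprintf(paste0("<im_parameters> theta1=%g theta2=%g thetaA=%g ",
                     "t=%g m1=%g m2=%g n=(%d,%d) L=%d rho=%g (%d blocks)\n"),
              x$theta1, x$theta2, x$thetaA, x$t_split, x$m1, x$m2,
              x$n1, x$n2, x$locus_length, x$rho, x$n_blocks))
  invisible(x)
}

#' Simulate a structured coalescent genealogy under the IM model
#'
#' Runs the two-population isolation-with-migration coalescent backwards in
#' time: within deme `i` each lineage pair coalesces at rate `2/theta_i` and
#' each lineage migrates to the other deme at rate `m_i` (mutation-scaled
#' time); at `t_split` all surviving lineages merge into the ancestral deme,
#' where pairs coalesce at rate `2/thetaA`. Tips `1..n1` are population-1
#' samples, `n1+1..n1+n2` population-2 samples.
#'
#' Uses R's global random number stream; seed it with `set.seed()` for
#' reproducibility.
#'
#' @param params An [im_parameters()] object.
#' @return An object of class `genealogy`: parent pointers, node times
#'   (mutation-scaled, tips at 0, strictly increasing toward the root), tip
#'   deme labels and sample sizes.
#' @export
simulate_genealogy <- function(params) {
  stopifnot(inherits(params, "im_parameters"))
  n1 <- params$n1
  n2 <- params$n2
  n <- n1 + n2
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  deme <- c(rep(1L, n1), rep(2L, n2))[active]
  t <- 0
  next_node <- n + 1L
  theta <- c(params$theta1, params$theta2)
  m <- c(params$m1, params$m2)
  pulsed <- params$pulse_frac == 0
  pulse_nodes <- integer(0)
  # pre-split phase: two demes with migration (and optional admixture pulse)
  while (length(active) > 1L && t < params$t_split) {
    k <- tabulate(deme, 2L)
    rate_coal <- k * (k - 1L) / theta
    rate_mig <- k * m
    total <- sum(rate_coal) + sum(rate_mig)
    boundary <- if (!pulsed && t < params$pulse_time) params$pulse_time else params$t_split
    dt <- if (total == 0) Inf else stats::rexp(1L, total)
    if (t + dt >= boundary) {
      t <- boundary
      if (!pulsed && boundary == params$pulse_time) {
        w <- which(deme == 2L)
        ids <- active[w[stats::runif(length(w)) < params$pulse_frac]]
        # sweep ancestry: collapse pulsed lineages into the founder set
        while (length(ids) > params$pulse_founders) {
          pos <- match(ids[1:2], active)
          parent[ids[1:2]] <- next_node
          time[next_node] <- t
          active <- c(active[-pos], next_node)
          deme <- c(deme[-pos], 2L)
          ids <- c(ids[-(1:2)], next_node)
          next_node <- next_node + 1L
        }
        deme[match(ids, active)] <- 1L
        pulse_nodes <- ids
        pulsed <- TRUE
        next
      }
      break
    }
    t <- t + dt
    ev <- sample.int(4L, 1L, prob = c(rate_coal, rate_mig))
    if (ev <= 2L) {
      d <- ev
      pick <- sample(which(deme == d), 2L)
      parent[active[pick]] <- next_node
      time[next_node] <- t
      active <- c(active[-pick], next_node)
      deme <- c(deme[-pick], d)
      next_node <- next_node + 1L
    } else {
      d <- ev - 2L
      w <- which(deme == d)
      pick <- if (length(w) == 1L) w else sample(w, 1L)
      deme[pick] <- 3L - d
    }
  }
  # ancestral phase: single deme
  while (length(active) > 1L) {
    k <- length(active)
    dt <- stats::rexp(1L, k * (k - 1L) / params$thetaA)
    t <- t + dt
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- next_node
    time[next_node] <- t
    active <- c(active[-pick], next_node)
    next_node <- next_node + 1L
  }
  structure(list(parent = parent, time = time, n_tips = n,
                 n1 = n1, n2 = n2,
                 tip_deme = c(rep(1L, n1), rep(2L, n2)),
                 pulse_nodes = pulse_nodes,
                 units = "mutational"),
            class = "genealogy")
}

#' Total branch length of a genealogy
#' @param genealogy A `genealogy` object.
#' @return Sum of all branch lengths, in the genealogy's time units.
#' @export
total_branch_length <- function(genealogy) {
  non_root <- which(genealogy$parent > 0L)
  sum(genealogy$time[genealogy$parent[non_root]] - genealogy$time[non_root])
}

# For each non-root node, the set of tips below it (list indexed by node).
.descendant_tips <- function(genealogy) {
  n_nodes <- length(genealogy$parent)
  n <- genealogy$n_tips
  tips <- vector("list", n_nodes)
  for (i in seq_len(n)) tips[[i]] <- i
  # internal nodes were created in increasing time order, so ascending index
  # order is a valid bottom-up traversal
  for (i in seq_len(n_nodes)) {
    p <- genealogy$parent[i]
    if (p > 0L) tips[[p]] <- c(tips[[p]], tips[[i]])
  }
  tips
}

# Sample infinite-sites mutations: returns a tips x n_mut 0/1 matrix (NULL if
# no mutations). Each mutation is assigned to a branch with probability
# proportional to its length; carriers are the tips below that branch.
# `rate` is the mutation rate per unit branch length (a block spanning a
# fraction of the locus uses that fraction).
.mutation_matrix <- function(genealogy, rate = 1) {
  non_root <- which(genealogy$parent > 0L)
  blen <- genealogy$time[genealogy$parent[non_root]] - genealogy$time[non_root]
  L <- sum(blen)
  n_mut <- stats::rpois(1L, rate * L)
  if (n_mut == 0L) return(NULL)
  branch <- sample(non_root, n_mut, replace = TRUE, prob = blen)
  desc <- .descendant_tips(genealogy)
  X <- matrix(0L, nrow = genealogy$n_tips, ncol = n_mut)
  for (k in seq_len(n_mut)) {
    X[desc[[branch[k]]], k] <- 1L
  }
  X
}

# Structured coalescent with intra-locus recombination (discretised
# ancestral recombination graph). Each ancestral lineage carries a
# n_blocks x n logical matrix: row b is the set of sampled tips inheriting
# block b through this lineage. Backwards in time, lineages coalesce within
# demes (rate 2/theta_i per pair), migrate whole (rate m_i per lineage, so a
# recent migrant moves its entire locus), and recombine at rate rho * span,
# splitting the carried blocks at a uniform crossover point. Mutations
# accumulate on each lineage segment at rate 1/n_blocks per carried block
# per unit (mutation-scaled) time. Blocks whose tip set reaches the full
# sample have found their MRCA and stop mutating. Returns list(X, block)
# with X an n x S 0/1 matrix of segregating sites and block the generating
# block index per column, or NULL when no mutations fell. This R
# implementation is the reference; .sim_arg dispatches to the compiled
# engine for sample sizes it supports.
.sim_arg_r <- function(params) {
  n1 <- params$n1
  n2 <- params$n2
  n <- n1 + n2
  B <- params$n_blocks
  rho <- params$rho
  theta <- c(params$theta1, params$theta2)
  mrate <- c(params$m1, params$m2)
  pos <- (seq_len(B) - 0.5) / B  # block midpoints on [0,1]

  mats <- vector("list", n)
  for (i in seq_len(n)) {
    M <- matrix(FALSE, B, n)
    M[, i] <- TRUE
    mats[[i]] <- M
  }
  deme <- c(rep(1L, n1), rep(2L, n2))
  birth <- numeric(n)
  span <- rep(if (B > 1L) pos[B] - pos[1L] else 0, n)

  mut_tips <- vector("list", 256L)
  mut_block <- integer(256L)
  n_mut <- 0L
  add_segment_mutations <- function(M, dur) {
    if (dur <= 0) return(invisible(NULL))
    load <- rowSums(M)
    carried <- which(load > 0L)
    if (length(carried) == 0L) return(invisible(NULL))
    nm <- stats::rpois(length(carried), dur / B)
    hit <- which(nm > 0L)
    for (h in hit) {
      b <- carried[h]
      for (rep_i in seq_len(nm[h])) {
        n_mut <<- n_mut + 1L
        if (n_mut > length(mut_tips)) {
          length(mut_tips) <<- 2L * length(mut_tips)
          length(mut_block) <<- 2L * length(mut_block)
        }
        mut_tips[[n_mut]] <<- M[b, ]
        mut_block[n_mut] <<- b
      }
    }
    invisible(NULL)
  }
  lineage_span <- function(M) {
    carried <- which(rowSums(M) > 0L)
    if (length(carried) < 2L) 0 else pos[carried[length(carried)]] - pos[carried[1L]]
  }

  t <- 0
  merged <- FALSE
  pulsed <- params$pulse_frac == 0
  pulse_tips <- integer(n)
  while (length(mats) > 1L) {
    if (!merged) {
      k <- tabulate(deme, 2L)
      rate_coal <- k * (k - 1L) / theta
      rate_mig <- k * mrate
      rate_rec <- rho * sum(span)
      total <- sum(rate_coal) + sum(rate_mig) + rate_rec
      boundary <- if (!pulsed && t < params$pulse_time) params$pulse_time else params$t_split
      dt <- if (total == 0) Inf else stats::rexp(1L, total)
      if (t + dt >= boundary) {
        t <- boundary
        if (!pulsed && boundary == params$pulse_time) {
          ptag <- deme == 2L & stats::runif(length(deme)) < params$pulse_frac
          # sweep ancestry: collapse pulsed lineages into the founder set
          while (sum(ptag) > params$pulse_founders) {
            pick <- which(ptag)[1:2]
            add_segment_mutations(mats[[pick[1L]]], t - birth[pick[1L]])
            add_segment_mutations(mats[[pick[2L]]], t - birth[pick[2L]])
            M <- mats[[pick[1L]]] | mats[[pick[2L]]]
            complete <- rowSums(M) == n
            if (any(complete)) M[complete, ] <- FALSE
            keep <- setdiff(seq_along(mats), pick)
            mats <- mats[keep]; deme <- deme[keep]; birth <- birth[keep]
            span <- span[keep]; ptag <- ptag[keep]
            if (any(rowSums(M) > 0L)) {
              mats[[length(mats) + 1L]] <- M
              deme <- c(deme, 2L)
              birth <- c(birth, t)
              span <- c(span, lineage_span(M))
              ptag <- c(ptag, TRUE)
            }
          }
          deme[ptag] <- 1L
          for (i in which(ptag)) {
            pulse_tips <- pulse_tips + colSums(mats[[i]])
          }
          pulsed <- TRUE
        } else {
          merged <- TRUE
        }
        next
      }
      t <- t + dt
      ev <- sample.int(5L, 1L, prob = c(rate_coal, rate_mig, rate_rec))
    } else {
      k <- length(mats)
      rate_coal_a <- k * (k - 1L) / params$thetaA
      rate_rec <- rho * sum(span)
      dt <- stats::rexp(1L, rate_coal_a + rate_rec)
      t <- t + dt
      ev <- if (stats::runif(1L) < rate_coal_a / (rate_coal_a + rate_rec)) 6L else 5L
    }
    if (ev <= 2L || ev == 6L) {
      # coalescence (in deme ev, or ancestral deme)
      cand <- if (ev == 6L) seq_along(mats) else which(deme == ev)
      pick <- sample(cand, 2L)
      a <- pick[1L]; b <- pick[2L]
      add_segment_mutations(mats[[a]], t - birth[a])
      add_segment_mutations(mats[[b]], t - birth[b])
      M <- mats[[a]] | mats[[b]]
      complete <- rowSums(M) == n
      if (any(complete)) M[complete, ] <- FALSE
      keep <- setdiff(seq_along(mats), pick)
      mats <- mats[keep]; deme <- deme[keep]
      birth <- birth[keep]; span <- span[keep]
      if (any(rowSums(M) > 0L)) {
        mats[[length(mats) + 1L]] <- M
        deme <- c(deme, if (ev == 6L) 0L else ev)
        birth <- c(birth, t)
        span <- c(span, lineage_span(M))
      }
    } else if (ev %in% c(3L, 4L)) {
      # migration: whole lineage changes deme
      d <- ev - 2L
      w <- which(deme == d)
      a <- if (length(w) == 1L) w else sample(w, 1L)
      deme[a] <- 3L - d
    } else {
      # recombination: split a lineage at a crossover inside its span
      a <- sample.int(length(mats), 1L, prob = span)
      add_segment_mutations(mats[[a]], t - birth[a])
      M <- mats[[a]]
      carried <- which(rowSums(M) > 0L)
      u <- stats::runif(1L, pos[carried[1L]], pos[carried[length(carried)]])
      left <- M; left[pos > u, ] <- FALSE
      right <- M; right[pos <= u, ] <- FALSE
      mats[[a]] <- left
      birth[a] <- t
      span[a] <- lineage_span(left)
      mats[[length(mats) + 1L]] <- right
      deme <- c(deme, deme[a])
      birth <- c(birth, t)
      span <- c(span, lineage_span(right))
    }
  }
  if (n_mut == 0L) {
    return(list(X = NULL, block = NULL, pulse_tips = pulse_tips))
  }
  X <- matrix(0L, nrow = n, ncol = n_mut)
  for (j in seq_len(n_mut)) X[mut_tips[[j]], j] <- 1L
  list(X = X, block = mut_block[seq_len(n_mut)], pulse_tips = pulse_tips)
}

# Dispatch to the compiled engine when the bit-mask fast path applies.
# Returns list(X (NULL if no mutations), block, pulse_tips).
.sim_arg <- function(params) {
  if (params$n1 + params$n2 <= 64L) {
    .sim_arg_cpp(params$n1, params$n2, params$theta1, params$theta2,
                 params$thetaA, params$t_split, params$m1, params$m2,
                 params$rho, params$n_blocks,
                 params$pulse_frac, params$pulse_time,
                 params$pulse_founders)
  } else {
    .sim_arg_r(params)
  }
}

# Fast path for null simulations: 0/1 matrix of segregating sites only (no
# column placement, no nucleotide rendering). NULL when no mutations.
.sim_binary_matrix <- function(params) {
  sim <- .sim_arg(params)
  if (is.null(sim$X)) return(NULL)
  X <- sim$X
  if (ncol(X) > params$locus_length) {
    X <- X[, seq_len(params$locus_length), drop = FALSE]
  }
  X
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' The mutation count is Poisson with mean equal to the total branch length
#' in mutation-scaled units (equivalently `theta/2` times the length in
#' coalescent units of `2N` generations); each mutation strikes a distinct
#' alignment column, so every simulated variable site is biallelic. Binary
#' states are rendered as `A` (ancestral) and `T` (derived).
#'
#' @param genealogy A `genealogy` from [simulate_genealogy()] (mutation-scaled
#'   branch lengths), or any genealogy with `units = "coalescent"` plus a
#'   `theta` giving the scaling.
#' @param locus_length Number of columns in the emitted alignment; must be
#'   able to hold all mutations (infinite-sites collision guard).
#' @param theta Required only for coalescent-unit genealogies.
#' @param ids Haplotype identifiers; defaults to `hap_1..hap_n` with
#'   population prefixes.
#' @param locus_name Locus label for the alignment.
#' @return A [haplotype_alignment()] of width `locus_length`.
#' @export
drop_mutations_infinite_sites <- function(genealogy, locus_length,
                                          theta = NULL, ids = NULL,
                                          locus_name = "simulated") {
  stopifnot(inherits(genealogy, "genealogy"))
  g <- genealogy
  if (identical(g$units, "coalescent")) {
    if (is.null(theta)) {
      stop("theta is required for coalescent-unit genealogies", call. = FALSE)
    }
    g$time <- g$time * theta / 2
    g$units <- "mutational"
  }
  X <- .mutation_matrix(g)
  n_mut <- if (is.null(X)) 0L else ncol(X)
  if (n_mut > locus_length) {
    stop("simulated ", n_mut, " mutations but locus_length is only ",
         locus_length, "; increase locus_length", call. = FALSE)
  }
  n <- g$n_tips
  mat <- matrix("A", nrow = n, ncol = locus_length)
  if (n_mut > 0L) {
    cols <- sort(sample.int(locus_length, n_mut))
    mat[, cols][X == 1L] <- "T"
  }
  if (is.null(ids)) {
    ids <- c(sprintf("pop1_h%02d", seq_len(g$n1)),
             sprintf("pop2_h%02d", seq_len(g$n2)))
  }
  haplotype_alignment(mat, ids = ids, locus_name = locus_name)
}

#' Simulate one locus under the IM model
#'
#' With `rho = 0`, a single genealogy receives infinite-sites mutations.
#' With `rho > 0`, the locus follows the discretised recombining coalescent:
#' `n_blocks` internally non-recombining segments linked by crossovers at
#' total rate `rho`, each mutation placed in an alignment column inside its
#' generating segment's range.
#'
#' @param params An [im_parameters()] object.
#' @param ids Haplotype identifiers (defaults to population-prefixed ids).
#' @param locus_name Locus label.
#' @return A `haplotype_alignment` of width `params$locus_length`, with a
#'   `"pulse_fraction"` attribute giving, per haplotype, the fraction of the
#'   locus inherited through the admixture pulse (all zero without a
#'   pulse) -- the generator's own ancestry truth, used for phenotype
#'   labelling and recovery tests.
#' @export
simulate_locus <- function(params, ids = NULL, locus_name = "simulated") {
  stopifnot(inherits(params, "im_parameters"))
  if (is.null(ids)) {
    ids <- c(sprintf("pop1_h%02d", seq_len(params$n1)),
             sprintf("pop2_h%02d", seq_len(params$n2)))
  }
  if (params$rho == 0) {
    g <- simulate_genealogy(params)
    aln <- drop_mutations_infinite_sites(g, params$locus_length, ids = ids,
                                         locus_name = locus_name)
    pf <- numeric(g$n_tips)
    if (length(g$pulse_nodes) > 0L) {
      desc <- .descendant_tips(g)
      pf[unique(unlist(desc[g$pulse_nodes]))] <- 1
    }
    attr(aln, "pulse_fraction") <- stats::setNames(pf, ids)
    return(aln)
  }
  B <- params$n_blocks
  L <- params$locus_length
  bounds <- floor(seq(0L, L, length.out = B + 1L))
  n <- params$n1 + params$n2
  mat <- matrix("A", nrow = n, ncol = L)
  sim <- .sim_arg(params)
  if (!is.null(sim$X)) {
    for (b in unique(sim$block)) {
      in_b <- which(sim$block == b)
      width <- bounds[b + 1L] - bounds[b]
      if (length(in_b) > width) {
        stop("simulated ", length(in_b), " mutations in a ", width,
             "-column segment; increase locus_length", call. = FALSE)
      }
      cols <- bounds[b] + sort(sample.int(width, length(in_b)))
      mat[, cols][sim$X[, in_b, drop = FALSE] == 1L] <- "T"
    }
  }
  aln <- haplotype_alignment(mat, ids = ids, locus_name = locus_name)
  attr(aln, "pulse_fraction") <- stats::setNames(sim$pulse_tips / B, ids)
  aln
}

#' Convert IM migration rates to effective migrants per generation
#'
#' Under the IM scaling (`theta = 4*N*mu`, `m = m/mu`) the effective number
#' of gene copies a population receives per generation is
#' `2*N_i*m_i = theta_i * m_i / 2`.
#'
#' @param params An [im_parameters()] object.
#' @return Named numeric vector `c(pop1 = 2*N1*m1, pop2 = 2*N2*m2)`.
#' @export
convert_to_2Nm <- function(params) {
  stopifnot(inherits(params, "im_parameters"))
  c(pop1 = params$theta1 * params$m1 / 2,
    pop2 = params$theta2 * params$m2 / 2)
}

#' Invert the 2Nm conversion
#'
#' @param two_Nm Effective migrants per generation (`2*N*m`).
#' @param theta The receiving population's mutation-scaled diversity.
#' @return The mutation-scaled migration rate `m`.
#' @export
m_from_2Nm <- function(two_Nm, theta) 2 * two_Nm / theta

#' Butterfly life-history rate constants
#'
#' Unit-conversion constants for this study system: 10 generations per year
#' (generation time 35 days) and per-locus mutation rates per year used to
#' put mutation-scaled parameter estimates on a calendar scale.
#'
#' @return A list with `generations_per_year`, `generation_time_days`, and
#'   `mu_per_locus_per_year` (named vector).
#' @export
rate_constants <- function() {
  list(generations_per_year = 10,
       generation_time_days = 35,
       mu_per_locus_per_year = c(COI = 6.2e-6, GAPDH = 7.1e-8,
                                 Hsp90 = 1.2e-6, HmB453k = 3.4e-5))
}

#' Mutation rate from calibrated divergence
#'
#' Given the per-site (or per-locus) divergence `d_xy` between two clades and
#' a calibration age `T_cal` for their split, the rate per year is
#' `mu = d_xy / (2 * T_cal)` and the per-generation rate divides by the
#' number of generations per year.
#'
#' @param d_xy Divergence between the calibrated clades (> 0).
#' @param T_cal Calibration time in years (> 0).
#' @param generations_per_year Generations per year (default from
#'   [rate_constants()]).
#' @return List with `per_year` and `per_generation` rates.
#' @export
mu_from_divergence <- function(d_xy, T_cal,
                               generations_per_year =
                                 rate_constants()$generations_per_year) {
  if (d_xy <= 0 || T_cal <= 0 || generations_per_year <= 0) {
    stop("d_xy, T_cal and generations_per_year must all be > 0",
         call. = FALSE)
  }
  per_year <- d_xy / (2 * T_cal)
  list(per_year = per_year, per_generation = per_year / generations_per_year)
}

#' Hudson-style Fst from a haplotype alignment
#'
#' `Fst = 1 - pi_within / pi_between`, where `pi_within` is the mean of the
#' two populations' mean pairwise difference counts and `pi_between` the mean
#' pairwise difference count across populations.
#'
#' @param aln A `haplotype_alignment`.
#' @param pop1,pop2 Haplotype id sets with at least 2 members each.
#' @return The Fst estimate, or `NA` when `pi_between` is 0.
#' @export
fst_summary <- function(aln, pop1, pop2) {
  pops <- .check_pops(aln, pop1, pop2)
  if (length(pops$pop1) < 2L || length(pops$pop2) < 2L) {
    stop("both populations need at least 2 haplotypes", call. = FALSE)
  }
  d <- pairwise_difference_matrix(aln)
  i1 <- match(pops$pop1, aln$ids)
  i2 <- match(pops$pop2, aln$ids)
  within_mean <- function(idx) {
    sub <- d[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  pi_w <- (within_mean(i1) + within_mean(i2)) / 2
  pi_b <- mean(d[i1, i2])
  if (pi_b == 0) return(NA_real_)
  1 - pi_w / pi_b
}
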