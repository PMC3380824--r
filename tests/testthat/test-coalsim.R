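test_that("IM parameters validate their domain", {
  expect_s3_class(im_parameters(1, 1, 1, 0.5), "im_parameters")
  expect_error(im_parameters(0, 1, 1, 1), "theta")
  expect_error(im_parameters(1, 1, 1, -1), "t_split")
  expect_error(im_parameters(1, 1, 1, 1, m1 = -0.1), "migration")
  expect_error(im_parameters(1, 1, 1, Inf, m1 = 1, m2 = 0), "Inf")
  expect_error(im_parameters(1, 1, 1, 1, n1 = 0), "n1")
  expect_error(im_parameters(1, 1, 1, 1, pulse_frac = 0.5, pulse_time = 2),
               "pulse_time")
  expect_error(im_parameters(1, 1, 1, 1, rho = -1), "rho")
})

test_that("genealogy node times increase toward the root", {
  set.seed(3)
  p <- im_parameters(theta1 = 2, theta2 = 1, thetaA = 1.5, t_split = 2,
                     m1 = 0.5, m2 = 0.5, n1 = 8, n2 = 8)
  for (r in 1:20) {
    g <- simulate_genealogy(p)
    non_root <- which(g$parent > 0)
    expect_true(all(g$time[g$parent[non_root]] >= g$time[non_root]))
    expect_equal(g$time[seq_len(g$n_tips)], rep(0, g$n_tips))
  }
})

test_that("mean pairwise differences equal theta for a panmictic pair", {
  set.seed(4)
  p <- im_parameters(theta1 = 2, theta2 = 2, thetaA = 2, t_split = 0,
                     n1 = 2, n2 = 1, locus_length = 1000)
  d <- replicate(4000, {
    aln <- simulate_locus(p)
    sum(aln$mat[1, ] != aln$mat[2, ])
  })
  # E[diff] = theta1 = 2; 3 standard errors
  expect_lt(abs(mean(d) - 2), 3 * sd(d) / sqrt(length(d)))
})

test_that("segregating sites follow the Watterson expectation", {
  set.seed(5)
  p <- im_parameters(theta1 = 5, theta2 = 5, thetaA = 5, t_split = 0,
                     n1 = 9, n2 = 1, locus_length = 2000)
  S <- replicate(3000, {
    g <- simulate_genealogy(p)
    X <- introgrescan:::.mutation_matrix(g)
    if (is.null(X)) 0 else ncol(X)
  })
  expected <- 5 * sum(1 / (1:9))
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
})

test_that("the site-frequency spectrum is neutral for one population", {
  set.seed(6)
  n <- 6
  p <- im_parameters(theta1 = 4, theta2 = 4, thetaA = 4, t_split = 0,
                     n1 = n, n2 = 1, locus_length = 2000)
  counts <- integer(n - 1)
  reps <- 3000
  for (r in 1:reps) {
    g <- simulate_genealogy(p)
    X <- introgrescan:::.mutation_matrix(g)
    if (is.null(X)) next
    X <- X[seq_len(n), , drop = FALSE]
    freq <- colSums(X)
    freq <- freq[freq > 0 & freq < n]
    counts <- counts + tabulate(freq, n - 1)
  }
  observed <- counts / reps
  expected <- 4 / (1:(n - 1))
  # each class within 4 combined standard errors (counts ~ Poisson-ish)
  se <- sqrt(counts) / reps
  expect_true(all(abs(observed - expected) < 4 * pmax(se, 0.02)))
})

test_that("zero theta-scaled length gives zero segregating sites", {
  set.seed(7)
  p <- im_parameters(theta1 = 1e-9, theta2 = 1e-9, thetaA = 1e-9,
                     t_split = 0, n1 = 5, n2 = 1, locus_length = 100)
  aln <- simulate_locus(p)
  expect_equal(sum(apply(aln$mat, 2, function(col) length(unique(col)) > 1)),
               0)
})

test_that("every simulated variable site is biallelic (infinite sites)", {
  set.seed(8)
  p <- im_parameters(theta1 = 6, theta2 = 3, thetaA = 4, t_split = 2,
                     m1 = 0.2, m2 = 0.5, n1 = 10, n2 = 10,
                     locus_length = 400, rho = 3, n_blocks = 10)
  for (r in 1:10) {
    aln <- simulate_locus(p)
    n_alleles <- apply(aln$mat, 2, function(col) length(unique(col)))
    expect_true(all(n_alleles <= 2))
  }
})

test_that("the collision guard rejects loci too short for their mutations", {
  set.seed(9)
  p <- im_parameters(theta1 = 50, theta2 = 50, thetaA = 50, t_split = 0,
                     n1 = 10, n2 = 1, locus_length = 3)
  expect_error({
    for (r in 1:50) {
      g <- simulate_genealogy(p)
      drop_mutations_infinite_sites(g, 3)
    }
  }, "locus_length")
})

test_that("a zero split time is indistinguishable from panmixia", {
  set.seed(10)
  p_split0 <- im_parameters(theta1 = 4, theta2 = 4, thetaA = 4, t_split = 0,
                            n1 = 5, n2 = 5)
  p_panmix <- im_parameters(theta1 = 4, theta2 = 4, thetaA = 4, t_split = 0,
                            n1 = 9, n2 = 1)
  tmrca <- function(p) replicate(1500, max(simulate_genealogy(p)$time))
  a <- tmrca(p_split0)
  b <- tmrca(p_panmix)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("deep isolation yields reciprocal monophyly", {
  set.seed(11)
  p <- im_parameters(theta1 = 1, theta2 = 1, thetaA = 1, t_split = 50,
                     m1 = 0, m2 = 0, n1 = 6, n2 = 6)
  mono <- replicate(100, {
    g <- simulate_genealogy(p)
    genealogy_monophyletic(g, 1:6) && genealogy_monophyletic(g, 7:12)
  })
  expect_gte(mean(mono), 0.99)
})

test_that("the compiled and reference recombination engines agree", {
  p <- im_parameters(theta1 = 4, theta2 = 2, thetaA = 3, t_split = 2,
                     m1 = 0.1, m2 = 0.5, n1 = 8, n2 = 8,
                     locus_length = 500, rho = 3, n_blocks = 10,
                     pulse_frac = 0.4, pulse_time = 0.1)
  stat <- function(engine, reps) {
    sapply(seq_len(reps), function(i) {
      s <- engine(p)
      c(S = if (is.null(s$X)) 0 else ncol(s$X),
        pulse = sum(s$pulse_tips))
    })
  }
  set.seed(12)
  cpp <- stat(introgrescan:::.sim_arg, 600)
  set.seed(12)
  ref <- stat(introgrescan:::.sim_arg_r, 200)
  # same model, independent implementations: means agree within MC error
  se <- sqrt(var(cpp["S", ]) / 600 + var(ref["S", ]) / 200)
  expect_lt(abs(mean(cpp["S", ]) - mean(ref["S", ])), 4 * se)
  se_p <- sqrt(var(cpp["pulse", ]) / 600 + var(ref["pulse", ]) / 200)
  expect_lt(abs(mean(cpp["pulse", ]) - mean(ref["pulse", ])), 4 * se_p)
})

test_that("summary statistics match an independent coalescent simulator", {
  # msprime as external oracle: mean segregating sites for a panmictic
  # sample and for a two-population isolation model (mutation-scaled
  # mapping: population size theta/2, mutation rate 1 per locus per
  # generation, split time t generations)
  script <- '
import msprime, json, sys
out = {}
S = []
for seed in range(1, 1201):
    ts = msprime.sim_ancestry(samples=5, population_size=2.5, ploidy=1,
                              random_seed=seed)
    mts = msprime.sim_mutations(ts, rate=1, random_seed=seed + 7,
                                discrete_genome=False)
    S.append(mts.num_sites)
out["panmictic_S"] = sum(S) / len(S)
dem = msprime.Demography()
dem.add_population(name="p1", initial_size=2.0)
dem.add_population(name="p2", initial_size=1.0)
dem.add_population(name="anc", initial_size=1.5)
dem.add_population_split(time=2.0, derived=["p1", "p2"], ancestral="anc")
S2 = []
for seed in range(1, 1201):
    ts = msprime.sim_ancestry(samples={"p1": 6, "p2": 6}, demography=dem,
                              ploidy=1, random_seed=seed)
    mts = msprime.sim_mutations(ts, rate=1, random_seed=seed + 7,
                                discrete_genome=False)
    S2.append(mts.num_sites)
out["im_S"] = sum(S2) / len(S2)
json.dump(out, sys.stdout)
'
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  oracle <- jsonlite::fromJSON(paste(res, collapse = ""))

  set.seed(13)
  p1 <- im_parameters(theta1 = 5, theta2 = 5, thetaA = 5, t_split = 0,
                      n1 = 5, n2 = 1, locus_length = 5000)
  p1$n2 <- 0L  # panmictic sample of 5 (single deme)
  p1 <- im_parameters(theta1 = 5, theta2 = 5, thetaA = 5, t_split = 0,
                      n1 = 4, n2 = 1, locus_length = 5000)
  S_mine <- replicate(2500, {
    g <- simulate_genealogy(p1)
    X <- introgrescan:::.mutation_matrix(g)
    if (is.null(X)) 0 else ncol(X)
  })
  se <- sd(S_mine) / sqrt(length(S_mine))
  expect_lt(abs(mean(S_mine) - oracle$panmictic_S), 4 * se + 0.2)

  p2 <- im_parameters(theta1 = 4, theta2 = 2, thetaA = 3, t_split = 2,
                      n1 = 6, n2 = 6, locus_length = 5000)
  S2_mine <- replicate(2500, {
    g <- simulate_genealogy(p2)
    X <- introgrescan:::.mutation_matrix(g)
    if (is.null(X)) 0 else ncol(X)
  })
  se2 <- sd(S2_mine) / sqrt(length(S2_mine))
  expect_lt(abs(mean(S2_mine) - oracle$im_S), 4 * se2 + 0.3)
})

test_that("2Nm conversion and its inverse are exact", {
  p <- im_parameters(theta1 = 2, theta2 = 1, thetaA = 1.5, t_split = 2,
                     m1 = 1, m2 = 25)
  two_nm <- convert_to_2Nm(p)
  expect_equal(two_nm, c(pop1 = 1, pop2 = 12.5))
  expect_equal(m_from_2Nm(two_nm["pop1"], p$theta1), c(pop1 = 1),
               tolerance = 1e-12)
  expect_equal(m_from_2Nm(two_nm["pop2"], p$theta2), c(pop2 = 25),
               tolerance = 1e-12)
  p0 <- im_parameters(theta1 = 2, theta2 = 1, thetaA = 1, t_split = 1)
  expect_equal(unname(convert_to_2Nm(p0)), c(0, 0))
})

test_that("mutation-rate calibration follows the divergence arithmetic", {
  expect_equal(mu_from_divergence(0.2, 1e6)$per_year, 1e-7)
  r <- mu_from_divergence(0.2, 1e6, generations_per_year = 10)
  expect_equal(r$per_generation, 1e-8)
  # doubling the calibration time halves the rate
  expect_equal(mu_from_divergence(0.2, 2e6)$per_year,
               mu_from_divergence(0.2, 1e6)$per_year / 2)
  expect_error(mu_from_divergence(0, 1e6), "> 0")
  # the study-system per-year rate converts to a per-generation rate
  rc <- rate_constants()
  mu_gen <- rc$mu_per_locus_per_year[["HmB453k"]] / rc$generations_per_year
  expect_equal(mu_gen, 3.4e-6)
})

test_that("Hudson Fst behaves at its boundaries and at equilibrium", {
  # two samples from one pool: Fst near 0
  set.seed(44)
  mat <- matrix(sample(c("A", "G"), 24 * 200, replace = TRUE), 24)
  aln <- haplotype_alignment(mat, ids = sprintf("h%02d", 1:24))
  expect_lt(abs(fst_summary(aln, aln$ids[1:12], aln$ids[13:24])), 0.05)
  # fixed differences only: Fst = 1
  fixed <- rbind(matrix("A", 4, 10), matrix("G", 4, 10))
  aln2 <- haplotype_alignment(fixed, ids = letters[1:8])
  expect_equal(fst_summary(aln2, letters[1:4], letters[5:8]), 1)
  # symmetric two-deme equilibrium: Fst = 1 / (1 + 2 * theta * m)
  set.seed(14)
  p <- im_parameters(theta1 = 2, theta2 = 2, thetaA = 2, t_split = Inf,
                     m1 = 1, m2 = 1, n1 = 8, n2 = 8, locus_length = 2000)
  fst <- replicate(400, {
    aln <- simulate_locus(p)
    fst_summary(aln, aln$ids[1:8], aln$ids[9:16])
  })
  expected <- 1 / (1 + 2 * 2 * 1)
  expect_lt(abs(mean(fst, na.rm = TRUE) - expected),
            3 * sd(fst, na.rm = TRUE) / sqrt(length(fst)) + 0.02)
})
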