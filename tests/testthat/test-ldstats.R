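test_that("D and D' match hand-computed values", {
  # complete association
  expect_equal(ld_D_and_Dprime(c("A", "A", "a", "a"), c("B", "B", "b", "b")),
               c(D = 0.25, D_prime = 1))
  # independence
  expect_equal(ld_D_and_Dprime(c("A", "A", "a", "a"), c("B", "b", "B", "b")),
               c(D = 0, D_prime = 0))
  # AB x3, Ab x1, aB x1, ab x5: p_A = p_B = 0.4, p_AB = 0.3, D_max = 0.24
  a <- c(rep("A", 4), rep("a", 6))
  b <- c(rep("B", 3), "b", "B", rep("b", 5))
  expect_equal(ld_D_and_Dprime(a, b), c(D = 0.14, D_prime = 0.14 / 0.24))
  expect_error(ld_D_and_Dprime(rep("A", 4), c("B", "B", "b", "b")),
               "biallelic")
})

test_that("|D'| is bounded by 1 and matches the scalar oracle", {
  set.seed(42)
  for (r in 1:40) {
    n <- sample(4:12, 1)
    a <- sample(c("A", "a"), n, replace = TRUE)
    b <- sample(c("B", "b"), n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    got <- ld_D_and_Dprime(a, b)
    expect_lte(abs(got["D_prime"]), 1 + 1e-12)
    expect_equal(got, oracle_dprime(a, b))
  }
})

test_that("x is NA when shared or exclusive polymorphisms are missing", {
  # fixed differences only: no shared polymorphism at all
  mat <- rbind(h1 = c("A", "A"), h2 = c("A", "A"),
               h3 = c("G", "G"), h4 = c("G", "G"))
  res <- x_statistic(haplotype_alignment(mat), c("h1", "h2"), c("h3", "h4"))
  expect_true(is.na(res$pop1$x))
  expect_true(is.na(res$pop2$x))
})

test_that("a constructed coupling alignment yields x_pop1 = 1", {
  # pop1: sites 1-2 shared and perfectly coupled (|D'| = 1), site 3
  # exclusive to pop1 and exactly independent of them (|D'| = 0)
  pop1 <- rbind(a1 = c("A", "A", "T"), a2 = c("A", "A", "C"),
                a3 = c("G", "G", "T"), a4 = c("G", "G", "C"))
  pop2 <- rbind(b1 = c("A", "A", "T"), b2 = c("A", "G", "T"),
                b3 = c("G", "A", "T"), b4 = c("G", "G", "T"))
  aln <- haplotype_alignment(rbind(pop1, pop2))
  res <- x_statistic(aln, rownames(pop1), rownames(pop2),
                     ld_measure = "magnitude")
  expect_equal(res$pop1$x, 1)
  expect_equal(res$pop1$D_SS_mean, 1)
  expect_equal(res$pop1$D_SX_mean, 0)
})

test_that("x_statistic agrees with exhaustive pair enumeration", {
  for (seed in 1:6) {
    aln <- random_two_pop_alignment(20, 20, 60, seed = seed)
    pop1 <- aln$ids[1:20]
    pop2 <- aln$ids[21:40]
    for (measure in c("signed", "magnitude")) {
      got <- x_statistic(aln, pop1, pop2, ld_measure = measure)
      want <- oracle_xstat(aln, pop1, pop2, measure = measure)
      expect_equal(c(got$pop1$x, got$pop2$x), want, tolerance = 1e-12)
    }
    # derived-allele orientation path
    got_d <- x_statistic(aln, pop1, pop2, ancestral = "A")
    want_d <- oracle_xstat(aln, pop1, pop2, ancestral = "A")
    expect_equal(c(got_d$pop1$x, got_d$pop2$x), want_d, tolerance = 1e-12)
  }
})

test_that("relabelling the two populations swaps the x values", {
  aln <- random_two_pop_alignment(14, 14, 50, seed = 9)
  p1 <- aln$ids[1:14]
  p2 <- aln$ids[15:28]
  ab <- x_statistic(aln, p1, p2)
  ba <- x_statistic(aln, p2, p1)
  expect_equal(ab$pop1$x, ba$pop2$x)
  expect_equal(ab$pop2$x, ba$pop1$x)
})

test_that("the gene-flow test is reproducible under a fixed seed", {
  p <- im_parameters(theta1 = 6, theta2 = 6, thetaA = 6, t_split = 1,
                     m1 = 0, m2 = 0, n1 = 12, n2 = 12, locus_length = 400,
                     rho = 4, n_blocks = 10)
  set.seed(77)
  aln <- simulate_locus(p)
  g1 <- geneflow_test(aln, aln$ids[1:12], aln$ids[13:24], n_sims = 150,
                      seed = 5, ancestral = "A")
  g2 <- geneflow_test(aln, aln$ids[1:12], aln$ids[13:24], n_sims = 150,
                      seed = 5, ancestral = "A")
  expect_identical(g1$p, g2$p)
  expect_identical(g1$null_x, g2$null_x)
  expect_true(all(is.na(g1$p) | (g1$p > 0 & g1$p <= 1)))
})

test_that("direction inference follows the largest positive significant x", {
  fake <- function(x1, p1, x2, p2) {
    structure(list(labels = c("mel", "tim"),
                   pop1 = list(x = x1), pop2 = list(x = x2),
                   p = c(p1, p2)), class = "gene_flow_result")
  }
  expect_equal(infer_direction(fake(0.205, 0.001, 0.056, 0.83)), "mel")
  expect_equal(infer_direction(fake(0.056, 0.83, 0.205, 0.001)), "tim")
  expect_equal(infer_direction(fake(-0.1, 0.9, -0.2, 0.9)), "undetermined")
  expect_equal(infer_direction(fake(0.3, 0.01, 0.3, 0.01)), "undetermined")
  expect_equal(infer_direction(fake(0.4, 0.01, 0.2, 0.01)), "mel")
  expect_error(infer_direction(fake(NA, NA, NA, NA)), "NA")
})

test_that("the whole-locus |D'| matrix is symmetric with unit diagonal", {
  mat <- matrix("A", 20, 6)
  mat[1:10, 1] <- "G"
  mat[1:10, 2] <- "G"  # perfectly coupled with site 1
  mat[c(1:5, 11:15), 3] <- "G"
  mat[1, 4] <- "G"     # singleton: freq 0.05, not strictly above 5%
  aln <- haplotype_alignment(mat)
  M <- pairwise_ld_matrix(aln, maf = 0.05)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, ncol(M)))
  expect_equal(M["1", "2"], 1)
  expect_false("4" %in% rownames(M))
  expect_error(pairwise_ld_matrix(haplotype_alignment(matrix("A", 4, 5))),
               "MAF")
})

test_that("gene-flow reports carry the standard table columns", {
  aln <- random_two_pop_alignment(10, 10, 40, seed = 3)
  res <- geneflow_test(aln, aln$ids[1:10], aln$ids[11:20], n_sims = 50,
                       seed = 1)
  rep <- geneflow_report(res)
  expect_named(rep, c("locus", "population", "observed_x",
                      "simulated_mean_x", "p", "n_sims"))
  expect_equal(nrow(rep), 2)
})
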