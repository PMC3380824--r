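test_that("p-distances use pairwise deletion of gaps", {
  aln <- haplotype_alignment(c(a = "ACGT", b = "ACGA", c = "AC-T"))
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)      # 3 comparable columns, all equal
  expect_equal(d["a", "a"], 0)
  bad <- haplotype_alignment(c(x = "AC--", y = "--GT"))
  expect_error(p_distance_matrix(bad), "x and y")
})

test_that("neighbour-joining reconstructs additive trees exactly", {
  set.seed(2)
  for (ntax in 4:8) {
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.5, 3))
    d <- ape::cophenetic.phylo(tr)
    got <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), got), 0,
                 ignore_attr = TRUE)
    # branch lengths recovered through path distances
    expect_equal(ape::cophenetic.phylo(got)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "3 taxa")
  m <- matrix(1, 4, 4); diag(m) <- 0; m[1, 2] <- 2
  expect_error(neighbor_joining(m), "symmetric")
})

test_that("ties in the distance matrix give a deterministic tree", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("bootstrap support flags planted clades and is seed-stable", {
  # two clades separated by 10 diagnostic sites
  mat <- matrix(sample(c("A", "C", "G", "T"), 8 * 80, replace = TRUE),
                nrow = 8)
  mat[1:4, 1:10] <- "A"
  mat[5:8, 1:10] <- "G"
  aln <- haplotype_alignment(mat, ids = letters[1:8])
  tr <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_true(any(as.numeric(tr$node.label) >= 95))
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  # a single replicate gives all-or-nothing support
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 1)
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 100)))
})

test_that("newick output round-trips topology and branch lengths", {
  set.seed(19)
  tr <- ape::unroot(ape::rtree(6))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
})

test_that("two-taxon JC likelihood matches the closed form", {
  aln <- haplotype_alignment(c(t1 = "ACGT", t2 = "ACGA"))
  tree <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  ll <- tree_loglikelihood(aln, tree, substitution_model())
  t <- 0.1
  same <- log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3)))
  diff <- log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3)))
  expect_equal(ll$site_loglik, c(same, same, same, diff), tolerance = 1e-10)
  expect_equal(ll$loglik, sum(ll$site_loglik))
})

test_that("pruning equals the exhaustive ancestral-state sum", {
  set.seed(6)
  tr <- ape::rtree(4)
  model <- substitution_model(rates = c(1.5, 3, 0.7, 1.2, 4, 1),
                              base_freqs = c(0.35, 0.2, 0.15, 0.3),
                              p_inv = 0.15, alpha = 0.8, n_categories = 3)
  aln <- simulate_gtr_alignment(tr, 20, model, seed = 7)
  got <- tree_loglikelihood(aln, tr, model)
  want <- oracle_tree_loglik(aln, tr, model)
  expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
  expect_equal(got$site_loglik, want$site_loglik, tolerance = 1e-10)
  # fully independent transition matrices (matrix exponential)
  want2 <- oracle_tree_loglik(aln, tr, model, pmat = "expm")
  expect_equal(got$loglik, want2$loglik, tolerance = 1e-6)
})

test_that("the likelihood is invariant to re-rooting and tip order", {
  set.seed(9)
  tr <- ape::rtree(6)
  model <- substitution_model(alpha = 1, n_categories = 4, p_inv = 0.1)
  aln <- simulate_gtr_alignment(tr, 100, model, seed = 2)
  base <- tree_loglikelihood(aln, tr, model)$loglik
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                        resolve.root = TRUE)
  expect_equal(tree_loglikelihood(aln, rerooted, model)$loglik, base,
               tolerance = 1e-8)
  shuffled <- haplotype_alignment(aln$mat[rev(aln$ids), ],
                                  ids = rev(aln$ids))
  expect_equal(tree_loglikelihood(shuffled, tr, model)$loglik, base,
               tolerance = 1e-10)
})

test_that("likelihood agrees with an independent implementation", {
  set.seed(11)
  tr <- ape::rtree(5)
  model <- substitution_model(rates = c(1.2, 3, 0.8, 1.1, 3.5, 1),
                              base_freqs = c(0.3, 0.2, 0.25, 0.25),
                              alpha = 0.7, n_categories = 4)
  aln <- simulate_gtr_alignment(tr, 200, model, seed = 3)
  got <- tree_loglikelihood(aln, tr, model)$loglik
  seqs <- lapply(aln$ids, function(i) aln$mat[i, ])
  names(seqs) <- aln$ids
  pd <- phangorn::phyDat(seqs)
  fit <- phangorn::pml(tr, pd, bf = model$base_freqs, Q = model$rates,
                       shape = 0.7, k = 4)
  expect_equal(got, fit$logLik, tolerance = 1e-8)
})

test_that("branch-length optimisation is monotone and finds a fixed point", {
  set.seed(13)
  tr <- ape::rtree(5)
  model <- substitution_model()
  aln <- simulate_gtr_alignment(tr, 300, model, seed = 5)
  before <- tree_loglikelihood(aln, tr, model)$loglik
  opt <- optimize_branch_lengths(aln, tr, model)
  expect_gte(attr(opt, "loglik"), before)
  expect_true(attr(opt, "converged"))
  # starting from the optimum changes nothing beyond tolerance
  opt2 <- optimize_branch_lengths(aln, opt, model)
  expect_lt(abs(attr(opt2, "loglik") - attr(opt, "loglik")), 1e-3)
})

test_that("optimised branch lengths recover the generating tree", {
  set.seed(15)
  tr <- ape::rtree(5, br = function(n) runif(n, 0.08, 0.4))
  model <- substitution_model()
  aln <- simulate_gtr_alignment(tr, 2000, model, seed = 6)
  opt <- optimize_branch_lengths(aln, tr, model)
  long <- tr$edge.length > 0.1
  expect_lt(median(abs(opt$edge.length[long] - tr$edge.length[long]) /
                   tr$edge.length[long]), 0.2)
})

test_that("the SH test is self-consistent", {
  set.seed(17)
  tr <- ape::rtree(5)
  model <- substitution_model()
  aln <- simulate_gtr_alignment(tr, 300, model, seed = 8)
  # best tree against a clone of itself
  sh0 <- sh_test(aln, list(a = tr, b = tr), model, n_resamples = 200,
                 seed = 1, optimize = FALSE)
  expect_equal(sh0$delta, c(a = 0, b = 0))
  expect_equal(unname(sh0$p[sh0$best]), 1)
  # p is monotone non-increasing in delta
  alts <- list(true = tr,
               r1 = ape::rtree(5, tip.label = tr$tip.label),
               r2 = ape::rtree(5, tip.label = tr$tip.label))
  sh <- sh_test(aln, alts, model, n_resamples = 300, seed = 2)
  ord <- order(sh$delta)
  expect_true(all(diff(sh$p[ord]) <= 1e-12))
  expect_equal(unname(colSums(sh$site_loglik)), unname(sh$loglik))
  expect_error(sh_test(aln, list(tr), model), "2 candidate")
})

test_that("constrained NJ makes the requested groups monophyletic", {
  st <- simulate_study(default_study_design(n_per_pop = 8,
                                            locus_length = 300), seed = 5)
  aln <- st$alignments[["COI"]]
  species <- stats::setNames(st$metadata$species, st$metadata$haplotype_id)
  tr <- constrained_nj(aln, species)
  mel <- names(species)[species == "melpomene"]
  expect_true(ape::is.monophyletic(tr, mel))
})
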