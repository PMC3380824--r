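test_that("alignment construction validates its inputs", {
  aln <- haplotype_alignment(c(h1 = "acgt", h2 = "ACGT"))
  expect_equal(alignment_length(aln), 4)
  expect_equal(n_haplotypes(aln), 2)
  expect_equal(aln$mat[1, ], c("A", "C", "G", "T"))

  expect_error(haplotype_alignment(c("ACGT", "ACGTA")), "ragged")
  expect_error(haplotype_alignment(character(0)), "at least one")
  expect_error(haplotype_alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(haplotype_alignment("AXGT"), "invalid characters")
})

test_that("FASTA reading and writing round-trips sequences and ids", {
  aln <- random_alignment(8, 40, gap_prob = 0.05, seed = 1)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta_alignment(aln, path)
  back <- read_fasta_alignment(path, locus_name = "random")
  expect_identical(back$mat, aln$mat)
  expect_identical(back$ids, aln$ids)

  ragged <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), ragged)
  expect_error(read_fasta_alignment(ragged), "ragged")
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_fasta_alignment(empty), "empty")
})

test_that("a multi-locus panel reports its total haplotype count", {
  alns <- lapply(1:9, function(i) {
    a <- random_alignment(c(25, 24, 25, 25, 24, 25, 24, 25, 24)[i], 30,
                          seed = i)
    a$locus_name <- paste0("L", i)
    a
  })
  summ <- loci_summary(alns)
  expect_equal(nrow(summ), 9)
  expect_equal(attr(summ, "total_haplotypes"), 221)
})

test_that("metadata is validated against vocabularies and alignment ids", {
  aln <- haplotype_alignment(c(h1 = "ACGT", h2 = "ACGA"))
  md <- data.frame(haplotype_id = c("h1", "h2"),
                   species = c("melpomene", "timareta"),
                   race = c("aglaope", "florencia"),
                   phenotype = c("rayed", "rayed"),
                   region = c("amazon", "amazon"),
                   locality = c("Tarapoto", "Tarapoto"),
                   stringsAsFactors = FALSE)
  expect_s3_class(read_metadata(md, aln), "specimen_metadata")

  bad <- md
  bad$phenotype[1] <- "blue"
  expect_error(read_metadata(bad, aln), "unknown phenotype")
  expect_error(read_metadata(md[1, ], aln), "h2")

  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(read_metadata(path, aln), "specimen_metadata")
})

test_that("metadata predicates select haplotypes by conjunction", {
  md <- data.frame(haplotype_id = c("a", "b", "c"),
                   species = c("melpomene", "melpomene", "timareta"),
                   race = "r", phenotype = c("rayed", "red_banded", "rayed"),
                   region = "amazon", locality = "x",
                   stringsAsFactors = FALSE)
  md <- read_metadata(md)
  expect_equal(select_haplotypes(md, "species=melpomene"), c("a", "b"))
  expect_equal(select_haplotypes(md, "species=melpomene & phenotype=rayed"),
               "a")
  expect_equal(select_haplotypes(md, "species=timareta,melpomene"),
               c("a", "b", "c"))
  expect_error(select_haplotypes(md, "colour=blue"), "unknown metadata field")
})

test_that("site classification matches the rule set on constructed columns", {
  mat <- rbind(h1 = c("A", "A", "A", "A", "A", "A"),
               h2 = c("G", "A", "A", "A", "A", "C"),
               h3 = c("A", "A", "G", "A", "-", "G"),
               h4 = c("G", "G", "G", "A", "A", "A"))
  aln <- haplotype_alignment(mat)
  cls <- classify_sites(aln, c("h1", "h2"), c("h3", "h4"))
  expect_equal(as.character(cls$klass),
               c("shared",           # both pops A/G
                 "exclusive_pop2",   # pop1 monomorphic A, pop2 A/G
                 "fixed_difference", # pop1 all A, pop2 all G
                 "monomorphic",
                 "excluded",         # gap in pop2
                 "excluded"))        # three alleles
  expect_error(classify_sites(aln, character(0), "h3"), "non-empty")
  expect_error(classify_sites(aln, c("h1", "h3"), c("h3", "h4")), "disjoint")
})

test_that("site classes partition the alignment and match brute force", {
  for (seed in 1:5) {
    aln <- random_alignment(10, 50, gap_prob = 0.04, seed = seed)
    pop1 <- aln$ids[1:5]
    pop2 <- aln$ids[6:10]
    cls <- classify_sites(aln, pop1, pop2)
    expect_equal(nrow(cls), 50)
    expect_false(any(is.na(cls$klass)))
    expect_equal(as.character(cls$klass), oracle_classify(aln, pop1, pop2))
  }
})

test_that("MAF filtering is strict and restricted to clean biallelic sites", {
  mat <- matrix("A", 20, 4)
  mat[1, 1] <- "G"          # singleton: freq 0.05, not > 0.05
  mat[1:2, 2] <- "G"        # freq 0.10
  mat[1:2, 3] <- "G"
  mat[3, 3] <- "-"          # gap column dropped
  aln <- haplotype_alignment(mat)
  expect_equal(maf_filter(aln, 0.05), 2L)
  expect_equal(maf_filter(aln, 0), c(1L, 2L))
  expect_error(maf_filter(aln, 0.5), "0.5")
})
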