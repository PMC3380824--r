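# Synthetic multi-locus study generator. Emulates the sampling design of a
# two-species introgression study: two diverged populations ("melpomene" and
# "timareta" in the metadata vocabulary), a panel of neutral loci exchanging
# migrants at a low background rate, and one colour-pattern locus where a
# recent admixture pulse carried donor haplotypes into population 2 -- the
# signature of adaptive introgression of a wing-pattern allele.

#' Default study design
#'
#' Nine 500-bp loci sampled for 20 haplotypes per population. The shared
#' demography is a two-population split (theta1 = 12 for the larger donor
#' species, theta2 = 6 for the recipient, ancestral thetaA = 8;
#' mutation-scaled split time 8, about 700 ky at these diversities) with
#' background gene flow of 0.1 effective migrant copies per generation in
#' each direction (`m_i = 2 * 0.1 / theta_i`) and intra-locus recombination
#' `rho = 2`. The colour locus (`HmB453k`) additionally carries the
#' signature of adaptive introgression: a hard selective sweep of a single
#' donor haplotype, modelled as an admixture pulse at `pulse_time = 0.05`
#' (about 1% of the split age) in which half of population 2's ancestry at
#' this locus coalesces into one population-1 founder
#' (`pulse_founders = 1`). Recent, single-origin introgression is exactly
#' the configuration the shared/exclusive LD statistic detects: the swept
#' donor variants are mutually coupled while native variants repulse them.
#'
#' @param n_per_pop Haplotypes sampled per population per locus.
#' @param locus_length Sites per locus.
#' @param theta1,theta2,thetaA,t_split Shared demographic parameters.
#' @param background_2Nm Continuous background gene flow, as effective
#'   migrant copies per generation per direction.
#' @param pulse_frac,pulse_time,pulse_founders Colour-locus sweep pulse into
#'   population 2 (see [im_parameters()]).
#' @param rho Mutation-scaled intra-locus recombination rate (see
#'   [im_parameters()]); the gene-flow LD statistic needs `rho > 0`.
#' @param n_blocks Recombination discretisation per locus.
#' @return A `study_design`: list of per-locus [im_parameters()] plus flags.
#' @export
default_study_design <- function(n_per_pop = 20, locus_length = 500,
                                 theta1 = 12, theta2 = 6, thetaA = 8,
                                 t_split = 8, background_2Nm = 0.1,
                                 pulse_frac = 0.5, pulse_time = 0.05,
                                 pulse_founders = 1,
                                 rho = 2, n_blocks = 20) {
  locus_names <- c("COI", "GAPDH", "Hsp90", "kinesin", "Hm01012",
                   "HmB449k", "HmB453k", "optix", "HmB520k")
  colour_locus <- "HmB453k"
  loci <- lapply(locus_names, function(nm) {
    colour <- nm == colour_locus
    list(name = nm,
         colour = colour,
         params = im_parameters(
           theta1 = theta1, theta2 = theta2, thetaA = thetaA,
           t_split = t_split,
           m1 = m_from_2Nm(background_2Nm, theta1),
           m2 = m_from_2Nm(background_2Nm, theta2),
           n1 = n_per_pop, n2 = n_per_pop,
           locus_length = locus_length, rho = rho, n_blocks = n_blocks,
           pulse_frac = if (colour) pulse_frac else 0,
           pulse_time = if (colour) pulse_time else 0,
           pulse_founders = pulse_founders))
  })
  names(loci) <- locus_names
  structure(list(loci = loci, n_per_pop = as.integer(n_per_pop),
                 colour_locus = colour_locus),
            class = "study_design")
}

# Introgression status of population-2 haplotypes at the colour locus,
# taken from the simulator's own ancestry record: a haplotype is
# introgressed when more than half of its locus was inherited through the
# admixture pulse.
.introgressed_flags <- function(colour_aln, pop2_ids) {
  pf <- attr(colour_aln, "pulse_fraction")
  if (is.null(pf)) return(rep(FALSE, length(pop2_ids)))
  pf[pop2_ids] > 0.5
}

#' Simulate a complete multi-locus study dataset
#'
#' Simulates every locus of a [default_study_design()] (or a custom design)
#' with a shared haplotype panel, builds a specimen metadata table whose
#' phenotype labels track colour-locus ancestry, and optionally writes the
#' dataset to disk (one FASTA per locus, a metadata TSV, and a JSON truth
#' table of the generating parameters).
#'
#' Population 1 ("melpomene") individuals are split evenly between the
#' `red_banded` and `rayed` phenotype classes. Population 2 ("timareta")
#' individuals whose colour-locus haplotypes cluster with population 1
#' (nearest-neighbour rule) receive the mimetic phenotype of their donor
#' group; the remainder are `non_red`. Regeneration from the same
#' `(design, seed)` is byte-identical.
#'
#' @param design A `study_design`, default [default_study_design()].
#' @param seed Integer seed (required for reproducible datasets).
#' @param dir Optional output directory; created if needed.
#' @return A list of class `simulated_study`: `alignments` (named list of
#'   `haplotype_alignment`), `metadata` (specimen metadata), `truth`
#'   (per-locus parameters, colour flag and per-haplotype introgression
#'   calls), `design`, `seed` and, when written, `paths`.
#' @export
simulate_study <- function(design = default_study_design(), seed = NULL,
                           dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (length(design$loci) == 0L) {
    stop("design contains no loci", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- design$loci[[1]]$params$n1
  n2 <- design$loci[[1]]$params$n2
  if (n1 < 4L || n2 < 4L) {
    stop("design needs at least 4 haplotypes per population so that every ",
         "phenotype class has members", call. = FALSE)
  }
  pop1_ids <- sprintf("mel_i%02d_h%d", rep(seq_len(ceiling(n1 / 2)), each = 2)[seq_len(n1)],
                      rep(1:2, length.out = n1))
  pop2_ids <- sprintf("tim_i%02d_h%d", rep(seq_len(ceiling(n2 / 2)), each = 2)[seq_len(n2)],
                      rep(1:2, length.out = n2))
  ids <- c(pop1_ids, pop2_ids)
  alignments <- lapply(design$loci, function(lc) {
    if (lc$params$n1 != n1 || lc$params$n2 != n2) {
      stop("all loci must share the same sample sizes", call. = FALSE)
    }
    simulate_locus(lc$params, ids = ids, locus_name = lc$name)
  })
  names(alignments) <- names(design$loci)

  colour_name <- design$colour_locus
  introgressed <- if (!is.null(colour_name) && colour_name %in% names(alignments)) {
    .introgressed_flags(alignments[[colour_name]], pop2_ids)
  } else {
    rep(FALSE, n2)
  }
  # phenotype is assigned at haplotype resolution (the analysis unit for
  # phased data): population 1 alternates red_banded / rayed by individual;
  # population 2 haplotypes whose colour-locus ancestry is donor-derived
  # mimic the donor phenotype matching their individual index parity, the
  # rest are non_red
  ind1 <- as.integer(sub("^mel_i(\\d+)_h\\d$", "\\1", pop1_ids))
  ind2 <- as.integer(sub("^tim_i(\\d+)_h\\d$", "\\1", pop2_ids))
  phen1 <- ifelse(ind1 %% 2L == 1L, "red_banded", "rayed")
  phen2 <- ifelse(introgressed,
                  ifelse(ind2 %% 2L == 1L, "red_banded", "rayed"),
                  "non_red")
  region1 <- ifelse(phen1 == "rayed", "amazon", "east_andes_foothills")
  region2 <- ifelse(phen2 == "rayed", "amazon",
                    ifelse(phen2 == "red_banded", "east_andes_foothills",
                           "magdalena_valley"))
  metadata <- data.frame(
    haplotype_id = ids,
    species = c(rep("melpomene", n1), rep("timareta", n2)),
    race = c(ifelse(phen1 == "rayed", "aglaope", "amaryllis"),
             ifelse(phen2 == "rayed", "florencia",
                    ifelse(phen2 == "red_banded", "ssp_nov", "timareta"))),
    phenotype = c(phen1, phen2),
    region = c(region1, region2),
    locality = c(rep("synthetic_site_1", n1), rep("synthetic_site_2", n2)),
    stringsAsFactors = FALSE)
  metadata <- read_metadata(metadata, alignments)

  truth <- list(
    seed = seed,
    colour_locus = colour_name,
    loci = lapply(design$loci, function(lc) {
      c(unclass(lc$params), list(colour = lc$colour,
                                 two_Nm = as.list(convert_to_2Nm(lc$params))))
    }),
    introgressed_pop2 = stats::setNames(as.list(introgressed), pop2_ids))

  out <- structure(list(alignments = alignments, metadata = metadata,
                        truth = truth, design = design, seed = seed),
                   class = "simulated_study")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = character(0))
    for (nm in names(alignments)) {
      fp <- file.path(dir, paste0(nm, ".fa"))
      write_fasta_alignment(alignments[[nm]], fp)
      paths$fasta[nm] <- fp
    }
    paths$metadata <- file.path(dir, "metadata.tsv")
    utils::write.table(metadata, paths$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", length(x$alignments), " loci, ",
      nrow(x$metadata), " haplotypes (seed ",
      if (is.null(x$seed)) "unset" else x$seed, ")\n", sep = "")
  invisible(x)
}
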