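# Configuration-driven orchestration: run the AMOVA, gene-flow, genealogy
# and topology-test stages over a set of loci and emit the standard report
# tables with an audit trail (seeds, replicate counts, versions).

#' Map a p-value to a report significance tier
#'
#' Star tiers used in the report tables: `***` for p at the permutation
#' floor (<= 1e-6), `**` for p < 0.001, `*` for p < 0.05, empty otherwise.
#'
#' @param p A p-value in `(0, 1]` (vectorised).
#' @return Character vector of tier labels.
#' @export
table_significance_tiers <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p must be in (0, 1]", call. = FALSE)
  }
  ifelse(p <= 1e-6, "***", ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "")))
}

#' Build a run configuration
#'
#' @param loci Named character vector or list of per-locus FASTA paths.
#' @param metadata Path to the specimen metadata TSV.
#' @param pop1,pop2 Metadata predicates defining the two focal populations
#'   for the gene-flow test (see [select_haplotypes()]); e.g.
#'   `"species=melpomene"` vs `"species=timareta,heurippa"`.
#' @param linked Optional named classification of loci as `linked`/`unlinked`
#'   to the colour locus (annotation only).
#' @param analyses Toggles: logical list with elements `amova`, `ldflow`,
#'   `nj`, `sh`.
#' @param n_perm,n_boot,n_sims,n_resamples Replicate counts; defaults are the
#'   production values (1000 permutations, 1000 bootstraps, 30000 gene-flow
#'   simulations, 1000 RELL resamples).
#' @param sh_locus Locus analysed by the topology-test stage (defaults to
#'   the last locus).
#' @param sh_max_tips Haplotype subsample size for the topology test.
#' @param ancestral Ancestral-state specification for the gene-flow test
#'   (see [x_statistic()]): an outgroup haplotype id, a single base (`"A"`
#'   for simulator output), or `NULL` for minor-allele orientation. When
#'   `NULL` and the metadata contain outgroup haplotypes, the first
#'   outgroup haplotype present in each alignment is used.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir Output directory for reports.
#' @return A `run_config` object.
#' @export
run_config <- function(loci, metadata, pop1 = "species=melpomene",
                       pop2 = "species=timareta,heurippa", linked = NULL,
                       analyses = list(amova = TRUE, ldflow = TRUE,
                                       nj = TRUE, sh = FALSE),
                       n_perm = 1000, n_boot = 1000, n_sims = 30000,
                       n_resamples = 1000, sh_locus = NULL, sh_max_tips = 16,
                       ancestral = NULL,
                       seed = 1, out_dir = tempfile("introgrescan_run_")) {
  loci <- unlist(loci)
  if (is.null(names(loci)) || any(names(loci) == "")) {
    names(loci) <- sub("\\.[^.]*$", "", basename(loci))
  }
  defaults <- list(amova = FALSE, ldflow = FALSE, nj = FALSE, sh = FALSE)
  defaults[names(analyses)] <- lapply(analyses, isTRUE)
  structure(list(loci = loci, metadata = metadata, pop1 = pop1, pop2 = pop2,
                 linked = linked, analyses = defaults,
                 n_perm = n_perm, n_boot = n_boot, n_sims = n_sims,
                 n_resamples = n_resamples, sh_locus = sh_locus,
                 sh_max_tips = sh_max_tips, ancestral = ancestral,
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
}

# Evenly subsample haplotype ids for the SH stage, stratified by
# species x phenotype so every haplotype class (including both native and
# introgressed recipient classes) is represented.
.sh_subsample <- function(ids, metadata, max_tips) {
  if (length(ids) <= max_tips) return(ids)
  md <- metadata[match(ids, metadata$haplotype_id), ]
  grp <- paste(md$species, md$phenotype, sep = "|")
  by_grp <- split(ids, grp)
  quota <- max(1L, floor(max_tips / length(by_grp)))
  picked <- unlist(lapply(by_grp, function(v) v[seq_len(min(quota, length(v)))]),
                   use.names = FALSE)
  extra <- setdiff(ids, picked)
  c(picked, extra[seq_len(max(0L, max_tips - length(picked)))])
}

#' Neighbour-joining tree constrained to respect a grouping
#'
#' Adds a large constant to the distances between haplotypes in different
#' groups before NJ, forcing each group to be monophyletic while letting the
#' data resolve the within-group structure. Used to encode alternative
#' phylogenetic hypotheses (species tree, independent phenotypic
#' convergence, ancestral polymorphism) as fully resolved topologies for the
#' SH test.
#'
#' @param aln A `haplotype_alignment`.
#' @param groups Group labels named by haplotype id; `NA` labels form a
#'   shared "other" pool, so a single labelled group is forced to one side
#'   of a split. A list of such vectors applies nested constraints with
#'   geometrically decreasing penalties.
#' @param penalty Added distance between different-group pairs.
#' @return An `ape::phylo` tree.
#' @export
constrained_nj <- function(aln, groups, penalty = 10) {
  d <- p_distance_matrix(aln)
  if (!is.list(groups)) groups <- list(groups)
  pen <- penalty
  for (g in groups) {
    lab <- g[rownames(d)]
    lab[is.na(lab)] <- ".other"
    diff_grp <- outer(lab, lab, FUN = `!=`)
    d <- d + pen * diff_grp
    pen <- pen / 4
  }
  neighbor_joining(d)
}

#' The three standard alternative topologies for the colour locus
#'
#' Encodes the competing explanations for phenotype clustering at a
#' colour-pattern locus as constraint topologies: (i) the species tree (each
#' species monophyletic, phenotypes free inside); (ii) independent
#' phenotypic convergence (species monophyletic with phenotype subclades
#' inside each, so identical patterns arose separately in each species);
#' (iii) ancestral polymorphism (species monophyletic with the recipient's
#' non-mimetic haplotypes forming a derived clade inside the recipient --
#' red patterns ancestral, lost on a derived branch). Under genuine
#' introgression the data tree instead clusters the recipient's mimetic
#' haplotypes with the donor, contradicting all three.
#'
#' @param aln A `haplotype_alignment` (typically a subsample).
#' @param metadata Specimen metadata covering the alignment ids.
#' @param recipient_species Species forming the recipient clade.
#' @return Named list of three `ape::phylo` trees.
#' @export
alternative_topologies <- function(aln, metadata,
                                   recipient_species = c("timareta",
                                                         "heurippa",
                                                         "cydno")) {
  md <- metadata[match(aln$ids, metadata$haplotype_id), ]
  species <- stats::setNames(md$species, md$haplotype_id)
  phen_in_sp <- stats::setNames(paste(md$species, md$phenotype, sep = "|"),
                                md$haplotype_id)
  recipient <- md$species %in% recipient_species
  loss_clade <- stats::setNames(
    ifelse(recipient & md$phenotype == "non_red", "derived_loss",
           NA_character_),
    md$haplotype_id)
  list(species_tree = constrained_nj(aln, species),
       independent_convergence = constrained_nj(aln,
                                                list(species, phen_in_sp)),
       ancestral_polymorphism = constrained_nj(aln,
                                               list(species, loss_clade)))
}

#' Run the configured analysis stages over all loci
#'
#' Reads every locus and the metadata, then runs the enabled stages: AMOVA
#' by phenotype/species/geography per locus, the gene-flow (x = Dss - Dsx)
#' test per locus, bootstrap NJ genealogies, and the SH topology test on one
#' locus against the three standard alternatives. Reports are written as TSV
#' under `config$out_dir` together with Newick trees, a structured JSON run
#' record and a log. Stage failures are caught, logged, and reflected in a
#' non-zero `exit_status`; completed stages still appear in the bundle.
#'
#' @param config A [run_config()].
#' @return A `run_bundle` list: `amova`, `geneflow`, `trees`, `sh`,
#'   `errors`, `exit_status`, `out_dir`. Re-running with the same config and
#'   seed yields byte-identical reports.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat("", file = log_path)
  bundle <- list(amova = NULL, geneflow = NULL, trees = NULL, sh = NULL,
                 errors = character(0), out_dir = config$out_dir)
  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    .log_line(log_path, "stage ", name, " starting")
    tryCatch(fun(), error = function(e) {
      msg <- paste0("stage ", name, " failed: ", conditionMessage(e))
      .log_line(log_path, msg)
      bundle$errors <<- c(bundle$errors, msg)
      NULL
    })
  }

  any_enabled <- any(unlist(config$analyses))
  inputs <- stage("load", any_enabled, function() {
    missing <- config$loci[!file.exists(config$loci)]
    if (length(missing) > 0L) {
      stop("FASTA path(s) not found: ", paste(missing, collapse = ", "))
    }
    alns <- lapply(names(config$loci), function(nm) {
      read_fasta_alignment(config$loci[[nm]], locus_name = nm)
    })
    names(alns) <- names(config$loci)
    md <- read_metadata(config$metadata, alns)
    list(alns = alns, md = md)
  })
  if (is.null(inputs) && any_enabled) {
    bundle$exit_status <- 1L
    .write_run_record(config, bundle)
    return(structure(bundle, class = "run_bundle"))
  }

  bundle$amova <- stage("amova", config$analyses$amova, function() {
    rep <- amova_report(inputs$alns, inputs$md, n_perm = config$n_perm,
                        seed = config$seed + 1L)
    utils::write.table(rep, file.path(config$out_dir, "amova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  bundle$geneflow <- stage("ldflow", config$analyses$ldflow, function() {
    pop1 <- select_haplotypes(inputs$md, config$pop1)
    pop2 <- select_haplotypes(inputs$md, config$pop2)
    outgroup_ids <- inputs$md$haplotype_id[
      inputs$md$species == "numata_outgroup"]
    results <- lapply(seq_along(inputs$alns), function(i) {
      aln <- inputs$alns[[i]]
      anc <- config$ancestral
      if (is.null(anc)) anc <- intersect(outgroup_ids, aln$ids)[1]
      if (length(anc) == 1 && is.na(anc)) anc <- NULL
      geneflow_test(aln, intersect(pop1, aln$ids), intersect(pop2, aln$ids),
                    n_sims = config$n_sims, seed = config$seed + 100L + i,
                    labels = c(config$pop1, config$pop2), ancestral = anc)
    })
    rep <- geneflow_report(results)
    rep$recipient <- vapply(results, function(r) {
      if (all(is.na(c(r$pop1$x, r$pop2$x)))) "NA" else infer_direction(r)
    }, character(1))[rep(seq_along(results), each = 2)]
    utils::write.table(rep, file.path(config$out_dir, "geneflow.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  bundle$trees <- stage("nj", config$analyses$nj, function() {
    tree_dir <- file.path(config$out_dir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    out <- lapply(seq_along(inputs$alns), function(i) {
      aln <- inputs$alns[[i]]
      outgroup_ids <- inputs$md$haplotype_id[
        inputs$md$species == "numata_outgroup"]
      tr <- bootstrap_support(aln, n_reps = config$n_boot,
                              seed = config$seed + 200L + i,
                              outgroup = intersect(outgroup_ids, aln$ids)[1])
      write_newick(tr, file.path(tree_dir, paste0(aln$locus_name, ".nwk")))
      tr
    })
    names(out) <- names(inputs$alns)
    out
  })

  bundle$sh <- stage("sh", config$analyses$sh, function() {
    locus <- if (is.null(config$sh_locus)) {
      names(inputs$alns)[length(inputs$alns)]
    } else {
      config$sh_locus
    }
    aln <- inputs$alns[[locus]]
    keep <- .sh_subsample(aln$ids, inputs$md, config$sh_max_tips)
    sub <- haplotype_alignment(aln$mat[keep, , drop = FALSE], ids = keep,
                               locus_name = aln$locus_name)
    best <- neighbor_joining(p_distance_matrix(sub))
    alts <- alternative_topologies(sub, inputs$md)
    res <- sh_test(sub, c(list(data_tree = best), alts),
                   n_resamples = config$n_resamples,
                   seed = config$seed + 300L)
    rep <- data.frame(locus = locus, topology = res$labels,
                      lnL = res$loglik, delta = res$delta, p = res$p,
                      n_resamples = res$n_resamples,
                      stringsAsFactors = FALSE)
    utils::write.table(rep, file.path(config$out_dir, "sh_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  bundle$exit_status <- if (length(bundle$errors) > 0L) 1L else 0L
  .log_line(log_path, "run complete, exit status ", bundle$exit_status)
  .write_run_record(config, bundle)
  structure(bundle, class = "run_bundle")
}

.write_run_record <- function(config, bundle) {
  record <- list(
    seed = config$seed,
    loci = as.list(config$loci),
    analyses = config$analyses,
    replicates = list(n_perm = config$n_perm, n_boot = config$n_boot,
                      n_sims = config$n_sims,
                      n_resamples = config$n_resamples),
    package_version = as.character(utils::packageVersion("introgrescan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    errors = bundle$errors,
    exit_status = bundle$exit_status)
  jsonlite::write_json(record, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(record)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle> out_dir ", x$out_dir, "; exit status ", x$exit_status,
      "\n", sep = "")
  if (length(x$errors) > 0L) cat("  errors:\n   ",
                                 paste(x$errors, collapse = "\n    "), "\n")
  invisible(x)
}
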