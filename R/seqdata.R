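# Alignment container, metadata validation, and site classification against a
# population pair. Sites are indexed 1-based throughout (R convention).

ALIGNMENT_ALPHABET <- c("A", "C", "G", "T", "-", "N")

SPECIES_LEVELS <- c("melpomene", "cydno", "timareta", "heurippa", "numata_outgroup")
PHENOTYPE_LEVELS <- c("red_banded", "rayed", "non_red")
REGION_LEVELS <- c("guiana_shield", "amazon", "pacific", "east_andes_foothills",
                   "cauca_valley", "magdalena_valley")

SITE_CLASSES <- c("shared", "exclusive_pop1", "exclusive_pop2",
                  "fixed_difference", "monomorphic", "excluded")

#' Construct a haplotype alignment
#'
#' A haplotype alignment holds equal-length phased nucleotide sequences for a
#' single locus, one record per haplotype. Bases are uppercased and restricted
#' to `A`, `C`, `G`, `T`, `-` (gap) and `N` (missing).
#'
#' @param sequences Character vector of aligned sequences (all the same
#'   length), or a character matrix with one row per haplotype and one column
#'   per alignment site.
#' @param ids Unique haplotype identifiers, one per sequence. Defaults to the
#'   names of `sequences` (or rownames of the matrix).
#' @param locus_name Label for the locus.
#'
#' @return An object of class `haplotype_alignment`: a list with elements
#'   `locus_name`, `ids`, and `mat` (character matrix, haplotypes x sites).
#' @export
#' @examples
#' aln <- haplotype_alignment(c(h1 = "ACGT", h2 = "ACGA"))
#' alignment_length(aln)
haplotype_alignment <- function(sequences, ids = NULL, locus_name = "locus") {
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(sequences)
    sequences <- as.character(sequences)
    if (length(sequences) == 0L) {
      stop("alignment must contain at least one sequence", call. = FALSE)
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequence lengths differ (",
           paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
    }
    if (unique(lens) < 1L) {
      stop("alignment length must be >= 1", call. = FALSE)
    }
    mat <- matrix(toupper(unlist(strsplit(sequences, "", fixed = TRUE))),
                  nrow = length(sequences), byrow = TRUE)
  }
  if (is.null(ids)) ids <- paste0("h", seq_len(nrow(mat)))
  ids <- as.character(ids)
  if (length(ids) != nrow(mat)) {
    stop("need exactly one id per sequence", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate haplotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (ncol(mat) < 1L) stop("alignment length must be >= 1", call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), ALIGNMENT_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dimnames(mat) <- list(ids, NULL)
  structure(list(locus_name = locus_name, ids = ids, mat = mat),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("<haplotype_alignment> locus ", x$locus_name, ": ",
      n_haplotypes(x), " haplotypes x ", alignment_length(x), " sites\n",
      sep = "")
  invisible(x)
}

#' Number of haplotypes in an alignment
#' @param aln A `haplotype_alignment`.
#' @return Integer count of haplotype records.
#' @export
n_haplotypes <- function(aln) nrow(aln$mat)

#' Alignment length (number of sites)
#' @param aln A `haplotype_alignment`.
#' @return Integer number of aligned columns.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Read a FASTA haplotype alignment
#'
#' Reads one locus from a FASTA file, uppercases bases, and validates that all
#' records have equal length and unique identifiers.
#'
#' @param path Path to a FASTA file.
#' @param locus_name Locus label; defaults to the file name without extension.
#' @return A [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (is.null(locus_name)) {
    locus_name <- sub("\\.(fa|fasta|fas|fna)$", "", basename(path),
                      ignore.case = TRUE)
  }
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment in ", path, ": sequence lengths differ (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  seqs <- vapply(as.character(recs), paste, character(1), collapse = "")
  haplotype_alignment(seqs, ids = names(recs), locus_name = locus_name)
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln A `haplotype_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  lines <- character(2L * n_haplotypes(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$mat, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Summarise a set of locus alignments
#'
#' @param alignments A list of `haplotype_alignment` objects (e.g. the nine
#'   loci of a study).
#' @return A data frame with one row per locus (`locus`, `n_haplotypes`,
#'   `length`, `segregating_sites`) plus a `"total_haplotypes"` attribute.
#' @export
loci_summary <- function(alignments) {
  if (inherits(alignments, "haplotype_alignment")) alignments <- list(alignments)
  rows <- lapply(alignments, function(a) {
    data.frame(locus = a$locus_name,
               n_haplotypes = n_haplotypes(a),
               length = alignment_length(a),
               segregating_sites = sum(apply(a$mat, 2L, function(col) {
                 length(unique(col[col %in% c("A", "C", "G", "T")])) > 1L
               })),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_haplotypes") <- sum(out$n_haplotypes)
  out
}

#' Read and validate specimen metadata
#'
#' Reads a tab-separated metadata table with columns `haplotype_id`,
#' `species`, `race`, `phenotype`, `region`, `locality` and checks it against
#' an alignment: every haplotype id in the alignment must appear exactly once,
#' and `species`, `phenotype` and `region` must come from their closed
#' vocabularies.
#'
#' @param path Path to a TSV file (or a data frame already in memory).
#' @param alignment Optional `haplotype_alignment` (or list of them) whose ids
#'   must all be present.
#' @return A data frame of class `specimen_metadata`.
#' @export
read_metadata <- function(path, alignment = NULL) {
  md <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  required <- c("haplotype_id", "species", "race", "phenotype", "region",
                "locality")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0L) {
    stop("metadata missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md <- md[, required]
  if (anyDuplicated(md$haplotype_id)) {
    stop("duplicate haplotype_id in metadata: ",
         paste(unique(md$haplotype_id[duplicated(md$haplotype_id)]),
               collapse = ", "), call. = FALSE)
  }
  check_vocab <- function(values, levels, field) {
    bad <- setdiff(unique(values), levels)
    if (length(bad) > 0L) {
      stop("unknown ", field, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
    }
  }
  check_vocab(md$species, SPECIES_LEVELS, "species")
  check_vocab(md$phenotype, PHENOTYPE_LEVELS, "phenotype")
  check_vocab(md$region, REGION_LEVELS, "region")
  if (!is.null(alignment)) {
    alns <- if (inherits(alignment, "haplotype_alignment")) list(alignment) else alignment
    for (a in alns) {
      absent <- setdiff(a$ids, md$haplotype_id)
      if (length(absent) > 0L) {
        stop("metadata missing haplotype id(s) from locus ", a$locus_name,
             ": ", paste(absent, collapse = ", "), call. = FALSE)
      }
    }
  }
  class(md) <- c("specimen_metadata", "data.frame")
  md
}

#' Select haplotype ids by a metadata predicate
#'
#' Predicates are conjunctions of `field=value` clauses joined by `&`, with
#' comma-separated alternatives inside a clause, e.g.
#' `"species=timareta,heurippa & phenotype=red_banded"`.
#'
#' @param metadata A `specimen_metadata` data frame.
#' @param predicate Predicate string.
#' @return Character vector of matching haplotype ids.
#' @export
select_haplotypes <- function(metadata, predicate) {
  clauses <- strsplit(predicate, "&", fixed = TRUE)[[1]]
  keep <- rep(TRUE, nrow(metadata))
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "") next
    parts <- strsplit(cl, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed predicate clause: '", cl, "'", call. = FALSE)
    }
    field <- trimws(parts[1])
    if (!field %in% names(metadata)) {
      stop("unknown metadata field in predicate: ", field, call. = FALSE)
    }
    values <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    keep <- keep & metadata[[field]] %in% values
  }
  metadata$haplotype_id[keep]
}

.check_pops <- function(aln, pop1, pop2) {
  pop1 <- as.character(pop1)
  pop2 <- as.character(pop2)
  if (length(pop1) == 0L || length(pop2) == 0L) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(c(pop1, pop2), aln$ids)
  if (length(unknown) > 0L) {
    stop("haplotype id(s) not in alignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(pop1, pop2)) > 0L) {
    stop("populations must be disjoint; overlapping ids: ",
         paste(intersect(pop1, pop2), collapse = ", "), call. = FALSE)
  }
  list(pop1 = pop1, pop2 = pop2)
}

#' Classify alignment sites relative to a population pair
#'
#' Each aligned column is classified as a shared polymorphism (both
#' populations segregate for the same two alleles), an exclusive polymorphism
#' of one population, a fixed difference, monomorphic, or excluded. Columns
#' containing a gap or `N` in either focal population, or more than two
#' alleles pooled across both, are excluded (D' is defined for biallelic
#' sites, and missing data are treated conservatively).
#'
#' @param aln A `haplotype_alignment`.
#' @param pop1,pop2 Disjoint, non-empty character vectors of haplotype ids.
#' @return A data frame with one row per column: `position` (1-based),
#'   `alleles` (e.g. `"A/G"`), and `klass` (factor over the six site classes).
#' @export
classify_sites <- function(aln, pop1, pop2) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  pops <- .check_pops(aln, pop1, pop2)
  m1 <- aln$mat[pops$pop1, , drop = FALSE]
  m2 <- aln$mat[pops$pop2, , drop = FALSE]
  L <- alignment_length(aln)
  klass <- character(L)
  alleles <- character(L)
  for (j in seq_len(L)) {
    c1 <- m1[, j]
    c2 <- m2[, j]
    if (any(c(c1, c2) %in% c("-", "N"))) {
      klass[j] <- "excluded"
      alleles[j] <- paste(sort(unique(c(c1, c2))), collapse = "/")
      next
    }
    a1 <- unique(c1)
    a2 <- unique(c2)
    all_alleles <- sort(unique(c(a1, a2)))
    alleles[j] <- paste(all_alleles, collapse = "/")
    if (length(all_alleles) > 2L) {
      klass[j] <- "excluded"
    } else if (length(a1) == 2L && length(a2) == 2L) {
      klass[j] <- "shared"
    } else if (length(a1) == 2L) {
      klass[j] <- "exclusive_pop1"
    } else if (length(a2) == 2L) {
      klass[j] <- "exclusive_pop2"
    } else if (a1 != a2) {
      klass[j] <- "fixed_difference"
    } else {
      klass[j] <- "monomorphic"
    }
  }
  data.frame(position = seq_len(L), alleles = alleles,
             klass = factor(klass, levels = SITE_CLASSES),
             stringsAsFactors = FALSE)
}

#' Filter biallelic sites by minor allele frequency
#'
#' Returns the (1-based) indices of biallelic segregating columns whose minor
#' allele frequency strictly exceeds `threshold`. Columns containing gaps or
#' `N` are not considered.
#'
#' @param aln A `haplotype_alignment`.
#' @param threshold Frequency in `[0, 0.5)`; the comparison is strict
#'   (`maf > threshold`), so a 5% allele does not pass a 0.05 threshold.
#' @return Integer vector of retained site indices.
#' @export
maf_filter <- function(aln, threshold = 0.05) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  if (threshold < 0 || threshold >= 0.5) {
    stop("threshold must be in [0, 0.5)", call. = FALSE)
  }
  keep <- vapply(seq_len(alignment_length(aln)), function(j) {
    col <- aln$mat[, j]
    if (any(col %in% c("-", "N"))) return(FALSE)
    tab <- table(col)
    if (length(tab) != 2L) return(FALSE)
    min(tab) / sum(tab) > threshold
  }, logical(1))
  which(keep)
}

#' Write a site-classification report as TSV
#'
#' @param sites Data frame from [classify_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
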