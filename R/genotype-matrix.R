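#' Construct a genotype matrix
#'
#' The central data container: a samples x loci matrix of diploid dosages
#' (0, 1, 2 copies of the alternate allele, \code{NA} for missing) together
#' with locus coordinates, alleles, and a generation label per sample.
#' Loci are stored sorted by (chromosome, position); duplicate coordinates
#' are an error.
#'
#' @param dosages integer matrix, samples in rows, loci in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (single bases), one row per column of
#'   \code{dosages}.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of \code{dosages}.
#' @param generation character vector of per-sample generation labels
#'   (e.g. \code{"G0"}); recycled if length 1.
#' @param contig_lengths optional named vector of chromosome lengths (bp),
#'   used when building window grids and writing VCF contig headers.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, loci, sample_ids = rownames(dosages),
                            generation = "unassigned", contig_lengths = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != nrow(dosages)) stop("sample_ids length mismatch")
  generation <- rep_len(as.character(generation), nrow(dosages))
  if (any(is.na(generation) | generation == "")) {
    stop("every sample needs a nonempty generation label")
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns chrom, pos, ref, alt")
  }
  if (nrow(loci) != ncol(dosages)) stop("loci rows must match dosage columns")
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  if (anyDuplicated(loci[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in loci")
  }
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- sample_ids
  rownames(loci) <- NULL
  if (!is.null(contig_lengths)) {
    if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
    miss <- setdiff(unique(loci$chrom), names(contig_lengths))
    if (length(miss)) stop("contig_lengths missing: ", paste(miss, collapse = ", "))
  }
  structure(
    list(dosages = dosages, loci = loci, sample_ids = sample_ids,
         generation = setNames(generation, sample_ids),
         contig_lengths = contig_lengths),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$generation)
  cat(sprintf("genotype_matrix: %d samples x %d loci on %d contig(s)\n",
              n_samples(x), n_loci(x), length(unique(x$loci$chrom))))
  cat("generations:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param gm a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname n_samples
#' @export
n_loci <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix
#'
#' @param gm a \code{genotype_matrix}.
#' @param samples indices, logical mask, or sample ids to keep.
#' @param loci indices or logical mask of loci to keep.
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  if (is.character(samples)) samples <- match(samples, gm$sample_ids)
  if (is.null(loci)) loci <- seq_len(n_loci(gm))
  genotype_matrix(gm$dosages[samples, loci, drop = FALSE],
                  gm$loci[loci, , drop = FALSE],
                  sample_ids = gm$sample_ids[samples],
                  generation = unname(gm$generation[samples]),
                  contig_lengths = gm$contig_lengths)
}

#' Split a genotype matrix by generation label
#' @param gm a \code{genotype_matrix}.
#' @return named list of \code{genotype_matrix}, one per generation.
#' @export
split_by_generation <- function(gm) {
  labs <- unique(unname(gm$generation))
  setNames(lapply(labs, function(g) {
    subset_genotypes(gm, samples = which(unname(gm$generation) == g))
  }), labs)
}

gm_pop_rows <- function(gm, population) {
  if (is.null(population)) return(seq_len(n_samples(gm)))
  rows <- which(unname(gm$generation) == population)
  if (!length(rows)) stop("no samples with generation label '", population, "'")
  rows
}
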