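#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input is parsed with \pkg{vcfR}; only biallelic SNP records (single
#' A/C/G/T REF and ALT) are kept, and diploid GT fields \code{0/0},
#' \code{0/1}, \code{1/1} (phased separators accepted) map to dosages
#' 0, 1, 2 with \code{./.} as missing. Multiallelic or non-SNP records are
#' dropped with a warning reporting the count. The TSV dialect is a header
#' row \code{chrom pos ref alt <sample ids...>} followed by one row per
#' locus with integer dosages (empty or NA = missing).
#'
#' @param path input file.
#' @param format \code{"vcf"}, \code{"tsv"} or \code{"auto"} (by extension).
#' @param labels optional path to a two-column TSV (sample, generation) or a
#'   named character vector assigning a generation label per sample.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  gm <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  if (!is.null(labels)) {
    labs <- if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      read_labels(labels)
    } else labels
    miss <- setdiff(gm$sample_ids, names(labs))
    if (length(miss)) stop("labels missing for samples: ", paste(miss, collapse = ", "))
    gm$generation <- setNames(unname(labs[gm$sample_ids]), gm$sample_ids)
  }
  gm
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_rej <- sum(!snp)
  if (n_rej > 0) {
    warning(sprintf("rejected %d multiallelic or non-SNP record(s)", n_rej))
  }
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  loci <- data.frame(chrom = fix[snp, "CHROM"],
                     pos = as.integer(fix[snp, "POS"]),
                     ref = ref[snp], alt = alt[snp],
                     stringsAsFactors = FALSE)
  contigs <- parse_contig_meta(v@meta)
  genotype_matrix(t(dos), loci, sample_ids = colnames(gt),
                  contig_lengths = contigs)
}

gt_to_dosage <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g %in% c("0/0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1")] <- 2L
  out
}

parse_contig_meta <- function(meta) {
  cl <- grep("^##contig=", meta, value = TRUE)
  if (!length(cl)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", cl)
  has_len <- grepl("length=", cl)
  if (!all(has_len)) return(NULL)
  lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", cl))
  setNames(lens, ids)
}

read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (ncol(tab) < 5 || !all(need %in% names(tab))) {
    stop("malformed dosage TSV: expected columns chrom, pos, ref, alt, <samples>")
  }
  samp <- setdiff(names(tab), need)
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  genotype_matrix(dos, tab[, need], sample_ids = samp)
}

#' Read a sample-to-generation label table
#' @param path TSV with columns \code{sample} and \code{generation} (a
#'   headerless two-column file is also accepted).
#' @return named character vector, generation keyed by sample id.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  if (!all(c("sample", "generation") %in% names(tab))) {
    tab <- read.delim(path, stringsAsFactors = FALSE, header = FALSE)
    names(tab)[1:2] <- c("sample", "generation")
  }
  setNames(as.character(tab$generation), as.character(tab$sample))
}

#' Write a genotype matrix as VCFv4.2
#'
#' One biallelic SNP per record, GT-only FORMAT, contig lengths in the
#' header (taken from the object, or the maximum observed position per
#' chromosome when absent).
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param path output file (plain text).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path) {
  lens <- gm$contig_lengths
  if (is.null(lens)) {
    lens <- tapply(gm$loci$pos, gm$loci$chrom, max)
    lens <- setNames(as.numeric(lens), names(lens))
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=hatchscan",
              sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n_loci(gm), n_samples(gm))
  ok <- !is.na(t(gm$dosages))
  gt[ok] <- code[t(gm$dosages)[ok] + 1L]
  body <- paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix in the dosage TSV dialect
#' @inheritParams write_vcf
#' @return \code{path}, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  tab <- cbind(gm$loci, as.data.frame(t(gm$dosages), check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample-to-generation labels
#' @inheritParams write_vcf
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(gm, path) {
  write.table(data.frame(sample = gm$sample_ids,
                         generation = unname(gm$generation)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
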