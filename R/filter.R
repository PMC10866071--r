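#' Filter samples and SNPs by call rate and minor allele frequency
#'
#' Applies the standard marker QC used for reduced-representation genotype
#' panels, in a fixed order: (1) drop samples with call rate at or below
#' \code{sample_call_rate_min}; (2) drop loci with call rate at or below
#' \code{locus_call_rate_min} among the retained samples; (3) recompute
#' allele frequencies on the survivors and drop loci with minor allele
#' frequency at or below \code{maf_min}. All comparisons are strict
#' (a sample or locus survives only if its value exceeds the threshold).
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param sample_call_rate_min,locus_call_rate_min,maf_min thresholds in
#'   [0, 1]; defaults 0.9, 0.9, 0.05.
#' @param maf_per_generation when \code{TRUE}, a locus survives the MAF
#'   stage if its MAF exceeds \code{maf_min} within at least one
#'   generation; the default computes MAF on the pooled samples.
#' @return list with elements \code{gm} (the filtered matrix) and
#'   \code{report} (a \code{filter_report}: counts in/out and removed
#'   items, each with the first failing rule as its reason).
#' @export
filter_dataset <- function(gm, sample_call_rate_min = 0.9,
                           locus_call_rate_min = 0.9, maf_min = 0.05,
                           maf_per_generation = FALSE) {
  for (th in c(sample_call_rate_min, locus_call_rate_min, maf_min)) {
    if (!is.finite(th) || th < 0 || th > 1) stop("thresholds must lie in [0, 1]")
  }
  n_s_in <- n_samples(gm); n_l_in <- n_loci(gm)
  X <- gm$dosages
  called <- !is.na(X)

  scr <- rowMeans(called)
  keep_s <- scr > sample_call_rate_min
  removed_samples <- data.frame(sample = gm$sample_ids[!keep_s],
                                reason = rep("call-rate", sum(!keep_s)),
                                stringsAsFactors = FALSE)
  if (!any(keep_s)) stop("sample call-rate stage removed all samples")
  X2 <- X[keep_s, , drop = FALSE]
  called2 <- called[keep_s, , drop = FALSE]

  lcr <- colMeans(called2)
  keep_cr <- lcr > locus_call_rate_min
  if (!any(keep_cr)) stop("locus call-rate stage removed all loci")

  maf <- locus_maf(X2, if (maf_per_generation) unname(gm$generation[keep_s]) else NULL)
  keep_maf <- !is.na(maf) & maf > maf_min
  keep_l <- keep_cr & keep_maf
  reason_l <- ifelse(!keep_cr, "call-rate", "maf")
  removed_loci <- data.frame(index = which(!keep_l),
                             chrom = gm$loci$chrom[!keep_l],
                             pos = gm$loci$pos[!keep_l],
                             reason = reason_l[!keep_l],
                             stringsAsFactors = FALSE)
  if (!any(keep_l)) stop("MAF stage removed all loci")

  out <- subset_genotypes(gm, samples = which(keep_s), loci = which(keep_l))
  report <- structure(
    list(n_samples_in = n_s_in, n_samples_out = n_samples(out),
         n_loci_in = n_l_in, n_loci_out = n_loci(out),
         removed_samples = removed_samples, removed_loci = removed_loci,
         thresholds = list(sample_call_rate_min = sample_call_rate_min,
                           locus_call_rate_min = locus_call_rate_min,
                           maf_min = maf_min,
                           maf_per_generation = maf_per_generation)),
    class = "filter_report")
  list(gm = out, report = report)
}

locus_maf <- function(X, generation = NULL) {
  one_maf <- function(M) {
    p <- colMeans(M, na.rm = TRUE) / 2
    p[is.nan(p)] <- NA_real_
    pmin(p, 1 - p)
  }
  if (is.null(generation)) return(one_maf(X))
  per <- vapply(unique(generation),
                function(g) one_maf(X[generation == g, , drop = FALSE]),
                numeric(ncol(X)))
  apply(as.matrix(per), 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: samples %d -> %d, loci %d -> %d\n",
              x$n_samples_in, x$n_samples_out, x$n_loci_in, x$n_loci_out))
  if (nrow(x$removed_loci)) {
    cat("loci removed by reason:\n")
    print(table(x$removed_loci$reason))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param report a \code{filter_report} from \code{\link{filter_dataset}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
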