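#' Assemble the windowed log2 theta-pi-ratio x Fst scan table
#'
#' Joins windowed nucleotide diversity of the ancestral and derived
#' populations with windowed Fst on a shared grid and computes
#' log2(pi_ancestral / pi_derived), so that diversity loss in the derived
#' line gives large positive values. Windows where either diversity is
#' zero or Fst is undefined are marked unusable with a reason code and are
#' excluded from threshold estimation.
#'
#' @param pi_anc,pi_der outputs of \code{\link{window_pi}} for the
#'   ancestral and derived populations (same window grid).
#' @param fst_win the \code{per_window} table of \code{\link{wc_fst}} on
#'   the same grid.
#' @return data.frame of class \code{scan_table}: chrom, start, end,
#'   pi_anc, pi_der, log2_pi_ratio, fst, usable, reason.
#' @export
pi_ratio_scan <- function(pi_anc, pi_der, fst_win) {
  key <- c("chrom", "start", "end")
  if (!identical(pi_anc[key], pi_der[key]) || !identical(pi_anc[key], fst_win[key])) {
    stop("window grids do not match")
  }
  out <- pi_anc[key]
  out$pi_anc <- pi_anc$pi
  out$pi_der <- pi_der$pi
  out$fst <- fst_win$fst
  out$log2_pi_ratio <- ifelse(out$pi_anc > 0 & out$pi_der > 0,
                              log2(out$pi_anc / out$pi_der), NA_real_)
  out$reason <- ""
  out$reason[out$pi_der == 0] <- "pi_der_zero"
  out$reason[out$pi_anc == 0] <- "pi_anc_zero"
  out$reason[out$pi_anc == 0 & out$pi_der == 0] <- "no_variants"
  out$reason[out$reason == "" & is.na(out$fst)] <- "fst_undefined"
  out$usable <- out$reason == ""
  class(out) <- c("scan_table", class(out))
  out
}

#' Classify windows by joint empirical quantiles
#'
#' A window is under putative positive selection when its log2 pi ratio
#' exceeds the (1-q) empirical quantile and its Fst exceeds the (1-q)
#' quantile; under negative selection when the ratio is below the q
#' quantile with the same Fst condition. Quantiles are computed over
#' usable windows with the linear-interpolation convention
#' (\code{stats::quantile} type 7) and the comparisons are strict.
#'
#' @param scan a \code{scan_table} from \code{\link{pi_ratio_scan}}.
#' @param q tail probability (default 0.05, i.e. top-5 percent cutoffs).
#' @return list with \code{thresholds} (q_hi_ratio, q_lo_ratio, q_hi_fst,
#'   q) and \code{table} (the scan table with a \code{class} column:
#'   "positive", "negative", "none", or NA for unusable windows).
#' @export
classify_windows <- function(scan, q = 0.05) {
  u <- scan$usable
  if (sum(u) < 1 / q) {
    warning(sprintf("only %d usable windows for quantiles at q = %g", sum(u), q))
  }
  ratio <- scan$log2_pi_ratio[u]
  fst <- scan$fst[u]
  thr <- list(q_hi_ratio = unname(quantile(ratio, 1 - q, type = 7)),
              q_lo_ratio = unname(quantile(ratio, q, type = 7)),
              q_hi_fst = unname(quantile(fst, 1 - q, type = 7)),
              q = q)
  cls <- rep(NA_character_, nrow(scan))
  cls[u] <- "none"
  pos <- u & scan$log2_pi_ratio > thr$q_hi_ratio & scan$fst > thr$q_hi_fst
  neg <- u & scan$log2_pi_ratio < thr$q_lo_ratio & scan$fst > thr$q_hi_fst
  cls[pos] <- "positive"
  cls[neg] <- "negative"
  scan$class <- cls
  list(thresholds = thr, table = scan)
}

#' Merge classified windows into candidate selection regions
#'
#' Overlapping or bookended windows of the same class on the same
#' chromosome are merged into regions; windows of opposite class are never
#' merged. Both granularities are reported: the per-class significant
#' window counts (attribute \code{window_counts}) and the merged regions.
#'
#' @param classified the \code{table} element of
#'   \code{\link{classify_windows}}.
#' @return data.frame with columns chrom, start, end, class, n_windows,
#'   max_fst, extreme_log2_ratio; attribute \code{window_counts}.
#' @export
merge_regions <- function(classified) {
  sig <- classified[!is.na(classified$class) &
                      classified$class %in% c("positive", "negative"), , drop = FALSE]
  counts <- c(positive = sum(sig$class == "positive"),
              negative = sum(sig$class == "negative"))
  out <- list()
  for (cl in c("positive", "negative")) {
    w <- sig[sig$class == cl, , drop = FALSE]
    if (!nrow(w)) next
    w <- w[order(w$chrom, w$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                      w$start[-1] > w$end[-nrow(w)] + 1))
    for (g in unique(grp)) {
      m <- w[grp == g, , drop = FALSE]
      ratio <- m$log2_pi_ratio
      out[[length(out) + 1]] <- data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        class = cl, n_windows = nrow(m), max_fst = max(m$fst),
        extreme_log2_ratio = if (cl == "positive") max(ratio) else min(ratio),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               class = character(0), n_windows = integer(0),
               max_fst = numeric(0), extreme_log2_ratio = numeric(0))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "window_counts") <- counts
  res
}

#' Permutation test for window Fst
#'
#' Pools the samples of the two populations, redraws B random relabelings
#' preserving the group sizes, recomputes the window's weighted
#' Weir-Cockerham Fst each time, and reports
#' p = (1 + #\{Fst_perm >= Fst_obs\}) / (B + 1), so p can never be 0.
#'
#' @param gm a filtered \code{\link{genotype_matrix}} containing both
#'   populations.
#' @param pop_a,pop_b generation labels.
#' @param window a single-row data.frame (or list) with chrom, start, end.
#' @param B number of permutations (at least 19, default 1000).
#' @param seed integer seed.
#' @param statistic \code{"fst"} (default) permutes the window's weighted
#'   Fst alone; \code{"joint"} counts permutations in which both the Fst
#'   and the window's log2 diversity ratio (ancestral/derived, by
#'   magnitude) reach their observed values.
#' @return list with \code{p}, \code{fst_obs}, \code{B}.
#' @export
permutation_test <- function(gm, pop_a, pop_b, window, B = 1000, seed = NULL,
                             statistic = c("fst", "joint")) {
  statistic <- match.arg(statistic)
  if (B < 19) stop("B must be at least 19 to resolve p < 0.05")
  if (!is.null(seed)) set.seed(seed)
  cols <- which(gm$loci$chrom == window$chrom[1] &
                  gm$loci$pos >= window$start[1] & gm$loci$pos <= window$end[1])
  if (!length(cols)) stop("window contains no loci")
  ra <- gm_pop_rows(gm, pop_a)
  rb <- gm_pop_rows(gm, pop_b)
  X <- gm$dosages[c(ra, rb), cols, drop = FALSE]
  na <- length(ra)
  n <- nrow(X)
  win_fst <- function(ia) {
    comp <- wc_components(X[ia, , drop = FALSE], X[-ia, , drop = FALSE])
    abc <- comp$a + comp$b + comp$c
    ok <- comp$ok & !is.na(abc)
    if (!any(ok)) return(NA_real_)
    sum(comp$a[ok]) / sum(abc[ok])
  }
  win_lratio <- function(ia) {
    pa <- sum(site_pi_components(X[ia, , drop = FALSE])$pi)
    pb <- sum(site_pi_components(X[-ia, , drop = FALSE])$pi)
    if (pa > 0 && pb > 0) abs(log2(pa / pb)) else NA_real_
  }
  obs <- win_fst(seq_len(na))
  if (is.na(obs)) stop("observed window Fst undefined")
  if (statistic == "fst") {
    perm <- vapply(seq_len(B), function(b) win_fst(sample.int(n, na)), numeric(1))
    hits <- sum(perm >= obs, na.rm = TRUE)
  } else {
    obs_r <- win_lratio(seq_len(na))
    hits <- sum(vapply(seq_len(B), function(b) {
      ia <- sample.int(n, na)
      f <- win_fst(ia)
      r <- win_lratio(ia)
      isTRUE(f >= obs) && (is.na(obs_r) || isTRUE(r >= obs_r))
    }, logical(1)))
  }
  list(p = (1 + hits) / (B + 1), fst_obs = obs, B = B)
}

#' Annotate selection regions with overlapping genes
#'
#' Gene intervals are read from GFF3 (records of the given type, 1-based
#' inclusive) or BED via \pkg{rtracklayer}; a gene is assigned to a region
#' when they overlap by at least 1 bp. Gene sets are deduplicated per
#' class across regions.
#'
#' @param regions output of \code{\link{merge_regions}}.
#' @param annotation path to a GFF3 or BED file, or a \code{GRanges}.
#' @param feature_type GFF3 feature type to keep (default "gene"; ignored
#'   for BED input).
#' @return list with \code{regions} (the input plus a \code{genes}
#'   comma-separated column and \code{n_genes}), \code{genes_by_class}
#'   (named list of unique gene ids), and \code{n_genes_by_class}.
#' @export
annotate_regions <- function(regions, annotation, feature_type = "gene") {
  genes <- if (methods::is(annotation, "GRanges")) annotation else {
    gr <- rtracklayer::import(annotation)
    if (!is.null(gr$type) && any(gr$type == feature_type)) {
      gr[gr$type == feature_type]
    } else gr
  }
  ids <- gene_ids(genes)
  if (nrow(regions) == 0) {
    return(list(regions = cbind(regions, genes = character(0), n_genes = integer(0)),
                genes_by_class = list(positive = character(0), negative = character(0)),
                n_genes_by_class = c(positive = 0L, negative = 0L)))
  }
  unmatched <- setdiff(unique(regions$chrom),
                       as.character(GenomicRanges::seqnames(genes)))
  if (length(unmatched)) {
    warning(sprintf("%d region chromosome(s) absent from annotation: %s",
                    length(unmatched), paste(unmatched, collapse = ", ")))
  }
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rgr, genes))
  per_region <- split(ids[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  regions$genes <- vapply(per_region, function(g) paste(unique(g), collapse = ","),
                          character(1))
  regions$n_genes <- vapply(per_region, function(g) length(unique(g)), integer(1))
  by_class <- lapply(setNames(c("positive", "negative"), c("positive", "negative")),
                     function(cl) {
                       sel <- which(regions$class == cl)
                       unique(unlist(per_region[sel], use.names = FALSE))
                     })
  list(regions = regions, genes_by_class = by_class,
       n_genes_by_class = vapply(by_class, length, integer(1)))
}

gene_ids <- function(gr) {
  md <- S4Vectors::mcols(gr)
  for (col in c("ID", "Name", "name", "gene_id", "locus_tag")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      return(as.character(md[[col]]))
    }
  }
  paste0(GenomicRanges::seqnames(gr), ":", GenomicRanges::start(gr))
}
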