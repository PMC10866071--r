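#' Per-locus allele-frequency and heterozygosity statistics
#'
#' For each locus (and each generation when \code{group_by_generation}) the
#' alternate-allele frequency p, minor allele frequency, observed
#' heterozygote fraction Ho, Hardy-Weinberg expected heterozygosity
#' He = 2p(1-p), and the per-locus inbreeding coefficient
#' Fis = 1 - Ho/He, all computed from called genotypes only. A population
#' with zero called genotypes at a locus gets \code{NA} for every
#' statistic, never a conventional zero.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @param group_by_generation compute within each generation label instead
#'   of on the pooled samples.
#' @param unbiased_he multiply He by n/(n-1) (n = called allele copies);
#'   the default reports the uncorrected 2pq used by genotype toolkits.
#' @return data.frame with columns population, chrom, pos,
#'   n_called_copies, p_alt, maf, ho, he, fis_locus.
#' @export
locus_statistics <- function(gm, group_by_generation = FALSE,
                             unbiased_he = FALSE) {
  pops <- if (group_by_generation) unique(unname(gm$generation)) else "all"
  out <- lapply(pops, function(pop) {
    rows <- if (identical(pop, "all")) seq_len(n_samples(gm)) else gm_pop_rows(gm, pop)
    X <- gm$dosages[rows, , drop = FALSE]
    n_gt <- colSums(!is.na(X))
    n_cp <- 2L * n_gt
    p <- colSums(X, na.rm = TRUE) / n_cp
    p[n_cp == 0] <- NA_real_
    he <- 2 * p * (1 - p)
    if (unbiased_he) he <- he * ifelse(n_cp > 1, n_cp / (n_cp - 1), NA_real_)
    ho <- colMeans(X == 1L, na.rm = TRUE)
    ho[n_gt == 0] <- NA_real_
    data.frame(population = pop, chrom = gm$loci$chrom, pos = gm$loci$pos,
               n_called_copies = n_cp, p_alt = p, maf = pmin(p, 1 - p),
               ho = ho, he = he,
               fis_locus = ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Method-of-moments individual inbreeding coefficients
#'
#' The excess-homozygosity statistic F = (O - E)/(L - E) per sample, where
#' O is the observed homozygote count over the sample's called loci, L the
#' number of called loci, and E the expected homozygote count
#' sum over loci of 1 - 2pq * n/(n-1), with p estimated from the chosen
#' population and n the called allele copies at the locus.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @param population generation label defining both the samples scored and
#'   the allele-frequency reference; \code{NULL} uses all samples.
#' @return data.frame with columns sample, generation, observed_hom,
#'   expected_hom, n_loci_used, F. Samples with zero called loci are
#'   dropped with a warning. The population-level Fis is \code{mean(F)}.
#' @export
individual_inbreeding <- function(gm, population = NULL) {
  rows <- gm_pop_rows(gm, population)
  X <- gm$dosages[rows, , drop = FALSE]
  called <- !is.na(X)
  n_cp <- 2 * colSums(called)
  p <- colSums(X, na.rm = TRUE) / n_cp
  exp_het <- ifelse(n_cp > 1, 2 * p * (1 - p) * n_cp / (n_cp - 1), 0)
  e_hom <- 1 - exp_het
  obs_hom <- rowSums(X != 1L, na.rm = TRUE)
  e_sum <- as.numeric(called %*% e_hom)
  l_used <- rowSums(called)
  keep <- l_used > 0
  if (!all(keep)) warning(sprintf("%d sample(s) with zero called loci excluded", sum(!keep)))
  data.frame(sample = gm$sample_ids[rows][keep],
             generation = unname(gm$generation[rows])[keep],
             observed_hom = obs_hom[keep], expected_hom = e_sum[keep],
             n_loci_used = l_used[keep],
             F = (obs_hom[keep] - e_sum[keep]) / (l_used[keep] - e_sum[keep]),
             stringsAsFactors = FALSE)
}

#' Transition/transversion spectrum
#'
#' Counts substitution classes over the unordered ref/alt allele pairs:
#' A/G and C/T are transitions; A/T, A/C, G/T and G/C transversions.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @return list with \code{counts} (named vector over the six classes),
#'   \code{percent}, \code{ts}, \code{tv}, and \code{ratio}
#'   (ts/tv; \code{Inf} when no transversions).
#' @export
tstv_spectrum <- function(gm) {
  pair <- paste(pmin(gm$loci$ref, gm$loci$alt), pmax(gm$loci$ref, gm$loci$alt), sep = "/")
  classes <- c("A/G", "C/T", "A/T", "A/C", "G/T", "C/G")
  counts <- setNames(integer(6), classes)
  tab <- table(pair)
  counts[names(tab)[names(tab) %in% classes]] <- tab[names(tab) %in% classes]
  ts <- sum(counts[c("A/G", "C/T")])
  tv <- sum(counts[c("A/T", "A/C", "G/T", "C/G")])
  list(counts = counts, percent = 100 * counts / sum(counts),
       ts = ts, tv = tv, ratio = if (tv == 0) Inf else ts / tv)
}

#' Build a sliding window grid
#'
#' Windows start at 1, 1+step, 1+2*step, ... on each chromosome. Full-size
#' windows are kept while they fit on the contig; when the last full window
#' does not reach the contig end, one trailing truncated window is added so
#' the grid covers every base (a contig shorter than \code{size} yields a
#' single truncated window).
#'
#' @param contig_lengths named vector of chromosome lengths in bp.
#' @param size window size in bp (default 40000).
#' @param step distance between window starts (default 20000,
#'   i.e. half-overlapping windows); must satisfy \code{size >= step >= 1}.
#' @return data.frame with columns chrom, start, end, length (1-based,
#'   inclusive).
#' @export
make_windows <- function(contig_lengths, size = 40000, step = 20000) {
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  if (!(size >= step && step >= 1)) stop("need size >= step >= 1")
  out <- lapply(names(contig_lengths), function(chr) {
    len <- contig_lengths[[chr]]
    n_full <- if (len >= size) (len - size) %/% step + 1 else 0
    starts <- if (n_full > 0) 1 + step * (seq_len(n_full) - 1) else numeric(0)
    ends <- starts + size - 1
    if (n_full == 0 || max(ends) < len) {
      starts <- c(starts, 1 + step * n_full)
      ends <- c(ends, len)
    }
    data.frame(chrom = chr, start = as.integer(starts), end = as.integer(ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$length <- out$end - out$start + 1L
  out
}

# locus indices per window (a locus can fall in several overlapping windows)
window_members <- function(windows, loci) {
  idx <- split(seq_len(nrow(loci)), loci$chrom)
  pos <- split(loci$pos, loci$chrom)
  lapply(seq_len(nrow(windows)), function(i) {
    chr <- windows$chrom[i]
    p <- pos[[chr]]
    if (is.null(p)) return(integer(0))
    idx[[chr]][p >= windows$start[i] & p <= windows$end[i]]
  })
}

# per-site unbiased pairwise diversity and allele copy counts for one population
site_pi_components <- function(X) {
  n_cp <- 2 * colSums(!is.na(X))
  c_alt <- colSums(X, na.rm = TRUE)
  c_ref <- n_cp - c_alt
  pi <- ifelse(n_cp > 1, 2 * c_ref * c_alt / (n_cp * (n_cp - 1)), 0)
  list(pi = pi, n_cp = n_cp, seg = c_alt > 0 & c_alt < n_cp)
}

#' Windowed nucleotide diversity
#'
#' Per segregating site the unbiased pairwise diversity
#' 2*c_ref*c_alt / (n*(n-1)) is computed from called allele copies; window
#' diversity is the sum of site values divided by the window length in bp
#' (\code{per_bp = FALSE} returns the raw sum). Windows with no called
#' variant sites get 0 with \code{n_variant_sites = 0}.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @param windows a window grid from \code{\link{make_windows}}.
#' @param population generation label; \code{NULL} pools all samples.
#' @param per_bp divide the window sum by window length (default); when
#'   \code{FALSE} the raw sum is returned.
#' @param normalize \code{"length"} (window bp, the convention that makes
#'   magnitudes comparable across marker densities) or \code{"n_sites"}
#'   (genotyped sites in the window, i.e. mean per-site diversity).
#'   Ignored when \code{per_bp = FALSE}.
#' @return \code{windows} with added columns \code{pi} and
#'   \code{n_variant_sites}.
#' @export
window_pi <- function(gm, windows, population = NULL, per_bp = TRUE,
                      normalize = c("length", "n_sites")) {
  normalize <- match.arg(normalize)
  rows <- gm_pop_rows(gm, population)
  comp <- site_pi_components(gm$dosages[rows, , drop = FALSE])
  members <- window_members(windows, gm$loci)
  windows$pi <- vapply(seq_len(nrow(windows)), function(i) {
    s <- sum(comp$pi[members[[i]]])
    if (!per_bp) return(s)
    den <- if (normalize == "length") windows$length[i] else length(members[[i]])
    if (den == 0) 0 else s / den
  }, numeric(1))
  windows$n_variant_sites <- vapply(members, function(m) sum(comp$seg[m]), integer(1))
  windows
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' D = (pi_sum - S/a1) / sqrt(e1*S + e2*S*(S-1)) with the Tajima (1989)
#' constants computed from the sample size n, where pi_sum is the window
#' sum of per-site pairwise diversity and S the number of segregating
#' sites. Because missingness lets n vary between sites, n is taken as the
#' modal called allele-copy count over the window's segregating sites;
#' windows with S = 0 or n < 3 are undefined (\code{NA}).
#'
#' @inheritParams window_pi
#' @return \code{windows} with added columns \code{tajima_d}, \code{S} and
#'   \code{n_used}.
#' @export
tajimas_d <- function(gm, windows, population = NULL) {
  rows <- gm_pop_rows(gm, population)
  comp <- site_pi_components(gm$dosages[rows, , drop = FALSE])
  members <- window_members(windows, gm$loci)
  res <- vapply(members, function(m) {
    seg <- m[comp$seg[m]]
    S <- length(seg)
    if (S == 0) return(c(NA_real_, 0, NA_real_))
    ns <- comp$n_cp[seg]
    n <- as.numeric(names(sort(-table(ns)))[1])
    if (n < 3) return(c(NA_real_, S, n))
    k <- tajima_constants(n)
    d <- (sum(comp$pi[seg]) - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    c(d, S, n)
  }, numeric(3))
  windows$tajima_d <- res[1, ]
  windows$S <- as.integer(res[2, ])
  windows$n_used <- res[3, ]
  windows
}

# Weir & Cockerham (1984) two-population variance components per locus.
# X1, X2: dosage matrices (samples x loci) of the two populations.
wc_components <- function(X1, X2) {
  stat <- function(X) {
    n <- colSums(!is.na(X))
    p <- ifelse(n > 0, colSums(X, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colMeans(X == 1L, na.rm = TRUE), NA_real_)
    list(n = n, p = p, h = h)
  }
  s1 <- stat(X1); s2 <- stat(X2)
  ok <- s1$n >= 2 & s2$n >= 2
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * s1$p + n2 * s2$p) / (n1 + n2)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / nbar
  hbar <- (n1 * s1$h + n2 * s2$h) / (n1 + n2)
  pq <- pbar * (1 - pbar)
  a <- nbar / nc * (s2v - (pq - s2v / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pq - s2v / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc, ok = ok)
}

#' Weir-Cockerham Fst between two populations
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) of the
#' Weir & Cockerham (1984) estimator, computed from called genotypes and
#' observed heterozygote frequencies. A locus contributes only when both
#' populations have at least two called genotypes. The weighted (ratio of
#' sums) estimate sum(a)/sum(a+b+c) is reported per window and overall;
#' negative estimates are retained, not clamped.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @param pop_a,pop_b generation labels of the two populations.
#' @param windows optional window grid; when given, per-window weighted
#'   Fst with its retained component sums is returned as well.
#' @return list with \code{per_locus} (chrom, pos, a, b, c, theta),
#'   \code{overall} (weighted Fst across all contributing loci), and, when
#'   \code{windows} is supplied, \code{per_window} (windows plus
#'   \code{sum_a}, \code{sum_abc}, \code{fst}, \code{n_loci}; windows with
#'   no contributing loci are \code{NA}).
#' @export
wc_fst <- function(gm, pop_a, pop_b, windows = NULL) {
  X1 <- gm$dosages[gm_pop_rows(gm, pop_a), , drop = FALSE]
  X2 <- gm$dosages[gm_pop_rows(gm, pop_b), , drop = FALSE]
  comp <- wc_components(X1, X2)
  abc <- comp$a + comp$b + comp$c
  per_locus <- data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                          a = comp$a, b = comp$b, c = comp$c,
                          theta = ifelse(!is.na(abc) & abc != 0, comp$a / abc, NA_real_),
                          stringsAsFactors = FALSE)
  contrib <- comp$ok & !is.na(abc)
  if (!any(contrib)) stop("no contributing loci for Fst between '",
                          pop_a, "' and '", pop_b, "'")
  out <- list(per_locus = per_locus,
              overall = sum(comp$a[contrib]) / sum(abc[contrib]))
  if (!is.null(windows)) {
    members <- window_members(windows, gm$loci)
    res <- vapply(members, function(m) {
      m <- m[contrib[m]]
      if (!length(m)) return(c(NA_real_, NA_real_, NA_real_, 0))
      sa <- sum(comp$a[m]); sabc <- sum(abc[m])
      c(sa, sabc, if (sabc != 0) sa / sabc else NA_real_, length(m))
    }, numeric(4))
    windows$sum_a <- res[1, ]
    windows$sum_abc <- res[2, ]
    windows$fst <- res[3, ]
    windows$n_loci <- as.integer(res[4, ])
    out$per_window <- windows
  }
  out
}

#' Per-generation diversity summary table
#'
#' Means over loci (and windows) of the headline diversity indices:
#' sample size, MAF, Ho, He, Fis (mean individual F) and windowed
#' nucleotide diversity per bp.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @param windows optional window grid for the pi column.
#' @return data.frame with one row per generation.
#' @export
diversity_summary <- function(gm, windows = NULL) {
  ls <- locus_statistics(gm, group_by_generation = TRUE)
  pops <- unique(unname(gm$generation))
  rows <- lapply(pops, function(pop) {
    sub <- ls[ls$population == pop, ]
    f <- individual_inbreeding(gm, pop)
    data.frame(generation = pop, n = sum(unname(gm$generation) == pop),
               maf = mean(sub$maf, na.rm = TRUE),
               ho = mean(sub$ho, na.rm = TRUE),
               he = mean(sub$he, na.rm = TRUE),
               fis = mean(f$F),
               pi = if (is.null(windows)) NA_real_ else
                 mean(window_pi(gm, windows, pop)$pi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
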