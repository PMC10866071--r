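#' Genomic relationship matrix
#'
#' The allele-frequency standardized relationship
#' G_ij = (1/m_ij) * sum_k (x_ik - 2p_k)(x_jk - 2p_k) / (2 p_k (1 - p_k)),
#' with x the dosage, p the pooled alternate-allele frequency, and m_ij the
#' number of loci called in both samples (pairwise-complete). Monomorphic
#' loci are excluded. For an outbred population in Hardy-Weinberg
#' proportions the diagonal averages about 1.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @return symmetric samples x samples matrix with attribute
#'   \code{m_used} (per-pair locus counts).
#' @export
relationship_matrix <- function(gm) {
  X <- gm$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(X)) stop("no polymorphic loci for relationship matrix")
  Z <- sweep(X, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(X))
  called <- !is.na(Z)
  Z[!called] <- 0
  m_used <- tcrossprod(called * 1)
  if (any(m_used == 0)) stop("sample pair with zero shared called loci")
  G <- tcrossprod(Z) / m_used
  dimnames(G) <- list(gm$sample_ids, gm$sample_ids)
  attr(G, "m_used") <- m_used
  G
}

#' Principal components of a relationship matrix
#'
#' Top-k eigenpairs of a genomic relationship matrix; the coordinates are
#' the eigenvectors and each variance fraction is eigenvalue / trace(G).
#' Eigenvector signs follow a fixed convention (the largest-magnitude
#' loading is positive) so results are reproducible.
#'
#' @param G a relationship matrix, e.g. from
#'   \code{\link{relationship_matrix}}.
#' @param k number of components, 1 <= k < nrow(G).
#' @return list with \code{coords} (samples x k), \code{varfrac}
#'   (length k), and \code{values} (all eigenvalues).
#' @export
pca <- function(G, k = 2) {
  if (any(!is.finite(G))) stop("non-finite entries in relationship matrix")
  if (k < 1 || k >= nrow(G)) stop("need 1 <= k < number of samples")
  e <- eigen(G, symmetric = TRUE)
  coords <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords,
       varfrac = e$values[seq_len(k)] / sum(diag(G)),
       values = e$values)
}

#' Identity-by-state distance matrix
#'
#' d_ij = 1 - (shared allele count) / (2 * co-called loci), where per locus
#' the shared count is 2 - |x_i - x_j|: identical genotypes (including two
#' heterozygotes) share both alleles, a homozygote and a heterozygote
#' share one, and opposite homozygotes share none. Identical samples are
#' therefore at distance zero.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @return symmetric distance matrix in [0, 1].
#' @export
ibs_distance <- function(gm) {
  X <- gm$dosages
  H0 <- (!is.na(X) & X == 0L) * 1
  H1 <- (!is.na(X) & X == 1L) * 1
  H2 <- (!is.na(X) & X == 2L) * 1
  called <- (H0 + H1 + H2)
  m <- tcrossprod(called)
  if (any(m == 0)) stop("sample pair with zero co-called loci")
  shared <- 2 * tcrossprod(H0) + 2 * tcrossprod(H2) + 2 * tcrossprod(H1) +
    tcrossprod(H0, H1) + tcrossprod(H1, H0) +
    tcrossprod(H1, H2) + tcrossprod(H2, H1)
  d <- 1 - shared / (2 * m)
  dimnames(d) <- list(gm$sample_ids, gm$sample_ids)
  d
}

#' Neighbor-joining tree with optional bootstrap over loci
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a distance matrix.
#' When a genotype matrix is supplied, clade support is estimated by
#' resampling loci with replacement, recomputing the IBS distance and the
#' tree, and counting clade recovery; supports are attached as node labels
#' (percent of replicates).
#'
#' @param d symmetric distance matrix (at least 3 taxa).
#' @param gm optional \code{\link{genotype_matrix}} for bootstrapping; must
#'   contain the same samples as \code{d}.
#' @param bootstrap_n bootstrap replicates (0 = none; 1000 is the
#'   conventional choice).
#' @param seed integer seed for the resampling.
#' @return list with \code{tree} (an \pkg{ape} \code{phylo}),
#'   \code{newick}, and \code{support} (counts per internal node, or
#'   \code{NULL}).
#' @export
nj_tree <- function(d, gm = NULL, bootstrap_n = 0, seed = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(d < 0)) stop("distances must be nonnegative")
  tree <- ape::nj(stats::as.dist(d))
  support <- NULL
  if (bootstrap_n > 0 && !is.null(gm)) {
    if (!is.null(seed)) set.seed(seed)
    boots <- lapply(seq_len(bootstrap_n), function(b) {
      idx <- sample.int(n_loci(gm), n_loci(gm), replace = TRUE)
      # duplicate coordinates are fine for a resampled distance; bypass the
      # constructor and reuse the IBS kernel directly
      sub <- gm
      sub$dosages <- gm$dosages[, idx, drop = FALSE]
      sub$loci <- gm$loci[idx, , drop = FALSE]
      ape::nj(stats::as.dist(ibs_distance(sub)))
    })
    support <- ape::prop.clades(tree, boots, rooted = FALSE)
    support[is.na(support)] <- 0
    tree$node.label <- round(100 * support / bootstrap_n)
  }
  list(tree = tree, newick = ape::write.tree(tree), support = support)
}

#' Linkage-disequilibrium decay
#'
#' For every same-chromosome locus pair separated by at most
#' \code{max_dist} bp, r^2 is the squared Pearson correlation of dosages
#' over co-called samples; pairs with zero dosage variance are skipped and
#' counted. Mean r^2 is reported in distance bins.
#'
#' @param gm a filtered \code{\link{genotype_matrix}}.
#' @param max_dist maximum pair distance in bp (default 50000).
#' @param bin_width distance bin width in bp (default 500).
#' @return data.frame with columns bin_lo, bin_hi, mid, mean_r2, n_pairs;
#'   attribute \code{n_skipped} counts zero-variance pairs.
#' @export
ld_decay <- function(gm, max_dist = 50000, bin_width = 500) {
  X <- gm$dosages
  dist_all <- numeric(0)
  r2_all <- numeric(0)
  skipped <- 0L
  for (chr in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == chr)
    pos <- gm$loci$pos[idx]
    hi <- findInterval(pos + max_dist, pos)
    for (ii in seq_along(idx)) {
      if (hi[ii] <= ii) next
      for (jj in seq(ii + 1, hi[ii])) {
        x <- X[, idx[ii]]; y <- X[, idx[jj]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) {
          skipped <- skipped + 1L
          next
        }
        r2_all <- c(r2_all, cor(x[ok], y[ok])^2)
        dist_all <- c(dist_all, pos[jj] - pos[ii])
      }
    }
  }
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  bin <- cut(dist_all, breaks, include.lowest = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$mid <- (out$bin_lo + out$bin_hi) / 2
  out$mean_r2 <- as.numeric(tapply(r2_all, bin, mean))[seq_len(nrow(out))]
  np <- table(bin)
  out$n_pairs <- as.integer(np)[seq_len(nrow(out))]
  out$n_pairs[is.na(out$n_pairs)] <- 0L
  attr(out, "n_skipped") <- skipped
  out
}
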