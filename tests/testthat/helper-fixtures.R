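# small genotype matrices built in code for unit tests

toy_gm <- function(dosages, chrom = "chr1", pos = NULL, generation = "G0",
                   contig_lengths = NULL) {
  dosages <- as.matrix(dosages)
  L <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  loci <- data.frame(chrom = rep_len(chrom, L), pos = pos,
                     ref = rep_len("A", L), alt = rep_len("G", L),
                     stringsAsFactors = FALSE)
  genotype_matrix(dosages, loci, generation = generation,
                  contig_lengths = contig_lengths)
}

# two-population matrix: rows of A then rows of B, one chromosome
two_pop_gm <- function(dosA, dosB, pos = NULL) {
  toy_gm(rbind(as.matrix(dosA), as.matrix(dosB)),
         pos = pos,
         generation = rep(c("A", "B"), c(nrow(as.matrix(dosA)), nrow(as.matrix(dosB)))))
}

# HWE genotypes at given allele frequencies
hwe_gm <- function(n, freqs, generation = "G0", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dos <- vapply(freqs, function(p) rbinom(n, 2, p), numeric(n))
  toy_gm(dos, generation = generation)
}

# brute-force pi: average pairwise difference count over all allele pairs
bruteforce_window_pi <- function(dosages, window_length) {
  total <- 0
  for (j in seq_len(ncol(as.matrix(dosages)))) {
    x <- as.matrix(dosages)[, j]
    alleles <- unlist(lapply(x[!is.na(x)], function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
      diffs <- diffs + (alleles[a] != alleles[b])
    }
    total <- total + diffs / choose(n, 2)
  }
  total / window_length
}

# independent Tajima's D evaluation (direct transcription of the published
# constants, kept separate from the package implementation)
oracle_tajima_d <- function(n, S, pi_sum) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# hand-computed Weir-Cockerham components for one locus, two populations,
# from genotype counts (n00, n01, n11) per population
oracle_wc <- function(cA, cB) {
  stat <- function(cc) {
    n <- sum(cc)
    p <- (2 * cc[3] + cc[2]) / (2 * n)
    h <- cc[2] / n
    list(n = n, p = p, h = h)
  }
  s1 <- stat(cA); s2 <- stat(cB)
  r <- 2
  nbar <- (s1$n + s2$n) / 2
  nc <- (s1$n + s2$n - (s1$n^2 + s2$n^2) / (s1$n + s2$n)) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / (s1$n + s2$n)
  s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / (s1$n + s2$n)
  a <- nbar / nc * (s2v - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2v * (r - 1) / r -
                              hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# genotype matrix from genotype counts (n00, n01, n11) per population
counts_gm <- function(cA, cB) {
  dosA <- rep(c(0, 1, 2), cA)
  dosB <- rep(c(0, 1, 2), cB)
  two_pop_gm(matrix(dosA, ncol = 1), matrix(dosB, ncol = 1))
}
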