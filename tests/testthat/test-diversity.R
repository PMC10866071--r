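test_that("per-locus statistics match direct arithmetic", {
  ls <- locus_statistics(toy_gm(matrix(c(0, 1, 2, 2), 4, 1)))
  expect_equal(ls$p_alt, 0.625)
  expect_equal(ls$maf, 0.375)
  expect_equal(ls$ho, 0.25)
  expect_equal(ls$he, 0.46875)
  expect_equal(ls$fis_locus, 1 - 0.25 / 0.46875, tolerance = 1e-12)

  ls2 <- locus_statistics(toy_gm(matrix(1, 4, 1)))
  expect_equal(ls2$ho, 1)
  expect_equal(ls2$he, 0.5)
  expect_equal(ls2$fis_locus, -1)
})

test_that("a population with no called genotypes is flagged, not zeroed", {
  gm <- toy_gm(rbind(c(0L, NA), c(2L, NA)), generation = "G0")
  ls <- locus_statistics(gm, group_by_generation = TRUE)
  expect_true(is.na(ls$p_alt[2]))
  expect_true(is.na(ls$ho[2]))
  expect_equal(ls$n_called_copies[2], 0)
})

test_that("fully heterozygous samples get negative inbreeding F", {
  dos <- matrix(1L, 4, 50)
  dos[3:4, ] <- rep(c(0L, 2L), 25)  # keep p near 0.5
  f <- individual_inbreeding(toy_gm(dos))
  expect_lt(f$F[1], 0)
  expect_equal(f$F[1], f$F[2])  # duplicated individuals, identical F
})

test_that("mean F is near zero for an exact-HWE-frequency population", {
  set.seed(11)
  gm <- hwe_gm(200, runif(1000, 0.1, 0.9))
  f <- individual_inbreeding(gm)
  expect_lt(abs(mean(f$F)), 0.02)
})

test_that("Ts/Tv spectrum counts unordered allele pairs", {
  loci <- data.frame(chrom = "c", pos = c(1L, 2L, 3L),
                     ref = c("A", "C", "A"), alt = c("G", "T", "T"))
  gm <- genotype_matrix(matrix(0L, 1, 3), loci)
  sp <- tstv_spectrum(gm)
  expect_equal(sp$ts, 2)
  expect_equal(sp$tv, 1)
  expect_equal(sp$ratio, 2)

  gm2 <- genotype_matrix(matrix(0L, 1, 2),
                         data.frame(chrom = "c", pos = 1:2,
                                    ref = c("A", "G"), alt = c("G", "A")))
  expect_equal(tstv_spectrum(gm2)$ratio, Inf)
})

test_that("window grids enumerate as expected", {
  w <- make_windows(c(chrA = 100000))
  expect_equal(nrow(w), 4)
  expect_equal(w$start, c(1, 20001, 40001, 60001))
  expect_equal(w$end, c(40000, 60000, 80000, 100000))

  w2 <- make_windows(c(chrA = 30000))
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(1, 30000))

  w3 <- make_windows(c(chrA = 120000), size = 40000, step = 40000)
  expect_equal(w3$start, c(1, 40001, 80001))
  expect_equal(w3$end, c(40000, 80000, 120000))

  # trailing truncated window appears when full windows stop short
  w4 <- make_windows(c(chrA = 110000))
  expect_equal(nrow(w4), 5)
  expect_equal(w4$end[5], 110000)
  expect_equal(w4$start[5], 80001)

  expect_error(make_windows(c(chrA = -5)), "positive")
  expect_error(make_windows(c(chrA = 1000), size = 10, step = 20), "size >= step")
})

test_that("window pi matches the per-site formula and scales with length", {
  # one site, 8 called copies, 4 alt: site pi = 2*4*4/(8*7) = 16/28
  gm <- toy_gm(matrix(c(2L, 2L, 0L, 0L), 4, 1), pos = 5L,
               contig_lengths = c(chr1 = 40000))
  w <- make_windows(c(chr1 = 40000))
  p <- window_pi(gm, w)
  expect_equal(p$pi, (16 / 28) / 40000)
  expect_equal(p$n_variant_sites, 1)
  p_sum <- window_pi(gm, w, per_bp = FALSE)
  expect_equal(p_sum$pi, 16 / 28)
  expect_equal(window_pi(gm, w, normalize = "n_sites")$pi, 16 / 28)

  # halving the window length doubles per-bp pi
  w2 <- make_windows(c(chr1 = 20000))
  expect_equal(window_pi(gm, w2)$pi[1], 2 * p$pi[1])

  # monomorphic window is exactly zero
  gm0 <- toy_gm(matrix(2L, 4, 3), contig_lengths = c(chr1 = 40000))
  expect_equal(window_pi(gm0, w)$pi, 0)
})

test_that("window pi equals exhaustive pairwise counting (<= 12 copies)", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    L <- sample(1:6, 1)
    dos <- matrix(sample(c(0L, 1L, 2L, NA), n * L, TRUE), n, L)
    if (all(is.na(dos))) next
    gm <- toy_gm(dos, pos = sort(sample.int(30000, L)),
                 contig_lengths = c(chr1 = 30000))
    w <- make_windows(c(chr1 = 30000))
    expect_equal(window_pi(gm, w)$pi[1],
                 bruteforce_window_pi(dos, w$length[1]),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches direct evaluation of the published constants", {
  # n = 10 allele copies (5 diploids), S in {1, 3, 5}
  for (S in c(1L, 3L, 5L)) {
    alt <- c(5L, 2L, 7L, 4L, 8L)[seq_len(S)]
    dos <- vapply(alt, function(a) {
      g <- c(rep(2L, a %/% 2), rep(1L, a %% 2))
      c(g, rep(0L, 5 - length(g)))
    }, integer(5))
    gm <- toy_gm(dos, pos = seq_len(S) * 10L, contig_lengths = c(chr1 = 40000))
    w <- make_windows(c(chr1 = 40000))
    d <- tajimas_d(gm, w)
    pi_sum <- sum(2 * alt * (10 - alt) / (10 * 9))
    expect_equal(d$tajima_d[1], oracle_tajima_d(10, S, pi_sum), tolerance = 1e-12)
    expect_equal(d$S[1], S)
    expect_equal(d$n_used[1], 10)
  }
})

test_that("Tajima's D is undefined without segregating sites or enough copies", {
  gm <- toy_gm(matrix(0L, 5, 2), contig_lengths = c(chr1 = 40000))
  w <- make_windows(c(chr1 = 40000))
  d <- tajimas_d(gm, w)
  expect_true(is.na(d$tajima_d[1]))
  expect_equal(d$S[1], 0)
})

test_that("Tajima's D sign tracks the frequency spectrum", {
  w <- make_windows(c(chr1 = 40000))
  # excess intermediate-frequency variants
  mid <- toy_gm(vapply(1:30, function(j) sample(rep(c(0L, 1L, 2L), c(5, 10, 5))),
                       integer(20)), pos = 1000L + 1:30,
                contig_lengths = c(chr1 = 40000))
  expect_gt(tajimas_d(mid, w)$tajima_d[1], 0)
  # excess singletons
  sing <- matrix(0L, 20, 30)
  for (j in 1:30) sing[sample.int(20, 1), j] <- 1L
  low <- toy_gm(sing, pos = 1000L + 1:30, contig_lengths = c(chr1 = 40000))
  expect_lt(tajimas_d(low, w)$tajima_d[1], 0)
})

test_that("neutral equilibrium windows average Tajima's D near zero", {
  # frequency spectrum approximation: S sites with allele counts drawn
  # proportional to 1/i, genotypes binomial at those frequencies
  set.seed(31)
  n_cop <- 40
  ds <- replicate(200, {
    S <- 12
    i <- sample(seq_len(n_cop - 1), S, TRUE, prob = 1 / seq_len(n_cop - 1))
    dos <- vapply(i, function(cnt) {
      alleles <- sample(c(rep(1L, cnt), rep(0L, n_cop - cnt)))
      alleles[seq(1, n_cop, 2)] + alleles[seq(2, n_cop, 2)]
    }, integer(n_cop / 2))
    gm <- toy_gm(dos, pos = 100L + seq_len(S), contig_lengths = c(chr1 = 40000))
    tajimas_d(gm, make_windows(c(chr1 = 40000)))$tajima_d[1]
  })
  expect_lt(abs(mean(ds)), 0.3)
})

test_that("Weir-Cockerham components match hand-computed toy tables", {
  # five printed genotype-count configurations, (n00, n01, n11) per pop
  cases <- list(list(A = c(10, 0, 0), B = c(0, 0, 10)),
                list(A = c(5, 5, 0), B = c(5, 5, 0)),
                list(A = c(3, 4, 3), B = c(8, 2, 0)),
                list(A = c(0, 10, 0), B = c(5, 0, 5)),
                list(A = c(12, 6, 2), B = c(2, 6, 12)))
  for (cs in cases) {
    gm <- counts_gm(cs$A, cs$B)
    res <- wc_fst(gm, "A", "B")
    ora <- oracle_wc(cs$A, cs$B)
    expect_equal(res$per_locus$a, ora$a, tolerance = 1e-12)
    expect_equal(res$per_locus$b, ora$b, tolerance = 1e-12)
    expect_equal(res$per_locus$c, ora$c, tolerance = 1e-12)
    expect_equal(res$overall, ora$theta, tolerance = 1e-12)
  }
})

test_that("fixed difference gives Fst 1; identical pops give small theta", {
  gm <- counts_gm(c(10, 0, 0), c(0, 0, 10))
  expect_equal(wc_fst(gm, "A", "B")$overall, 1)
  gm2 <- counts_gm(c(5, 5, 0), c(5, 5, 0))
  th <- wc_fst(gm2, "A", "B")$overall
  expect_lt(abs(th), 0.05)
  expect_lte(th, 0)  # identical samples: small negative expected
})

test_that("windowed Fst is the ratio of sums, not the mean of ratios", {
  dosA <- cbind(rep(0L, 10), rep(c(0L, 1L), 5))
  dosB <- cbind(rep(2L, 10), rep(c(0L, 1L), 5))
  gm <- two_pop_gm(dosA, dosB, pos = c(100L, 200L))
  gm$contig_lengths <- c(chr1 = 40000)
  w <- make_windows(c(chr1 = 40000))
  res <- wc_fst(gm, "A", "B", w)
  pl <- res$per_locus
  expect_equal(res$per_window$fst[1],
               sum(pl$a) / sum(pl$a + pl$b + pl$c), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res$per_window$fst[1], mean(pl$theta))))
  # single-locus window: weighted equals per-locus
  w1 <- data.frame(chrom = "chr1", start = 1L, end = 150L, length = 150L)
  expect_equal(wc_fst(gm, "A", "B", w1)$per_window$fst[1], pl$theta[1])
})

test_that("estimators are invariant to sample order and allele-label swap", {
  set.seed(5)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE, prob = c(.35, .3, .3, .05)),
                20, 10)
  gm <- toy_gm(dos, generation = rep(c("A", "B"), each = 10),
               contig_lengths = c(chr1 = 40000))
  w <- make_windows(c(chr1 = 40000))
  perm <- sample(20)
  gp <- subset_genotypes(gm, samples = perm)
  expect_equal(window_pi(gp, w, "A")$pi, window_pi(gm, w, "A")$pi)
  expect_equal(wc_fst(gp, "A", "B", w)$per_window$fst,
               wc_fst(gm, "A", "B", w)$per_window$fst)

  gs <- gm
  gs$dosages <- 2L - gm$dosages
  expect_equal(window_pi(gs, w, "A")$pi, window_pi(gm, w, "A")$pi)
  expect_equal(tajimas_d(gs, w, "A")$tajima_d, tajimas_d(gm, w, "A")$tajima_d)
  expect_equal(wc_fst(gs, "A", "B", w)$per_window$fst,
               wc_fst(gm, "A", "B", w)$per_window$fst)
  lsa <- locus_statistics(gm)
  lsb <- locus_statistics(gs)
  expect_equal(lsb$p_alt, 1 - lsa$p_alt)
  expect_equal(lsb$maf, lsa$maf)
})

test_that("diversity summary reports one row per generation", {
  set.seed(9)
  gm <- hwe_gm(40, runif(50, 0.2, 0.5), generation = rep(c("G0", "G6"), 20))
  gm$contig_lengths <- c(chr1 = 40000)
  s <- diversity_summary(gm, make_windows(c(chr1 = 40000)))
  expect_setequal(s$generation, c("G0", "G6"))
  expect_equal(s$n, c(20, 20))
  expect_true(all(s$he > 0 & s$he <= 0.5))
  expect_true(all(s$pi > 0))
})
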