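make_scan <- function(ratio, fst, chrom = "c1", start = NULL) {
  n <- length(ratio)
  if (is.null(start)) start <- seq(1, by = 20000, length.out = n)
  pi_a <- data.frame(chrom = chrom, start = start, end = start + 39999,
                     length = 40000, pi = 2^ratio * 1e-5, n_variant_sites = 1L)
  pi_d <- pi_a
  pi_d$pi <- 1e-5
  fst_w <- pi_a[, c("chrom", "start", "end")]
  fst_w$fst <- fst
  pi_ratio_scan(pi_a, pi_d, fst_w)
}

test_that("the scan table computes the oriented log2 ratio", {
  pi_a <- data.frame(chrom = "c1", start = 1, end = 40000, length = 40000,
                     pi = 2e-5, n_variant_sites = 2L)
  pi_d <- pi_a; pi_d$pi <- 1e-5
  fst_w <- data.frame(chrom = "c1", start = 1, end = 40000, fst = 0.2)
  sc <- pi_ratio_scan(pi_a, pi_d, fst_w)
  expect_equal(sc$log2_pi_ratio, 1)
  expect_true(sc$usable)

  sc2 <- pi_ratio_scan(pi_a, pi_a, fst_w)
  expect_equal(sc2$log2_pi_ratio, 0)

  pi_d0 <- pi_d; pi_d0$pi <- 0
  sc3 <- pi_ratio_scan(pi_a, pi_d0, fst_w)
  expect_false(sc3$usable)
  expect_equal(sc3$reason, "pi_der_zero")

  pi_b <- pi_a; pi_b$start <- 20001; pi_b$end <- 60000
  expect_error(pi_ratio_scan(pi_a, pi_b, fst_w), "grids")
})

test_that("classification flags exactly the constructed exceedances", {
  set.seed(43)
  ratio <- c(rnorm(99, 0, 0.2), 5)
  fst <- c(runif(99, 0, 0.05), 0.9)
  cl <- classify_windows(make_scan(ratio, fst), q = 0.05)
  expect_equal(sum(cl$table$class == "positive"), 1)
  expect_equal(which(cl$table$class == "positive"), 100)
  expect_equal(cl$thresholds$q_hi_ratio,
               unname(quantile(ratio, 0.95, type = 7)))

  # all-identical windows: strict inequalities classify nothing
  cl2 <- classify_windows(make_scan(rep(1, 40), rep(0.1, 40)), q = 0.05)
  expect_true(all(cl2$table$class == "none"))
})

test_that("negating the ratios swaps positive and negative counts", {
  set.seed(47)
  ratio <- rnorm(200)
  fst <- runif(200)
  c1 <- classify_windows(make_scan(ratio, fst))
  c2 <- classify_windows(make_scan(-ratio, fst))
  expect_equal(sum(c1$table$class == "positive"), sum(c2$table$class == "negative"))
  expect_equal(sum(c1$table$class == "negative"), sum(c2$table$class == "positive"))
})

test_that("classification is invariant to monotone rescaling", {
  set.seed(53)
  ratio <- rnorm(100)
  fst <- runif(100)
  c1 <- classify_windows(make_scan(ratio, fst))
  c2 <- classify_windows(make_scan(3 * ratio + 2, fst^3))
  expect_equal(c1$table$class, c2$table$class)
})

test_that("quantile warning fires with too few usable windows", {
  expect_warning(classify_windows(make_scan(rnorm(10), runif(10)), q = 0.05),
                 "usable windows")
})

test_that("same-class overlapping or bookended windows merge; classes never mix", {
  tab <- make_scan(rep(0, 6), rep(0, 6))
  tab$class <- c("positive", "positive", "none", "positive", "negative", "negative")
  tab$start <- c(1, 20001, 60002, 100002, 140002, 200004)
  tab$end <- tab$start + 39999
  tab$fst <- c(.2, .3, 0, .4, .5, .6)
  tab$log2_pi_ratio <- c(1.5, 2, 0, 1.2, -2, -3)
  rg <- merge_regions(tab)
  expect_equal(nrow(rg), 4)
  pos <- rg[rg$class == "positive", ]
  expect_equal(pos$start, c(1, 100002))     # overlapping pair merged
  expect_equal(pos$end, c(60000, 140001))
  expect_equal(pos$n_windows, c(2L, 1L))
  expect_equal(pos$max_fst[1], 0.3)
  expect_equal(pos$extreme_log2_ratio[1], 2)
  neg <- rg[rg$class == "negative", ]
  expect_equal(nrow(neg), 2)                # disjoint negatives stay apart
  # a positive window bookended by a negative one is never merged with it
  expect_true(all(pos$end < min(neg$start)))
  expect_equal(attr(rg, "window_counts"), c(positive = 3L, negative = 2L))

  # bookended windows (end + 1 == next start) do merge
  tab2 <- tab[1:2, ]
  tab2$start <- c(1, 40001); tab2$end <- c(40000, 80000)
  expect_equal(nrow(merge_regions(tab2)), 1)
})

test_that("permutation p follows the counting definition and is never zero", {
  set.seed(59)
  dosA <- matrix(0L, 10, 3)
  dosB <- matrix(2L, 10, 3)
  gm <- two_pop_gm(dosA, dosB, pos = c(100L, 200L, 300L))
  win <- data.frame(chrom = "chr1", start = 1L, end = 1000L)
  res <- permutation_test(gm, "A", "B", win, B = 99, seed = 7)
  expect_equal(res$fst_obs, 1)
  expect_equal(res$p, 1 / 100)  # observed exceeds all 99 permuted values
  expect_gt(res$p, 0)
  expect_error(permutation_test(gm, "A", "B", win, B = 10), "at least 19")
  # joint-statistic mode is at least as strict and equally seeded
  gm2 <- two_pop_gm(matrix(rbinom(60, 2, 0.2), 10, 6) + 0L,
                    matrix(rbinom(60, 2, 0.8), 10, 6) + 0L,
                    pos = c(100L, 200L, 300L, 400L, 500L, 600L))
  rj1 <- permutation_test(gm2, "A", "B", win, B = 49, seed = 2, statistic = "joint")
  rj2 <- permutation_test(gm2, "A", "B", win, B = 49, seed = 2, statistic = "joint")
  rf <- permutation_test(gm2, "A", "B", win, B = 49, seed = 2)
  expect_identical(rj1$p, rj2$p)
  expect_lte(rj1$p, rf$p + 1e-12)
})

test_that("permutation p is reproducible under a seed and valid under the null", {
  set.seed(61)
  dos <- matrix(rbinom(200, 2, 0.4), 20, 10)
  gm <- toy_gm(dos, generation = rep(c("A", "B"), each = 10))
  win <- data.frame(chrom = "chr1", start = 1L, end = 2000L)
  r1 <- permutation_test(gm, "A", "B", win, B = 49, seed = 3)
  r2 <- permutation_test(gm, "A", "B", win, B = 49, seed = 3)
  expect_identical(r1$p, r2$p)
  # exchangeable labels: p should not concentrate near zero
  ps <- vapply(1:40, function(i) {
    g <- toy_gm(matrix(rbinom(120, 2, 0.5), 12, 10),
                generation = sample(rep(c("A", "B"), 6)))
    permutation_test(g, "A", "B", win, B = 39, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("genes annotate to regions by 1-bp overlap on matching chromosomes", {
  gr <- GenomicRanges::GRanges(
    c("c1", "c1", "c1", "c2"),
    IRanges::IRanges(c(5000, 39000, 41001, 5000),
                     c(8000, 41000, 42000, 8000)))
  gr$type <- "gene"
  gr$ID <- paste0("g", 1:4)
  regions <- data.frame(chrom = "c1", start = 1L, end = 41000L,
                        class = "positive", n_windows = 1L,
                        max_fst = 0.5, extreme_log2_ratio = 2)
  ann <- annotate_regions(regions, gr)
  expect_equal(ann$regions$genes, "g1,g2")  # inside + 1-bp boundary overlap
  expect_equal(ann$n_genes_by_class[["positive"]], 2)
  expect_equal(ann$n_genes_by_class[["negative"]], 0)

  regions2 <- rbind(regions,
                    data.frame(chrom = "c3", start = 1L, end = 100L,
                               class = "negative", n_windows = 1L,
                               max_fst = 0.2, extreme_log2_ratio = -2))
  expect_warning(annotate_regions(regions2, gr), "absent from annotation")
})

test_that("gene sets deduplicate across regions and GFF3 files are readable", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "genes.gff3")
  chroms <- data.frame(name = c("c1", "c2"), length_bp = c(2e5, 2e5))
  gr <- synthetic_annotation(chroms, n_genes = 20, path = gff, seed = 5)
  expect_equal(length(gr), 20)
  expect_true(all(IRanges::width(gr) >= 2000))
  # pairwise disjoint
  expect_equal(sum(IRanges::width(GenomicRanges::reduce(gr))), sum(IRanges::width(gr)))
  regions <- data.frame(chrom = c("c1", "c1"), start = c(1L, 50001L),
                        end = c(100000L, 150000L),
                        class = "positive", n_windows = 1L,
                        max_fst = 0.5, extreme_log2_ratio = 2)
  ann <- annotate_regions(regions, gff)
  genes_listed <- unlist(strsplit(ann$regions$genes, ","))
  expect_equal(ann$n_genes_by_class[["positive"]],
               length(unique(genes_listed)))
  # empty annotation: header-only file
  gff0 <- file.path(dir, "empty.gff3")
  synthetic_annotation(chroms, n_genes = 0, path = gff0)
  expect_equal(readLines(gff0), "##gff-version 3")
})
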