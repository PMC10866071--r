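#' Configuration for the forward-time breeding simulator
#'
#' Describes a multi-generation hatchery breeding experiment: discrete
#' non-overlapping generations founded from a common pool, mass spawning
#' with a fixed number of dams and sires, Haldane (no-interference)
#' recombination, optional sweepstakes-style reproductive skew, and
#' viability selection at a small set of truth loci. Defaults emulate a
#' laboratory line bred from 200 founders with 87 dams and 93 sires per
#' generation, genotyped at ~1 SNP per 40 kb on a 19-chromosome
#' scaled-down genome.
#'
#' @param n_founders founder individuals (G0 census).
#' @param generations number of discrete generations including G0
#'   (labels G0, G1, ...).
#' @param n_females,n_males breeders contributing per generation.
#' @param offspring_n census of each offspring generation.
#' @param chromosomes data.frame with columns name, length_bp, morgans.
#' @param n_loci total biallelic SNPs, distributed over chromosomes
#'   proportionally to physical length.
#' @param founder_freq_law range of the uniform law for founder alternate
#'   allele frequencies (a single value gives a point mass).
#' @param selected_loci \code{NULL}, or data.frame with columns chrom,
#'   pos, s (selection coefficient, >= 0), h (dominance in [0, 1]); the
#'   positions are inserted as loci.
#' @param selected_founder_freq founder frequency of the selected alleles
#'   (default 0.5: selection acting on common standing variation);
#'   \code{NA} draws from \code{founder_freq_law}.
#' @param skew_alpha Dirichlet concentration of per-parent contribution
#'   weights; \code{Inf} (default) gives equal expected contributions,
#'   small values give sweepstakes-like reproductive skew.
#' @param missing_rate genotype missingness applied when extracting
#'   genotype matrices.
#' @param n_genotyped individuals genotyped per generation.
#' @param seed integer seed recorded in the config and used by
#'   \code{\link{run_breeding_experiment}}.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_founders = 200, generations = 7,
                       n_females = 87, n_males = 93, offspring_n = 180,
                       chromosomes = default_chromosomes(),
                       n_loci = 2000,
                       founder_freq_law = c(0.05, 0.5),
                       selected_loci = NULL,
                       selected_founder_freq = 0.5,
                       skew_alpha = Inf, missing_rate = 0.02,
                       n_genotyped = 50, seed = NULL) {
  if (n_loci < 1) stop("n_loci must be positive")
  if (generations < 2) stop("need at least two generations")
  if (!all(c("name", "length_bp", "morgans") %in% names(chromosomes))) {
    stop("chromosomes needs columns name, length_bp, morgans")
  }
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$morgans < 0)) {
    stop("invalid chromosome lengths")
  }
  if (n_females + n_males > offspring_n) {
    stop("breeders per generation exceed offspring census")
  }
  if (n_females + n_males > n_founders) {
    stop("breeders exceed founder count")
  }
  if (!is.null(selected_loci)) {
    if (!all(c("chrom", "pos", "s", "h") %in% names(selected_loci))) {
      stop("selected_loci needs columns chrom, pos, s, h")
    }
    if (any(selected_loci$s < 0)) stop("selection coefficients must be >= 0")
    if (any(selected_loci$h < 0 | selected_loci$h > 1)) stop("dominance must lie in [0, 1]")
    len <- setNames(chromosomes$length_bp, chromosomes$name)
    if (any(!selected_loci$chrom %in% names(len)) ||
        any(selected_loci$pos < 1 | selected_loci$pos > len[selected_loci$chrom])) {
      stop("selected loci outside chromosome bounds")
    }
  }
  if (!(skew_alpha > 0)) stop("skew_alpha must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (length(founder_freq_law) == 1) founder_freq_law <- rep(founder_freq_law, 2)
  structure(list(
    n_founders = n_founders, generations = generations,
    n_females = n_females, n_males = n_males, offspring_n = offspring_n,
    chromosomes = chromosomes, n_loci = n_loci,
    founder_freq_law = founder_freq_law, selected_loci = selected_loci,
    selected_founder_freq = selected_founder_freq,
    skew_alpha = skew_alpha, missing_rate = missing_rate,
    n_genotyped = n_genotyped, seed = seed), class = "sim_config")
}

#' Default scaled-down genome: 19 chromosomes x 4 Mb x 1 Morgan
#' @param n number of chromosomes.
#' @param length_bp physical length per chromosome.
#' @param morgans genetic length per chromosome.
#' @return data.frame usable as the \code{chromosomes} field of
#'   \code{\link{sim_config}}.
#' @export
default_chromosomes <- function(n = 19, length_bp = 4e6, morgans = 1) {
  data.frame(name = sprintf("chr%02d", seq_len(n)),
             length_bp = length_bp, morgans = morgans,
             stringsAsFactors = FALSE)
}

#' Demo configuration: 5 chromosomes with 5 selected loci
#'
#' A small end-to-end preset: 5 chromosomes of 16 Mb (preserving the
#' default marker density of ~1 SNP per 40 kb with 2,000 SNPs), one
#' additively selected locus (s = 0.8, h = 0.5) in the middle of each
#' chromosome.
#'
#' @param seed integer seed (default 42).
#' @param s,h selection coefficient and dominance of the truth loci.
#' @return a \code{\link{sim_config}}.
#' @export
demo_config <- function(seed = 42, s = 0.8, h = 0.5) {
  chroms <- default_chromosomes(n = 5, length_bp = 16e6)
  sim_config(chromosomes = chroms, n_loci = 2000,
             selected_loci = data.frame(chrom = chroms$name,
                                        pos = as.integer(chroms$length_bp / 2),
                                        s = s, h = h, stringsAsFactors = FALSE),
             seed = seed)
}

# empirical substitution-class frequencies of bivalve RAD SNP panels
SUBSTITUTION_SPECTRUM <- c("A/G" = 27.56, "C/T" = 27.90, "A/T" = 20.98,
                           "A/C" = 9.57, "G/T" = 9.76, "C/G" = 4.23)

draw_alleles <- function(n) {
  pick <- sample(names(SUBSTITUTION_SPECTRUM), n, replace = TRUE,
                 prob = SUBSTITUTION_SPECTRUM)
  parts <- strsplit(pick, "/", fixed = TRUE)
  swap <- runif(n) < 0.5
  ref <- vapply(parts, `[`, character(1), 1)
  alt <- vapply(parts, `[`, character(1), 2)
  data.frame(ref = ifelse(swap, alt, ref), alt = ifelse(swap, ref, alt),
             stringsAsFactors = FALSE)
}

draw_loci <- function(config) {
  chroms <- config$chromosomes
  n_per <- round(config$n_loci * chroms$length_bp / sum(chroms$length_bp))
  n_per[length(n_per)] <- config$n_loci - sum(n_per[-length(n_per)])
  loci <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    data.frame(chrom = chroms$name[i],
               pos = sort(sample.int(chroms$length_bp[i], n_per[i])),
               stringsAsFactors = FALSE)
  }))
  sel_idx <- integer(0)
  if (!is.null(config$selected_loci)) {
    sel <- config$selected_loci
    loci <- unique(rbind(loci, sel[, c("chrom", "pos")]))
    loci <- loci[order(loci$chrom, loci$pos), ]
    sel_idx <- match(paste(sel$chrom, sel$pos), paste(loci$chrom, loci$pos))
  }
  rownames(loci) <- NULL
  cbind(loci, draw_alleles(nrow(loci)),
        selected = seq_len(nrow(loci)) %in% sel_idx)
}

assign_sexes <- function(n, config) {
  nf <- round(n * config$n_females / (config$n_females + config$n_males))
  nf <- max(nf, config$n_females)
  if (n - nf < config$n_males) stop("census too small for required sires")
  sample(c(rep("F", nf), rep("M", n - nf)))
}

#' Simulate the founder generation
#'
#' Founder alternate-allele frequencies are drawn from the configured
#' uniform law (selected loci from \code{selected_founder_freq}) and
#' haplotypes in Hardy-Weinberg/linkage equilibrium.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an internal population object of class \code{sim_population};
#'   convert with \code{\link{as_genotype_matrix}}.
#' @export
simulate_founders <- function(config) {
  loci <- draw_loci(config)
  L <- nrow(loci)
  freq <- runif(L, config$founder_freq_law[1], config$founder_freq_law[2])
  if (any(loci$selected) && !is.na(config$selected_founder_freq)) {
    freq[loci$selected] <- config$selected_founder_freq
  }
  n <- config$n_founders
  Hm <- matrix(rbinom(n * L, 1L, rep(freq, each = n)), n, L)
  Hp <- matrix(rbinom(n * L, 1L, rep(freq, each = n)), n, L)
  structure(list(Hm = Hm, Hp = Hp, sex = assign_sexes(n, config),
                 loci = loci, founder_freq = freq, generation_index = 0L,
                 config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: generation index %d, %d individuals x %d loci\n",
              x$generation_index, nrow(x$Hm), ncol(x$Hm)))
  invisible(x)
}

# one recombinant gamete per entry of `parents` (row indices into Hm/Hp)
make_gametes <- function(pop, parents) {
  loci <- pop$loci
  chroms <- pop$config$chromosomes
  n <- length(parents)
  out <- matrix(0L, n, nrow(loci))
  for (ci in seq_len(nrow(chroms))) {
    cols <- which(loci$chrom == chroms$name[ci])
    if (!length(cols)) next
    pos <- loci$pos[cols]
    len <- chroms$length_bp[ci]
    M <- chroms$morgans[ci]
    k <- if (M > 0) rpois(n, M) else integer(n)
    start <- sample.int(2L, n, replace = TRUE) - 1L  # 0 = maternal haplotype
    i0 <- which(k == 0L)
    if (length(i0)) {
      m0 <- i0[start[i0] == 0L]
      p0 <- i0[start[i0] == 1L]
      if (length(m0)) out[m0, cols] <- pop$Hm[parents[m0], cols]
      if (length(p0)) out[p0, cols] <- pop$Hp[parents[p0], cols]
    }
    for (i in which(k > 0L)) {
      xo <- sort(runif(k[i]) * len)
      hap <- (start[i] + findInterval(pos, xo)) %% 2L
      g <- pop$Hm[parents[i], cols]
      sel <- hap == 1L
      g[sel] <- pop$Hp[parents[i], cols][sel]
      out[i, cols] <- g
    }
  }
  out
}

parent_weights <- function(k, alpha) {
  if (is.infinite(alpha)) return(rep(1 / k, k))
  w <- stats::rgamma(k, shape = alpha)
  if (sum(w) == 0) w <- rep(1, k)
  w / sum(w)
}

#' Advance the breeding population by one generation
#'
#' Samples the configured numbers of dams and sires without replacement,
#' assigns each offspring a dam and a sire independently with
#' Dirichlet-weighted contribution probabilities, forms gametes with
#' Poisson(genetic length) crossovers placed uniformly (Haldane model, no
#' interference), and applies viability selection at the truth loci by
#' rejection sampling with genotype fitness 1, 1+h*s, 1+s.
#'
#' @param pop a \code{sim_population}.
#' @param config a \code{\link{sim_config}} (defaults to the population's
#'   own config).
#' @return the next-generation \code{sim_population}; attribute
#'   \code{parent_contributions} records per-dam and per-sire offspring
#'   counts.
#' @export
next_generation <- function(pop, config = pop$config) {
  sex <- pop$sex
  fem <- which(sex == "F")
  mal <- which(sex == "M")
  if (length(fem) < config$n_females || length(mal) < config$n_males) {
    stop("breeders exceed available parents of required sex")
  }
  dams <- sample(fem, config$n_females)
  sires <- sample(mal, config$n_males)
  w_dam <- parent_weights(config$n_females, config$skew_alpha)
  w_sire <- parent_weights(config$n_males, config$skew_alpha)
  sel <- which(pop$loci$selected)
  scoef <- if (length(sel)) config$selected_loci[
    match(paste(pop$loci$chrom[sel], pop$loci$pos[sel]),
          paste(config$selected_loci$chrom, config$selected_loci$pos)), ] else NULL
  wmax <- if (length(sel)) prod(1 + scoef$s) else 1
  need <- config$offspring_n
  Hm_new <- matrix(0L, need, ncol(pop$Hm))
  Hp_new <- matrix(0L, need, ncol(pop$Hm))
  dam_of <- integer(need); sire_of <- integer(need)
  got <- 0L
  tries <- 0L
  while (got < need) {
    tries <- tries + 1L
    if (tries > 200L) stop("viability rejection sampling failed to converge")
    batch <- max(need - got, 32L)
    if (length(sel)) batch <- ceiling(batch * 1.5)
    d <- sample.int(config$n_females, batch, replace = TRUE, prob = w_dam)
    s <- sample.int(config$n_males, batch, replace = TRUE, prob = w_sire)
    g1 <- make_gametes(pop, dams[d])
    g2 <- make_gametes(pop, sires[s])
    if (length(sel)) {
      geno <- g1[, sel, drop = FALSE] + g2[, sel, drop = FALSE]
      w <- rep(1, batch)
      for (j in seq_along(sel)) {
        fit <- c(1, 1 + scoef$h[j] * scoef$s[j], 1 + scoef$s[j])
        w <- w * fit[geno[, j] + 1L]
      }
      keep <- which(runif(batch) < w / wmax)
    } else keep <- seq_len(batch)
    if (length(keep) > need - got) keep <- keep[seq_len(need - got)]
    if (length(keep)) {
      idx <- got + seq_along(keep)
      Hm_new[idx, ] <- g1[keep, , drop = FALSE]
      Hp_new[idx, ] <- g2[keep, , drop = FALSE]
      dam_of[idx] <- d[keep]; sire_of[idx] <- s[keep]
      got <- got + length(keep)
    }
  }
  out <- structure(list(Hm = Hm_new, Hp = Hp_new,
                        sex = assign_sexes(need, config), loci = pop$loci,
                        founder_freq = pop$founder_freq,
                        generation_index = pop$generation_index + 1L,
                        config = config),
                   class = "sim_population")
  attr(out, "parent_contributions") <-
    list(dam = tabulate(dam_of, config$n_females),
         sire = tabulate(sire_of, config$n_males))
  out
}

#' Extract a genotype matrix from a simulated population
#'
#' Samples individuals without replacement, sums the two haplotypes into
#' dosages, and applies the configured genotype missingness.
#'
#' @param pop a \code{sim_population}.
#' @param n_sample individuals to genotype (\code{NULL} = all).
#' @param label generation label for the samples.
#' @param missing_rate per-genotype missingness (defaults to the config).
#' @return a \code{\link{genotype_matrix}}.
#' @export
as_genotype_matrix <- function(pop, n_sample = NULL, label = NULL,
                               missing_rate = pop$config$missing_rate) {
  n <- nrow(pop$Hm)
  idx <- if (is.null(n_sample) || n_sample >= n) seq_len(n) else sample.int(n, n_sample)
  dos <- pop$Hm[idx, , drop = FALSE] + pop$Hp[idx, , drop = FALSE]
  if (missing_rate > 0) {
    dos[matrix(runif(length(dos)) < missing_rate, nrow(dos))] <- NA_integer_
  }
  label <- label %||% paste0("G", pop$generation_index)
  rownames(dos) <- sprintf("%s_i%03d", label, seq_along(idx))
  genotype_matrix(dos, pop$loci[, c("chrom", "pos", "ref", "alt")],
                  generation = label,
                  contig_lengths = setNames(pop$config$chromosomes$length_bp,
                                            pop$config$chromosomes$name))
}

#' Run a full multi-generation breeding experiment
#'
#' Iterates \code{\link{next_generation}} from simulated founders,
#' recording true per-generation allele-frequency trajectories at every
#' locus, parental-contribution variances, and a genotyped subsample per
#' generation. Fully reproducible from (config, seed).
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional directory; when given, one VCF per generation,
#'   a combined VCF, a labels TSV, the truth as JSON, and the config as
#'   YAML are written there.
#' @return list with \code{genotypes} (named list of per-generation
#'   \code{\link{genotype_matrix}}), \code{combined} (all generations in
#'   one matrix), and \code{truth} (selected loci with s and h,
#'   trajectory matrix generations x loci, founder frequencies, and
#'   per-transition parental contribution variances).
#' @export
run_breeding_experiment <- function(config, out_dir = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- simulate_founders(config)
  labels <- paste0("G", seq_len(config$generations) - 1)
  traj <- matrix(NA_real_, config$generations, ncol(pop$Hm),
                 dimnames = list(labels, paste(pop$loci$chrom, pop$loci$pos, sep = ":")))
  contrib <- list()
  gms <- setNames(vector("list", config$generations), labels)
  for (g in seq_len(config$generations)) {
    if (g > 1) {
      pop <- next_generation(pop, config)
      contrib[[labels[g]]] <- attr(pop, "parent_contributions")
    }
    traj[g, ] <- colMeans(pop$Hm + pop$Hp) / 2
    gms[[g]] <- as_genotype_matrix(pop, n_sample = config$n_genotyped,
                                   label = labels[g])
  }
  combined <- do.call(rbind_genotypes, unname(gms))
  truth <- list(
    selected_loci = config$selected_loci,
    trajectories = traj,
    founder_freq = pop$founder_freq,
    contribution_variance = lapply(contrib, function(x)
      c(dam = var(x$dam), sire = var(x$sire))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in labels) write_vcf(gms[[g]], file.path(out_dir, paste0(g, ".vcf")))
    write_vcf(combined, file.path(out_dir, "all_generations.vcf"))
    write_labels(combined, file.path(out_dir, "labels.tsv"))
    tr <- truth; tr$trajectories <- as.data.frame(tr$trajectories)
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  }
  list(genotypes = gms, combined = combined, truth = truth)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$chromosomes <- as.list(as.data.frame(out$chromosomes))
  if (!is.null(out$selected_loci)) {
    out$selected_loci <- as.list(as.data.frame(out$selected_loci))
  }
  out$skew_alpha <- if (is.infinite(out$skew_alpha)) "Inf" else out$skew_alpha
  out
}

# stack genotype matrices that share an identical locus table
rbind_genotypes <- function(...) {
  gms <- list(...)
  loci <- gms[[1]]$loci
  for (g in gms[-1]) {
    if (!identical(g$loci[, c("chrom", "pos")], loci[, c("chrom", "pos")])) {
      stop("genotype matrices do not share a locus table")
    }
  }
  genotype_matrix(do.call(rbind, lapply(gms, `[[`, "dosages")), loci,
                  sample_ids = unlist(lapply(gms, `[[`, "sample_ids")),
                  generation = unlist(lapply(gms, function(g) unname(g$generation))),
                  contig_lengths = gms[[1]]$contig_lengths)
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene intervals uniformly on the given
#' chromosomes with stable ids and writes them as GFF3 (type "gene").
#' The file is synthetic: it stands in for a real genome annotation in
#' tests and demonstrations.
#'
#' @param chromosomes data.frame with columns name, length_bp.
#' @param n_genes number of genes to place.
#' @param path output GFF3 path.
#' @param gene_length range of gene lengths in bp.
#' @param seed integer seed.
#' @return the genes as a \code{GRanges}, invisibly; \code{path} is
#'   written as a side effect.
#' @export
synthetic_annotation <- function(chromosomes, n_genes, path,
                                 gene_length = c(2000, 10000), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(GenomicRanges::GRanges()))
  }
  lens <- stats::setNames(chromosomes$length_bp, chromosomes$name)
  mean_len <- mean(gene_length)
  if (n_genes * mean_len > 0.6 * sum(lens)) stop("infeasible gene density")
  n_per <- round(n_genes * lens / sum(lens))
  n_per[length(n_per)] <- n_genes - sum(n_per[-length(n_per)])
  rows <- list()
  for (ci in seq_along(lens)) {
    if (n_per[ci] == 0) next
    glen <- sample(seq(gene_length[1], gene_length[2]), n_per[ci], replace = TRUE)
    # uniform non-overlapping placement: draw gap anchors in the free space
    # left after removing all gene lengths, then shift by cumulative lengths
    free <- lens[ci] - sum(glen)
    if (free <= n_per[ci]) stop("infeasible gene density on ", names(lens)[ci])
    anchors <- sort(sample.int(free, n_per[ci]))
    starts <- anchors + c(0, cumsum(glen[-length(glen)]))
    ends <- starts + glen - 1
    rows[[ci]] <- data.frame(chrom = names(lens)[ci], start = starts, end = ends)
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end),
                               strand = "+")
  gr$type <- "gene"
  gr$ID <- sprintf("gene%05d", seq_along(gr))
  gr$Name <- gr$ID
  rtracklayer::export(gr, path, format = "gff3")
  invisible(gr)
}
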