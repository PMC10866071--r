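#' Run the full selection-signature pipeline
#'
#' End-to-end driver: obtain genotypes (from files or from the bundled
#' breeding simulator), apply SNP/sample filters, compute per-generation
#' diversity summaries, windowed diversity and Fst between the ancestral
#' and derived populations, classify windows by joint empirical quantiles
#' of the log2 theta-pi ratio and Fst, merge candidate regions, attach
#' permutation p-values, and annotate regions with overlapping genes.
#' All outputs are plain text (TSV/BED/JSON) and the run is deterministic
#' under a fixed seed.
#'
#' @param config a list, or path to a YAML file, with either
#'   \describe{
#'     \item{input}{list(genotypes = VCF/TSV path, labels = labels TSV,
#'       annotation = optional GFF3/BED, contig_lengths = optional named
#'       lengths)}
#'     \item{simulate}{a \code{\link{sim_config}} or a list of its
#'       arguments}
#'   }
#'   (exactly one of the two), plus optional analysis settings:
#'   \code{pop_anc} (default "G0"), \code{pop_der} (default the last
#'   generation label), \code{window_size} (40000), \code{window_step}
#'   (20000), \code{q} (0.05), \code{permutation_b} (199; 0 disables),
#'   \code{seed}.
#' @param out_dir output directory; created if needed.
#' @return (invisibly) list with the filtered matrix, filter report,
#'   diversity summary, classified scan table, thresholds, regions,
#'   annotation result, and simulation truth when simulated.
#' @export
run_full_scan <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config needs exactly one of 'input' or 'simulate'")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message("hatchscan: ", line)
    log_lines <<- c(log_lines, line)
  }

  truth <- NULL
  annotation <- NULL
  if (has_sim) {
    sc <- config$simulate
    if (!inherits(sc, "sim_config")) sc <- do.call(sim_config, sc)
    if (is.null(sc$seed)) sc$seed <- seed
    sim <- run_breeding_experiment(sc)
    gm <- sim$combined
    truth <- sim$truth
    annotation <- config$annotation
  } else {
    inp <- config$input
    gm <- read_genotypes(inp$genotypes, labels = inp$labels)
    if (!is.null(inp$contig_lengths)) {
      gm$contig_lengths <- unlist(inp$contig_lengths)
    }
    annotation <- inp$annotation
  }

  say("input: %d samples x %d loci", n_samples(gm), n_loci(gm))
  flt <- filter_dataset(gm)
  gmf <- flt$gm
  say("filtered: %d samples x %d loci retained", n_samples(gmf), n_loci(gmf))
  labs <- unique(unname(gmf$generation))
  pop_anc <- config$pop_anc %||% labs[1]
  pop_der <- config$pop_der %||% labs[length(labs)]
  if (is.null(gmf$contig_lengths)) {
    stop("contig lengths unavailable; supply input$contig_lengths")
  }
  windows <- make_windows(gmf$contig_lengths,
                          size = config$window_size %||% 40000,
                          step = config$window_step %||% 20000)
  summary_tab <- diversity_summary(gmf, windows)
  pi_a <- window_pi(gmf, windows, pop_anc)
  pi_d <- window_pi(gmf, windows, pop_der)
  fst <- wc_fst(gmf, pop_anc, pop_der, windows)
  scan <- pi_ratio_scan(pi_a, pi_d, fst$per_window)
  cls <- classify_windows(scan, q = config$q %||% 0.05)
  regions <- merge_regions(cls$table)
  wc <- attr(regions, "window_counts")
  say("scan %s vs %s: %d usable windows; %d positive / %d negative windows -> %d regions",
      pop_anc, pop_der, sum(scan$usable), wc[["positive"]], wc[["negative"]],
      nrow(regions))

  B <- config$permutation_b %||% 199
  if (B > 0 && nrow(regions)) {
    regions$perm_p <- vapply(seq_len(nrow(regions)), function(i) {
      permutation_test(gmf, pop_anc, pop_der, regions[i, ], B = B,
                       seed = seed + i)$p
    }, numeric(1))
  }

  ann <- NULL
  if (!is.null(annotation)) {
    if (file.exists(annotation)) {
      ann <- annotate_regions(regions, annotation)
      regions <- ann$regions
    } else {
      warning("annotation file not found, annotation step skipped: ", annotation)
    }
  }

  write.table(cls$table, file.path(out_dir, "windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary_tab, file.path(out_dir, "diversity_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(regions, file.path(out_dir, "regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  jsonlite::write_json(cls$thresholds, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_filter_report(flt$report, file.path(out_dir, "filter_report.json"))
  if (!is.null(ann)) {
    for (cl in names(ann$genes_by_class)) {
      writeLines(ann$genes_by_class[[cl]],
                 file.path(out_dir, paste0("genes_", cl, ".txt")))
    }
  }
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  manifest <- list(
    package = "hatchscan", version = as.character(packageVersion("hatchscan")),
    seed = seed, pop_anc = pop_anc, pop_der = pop_der,
    ratio_orientation = "log2(pi_ancestral/pi_derived)",
    window_counts = as.list(attr(regions, "window_counts") %||%
                              attr(merge_regions(cls$table), "window_counts")),
    config = if (has_sim) config_as_list(if (inherits(config$simulate, "sim_config"))
      config$simulate else do.call(sim_config, config$simulate)) else config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(gm = gmf, filter_report = flt$report,
                 diversity_summary = summary_tab, scan = cls$table,
                 thresholds = cls$thresholds, regions = regions,
                 annotation = ann, truth = truth))
}

write_regions_bed <- function(regions, path) {
  if (!nrow(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(pmax(round(1000 * regions$max_fst), 0), 1000)
  bed <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                    regions$class, score, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
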