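{
  "windows.tsv": {
    "chrom": "chromosome name",
    "start": "window start, 1-based inclusive bp",
    "end": "window end, 1-based inclusive bp",
    "pi_anc": "ancestral-population nucleotide diversity per bp in the window",
    "pi_der": "derived-population nucleotide diversity per bp in the window",
    "fst": "weighted Weir-Cockerham Fst, sum(a)/sum(a+b+c) over window loci",
    "log2_pi_ratio": "log2(pi_anc / pi_der); NA when unusable",
    "reason": "empty, or why the window is unusable (pi_anc_zero | pi_der_zero | no_variants | fst_undefined)",
    "usable": "TRUE when the window enters quantile estimation",
    "class": "positive | negative | none | NA (unusable)"
  },
  "diversity_summary.tsv": {
    "generation": "generation label",
    "n": "samples genotyped",
    "maf": "mean minor allele frequency over loci",
    "ho": "mean observed heterozygosity over loci",
    "he": "mean expected heterozygosity 2pq over loci",
    "fis": "mean per-individual inbreeding coefficient F",
    "pi": "mean windowed nucleotide diversity per bp"
  },
  "regions.tsv": {
    "chrom": "chromosome name",
    "start": "region start, 1-based inclusive bp",
    "end": "region end, 1-based inclusive bp",
    "class": "positive | negative",
    "n_windows": "significant windows merged into the region",
    "max_fst": "maximum member-window Fst",
    "extreme_log2_ratio": "most extreme member-window log2 pi ratio",
    "perm_p": "permutation p-value of the region's window Fst (when enabled)",
    "genes": "comma-separated overlapping gene ids (when annotated)",
    "n_genes": "count of overlapping genes (when annotated)"
  },
  "regions.bed": "BED6: chrom, 0-based start, end, class, score = round(1000 * max_fst), strand '.'",
  "thresholds.json": {
    "q_hi_ratio": "(1-q) empirical quantile of log2 pi ratio over usable windows",
    "q_lo_ratio": "q empirical quantile of log2 pi ratio",
    "q_hi_fst": "(1-q) empirical quantile of window Fst",
    "q": "tail probability used"
  },
  "filter_report.json": "counts in/out and removed samples/loci with first-failing-rule reasons",
  "manifest.json": "package version, seed, population pair, ratio orientation, window counts, echoed configuration"
}
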