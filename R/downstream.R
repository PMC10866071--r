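#' Life-cycle trait metrics for a breeding record
#'
#' Standard hatchery performance metrics from stage counts and shell
#' lengths: fertilization\% = zygotes/eggs x 100, hatching\% =
#' D-larvae/zygotes x 100, stage survival\% = end count/start count x 100,
#' metamorphosis\% = juveniles at 20 dpf / creeping larvae at 11 dpf x
#' 100, and growth rates (length change / days): larval and metamorphic
#' stages in um/day over 10 days, grow-out in mm/day over 30 days.
#' A zero denominator leaves the metric undefined (\code{NA}, listed in
#' the \code{undefined} attribute); percentages above 100 are flagged in
#' the \code{data_errors} attribute, never clipped.
#'
#' @param record named list or one-row data.frame; recognized fields:
#'   eggs, zygotes, d_larvae, larvae_1dpf, larvae_10dpf, creeping_11dpf,
#'   juveniles_20dpf, juveniles_21dpf, adults_50dpf, len_larva_1dpf,
#'   len_larva_10dpf, len_creeping_11dpf, len_juvenile_20dpf,
#'   len_juvenile_21dpf, len_adult_50dpf. Missing fields simply leave the
#'   corresponding metrics out.
#' @return named numeric vector of the computable metrics with attributes
#'   \code{undefined} and \code{data_errors}.
#' @export
trait_metrics <- function(record) {
  r <- as.list(record)
  if (any(unlist(r[sapply(r, is.numeric)]) < 0, na.rm = TRUE)) {
    stop("counts and lengths must be nonnegative")
  }
  pick <- function(field) if (!is.null(r[[field]])) as.numeric(r[[field]]) else NA_real_
  pct <- function(num, den) if (is.na(num) || is.na(den)) NULL else
    if (den == 0) NA_real_ else 100 * num / den
  rate <- function(l1, l0, days) if (is.na(l1) || is.na(l0)) NULL else (l1 - l0) / days
  out <- list(
    fertilization_pct = pct(pick("zygotes"), pick("eggs")),
    hatching_pct = pct(pick("d_larvae"), pick("zygotes")),
    larval_survival_pct = pct(pick("larvae_10dpf"), pick("larvae_1dpf")),
    metamorphosis_pct = pct(pick("juveniles_20dpf"), pick("creeping_11dpf")),
    growout_survival_pct = pct(pick("adults_50dpf"), pick("juveniles_21dpf")),
    larval_growth_um_d = rate(pick("len_larva_10dpf"), pick("len_larva_1dpf"), 10),
    metamorphic_growth_um_d = rate(pick("len_juvenile_20dpf"), pick("len_creeping_11dpf"), 10),
    growout_growth_mm_d = rate(pick("len_adult_50dpf"), pick("len_juvenile_21dpf"), 30))
  out <- out[!vapply(out, is.null, logical(1))]
  vals <- unlist(out)
  structure(vals,
            undefined = names(vals)[is.na(vals)],
            data_errors = names(vals)[!is.na(vals) & grepl("_pct$", names(vals)) &
                                        vals > 100])
}

#' Construct a gene-expression TPM table
#'
#' @param tpm numeric matrix of TPM values, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param generation character vector of per-sample generation labels.
#' @param sex optional per-sample sex labels.
#' @return object of class \code{expression_table}.
#' @export
expression_table <- function(tpm, generation, sex = NULL) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) stop("tpm needs gene ids as rownames")
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be nonnegative")
  if (length(generation) != ncol(tpm)) stop("one generation label per sample required")
  if (is.null(colnames(tpm))) colnames(tpm) <- paste0("sample", seq_len(ncol(tpm)))
  structure(list(tpm = tpm, generation = as.character(generation),
                 sex = if (is.null(sex)) NULL else as.character(sex)),
            class = "expression_table")
}

#' Relative expression against a reference gene
#'
#' TPM of the target gene divided by TPM of the internal reference gene
#' (EF1A by convention) per sample; the ratio is invariant to any global
#' rescaling of a sample's library.
#'
#' @param tbl an \code{\link{expression_table}}.
#' @param gene target gene id.
#' @param ref reference gene id (default "EF1A").
#' @return named numeric vector of per-sample ratios.
#' @export
relative_expression <- function(tbl, gene, ref = "EF1A") {
  for (g in c(gene, ref)) {
    if (!g %in% rownames(tbl$tpm)) stop("gene not in table: ", g)
  }
  refv <- tbl$tpm[ref, ]
  if (any(refv == 0)) {
    stop("reference TPM is zero in sample(s): ",
         paste(colnames(tbl$tpm)[refv == 0], collapse = ", "))
  }
  tbl$tpm[gene, ] / refv
}

#' Two-sample Student t-test
#'
#' Equal-variance two-sided t-test with df = nA + nB - 2 (the convention
#' for small-replicate expression comparisons); Welch's correction is
#' available via \code{var_equal = FALSE}. Degenerate inputs are resolved
#' before dispatch: zero pooled variance with equal means gives t = 0,
#' p = 1; zero pooled variance with unequal means is an error.
#'
#' @param group_a,group_b numeric vectors, each with at least two values.
#' @param var_equal pool the variances (default \code{TRUE}).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two values")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    stop("zero pooled variance with unequal means: t undefined")
  }
  res <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Compare a candidate gene's relative expression between two generations
#'
#' Convenience wrapper: computes relative expression, splits the samples
#' by generation label, and runs \code{\link{two_sample_ttest}}.
#'
#' @param tbl an \code{\link{expression_table}}.
#' @param gene candidate gene id.
#' @param gen_a,gen_b generation labels to compare.
#' @param ref reference gene id.
#' @return list with per-group ratios and the test result.
#' @export
compare_expression <- function(tbl, gene, gen_a, gen_b, ref = "EF1A") {
  ratio <- relative_expression(tbl, gene, ref)
  a <- ratio[tbl$generation == gen_a]
  b <- ratio[tbl$generation == gen_b]
  list(ratios_a = a, ratios_b = b, test = two_sample_ttest(a, b))
}
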