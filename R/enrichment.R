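#' Gene-usage tabulation and enrichment
#'
#' Per-gene usage counts are tabulated per cohort over records with complete
#' or incomplete V-J coverage (excluded records never count), on
#' paralog-collapsed gene ids. Enrichment of a gene in a case cohort versus a
#' control cohort is measured by the odds ratio of the per-gene 2x2 table
#' (gene vs all other genes, case vs control) — the exact single-predictor
#' equivalent of a binomial logistic regression — with a Wald 95% CI on the
#' log odds ratio and Benjamini-Hochberg FDR across all genes of both loci
#' jointly.
#'
#' @name gene_usage_enrichment
#' @keywords internal
NULL

#' Tabulate paralog-collapsed gene usage per cohort
#'
#' @param assignments data.frame from [assign_repertoire()] carrying
#'   `coverage_class` and a cohort label (`cohort` or `subcategory` column).
#' @param cohorts cohort labels to tabulate (columns of the result); must all
#'   be present in the metadata.
#' @return `GeneUsageTable`: data.frame keyed by `v_gene` with one count
#'   column per cohort; per-cohort totals in `attr(, "totals")`. Genes never
#'   observed are absent.
#' @export
tabulate_usage <- function(assignments, cohorts) {
  if (length(cohorts) == 0L) stop_lcrep("cohorts must be non-empty")
  lab <- assignments$cohort %||% assignments$subcategory
  if (is.null(lab)) stop_lcrep("assignments carry no cohort labels")
  missing_cohorts <- setdiff(cohorts, unique(lab))
  if (length(missing_cohorts) > 0L)
    stop_lcrep("cohort label(s) absent from metadata: ",
               paste(missing_cohorts, collapse = ", "))
  keep <- assignments$coverage_class %in% c("complete", "incomplete") &
    lab %in% cohorts
  a <- assignments[keep, , drop = FALSE]
  lab <- lab[keep]
  genes <- sort(unique(a$v_call))
  tab <- data.frame(v_gene = genes, stringsAsFactors = FALSE)
  for (co in cohorts)
    tab[[co]] <- as.integer(table(factor(a$v_call[lab == co], levels = genes)))
  totals <- vapply(cohorts, function(co) sum(tab[[co]]), integer(1))
  structure(tab, totals = totals, class = c("GeneUsageTable", "data.frame"))
}

#' Per-gene enrichment odds ratios
#'
#' For gene g with count `a` among `A` case sequences and `b` among `B`
#' control sequences: `OR = (a (B - b)) / (b (A - a))`, Wald 95% CI from
#' `SE = sqrt(1/a + 1/(A-a) + 1/b + 1/(B-b))` on the log scale, two-sided
#' Wald p. When any cell is zero, the Haldane-Anscombe correction adds 0.5
#' to all four cells. q-values are BH-adjusted across all genes jointly;
#' direction is "over"/"under" only at `q <= fdr_level`.
#'
#' @param table a `GeneUsageTable`.
#' @param case_cohort,control_cohort column names of `table`.
#' @param min_count drop genes observed fewer than this many times in both
#'   cohorts combined before adjustment (default 1, i.e. keep all observed).
#' @param fdr_level FDR significance level (default 0.05).
#' @return data.frame of `EnrichmentResult` rows sorted by descending OR:
#'   `v_gene`, counts, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `q_value`, `direction`.
#' @examples
#' tab <- structure(data.frame(v_gene = c("g1", "g2"), AL = c(50L, 731L),
#'                             MM = c(5L, 1117L)),
#'                  totals = c(AL = 781L, MM = 1122L),
#'                  class = c("GeneUsageTable", "data.frame"))
#' gene_enrichment(tab, "AL", "MM")
#' @export
gene_enrichment <- function(table, case_cohort, control_cohort,
                            min_count = 1L, fdr_level = 0.05) {
  for (co in c(case_cohort, control_cohort))
    if (!co %in% names(table)) stop_lcrep("cohort not in usage table: ", co)
  A <- sum(table[[case_cohort]])
  B <- sum(table[[control_cohort]])
  if (A <= 0 || B <= 0) stop_lcrep("zero cohort total")
  keep <- table[[case_cohort]] + table[[control_cohort]] >= min_count
  tab <- table[keep, , drop = FALSE]
  a <- tab[[case_cohort]]; b <- tab[[control_cohort]]
  cells <- cbind(a, A - a, b, B - b)
  corr <- apply(cells == 0, 1, any)
  cells[corr, ] <- cells[corr, , drop = FALSE] + 0.5
  or <- (cells[, 1] * cells[, 4]) / (cells[, 2] * cells[, 3])
  se <- sqrt(rowSums(1 / cells))
  z <- stats::qnorm(0.975)
  ci_low <- exp(log(or) - z * se)
  ci_high <- exp(log(or) + z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  q <- bh_adjust(p)
  direction <- ifelse(q <= fdr_level & or > 1, "over",
                      ifelse(q <= fdr_level & or < 1, "under", "none"))
  out <- data.frame(v_gene = tab$v_gene,
                    case_count = a, case_total = A,
                    control_count = b, control_total = B,
                    odds_ratio = or, ci_low = ci_low, ci_high = ci_high,
                    p_value = p, q_value = q, direction = direction,
                    continuity_corrected = corr,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$odds_ratio, out$v_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} m p_(j) / j` over ranked p-values, clipped at 1.
#' Implemented directly (rather than via [stats::p.adjust()]) because the
#' step-up is itself a tested surface of this package.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_lcrep("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values, decreasing = TRUE)
  q_sorted <- cummin(m / seq(m, 1) * p_values[ord])
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Pearson correlation between two gene-frequency profiles
#'
#' Frequencies are taken over the union of genes; a gene missing from one
#' profile contributes frequency 0 there.
#'
#' @param freq_a,freq_b named numeric vectors of per-gene frequencies (or
#'   counts, which are normalised).
#' @return list with `r` and two-sided `p`.
#' @export
usage_correlation <- function(freq_a, freq_b) {
  if (is.null(names(freq_a)) || is.null(names(freq_b)))
    stop_lcrep("frequency vectors must be named by gene")
  genes <- union(names(freq_a), names(freq_b))
  if (length(genes) < 3L) stop_lcrep("need at least 3 genes")
  x <- freq_a[genes]; x[is.na(x)] <- 0
  y <- freq_b[genes]; y[is.na(y)] <- 0
  if (sum(x) > 0) x <- x / sum(x)
  if (sum(y) > 0) y <- y / sum(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_lcrep("zero-variance frequency vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
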