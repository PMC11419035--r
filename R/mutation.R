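#' Somatic mutation-frequency statistic
#'
#' All differences between a record and its assigned germline genes are
#' attributed to somatic hypermutation. The per-record statistic normalises
#' each edit type by the germline span it is measured against and is
#' expressed as a percentage:
#'
#' \deqn{100 \left( \frac{S}{L} + \frac{I}{L + I} + \frac{D}{L - D} \right)}
#'
#' where `S`, `I`, `D` are amino-acid substitution, insertion and deletion
#' counts and `L` is the aligned germline V-J length. The three denominators
#' differ deliberately: insertions grow the observed sequence relative to the
#' germline (`L + I`), deletions shrink it (`L - D`). The statistic is zero
#' exactly when the record matches its germline.
#'
#' @name mutation_metrics
#' @keywords internal
NULL

#' Mutation frequency of one record
#'
#' @param substitutions,insertions,deletions non-negative integer edit counts.
#' @param germline_length aligned germline V-J length `L > 0`;
#'   `substitutions <= L` and `deletions < L` are required.
#' @return percentage (can exceed 100 for extreme indel loads).
#' @examples
#' mutation_frequency(10, 0, 0, 100)  # 10%
#' mutation_frequency(5, 5, 2, 100)   # 11.803...%
#' @export
mutation_frequency <- function(substitutions, insertions, deletions,
                               germline_length) {
  s <- substitutions; i <- insertions; d <- deletions; L <- germline_length
  if (any(L <= 0)) stop_lcrep("germline_length must be positive")
  if (any(s < 0 | i < 0 | d < 0)) stop_lcrep("edit counts must be non-negative")
  if (any(s > L)) stop_lcrep("substitutions cannot exceed germline_length")
  if (any(d >= L)) stop_lcrep("deletions must be smaller than germline_length")
  100 * (s / L + i / (L + i) + d / (L - d))
}

#' Per-record mutation profiles from an assignment table
#'
#' Restricted to records with complete coverage, matching how the statistic
#' is used in cohort comparisons.
#'
#' @param assignments data.frame from [assign_repertoire()], with cohort
#'   labels in `subcategory` (or a `cohort` column).
#' @param coverage which coverage classes to keep (default "complete").
#' @return data.frame `record_id`, `v_gene`, `locus`, `cohort`,
#'   `fraction_mutated`.
#' @export
mutation_profiles <- function(assignments, coverage = "complete") {
  a <- assignments[assignments$coverage_class %in% coverage &
                     !is.na(assignments$v_call), , drop = FALSE]
  cohort <- a$cohort %||% a$subcategory
  data.frame(record_id = a$sequence_id, v_gene = a$v_call, locus = a$locus,
             cohort = cohort,
             fraction_mutated = mutation_frequency(
               a$substitutions, a$insertions, a$deletions, a$germline_length),
             stringsAsFactors = FALSE)
}

# shared engine for rank-based cohort comparisons of a per-record value;
# used for mutation load and for the physicochemical scores
compare_groups_engine <- function(df, value_col, grouping_col,
                                  cohort_col = "cohort", pairs = NULL,
                                  min_group = 5L, fdr_level = 0.05) {
  if (nrow(df) == 0L) stop_lcrep("empty grouping: no records to compare")
  units <- split(df, df[[grouping_col]])
  res <- list(); skipped <- list()
  for (unit in names(units)) {
    d <- units[[unit]]
    grp <- split(d[[value_col]], d[[cohort_col]])
    sizes <- vapply(grp, length, 1L)
    small <- names(sizes)[sizes < min_group]
    if (length(small) > 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        unit = unit, reason = paste0("group(s) below minimum size ", min_group,
                                     ": ", paste(small, collapse = ",")),
        stringsAsFactors = FALSE)
      grp <- grp[sizes >= min_group]
    }
    if (length(grp) < 2L) next
    omni <- stats::kruskal.test(grp)$p.value
    cohort_pairs <- if (is.null(pairs)) utils::combn(names(grp), 2, simplify = FALSE)
                    else Filter(function(p) all(p %in% names(grp)), pairs)
    for (p in cohort_pairs) {
      x <- grp[[p[1]]]; y <- grp[[p[2]]]
      pw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      if (is.nan(pw)) pw <- 1    # identical constant samples
      res[[length(res) + 1L]] <- data.frame(
        unit = unit, group1 = p[1], group2 = p[2],
        n1 = length(x), n2 = length(y),
        median1 = stats::median(x), median2 = stats::median(y),
        omnibus_p = omni, p_value = pw, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
         else data.frame(unit = character(0), group1 = character(0),
                         group2 = character(0), n1 = integer(0), n2 = integer(0),
                         median1 = numeric(0), median2 = numeric(0),
                         omnibus_p = numeric(0), p_value = numeric(0))
  out$q_value <- if (nrow(out)) bh_adjust(out$p_value) else numeric(0)
  out$significant <- out$q_value <= fdr_level
  attr(out, "skipped") <- if (length(skipped))
    do.call(rbind, c(skipped, make.row.names = FALSE)) else NULL
  out
}

#' Compare mutation loads between cohorts
#'
#' For each grouping unit (locus or individual V gene) an omnibus
#' Kruskal-Wallis test is run across cohorts, followed by pairwise Wilcoxon
#' rank-sum tests (normal approximation with tie correction); q-values are
#' Benjamini-Hochberg adjusted jointly across all pairwise tests. Groups
#' below `min_group` observations are skipped with a logged reason
#' (see `attr(, "skipped")`).
#'
#' @param profiles data.frame from [mutation_profiles()].
#' @param grouping "locus" or "v_gene".
#' @param pairs optional list of cohort pairs to test (default: all pairs).
#' @param min_group minimum observations per group (default 5).
#' @param fdr_level FDR significance level (default 0.05).
#' @return data.frame of group medians, p-values and q-values.
#' @export
compare_mutation_loads <- function(profiles, grouping = c("locus", "v_gene"),
                                   pairs = NULL, min_group = 5L,
                                   fdr_level = 0.05) {
  grouping <- match.arg(grouping)
  compare_groups_engine(profiles, "fraction_mutated", grouping,
                        pairs = pairs, min_group = min_group,
                        fdr_level = fdr_level)
}
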