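#' Physicochemical scoring of variable domains
#'
#' Isoelectric point under the EMBOSS pKa set and grand average of hydropathy
#' (GRAVY, Kyte-Doolittle). Both are computed on the bare V-domain sequence
#' with free N- and C-terminal groups, so values differ from whole-chain
#' calculations that include the constant domain.
#'
#' @name physchem_properties
#' @keywords internal
NULL

# EMBOSS pKa values
PKA_EMBOSS <- list(
  positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch charge model over the EMBOSS pKa set: the free
#' N-terminus and K/R/H side chains contribute positive charge, the free
#' C-terminus and D/E/C/Y side chains negative charge. Unknown residues
#' ('X' etc.) are treated as neutral. Strictly decreasing in pH.
#'
#' @param seq amino-acid string.
#' @param pH pH value(s).
#' @return net charge (vectorised over `pH`).
#' @export
net_charge <- function(seq, pH) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop_lcrep("empty sequence")
  npos <- c(Nterm = 1, table(chars)[names(PKA_EMBOSS$positive)[-1]])
  nneg <- c(Cterm = 1, table(chars)[names(PKA_EMBOSS$negative)[-1]])
  npos[is.na(npos)] <- 0; nneg[is.na(nneg)] <- 0
  vapply(pH, function(ph) {
    pos <- sum(npos / (1 + 10^(ph - PKA_EMBOSS$positive)))
    neg <- sum(nneg / (1 + 10^(PKA_EMBOSS$negative - ph)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point (EMBOSS pKa set)
#'
#' pH of zero net charge, found by bisection on `[0, 14]` to a charge
#' tolerance of 1e-4 (at most 200 iterations; monotonicity of the charge
#' curve guarantees convergence).
#'
#' @param seq amino-acid string (unknown residues neutral).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq) {
  if (!nzchar(seq)) stop_lcrep("empty sequence")
  lo <- 0; hi <- 14
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle residue values; residues outside the
#' 20-letter alphabet are excluded from both numerator and denominator.
#'
#' @param seq amino-acid string.
#' @return mean hydropathy in `[-4.5, 4.5]`.
#' @examples
#' gravy("II")  # 4.5
#' gravy("IR")  # 0
#' @export
gravy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vals <- KD_SCALE[chars]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop_lcrep("sequence contains no scorable residues")
  mean(vals)
}

#' Per-record physicochemical property table
#'
#' @param sequences named character vector of complete V-domain sequences.
#' @param cohorts optional cohort label per record.
#' @param v_genes optional assigned V gene per record.
#' @return data.frame `record_id`, `pI`, `gravy` (plus `cohort`, `v_gene`
#'   when supplied).
#' @export
property_records <- function(sequences, cohorts = NULL, v_genes = NULL) {
  out <- data.frame(record_id = names(sequences),
                    pI = vapply(sequences, isoelectric_point, numeric(1)),
                    gravy = vapply(sequences, gravy, numeric(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(cohorts)) out$cohort <- cohorts
  if (!is.null(v_genes)) out$v_gene <- v_genes
  rownames(out) <- NULL
  out
}

#' Compare physicochemical properties between cohorts
#'
#' Same contract as [compare_mutation_loads()], applied to pI and GRAVY:
#' per grouping unit, Kruskal-Wallis omnibus plus pairwise Wilcoxon
#' rank-sum tests, BH-adjusted jointly per property.
#'
#' @param properties data.frame from [property_records()] with `cohort` and
#'   the grouping column.
#' @param grouping grouping column, default "v_gene".
#' @param pairs,min_group,fdr_level see [compare_mutation_loads()].
#' @return data.frame with a `property` column stacking the pI and GRAVY
#'   comparisons.
#' @export
compare_properties <- function(properties, grouping = "v_gene", pairs = NULL,
                               min_group = 5L, fdr_level = 0.05) {
  out <- list()
  for (prop in c("pI", "gravy")) {
    cmp <- compare_groups_engine(properties, prop, grouping, pairs = pairs,
                                 min_group = min_group, fdr_level = fdr_level)
    if (nrow(cmp)) cmp$property <- prop
    out[[prop]] <- cmp
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}
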