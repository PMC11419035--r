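#' Category count tables
#'
#' A `CategoryCountTable` holds, per clinical (category, subcategory) pair,
#' kappa/lambda sequence counts in the three coverage classes (complete,
#' incomplete, fragment/non-productive). The bundled fixture is a
#' machine-readable transcription of the repository's published census.
#' "Analyzed" totals count complete + incomplete sequences — the set that
#' enters gene-level analyses; fragments are retained for reference only.
#'
#' @name category_counts
#' @keywords internal
NULL

CCT_CELLS <- c("kappa_complete", "lambda_complete", "kappa_incomplete",
               "lambda_incomplete", "kappa_fragment", "lambda_fragment")

#' Load a category count table
#'
#' @param path TSV with columns `category`, `subcategory`, the six
#'   kappa/lambda-by-coverage cells, and redundant `total_*`/`total` columns
#'   which are validated against the cells.
#' @return validated `CategoryCountTable` data.frame.
#' @export
load_category_counts <- function(path = system.file(
  "extdata", "albase_category_counts.tsv", package = "lcrep")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("category", "subcategory", CCT_CELLS)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop_lcrep("count table missing column(s): ",
               paste(missing_cols, collapse = ", "))
  for (cls in c("complete", "incomplete", "fragment")) {
    tot_col <- paste0("total_", cls)
    if (tot_col %in% names(tab)) {
      expect <- tab[[paste0("kappa_", cls)]] + tab[[paste0("lambda_", cls)]]
      bad <- which(tab[[tot_col]] != expect)
      if (length(bad) > 0L)
        stop_lcrep("inconsistent ", tot_col, " in row(s): ",
                   paste(tab$subcategory[bad], collapse = ", "))
    }
  }
  if ("total" %in% names(tab)) {
    expect <- rowSums(tab[, CCT_CELLS])
    bad <- which(tab$total != expect)
    if (length(bad) > 0L)
      stop_lcrep("inconsistent row total in row(s): ",
                 paste(tab$subcategory[bad], collapse = ", "))
  }
  if (any(tab[, CCT_CELLS] < 0)) stop_lcrep("negative counts")
  structure(tab, class = c("CategoryCountTable", "data.frame"))
}

share <- function(num, den, digits = 1) {
  if (den > 0)
    list(fraction = num / den, percent = percent_printed(num / den, digits))
  else list(fraction = NA_real_, percent = NA_real_)
}

#' Aggregate a category count table
#'
#' Computes, from cell values only: per-category and PCD-wide totals by
#' coverage class, "analyzed" totals (complete + incomplete), and kappa/lambda
#' shares per category and subcategory. Shares are reported both as raw
#' fractions and as percentages rounded half-away-from-zero at the printed
#' precision (1 decimal), so they can be compared against published figures.
#'
#' @param counts a `CategoryCountTable` from [load_category_counts()].
#' @param pcd_categories categories counted as plasma cell dyscrasias.
#' @return nested list: `per_category`, `per_subcategory`, `pcd` (totals and
#'   shares over the PCD categories).
#' @export
aggregate_counts <- function(counts, pcd_categories = c("AL-PCD", "Other-PCD")) {
  stopifnot(inherits(counts, "CategoryCountTable"))
  row_tot <- function(rows, cols) sum(counts[rows, cols])
  summarize_rows <- function(rows) {
    complete <- row_tot(rows, c("kappa_complete", "lambda_complete"))
    incomplete <- row_tot(rows, c("kappa_incomplete", "lambda_incomplete"))
    fragment <- row_tot(rows, c("kappa_fragment", "lambda_fragment"))
    analyzed <- complete + incomplete
    kappa_analyzed <- row_tot(rows, c("kappa_complete", "kappa_incomplete"))
    lambda_analyzed <- row_tot(rows, c("lambda_complete", "lambda_incomplete"))
    list(complete = complete, incomplete = incomplete, fragment = fragment,
         total = complete + incomplete + fragment, analyzed = analyzed,
         kappa_analyzed = kappa_analyzed, lambda_analyzed = lambda_analyzed,
         kappa_share = share(kappa_analyzed, analyzed),
         lambda_share = share(lambda_analyzed, analyzed))
  }
  per_category <- lapply(split(seq_len(nrow(counts)), counts$category),
                         summarize_rows)
  sub_key <- paste(counts$category, counts$subcategory, sep = ":")
  per_subcategory <- lapply(split(seq_len(nrow(counts)), sub_key),
                            summarize_rows)
  pcd_rows <- which(counts$category %in% pcd_categories)
  pcd <- summarize_rows(pcd_rows)
  pcd$complete_share <- share(pcd$complete, pcd$total)
  pcd$incomplete_share <- share(pcd$incomplete, pcd$total)
  pcd$fragment_share <- share(pcd$fragment, pcd$total)
  # subcategory shares within their parent category's analyzed total
  sub_of_category <- list()
  for (k in names(per_subcategory)) {
    cat_name <- sub(":.*$", "", k)
    s <- per_subcategory[[k]]
    parent <- per_category[[cat_name]]
    sub_of_category[[k]] <- list(
      kappa_of_category = share(s$kappa_analyzed, parent$analyzed),
      lambda_of_category = share(s$lambda_analyzed, parent$analyzed),
      analyzed_of_category = share(s$analyzed, parent$analyzed))
  }
  list(per_category = per_category, per_subcategory = per_subcategory,
       subcategory_of_category = sub_of_category, pcd = pcd)
}
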