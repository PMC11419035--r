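#' End-to-end pipeline
#'
#' Orchestrates a full run: synthetic cohort generation (or user FASTA
#' input), duplicate collapsing, germline assignment, coverage
#' classification, gene-usage tabulation, enrichment, mutation statistics,
#' physicochemical scoring and optional predictor evaluation, with TSV
#' outputs and a JSON run summary. Re-running with the same configuration
#' and seed reproduces every table byte-for-byte (only the summary timestamp
#' differs).
#'
#' @name pipeline
#' @keywords internal
NULL

#' Build a run configuration
#'
#' @param cohorts list of [cohort_spec()]s; their seeds are re-derived from
#'   the run `seed` so one integer reproduces the whole run.
#' @param case_cohort cohort treated as cases in enrichment.
#' @param control_cohorts cohorts each compared against the cases.
#' @param reference a `ReferenceSet`, or NULL for the bundled reference.
#' @param min_identity assignment identity floor (percent).
#' @param duplicate_threshold pairwise identity for duplicate collapsing.
#' @param fdr_level FDR significance level in (0, 1).
#' @param min_residues contiguous-residue floor of the incomplete class.
#' @param seed integer master seed.
#' @param predictions optional prediction table (see
#'   [evaluate_predictions()]).
#' @return a `RunConfig`.
#' @export
run_config <- function(cohorts, case_cohort, control_cohorts,
                       reference = NULL, min_identity = 50,
                       duplicate_threshold = 0.98, fdr_level = 0.05,
                       min_residues = 80L, seed = 1L, predictions = NULL) {
  stopifnot(fdr_level > 0, fdr_level < 1, length(cohorts) >= 1L)
  for (sp in cohorts) stopifnot(inherits(sp, "CohortSpec"))
  nm <- vapply(cohorts, function(sp) sp$name, "")
  stopifnot(case_cohort %in% nm, all(control_cohorts %in% nm))
  structure(list(cohorts = cohorts, case_cohort = case_cohort,
                 control_cohorts = control_cohorts, reference = reference,
                 min_identity = min_identity,
                 duplicate_threshold = duplicate_threshold,
                 fdr_level = fdr_level, min_residues = min_residues,
                 seed = as.integer(seed), predictions = predictions),
            class = "RunConfig")
}

#' Demo configuration
#'
#' Three synthetic cohorts against the bundled reference: a case cohort with
#' two genes at strongly elevated usage (IGLV6-57, IGKV1-33), a monoclonal
#' comparator and a polyclonal-style control, 300 records each by default.
#'
#' @param seed master seed.
#' @param n records per cohort.
#' @return a `RunConfig`.
#' @export
demo_config <- function(seed = 1L, n = 300L) {
  base <- c("IGKV1-33" = 0.05, "IGKV1-39" = 0.10, "IGKV3-11" = 0.15,
            "IGKV3-20" = 0.15, "IGKV4-1" = 0.10, "IGLV1-36" = 0.05,
            "IGLV1-44" = 0.10, "IGLV2-14" = 0.12, "IGLV3-1" = 0.10,
            "IGLV6-57" = 0.08)
  elevated <- c("IGKV1-33" = 0.25, "IGKV1-39" = 0.06, "IGKV3-11" = 0.08,
                "IGKV3-20" = 0.08, "IGKV4-1" = 0.05, "IGLV1-36" = 0.04,
                "IGLV1-44" = 0.06, "IGLV2-14" = 0.06, "IGLV3-1" = 0.04,
                "IGLV6-57" = 0.28)
  j <- c(IGKJ1 = 0.3, IGKJ2 = 0.2, IGLJ2 = 0.3, IGLJ3 = 0.2)
  mk <- function(name, usage, category, sub_rate, stream)
    cohort_spec(name, n, usage, j, sub_rate = sub_rate, ins_rate = 0.05,
                del_rate = 0.05, truncate_prob = 0.08, exclude_prob = 0.04,
                duplicate_prob = 0.03, category = category,
                seed = derive_seed(seed, stream))
  cfg <- run_config(
    cohorts = list(mk("AL", elevated, "AL-PCD", 0.09, 1L),
                   mk("MM", base, "Other-PCD", 0.10, 2L),
                   mk("control", base, "control", 0.08, 3L)),
    case_cohort = "AL", control_cohorts = c("MM", "control"), seed = seed)
  attr(cfg, "elevated_genes") <- c("IGKV1-33", "IGLV6-57")
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_lcrep("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full pipeline
#'
#' @param config a `RunConfig` (see [run_config()], [demo_config()]).
#' @param out_dir optional output directory; when given, all stage tables are
#'   written as TSV plus a JSON run summary.
#' @return invisibly, a list with `assignments`, `usage`, `enrichment` (one
#'   data.frame per control cohort), `mutation_profiles`,
#'   `mutation_comparison`, `properties`, `property_comparison`,
#'   `duplicate_log`, `truth`, `predictor_metrics` (or NULL) and `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  reference <- stage("reference", config$reference %||% bundled_reference())

  cohorts <- stage("simulate", {
    specs <- lapply(seq_along(config$cohorts), function(i) {
      sp <- config$cohorts[[i]]
      sp$seed <- derive_seed(config$seed, i * 131L)
      sp
    })
    lapply(specs, generate_cohort, reference = reference)
  })
  sequences <- do.call(c, lapply(cohorts, `[[`, "sequences"))
  metadata <- do.call(rbind, lapply(cohorts, `[[`, "metadata"))
  truth <- do.call(rbind, lapply(cohorts, `[[`, "truth"))

  dup <- stage("collapse_duplicates",
               collapse_duplicates(sequences, metadata,
                                   config$duplicate_threshold))
  kept_seqs <- c(dup$kept, setNames(dup$consensus$seq, dup$consensus$record_id))
  # consensus records inherit the metadata of their first member
  cons_meta <- NULL
  if (nrow(dup$consensus) > 0L) {
    first_member <- vapply(strsplit(dup$consensus$members, ","), `[`, "", 1L)
    cons_meta <- metadata[match(first_member, metadata$record_id), , drop = FALSE]
    cons_meta$record_id <- dup$consensus$record_id
  }
  meta_kept <- rbind(metadata[metadata$record_id %in% names(dup$kept), ,
                              drop = FALSE], cons_meta)

  assignments <- stage("assign",
                       assign_repertoire(kept_seqs, reference, meta_kept,
                                         min_identity = config$min_identity,
                                         min_residues = config$min_residues))

  cohort_names <- vapply(config$cohorts, function(sp) sp$name, "")
  usage <- stage("usage", tabulate_usage(assignments, cohort_names))
  enrichment <- stage("enrich", {
    out <- lapply(config$control_cohorts, function(ctrl)
      gene_enrichment(usage, config$case_cohort, ctrl,
                      fdr_level = config$fdr_level))
    names(out) <- config$control_cohorts
    out
  })
  profiles <- stage("mutstats", mutation_profiles(assignments))
  mut_cmp <- stage("mutstats",
                   compare_mutation_loads(profiles, "locus",
                                          fdr_level = config$fdr_level))
  props <- stage("props", {
    complete_ids <- assignments$sequence_id[
      assignments$coverage_class == "complete"]
    s <- kept_seqs[complete_ids]
    property_records(s,
                     cohorts = assignments$subcategory[
                       match(complete_ids, assignments$sequence_id)],
                     v_genes = assignments$v_call[
                       match(complete_ids, assignments$sequence_id)])
  })
  prop_cmp <- stage("props",
                    compare_properties(props, fdr_level = config$fdr_level))
  pred <- NULL
  if (!is.null(config$predictions))
    pred <- stage("evaluate", {
      labels <- data.frame(record_id = assignments$sequence_id,
                           cohort = assignments$subcategory,
                           locus = assignments$locus,
                           stringsAsFactors = FALSE)
      evaluate_predictions(config$predictions, labels)
    })

  summary <- list(
    seed = config$seed,
    n_input = length(sequences),
    n_after_collapse = length(kept_seqs),
    n_excluded_ambiguous = sum(dup$log$fate == "excluded"),
    coverage = as.list(table(assignments$coverage_class)),
    cohorts = as.list(table(metadata$subcategory)),
    n_genes_observed = nrow(usage),
    package_version = as.character(utils::packageVersion("lcrep")))

  result <- list(assignments = assignments, usage = usage,
                 enrichment = enrichment, mutation_profiles = profiles,
                 mutation_comparison = mut_cmp, properties = props,
                 property_comparison = prop_cmp, duplicate_log = dup$log,
                 truth = truth, predictor_metrics = pred, summary = summary)

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
      write_tsv(as.data.frame(usage), file.path(out_dir, "gene_usage.tsv"))
      for (ctrl in names(enrichment))
        write_tsv(enrichment[[ctrl]],
                  file.path(out_dir, paste0("enrichment_",
                                            gsub("\\W", "_", ctrl), ".tsv")))
      write_tsv(profiles, file.path(out_dir, "mutation_profiles.tsv"))
      write_tsv(mut_cmp, file.path(out_dir, "mutation_comparison.tsv"))
      write_tsv(props, file.path(out_dir, "properties.tsv"))
      write_tsv(prop_cmp, file.path(out_dir, "property_comparison.tsv"))
      write_tsv(dup$log, file.path(out_dir, "duplicate_log.tsv"))
      write_tsv(truth, file.path(out_dir, "ground_truth.tsv"))
      if (!is.null(pred))
        write_tsv(pred, file.path(out_dir, "predictor_metrics.tsv"))
      summary$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  invisible(result)
}
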