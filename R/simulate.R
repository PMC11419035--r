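#' Synthetic light-chain repertoires with ground truth
#'
#' The generator emits cohorts of rearranged V-J amino-acid sequences from a
#' germline reference, with configurable per-gene usage, per-residue
#' substitution rate, per-sequence indel expectations, truncation (incomplete
#' coverage) and duplicate re-emission — a stand-in for monoclonal AL/MM
#' cohorts and a polyclonal control repertoire. Every record carries ground
#' truth (true genes, exact edit counts, intended coverage class) so that
#' downstream assignment and statistics can be validated against a known
#' answer.
#'
#' @name synthetic_repertoire
#' @keywords internal
NULL

#' Specify one synthetic cohort
#'
#' @param name cohort label (used as the clinical subcategory, e.g. "AL").
#' @param n_sequences number of records to emit.
#' @param gene_usage named probability vector over canonical V gene ids.
#' @param j_usage named probability vector over J gene ids.
#' @param sub_rate per-residue substitution probability in `[0, 1)`.
#' @param ins_rate,del_rate expected number of single-residue insertions /
#'   deletions per sequence (Poisson means), `>= 0`.
#' @param truncate_prob probability a record is emitted truncated but still
#'   classifiable (intended coverage class "incomplete").
#' @param exclude_prob probability a record is emitted too short or with a
#'   broken CDR span (intended coverage class "excluded").
#' @param duplicate_prob probability a record is re-emitted as a near-duplicate
#'   clone carrying at most one additional substitution.
#' @param category clinical category label attached to the metadata.
#' @param seed integer seed making the cohort reproducible.
#' @return a `CohortSpec`.
#' @export
cohort_spec <- function(name, n_sequences, gene_usage, j_usage,
                        sub_rate = 0.08, ins_rate = 0, del_rate = 0,
                        truncate_prob = 0, exclude_prob = 0,
                        duplicate_prob = 0, category = "AL-PCD",
                        seed = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            n_sequences >= 0, sub_rate >= 0, sub_rate < 1,
            ins_rate >= 0, del_rate >= 0,
            truncate_prob >= 0, truncate_prob <= 1,
            exclude_prob >= 0, exclude_prob <= 1,
            truncate_prob + exclude_prob <= 1,
            duplicate_prob >= 0, duplicate_prob <= 1)
  for (p in list(gene_usage, j_usage)) {
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop_lcrep("usage vectors must be named by gene id")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_lcrep("usage probabilities must be non-negative and sum to 1")
  }
  structure(list(name = name, n_sequences = as.integer(n_sequences),
                 gene_usage = gene_usage, j_usage = j_usage,
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 truncate_prob = truncate_prob, exclude_prob = exclude_prob,
                 duplicate_prob = duplicate_prob, category = category,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

check_spec_against_reference <- function(spec, reference) {
  vc <- assignment_candidates(reference, "V")
  jc <- assignment_candidates(reference, "J")
  bad_v <- setdiff(names(spec$gene_usage), vc$paralog_canonical)
  if (length(bad_v) > 0L)
    stop_lcrep("gene_usage names not canonical functional V genes: ",
               paste(bad_v, collapse = ", "))
  bad_j <- setdiff(names(spec$j_usage), jc$gene_id)
  if (length(bad_j) > 0L)
    stop_lcrep("j_usage names not functional J genes: ",
               paste(bad_j, collapse = ", "))
  invisible(TRUE)
}

#' Apply synthetic somatic hypermutation to a germline sequence
#'
#' Substitutions are drawn per residue at `sub_rate` (replacement uniform over
#' the 19 other amino acids); insertion and deletion event counts are Poisson
#' with means `ins_rate` and `del_rate`, each event adding or removing a single
#' residue at a uniform position. A deletion draw that would remove the whole
#' sequence is resampled. The returned edit script describes the transformation
#' exactly: deletions and substitutions are indexed on germline coordinates,
#' insertions on the coordinates of the emitted sequence.
#'
#' @param germline_vj_seq germline amino-acid string.
#' @param sub_rate per-residue substitution probability.
#' @param ins_rate,del_rate expected event counts per sequence.
#' @return list with `seq`, counts `substitutions`, `insertions`, `deletions`,
#'   and an `edits` list (`del_pos`, `sub_pos`, `sub_aa`, `ins_pos`, `ins_aa`)
#'   replayable via [replay_edits()].
#' @export
simulate_shm <- function(germline_vj_seq, sub_rate, ins_rate = 0, del_rate = 0) {
  chars <- strsplit(germline_vj_seq, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop_lcrep("germline sequence must be non-empty")

  n_del <- stats::rpois(1L, del_rate)
  while (n_del >= n) n_del <- stats::rpois(1L, del_rate)
  del_pos <- sort(sample.int(n, n_del))

  keep <- setdiff(seq_len(n), del_pos)
  sub_mask <- stats::runif(length(keep)) < sub_rate
  sub_pos <- keep[sub_mask]
  sub_aa <- vapply(sub_pos, function(i)
    sample(setdiff(AA20, chars[i]), 1L), character(1))
  chars[sub_pos] <- sub_aa

  out <- chars[keep]
  n_ins <- stats::rpois(1L, ins_rate)
  ins_pos <- integer(0); ins_aa <- character(0)
  for (k in seq_len(n_ins)) {
    pos <- sample.int(length(out) + 1L, 1L)  # insert before this position
    aa <- sample(AA20, 1L)
    out <- append(out, aa, after = pos - 1L)
    ins_pos <- c(ins_pos, pos); ins_aa <- c(ins_aa, aa)
  }
  list(seq = paste(out, collapse = ""),
       substitutions = length(sub_pos), insertions = n_ins, deletions = n_del,
       edits = list(del_pos = del_pos, sub_pos = sub_pos, sub_aa = sub_aa,
                    ins_pos = ins_pos, ins_aa = ins_aa))
}

#' Replay an edit script against its germline
#'
#' Reconstructs the emitted sequence from a germline and the edit script
#' returned by [simulate_shm()]; used to verify that ground-truth edit counts
#' exactly describe each synthetic record.
#'
#' @param germline_vj_seq germline amino-acid string.
#' @param edits edit script list from [simulate_shm()].
#' @return the reconstructed amino-acid string.
#' @export
replay_edits <- function(germline_vj_seq, edits) {
  chars <- strsplit(germline_vj_seq, "")[[1]]
  chars[edits$sub_pos] <- edits$sub_aa
  if (length(edits$del_pos) > 0L) chars <- chars[-edits$del_pos]
  for (k in seq_along(edits$ins_pos))
    chars <- append(chars, edits$ins_aa[k], after = edits$ins_pos[k] - 1L)
  paste(chars, collapse = "")
}

serialize_edits <- function(edits) {
  paste(c(sprintf("D%d", edits$del_pos),
          sprintf("S%d:%s", edits$sub_pos, edits$sub_aa),
          sprintf("I%d:%s", edits$ins_pos, edits$ins_aa)),
        collapse = ";")
}

parse_edits <- function(s) {
  out <- list(del_pos = integer(0), sub_pos = integer(0), sub_aa = character(0),
              ins_pos = integer(0), ins_aa = character(0))
  if (!nzchar(s)) return(out)
  for (tok in strsplit(s, ";", fixed = TRUE)[[1]]) {
    type <- substr(tok, 1, 1)
    body <- substring(tok, 2)
    if (type == "D") {
      out$del_pos <- c(out$del_pos, as.integer(body))
    } else {
      kv <- strsplit(body, ":", fixed = TRUE)[[1]]
      if (type == "S") {
        out$sub_pos <- c(out$sub_pos, as.integer(kv[1]))
        out$sub_aa <- c(out$sub_aa, kv[2])
      } else {
        out$ins_pos <- c(out$ins_pos, as.integer(kv[1]))
        out$ins_aa <- c(out$ins_aa, kv[2])
      }
    }
  }
  out
}

# truncate a full-length V-J sequence; germline coordinates of the template
# drive the CDR-coverage intent. Returns the truncated seq.
truncate_record <- function(seq, cdr_windows, intend_excluded) {
  n <- nchar(seq)
  cdr_start <- cdr_windows[[1]][1]
  cdr_end <- min(cdr_windows[[3]][2], n)
  if (!intend_excluded) {
    # keep >= 80 contiguous residues spanning all CDRs: cut from one end
    # without entering the CDR span or dropping below 80 residues
    head_max <- min(cdr_start - 1L, n - 80L)
    tail_max <- min(n - cdr_end, n - 80L)
    side <- sample(c("N", "C"), 1L)
    if (side == "N" && head_max < 1L) side <- "C"
    if (side == "C" && tail_max < 1L) side <- "N"
    if (side == "N") {
      k <- sample.int(head_max, 1L)
      substring(seq, k + 1L, n)
    } else {
      k <- sample.int(tail_max, 1L)
      substring(seq, 1L, n - k)
    }
  } else {
    # violate the rule: keep fewer than 80 residues (always breaks the
    # 80-contiguous-residue criterion, usually a CDR too)
    keep <- sample(40:70, 1L)
    if (sample(c(TRUE, FALSE), 1L)) substring(seq, n - keep + 1L, n)
    else substring(seq, 1L, keep)
  }
}

#' Generate a synthetic cohort
#'
#' Draws V and J genes per record from the spec's usage distributions
#' (restricted to same-locus V-J pairings), mutates the concatenated germline
#' with [simulate_shm()], then applies truncation and near-duplicate
#' re-emission. Reproducible: the spec's `seed` fully determines the output.
#'
#' When a canonical V gene has several paralogous reference copies the emitting
#' copy is drawn uniformly among them, so paralog collapsing is exercised.
#'
#' @param spec a [cohort_spec()].
#' @param reference a `ReferenceSet`; all genes named in the spec must be
#'   functional genes of the reference.
#' @return a `SyntheticCohort`: list with `sequences` (named character vector),
#'   `metadata` (record_id, category, subcategory, molecule) and `truth`
#'   (record_id, true_v_gene, true_j_gene, emitting_v_copy, true_substitutions,
#'   true_insertions, true_deletions, true_coverage_class, is_duplicate,
#'   edit_script, germline_length).
#' @export
generate_cohort <- function(spec, reference) {
  stopifnot(inherits(spec, "CohortSpec"))
  check_spec_against_reference(spec, reference)
  vc <- assignment_candidates(reference, "V")
  jc <- assignment_candidates(reference, "J")
  j_locus <- jc$locus[match(names(spec$j_usage), jc$gene_id)]

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  n <- spec$n_sequences
  cap <- 2L * n + 1L   # room for duplicates
  id <- character(cap); seq_out <- character(cap)
  v_canon_v <- character(cap); v_copy_v <- character(cap)
  j_gene_v <- character(cap); cls_v <- character(cap)
  subs_v <- integer(cap); ins_v <- integer(cap); del_v <- integer(cap)
  dup_v <- logical(cap); script_v <- character(cap); glen_v <- integer(cap)
  m <- 0L

  if (n > 0L) {
    v_draw <- sample(names(spec$gene_usage), n, replace = TRUE, prob = spec$gene_usage)
    for (i in seq_len(n)) {
      v_canon <- v_draw[i]
      copies <- vc$gene_id[vc$paralog_canonical == v_canon]
      v_copy <- if (length(copies) == 1L) copies else sample(copies, 1L)
      v_locus <- vc$locus[vc$gene_id == v_copy]
      j_ok <- j_locus == v_locus
      j_gene <- sample(names(spec$j_usage)[j_ok], 1L,
                       prob = spec$j_usage[j_ok] / sum(spec$j_usage[j_ok]))
      germ <- paste0(vc$aa_seq[vc$gene_id == v_copy],
                     jc$aa_seq[jc$gene_id == j_gene])
      mut <- simulate_shm(germ, spec$sub_rate, spec$ins_rate, spec$del_rate)
      u <- stats::runif(1)
      cls <- if (u < spec$exclude_prob) "excluded"
             else if (u < spec$exclude_prob + spec$truncate_prob) "incomplete"
             else "complete"
      out_seq <- mut$seq
      if (cls != "complete")
        out_seq <- truncate_record(mut$seq, reference$cdr_windows,
                                   intend_excluded = cls == "excluded")
      m <- m + 1L
      id[m] <- sprintf("%s_%05d", spec$name, i)
      seq_out[m] <- out_seq
      v_canon_v[m] <- v_canon; v_copy_v[m] <- v_copy; j_gene_v[m] <- j_gene
      cls_v[m] <- cls; subs_v[m] <- mut$substitutions
      ins_v[m] <- mut$insertions; del_v[m] <- mut$deletions
      dup_v[m] <- FALSE; script_v[m] <- serialize_edits(mut$edits)
      glen_v[m] <- nchar(germ)
      if (stats::runif(1) < spec$duplicate_prob) {
        dup_seq <- out_seq
        extra <- 0L
        if (stats::runif(1) < 0.5 && nchar(out_seq) > 0L) {
          pos <- sample.int(nchar(dup_seq), 1L)
          aa <- sample(setdiff(AA20, substr(dup_seq, pos, pos)), 1L)
          substr(dup_seq, pos, pos) <- aa
          extra <- 1L
        }
        m <- m + 1L
        id[m] <- paste0(id[m - 1L], "_dup")
        seq_out[m] <- dup_seq
        v_canon_v[m] <- v_canon; v_copy_v[m] <- v_copy; j_gene_v[m] <- j_gene
        cls_v[m] <- cls; subs_v[m] <- mut$substitutions + extra
        ins_v[m] <- mut$insertions; del_v[m] <- mut$deletions
        dup_v[m] <- TRUE; script_v[m] <- NA_character_
        glen_v[m] <- nchar(germ)
      }
    }
  }
  keep <- seq_len(m)
  structure(list(
    sequences = setNames(seq_out[keep], id[keep]),
    metadata = data.frame(record_id = id[keep],
                          category = rep(spec$category, m),
                          subcategory = rep(spec$name, m),
                          molecule = rep("protein", m),
                          stringsAsFactors = FALSE),
    truth = data.frame(record_id = id[keep], true_v_gene = v_canon_v[keep],
                       true_j_gene = j_ambiguity_label(j_gene_v[keep]),
                       emitting_v_copy = v_copy_v[keep],
                       true_substitutions = subs_v[keep],
                       true_insertions = ins_v[keep],
                       true_deletions = del_v[keep],
                       true_coverage_class = cls_v[keep],
                       is_duplicate = dup_v[keep],
                       edit_script = script_v[keep],
                       germline_length = glen_v[keep],
                       stringsAsFactors = FALSE),
    spec = spec), class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort", shQuote(x$spec$name), ":", length(x$sequences),
      "records (", sum(x$truth$is_duplicate), "duplicates )\n")
  invisible(x)
}

CODON1 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
            H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
            P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
            W = "TGG", Y = "TAT")

#' Back-translate an amino-acid sequence with a fixed codon table
#'
#' One canonical codon per amino acid; used to exercise the nucleotide input
#' path (frame selection, stop-codon rejection) with a known protein answer.
#'
#' @param aa_seq amino-acid string.
#' @param frame_shift number of leading nucleotides (0-2) prepended to move
#'   the reading frame, useful for testing frame recovery.
#' @return nucleotide string.
#' @export
back_translate <- function(aa_seq, frame_shift = 0L) {
  chars <- strsplit(aa_seq, "")[[1]]
  bad <- setdiff(chars, names(CODON1))
  if (length(bad) > 0L)
    stop_lcrep("cannot back-translate residue(s): ", paste(unique(bad), collapse = ", "))
  paste0(strrep("G", frame_shift), paste(CODON1[chars], collapse = ""))
}

#' Write a synthetic cohort to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>_metadata.tsv` and `<prefix>_truth.tsv`.
#' Output is byte-stable for a fixed spec.
#'
#' @param cohort a `SyntheticCohort`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, prefix) {
  fa <- paste0(prefix, ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(cohort$sequences)),
                             cohort$sequences)), fa)
  mt <- paste0(prefix, "_metadata.tsv")
  write.table(cohort$metadata, mt, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- paste0(prefix, "_truth.tsv")
  write.table(cohort$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, mt, tr))
}
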