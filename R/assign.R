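#' Germline V/J assignment
#'
#' Each rearranged light-chain record is aligned against every same-locus
#' concatenated V+J germline template (functional genes only) with an
#' affine-gap BLOSUM62 alignment that is global on the query and ends-free on
#' the germline, so N-/C-terminal truncation of the record is treated as
#' missing coverage rather than as deletion mutations. The best-scoring (V, J)
#' pair wins; ties break by fewest edits, then lexicographic gene ids, making
#' assignment invariant to reference ordering. Reported V genes are
#' paralog-collapsed and J genes pass the IGLJ2/IGLJ3 merge.
#'
#' For throughput, all queries are aligned against one template per call
#' (Biostrings vectorises over patterns), so a repertoire costs one call per
#' template rather than one per record.
#'
#' @name germline_assignment
#' @keywords internal
NULL

ALIGN_GAP_OPEN <- 10
ALIGN_GAP_EXTEND <- 1

# all same-locus functional V+J concatenations of a reference
build_templates <- function(reference) {
  vc <- assignment_candidates(reference, "V")
  jc <- assignment_candidates(reference, "J")
  rows <- list()
  for (i in seq_len(nrow(vc))) {
    jj <- jc[jc$locus == vc$locus[i], , drop = FALSE]
    rows[[i]] <- data.frame(
      v_copy = vc$gene_id[i], j_copy = jj$gene_id,
      locus = vc$locus[i], v_len = nchar(vc$aa_seq[i]),
      template = paste0(vc$aa_seq[i], jj$aa_seq),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$template_len <- nchar(out$template)
  out
}

# queries global (pattern), germline ends-free (subject)
align_batch <- function(queries, template) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(template),
    type = "global-local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
}

# substitutions / insertions (gap in germline = subject) / deletions (gap in
# query = pattern) for every pair of a PairwiseAlignments object, via the
# vectorised accessors; end-gaps never occur by construction, so every gap
# is a real indel and identity = matches / alignment columns
edit_table <- function(pa) {
  ni <- Biostrings::nindel(pa)
  ins <- Biostrings::insertion(ni)[, "WidthSum"]
  del <- Biostrings::deletion(ni)[, "WidthSum"]
  matches <- Biostrings::nmatch(pa)
  mism <- Biostrings::nmismatch(pa)
  columns <- matches + mism + ins + del
  data.frame(substitutions = mism, insertions = ins, deletions = del,
             matches = matches, columns = columns,
             identity = 100 * matches / columns,
             germline_start = Biostrings::start(Biostrings::subject(pa)),
             germline_end = Biostrings::end(Biostrings::subject(pa)),
             query_start = Biostrings::start(Biostrings::pattern(pa)),
             query_end = Biostrings::end(Biostrings::pattern(pa)))
}

# The ends-free alignment clips a terminal mismatch from both strings at no
# cost, which would misclassify a fully covered record with a substitution in
# its first or last position. Re-pair clipped overhangs ungapped: paired
# positions are counted as matches/substitutions and extend the germline
# span; query residues left over once the germline end is reached are
# terminal insertions.
extend_terminal <- function(d, query, template) {
  qlen <- nchar(query); tlen <- nchar(template)
  left <- min(d$query_start - 1L, d$germline_start - 1L)
  if (left > 0L) {
    qs <- substr(query, d$query_start - left, d$query_start - 1L)
    gs <- substr(template, d$germline_start - left, d$germline_start - 1L)
    mm <- hamming_str(qs, gs)
    d$substitutions <- d$substitutions + mm
    d$matches <- d$matches + (left - mm)
    d$columns <- d$columns + left
    d$germline_start <- d$germline_start - left
    d$query_start <- d$query_start - left
  }
  right <- min(qlen - d$query_end, tlen - d$germline_end)
  if (right > 0L) {
    qs <- substr(query, d$query_end + 1L, d$query_end + right)
    gs <- substr(template, d$germline_end + 1L, d$germline_end + right)
    mm <- hamming_str(qs, gs)
    d$substitutions <- d$substitutions + mm
    d$matches <- d$matches + (right - mm)
    d$columns <- d$columns + right
    d$germline_end <- d$germline_end + right
    d$query_end <- d$query_end + right
  }
  # query residues beyond a fully covered germline end are insertions
  extra <- (d$query_start - 1L) * (d$germline_start == 1L) +
    (qlen - d$query_end) * (d$germline_end == tlen)
  if (extra > 0L) {
    d$insertions <- d$insertions + extra
    d$columns <- d$columns + extra
  }
  d$identity <- 100 * d$matches / d$columns
  d
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# frames of a nucleotide sequence that translate without internal stops
productive_frames <- function(nt_seq) {
  out <- character(0)
  for (f in 0:2) {
    body <- substring(nt_seq, f + 1L)
    body <- substring(body, 1L, 3L * (nchar(body) %/% 3L))
    if (nchar(body) < 60L) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(body), if.fuzzy.codon = "X"))
    if (!grepl("\\*", aa)) out <- c(out, aa)
  }
  out
}

#' Classify V-J coverage of an assigned record
#'
#' Coverage classes follow the counting rules of the repository analysis:
#' `complete` — the full germline V-J span is aligned and the record has no
#' missing or ambiguous residues; `incomplete` — V and J genes are
#' unambiguously assigned, the record retains at least `min_residues`
#' contiguous unambiguous residues, and the aligned germline span covers all
#' three CDR windows; anything else is `excluded`. Complete and incomplete
#' records enter gene-usage counting; excluded records do not.
#'
#' @param assignment a single-row assignment (or list) with `v_gene` (or
#'   `v_call`), `germline_start`, `germline_end`, `template_len`, `v_len`.
#' @param seq the record's amino-acid sequence.
#' @param cdr_windows three CDR intervals on the template scale.
#' @param min_residues contiguous-residue floor for the incomplete class.
#' @return one of "complete", "incomplete", "excluded".
#' @export
classify_coverage <- function(assignment, seq,
                              cdr_windows = default_cdr_windows(),
                              min_residues = 80L) {
  v <- assignment$v_gene %||% assignment$v_call
  if (is.null(v) || is.na(v)) return("excluded")
  gs <- assignment$germline_start
  ge <- assignment$germline_end
  tlen <- assignment$template_len
  has_x <- grepl("X", seq, fixed = TRUE)
  if (!has_x && gs == 1L && ge == tlen) return("complete")
  runs <- nchar(strsplit(seq, "X", fixed = TRUE)[[1]])
  if (length(runs) == 0L || max(runs) < min_residues) return("excluded")
  covers_v <- gs <= assignment$v_len
  covers_j <- ge > assignment$v_len
  cdr_ok <- all(vapply(cdr_windows, function(w)
    gs <= w[1] && ge >= min(w[2], tlen), logical(1)))
  if (covers_v && covers_j && cdr_ok) "incomplete" else "excluded"
}

excluded_row <- function(record_id, reason) data.frame(
  sequence_id = record_id, v_call = NA_character_, j_call = NA_character_,
  v_copy = NA_character_, j_copy = NA_character_, locus = NA_character_,
  score = NA_real_, identity = NA_real_,
  substitutions = NA_integer_, insertions = NA_integer_,
  deletions = NA_integer_, germline_length = NA_integer_,
  germline_start = NA_integer_, germline_end = NA_integer_,
  template_len = NA_integer_, v_len = NA_integer_,
  coverage_class = "excluded", exclusion_reason = reason,
  stringsAsFactors = FALSE)

# core driver over protein sequences (already frame-resolved)
assign_protein_batch <- function(sequences, templates, reference,
                                 min_identity, cdr_windows, min_residues) {
  ids <- names(sequences)
  n <- length(sequences)
  if (n == 0L) return(NULL)
  rows <- vector("list", n)
  ok <- nchar(sequences) >= 20L
  for (i in which(!ok)) rows[[i]] <- excluded_row(ids[i], "too short")
  if (any(ok)) {
    qs <- Biostrings::AAStringSet(unname(sequences[ok]))
    n_ok <- sum(ok)
    n_tpl <- nrow(templates)
    scores <- matrix(NA_real_, n_ok, n_tpl)
    edits <- vector("list", n_tpl)
    for (t in seq_len(n_tpl)) {
      pa <- align_batch(qs, templates$template[t])
      scores[, t] <- Biostrings::score(pa)
      edits[[t]] <- edit_table(pa)
    }
    total_edits <- vapply(edits, function(e)
      e$substitutions + e$insertions + e$deletions, numeric(n_ok))
    total_edits <- matrix(total_edits, nrow = n_ok)
    idx_ok <- which(ok)
    for (k in seq_along(idx_ok)) {
      i <- idx_ok[k]
      top <- which(scores[k, ] == max(scores[k, ]))
      top <- top[total_edits[k, top] == min(total_edits[k, top])]
      best <- top[order(templates$v_copy[top], templates$j_copy[top])[1]]
      d <- extend_terminal(edits[[best]][k, ], sequences[[i]],
                           templates$template[best])
      if (d$identity < min_identity) {
        rows[[i]] <- excluded_row(ids[i], "unassignable")
        next
      }
      row <- data.frame(
        sequence_id = ids[i],
        v_call = collapse_paralog(templates$v_copy[best], reference),
        j_call = j_ambiguity_label(templates$j_copy[best], reference),
        v_copy = templates$v_copy[best], j_copy = templates$j_copy[best],
        locus = templates$locus[best],
        score = scores[k, best], identity = d$identity,
        substitutions = d$substitutions, insertions = d$insertions,
        deletions = d$deletions,
        germline_length = d$germline_end - d$germline_start + 1L,
        germline_start = d$germline_start, germline_end = d$germline_end,
        template_len = templates$template_len[best],
        v_len = templates$v_len[best],
        coverage_class = NA_character_, exclusion_reason = NA_character_,
        stringsAsFactors = FALSE)
      row$coverage_class <- classify_coverage(row, sequences[[i]],
                                              cdr_windows, min_residues)
      rows[[i]] <- row
    }
  }
  rbind_rows(rows)
}

#' Assign a single record to its germline V and J genes
#'
#' @param seq amino-acid (or nucleotide, with `molecule = "nucleotide"`)
#'   sequence of the record.
#' @param reference a `ReferenceSet`.
#' @param record_id identifier carried into the result.
#' @param molecule "protein" or "nucleotide". Nucleotide input is translated
#'   in the forward frame that maximises the germline alignment score; frames
#'   containing internal stop codons are rejected, and a record with no clean
#'   frame is excluded as non-productive.
#' @param min_identity minimum percent identity of the best alignment; below
#'   the floor the record is excluded with reason "unassignable".
#' @return one-row data.frame with AIRR-style columns (`sequence_id`,
#'   `v_call`, `j_call`, edit counts, `germline_length`, `coverage_class`,
#'   `exclusion_reason`, alignment bookkeeping).
#' @examples
#' ref <- bundled_reference()
#' g <- paste0(ref$genes$aa_seq[ref$genes$gene_id == "IGKV1-33"],
#'             ref$genes$aa_seq[ref$genes$gene_id == "IGKJ1"])
#' assign_germline(g, ref)[, c("v_call", "j_call", "substitutions")]
#' @export
assign_germline <- function(seq, reference, record_id = "query",
                            molecule = c("protein", "nucleotide"),
                            min_identity = 50) {
  molecule <- match.arg(molecule)
  assign_repertoire(setNames(seq, record_id), reference,
                    metadata = data.frame(record_id = record_id,
                                          molecule = molecule,
                                          stringsAsFactors = FALSE),
                    min_identity = min_identity)
}

#' Assign every record of a repertoire
#'
#' Vectorised driver over a named sequence vector (names are record ids) with
#' an optional metadata table carrying `molecule`, `category`, `subcategory`.
#'
#' @param sequences named character vector of sequences.
#' @param reference a `ReferenceSet`.
#' @param metadata optional data.frame keyed by `record_id`.
#' @param min_identity see [assign_germline()].
#' @param min_residues contiguous-residue floor of the incomplete class.
#' @return data.frame, one row per record, metadata columns appended.
#' @export
assign_repertoire <- function(sequences, reference, metadata = NULL,
                              min_identity = 50, min_residues = 80L) {
  stopifnot(!is.null(names(sequences)))
  templates <- build_templates(reference)
  cdrw <- reference$cdr_windows
  molecule <- rep("protein", length(sequences))
  if (!is.null(metadata) && "molecule" %in% names(metadata))
    molecule <- metadata$molecule[match(names(sequences), metadata$record_id)]

  is_nt <- !is.na(molecule) & molecule == "nucleotide"
  # resolve nucleotide records to their best productive frame
  aa_seqs <- sequences
  nonproductive <- rep(FALSE, length(sequences))
  for (i in which(is_nt)) {
    frames <- productive_frames(sequences[[i]])
    if (length(frames) == 0L) { nonproductive[i] <- TRUE; next }
    if (length(frames) == 1L) { aa_seqs[[i]] <- frames[[1]]; next }
    best_sc <- -Inf
    for (aa in frames) {
      sc <- max(vapply(templates$template, function(tp)
        Biostrings::score(align_batch(aa, tp)), numeric(1)))
      if (sc > best_sc) { best_sc <- sc; aa_seqs[[i]] <- aa }
    }
  }

  rows_np <- lapply(names(sequences)[nonproductive], excluded_row,
                    reason = "non-productive")
  live <- !nonproductive
  out_live <- assign_protein_batch(aa_seqs[live], templates, reference,
                                   min_identity, cdrw, min_residues)
  out <- rbind(out_live, rbind_rows(rows_np))
  out <- out[match(names(sequences), out$sequence_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(metadata)) {
    keep <- setdiff(names(metadata), "molecule")
    out <- merge(out, metadata[, keep, drop = FALSE],
                 by.x = "sequence_id", by.y = "record_id",
                 all.x = TRUE, sort = FALSE)
    out <- out[match(names(sequences), out$sequence_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
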