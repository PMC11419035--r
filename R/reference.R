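#' Germline V/J reference sets
#'
#' A `ReferenceSet` holds the germline V and J gene segments that rearranged
#' light-chain sequences are assigned to, together with the three CDR windows
#' on the V-J coordinate scale used by the coverage classifier. Genes carry a
#' locus (IGK or IGL), a segment (V or J), a functionality flag and a paralog
#' collapse target: proximal/distal IGKV paralog pairs cannot be distinguished
#' by mRNA alignment, so both members are counted under the proximal gene name.
#'
#' @name ReferenceSet
#' @keywords internal
NULL

new_reference_set <- function(genes, cdr_windows) {
  structure(list(genes = genes, cdr_windows = cdr_windows),
            class = "ReferenceSet")
}

#' Default CDR windows on the IMGT-style V-J scale
#'
#' Position intervals (1-based, inclusive) of the three complementarity
#' determining regions used by the coverage rule. Defaults follow the IMGT
#' unique-numbering CDR intervals; they are configurable because references
#' differ in gapping conventions.
#'
#' @return list of three integer vectors `c(start, end)`.
#' @export
default_cdr_windows <- function() {
  list(cdr1 = c(27L, 38L), cdr2 = c(56L, 65L), cdr3 = c(105L, 117L))
}

validate_reference_set <- function(ref) {
  g <- ref$genes
  need <- c("gene_id", "locus", "segment", "functional", "paralog_canonical", "aa_seq")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0L)
    stop_lcrep("reference metadata is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop_lcrep("duplicate gene id(s): ",
               paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  if (!all(g$locus %in% c("IGK", "IGL")))
    stop_lcrep("locus must be IGK or IGL")
  if (!all(g$segment %in% c("V", "J")))
    stop_lcrep("segment must be V or J")
  if (!is.logical(g$functional))
    stop_lcrep("functional must be logical")
  bad_seq <- !vapply(strsplit(g$aa_seq, ""), function(ch)
    length(ch) > 0L && all(ch %in% AA20), logical(1))
  if (any(bad_seq))
    stop_lcrep("non-amino-acid character or empty sequence in gene(s): ",
               paste(g$gene_id[bad_seq], collapse = ", "))
  # paralog target must exist, same locus and segment
  idx <- match(g$paralog_canonical, g$gene_id)
  if (anyNA(idx))
    stop_lcrep("paralog_canonical refers to unknown gene(s): ",
               paste(g$paralog_canonical[is.na(idx)], collapse = ", "))
  if (!all(g$locus == g$locus[idx] & g$segment == g$segment[idx]))
    stop_lcrep("paralog_canonical must point to a gene of the same locus and segment")
  # canonical targets must be fixed points so collapsing is idempotent
  canon <- unique(g$paralog_canonical)
  if (!all(g$paralog_canonical[match(canon, g$gene_id)] == canon))
    stop_lcrep("paralog_canonical targets must themselves be canonical")
  for (loc in unique(g$locus)) {
    for (seg in c("V", "J")) {
      if (!any(g$locus == loc & g$segment == seg & g$functional))
        stop_lcrep("reference has no functional ", seg, " gene for locus ", loc)
    }
  }
  w <- ref$cdr_windows
  if (length(w) != 3L || !all(vapply(w, length, 1L) == 2L))
    stop_lcrep("cdr_windows must be three start/end intervals")
  wm <- do.call(rbind, w)
  if (any(wm[, 1] > wm[, 2]) || is.unsorted(as.vector(t(wm)), strictly = TRUE))
    stop_lcrep("cdr_windows must be ordered and non-overlapping")
  ref
}

#' Load a germline V/J reference
#'
#' Reads germline amino-acid sequences from FASTA plus a tab-separated
#' metadata table with columns `gene_id`, `locus`, `segment`, `functional`,
#' `paralog_canonical`. Every FASTA record must have a metadata row and vice
#' versa. Non-functional genes are retained, flagged, and never used as
#' assignment candidates.
#'
#' @param fasta_path path to the reference FASTA (amino acid).
#' @param metadata_path path to the tab-separated metadata table.
#' @param cdr_windows three CDR position intervals on the V-J scale; see
#'   [default_cdr_windows()].
#' @return a `ReferenceSet`.
#' @examples
#' ref <- load_reference(
#'   system.file("extdata", "germline_synthetic.fasta", package = "lcrep"),
#'   system.file("extdata", "germline_synthetic.tsv", package = "lcrep"))
#' nrow(ref$genes)
#' @export
load_reference <- function(fasta_path, metadata_path,
                           cdr_windows = default_cdr_windows()) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop_lcrep("duplicate FASTA id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$gene_id))
    stop_lcrep("duplicate metadata gene_id(s): ",
               paste(unique(meta$gene_id[duplicated(meta$gene_id)]), collapse = ", "))
  no_meta <- setdiff(ids, meta$gene_id)
  if (length(no_meta) > 0L)
    stop_lcrep("FASTA record(s) without metadata row: ",
               paste(no_meta, collapse = ", "))
  no_seq <- setdiff(meta$gene_id, ids)
  if (length(no_seq) > 0L)
    stop_lcrep("metadata row(s) without FASTA record: ",
               paste(no_seq, collapse = ", "))
  meta$functional <- as.logical(meta$functional)
  meta$aa_seq <- as.character(seqs)[match(meta$gene_id, ids)]
  validate_reference_set(new_reference_set(meta, cdr_windows))
}

#' Build a ReferenceSet from an in-memory gene table
#'
#' Programmatic counterpart of [load_reference()]; mainly used by the
#' synthetic-data tooling and tests.
#'
#' @param genes data.frame with the reference metadata columns plus `aa_seq`.
#' @param cdr_windows see [default_cdr_windows()].
#' @return a `ReferenceSet`.
#' @export
reference_set <- function(genes, cdr_windows = default_cdr_windows()) {
  validate_reference_set(new_reference_set(genes, cdr_windows))
}

#' @export
print.ReferenceSet <- function(x, ...) {
  g <- x$genes
  cat("ReferenceSet:", nrow(g), "genes (",
      sum(g$segment == "V"), "V,", sum(g$segment == "J"), "J;",
      sum(g$functional), "functional )\n")
  cat("  loci:", paste(sort(unique(g$locus)), collapse = ", "), "\n")
  w <- vapply(x$cdr_windows, paste, "", collapse = "-")
  cat("  CDR windows:", paste(w, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse an IGKV paralog to its proximal (canonical) gene
#'
#' Proximal/distal IGKV paralog pairs are treated as the same gene and counted
#' under the proximal name (e.g. IGKV1D-33 is counted as IGKV1-33). Collapse is
#' idempotent: a canonical id maps to itself.
#'
#' @param gene_id gene id(s) present in the reference.
#' @param reference a `ReferenceSet`.
#' @return canonical gene id(s).
#' @export
collapse_paralog <- function(gene_id, reference) {
  idx <- match(gene_id, reference$genes$gene_id)
  if (anyNA(idx))
    stop_lcrep("unknown gene id(s): ", paste(gene_id[is.na(idx)], collapse = ", "))
  reference$genes$paralog_canonical[idx]
}

#' Reported label for a J gene, merging IGLJ2/IGLJ3
#'
#' IGLJ2 and IGLJ3 encode indistinguishable protein sequences and cannot be
#' unambiguously assigned; both report the merged label "IGLJ2/IGLJ3". All
#' other J genes report themselves.
#'
#' @param gene_id J gene id(s).
#' @param reference optional `ReferenceSet` used to verify the segment; when
#'   supplied, non-J ids raise an error.
#' @return reported label(s).
#' @export
j_ambiguity_label <- function(gene_id, reference = NULL) {
  if (!is.null(reference)) {
    idx <- match(gene_id, reference$genes$gene_id)
    if (anyNA(idx))
      stop_lcrep("unknown gene id(s): ", paste(gene_id[is.na(idx)], collapse = ", "))
    if (any(reference$genes$segment[idx] != "J"))
      stop_lcrep("j_ambiguity_label applies to J genes only; got: ",
                 paste(gene_id[reference$genes$segment[idx] != "J"], collapse = ", "))
  } else if (any(!grepl("^IG[KL]J", gene_id))) {
    stop_lcrep("j_ambiguity_label applies to J genes only; got: ",
               paste(gene_id[!grepl("^IG[KL]J", gene_id)], collapse = ", "))
  }
  ifelse(gene_id %in% c("IGLJ2", "IGLJ3"), "IGLJ2/IGLJ3", gene_id)
}

#' Assignment candidates of a reference
#'
#' Functional genes of one segment, the only genes eligible for germline
#' assignment.
#'
#' @param reference a `ReferenceSet`.
#' @param segment "V" or "J".
#' @return data.frame subset of the gene table.
#' @export
assignment_candidates <- function(reference, segment) {
  g <- reference$genes
  g[g$segment == segment & g$functional, , drop = FALSE]
}

#' Bundled synthetic test reference
#'
#' Loads the reference shipped under `inst/extdata`: 12 V and 4 J genes with
#' real IMGT gene names but synthetic sequences (the files are labelled
#' accordingly). It encodes two IGKV proximal/distal paralog pairs with
#' identical sequences and the IGLJ2/IGLJ3 pair with identical sequences.
#'
#' @inheritParams load_reference
#' @return a `ReferenceSet`.
#' @export
bundled_reference <- function(cdr_windows = default_cdr_windows()) {
  load_reference(
    system.file("extdata", "germline_synthetic.fasta", package = "lcrep"),
    system.file("extdata", "germline_synthetic.tsv", package = "lcrep"),
    cdr_windows = cdr_windows)
}
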