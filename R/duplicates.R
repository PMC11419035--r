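#' Collapse duplicate and near-identical records
#'
#' Repository depositions often contain the same clone several times —
#' multiple colonies from one cloning procedure, or re-deposited updates.
#' Records with pairwise identity at or above a threshold are clustered
#' (single linkage) and replaced by one entry: when the members agree
#' everywhere they overlap, the longest, most complete record is retained
#' (nucleotide-derived preferred over protein-only); otherwise a per-column
#' majority consensus is built, and a cluster whose consensus has a tied
#' column is excluded as ambiguous.
#'
#' @name duplicate_collapsing
#' @keywords internal
NULL

# mismatch counts between equal-length sequences via one-hot crossproduct;
# returns pair list (i, j, identity)
equal_length_pairs <- function(seqs, threshold) {
  n <- length(seqs)
  if (n < 2L) return(NULL)
  L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  alpha <- sort(unique(as.vector(mat)))
  onehot <- matrix(0L, n, L * length(alpha))
  for (k in seq_along(alpha)) {
    idx <- which(mat == alpha[k], arr.ind = TRUE)
    onehot[cbind(idx[, 1], (idx[, 2] - 1L) * length(alpha) + k)] <- 1L
  }
  matches <- tcrossprod(onehot)
  ident <- matches / L
  hits <- which(upper.tri(ident) & ident >= threshold, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  data.frame(i = hits[, 1], j = hits[, 2],
             identity = ident[hits], stringsAsFactors = FALSE)
}

# union-find single linkage
cluster_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (!is.null(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges$i[k]); b <- find(edges$j[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

# anchor-based column votes for a cluster; returns consensus string or NA on tie
column_consensus <- function(seqs) {
  lens <- nchar(seqs)
  anchor <- seqs[[which.max(lens)]]
  L <- nchar(anchor)
  votes <- matrix("", nrow = length(seqs), ncol = L)
  for (m in seq_along(seqs)) {
    if (nchar(seqs[[m]]) == L) {
      votes[m, ] <- strsplit(seqs[[m]], "")[[1]]
    } else {
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(anchor),
        subject = Biostrings::AAString(seqs[[m]]),
        type = "global-local", substitutionMatrix = "BLOSUM62",
        gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
      p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      col <- cumsum(p != "-")            # anchor coordinate of each column
      keep <- p != "-" & s != "-"
      row <- rep("", L)
      row[col[keep]] <- s[keep]
      votes[m, ] <- row
    }
  }
  cons <- character(L)
  for (j in seq_len(L)) {
    v <- votes[, j]
    v <- v[nzchar(v)]
    if (length(v) == 0L) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return(NA_character_)
    cons[j] <- names(tab)[1]
  }
  paste(cons, collapse = "")
}

#' Collapse duplicates in a set of records
#'
#' @param sequences named character vector (names are record ids).
#' @param metadata optional data.frame with `record_id` and `molecule`
#'   ("nucleotide" records are preferred representatives over "protein").
#' @param identity_threshold pairwise identity in `(0.9, 1]` above which two
#'   records are considered the same clone; default 0.98.
#' @return list with `kept` (named vector: untouched records plus retained
#'   representatives), `consensus` (data.frame `record_id`, `seq`, `members`),
#'   and `log` (data.frame `record_id`, `fate`, `reason`) accounting for every
#'   input record exactly once.
#' @export
collapse_duplicates <- function(sequences, metadata = NULL,
                                identity_threshold = 0.98) {
  stopifnot(identity_threshold > 0.9, identity_threshold <= 1,
            !is.null(names(sequences)))
  ids <- names(sequences)
  n <- length(sequences)
  molecule <- rep("protein", n)
  if (!is.null(metadata) && "molecule" %in% names(metadata))
    molecule <- metadata$molecule[match(ids, metadata$record_id)]

  # candidate edges: equal-length one-hot Hamming, plus cross-length pairs
  # sharing a terminus (cheap prescreen) scored by edit distance
  edges <- NULL
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    e <- equal_length_pairs(unname(sequences[idx]), identity_threshold)
    if (!is.null(e)) {
      e$i <- idx[e$i]; e$j <- idx[e$j]
      edges <- rbind(edges, e)
    }
  }
  if (length(unique(lens)) > 1L) {
    pre <- substr(sequences, 1L, 15L)
    suf <- substr(sequences, pmax(1L, lens - 14L), lens)
    cand <- which(outer(lens, lens, "!=") &
                  (outer(pre, pre, "==") | outer(suf, suf, "==")) &
                  upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        d <- utils::adist(sequences[[i]], sequences[[j]])[1, 1]
        ident <- 1 - d / max(lens[i], lens[j])
        if (ident >= identity_threshold)
          edges <- rbind(edges, data.frame(i = i, j = j, identity = ident))
      }
    }
  }

  comp <- cluster_edges(n, edges)
  kept <- character(0); cons_rows <- list(); log_rows <- list()
  add_log <- function(id, fate, reason = NA_character_)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      record_id = id, fate = fate, reason = reason, stringsAsFactors = FALSE)

  for (cl in unique(comp)) {
    members <- which(comp == cl)
    if (length(members) == 1L) {
      kept[ids[members]] <- sequences[[members]]
      add_log(ids[members], "kept")
      next
    }
    mseqs <- sequences[members]
    cons <- column_consensus(unname(mseqs))
    if (is.na(cons)) {
      for (m in members) add_log(ids[m], "excluded", "ambiguous consensus")
      next
    }
    # if the consensus equals an existing member over its full length, retain
    # that record (longest first, nucleotide-derived preferred)
    ord <- members[order(-lens[members], molecule[members] != "nucleotide",
                         ids[members])]
    hit <- NA_integer_
    for (m in ord) {
      if (sequences[[m]] == cons) { hit <- m; break }
    }
    if (!is.na(hit)) {
      kept[ids[hit]] <- sequences[[hit]]
      add_log(ids[hit], "kept")
      for (m in setdiff(members, hit)) add_log(ids[m], "merged", ids[hit])
    } else {
      cid <- paste0("consensus_", ids[ord[1]])
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        record_id = cid, seq = cons,
        members = paste(ids[members], collapse = ","),
        stringsAsFactors = FALSE)
      for (m in members) add_log(ids[m], "merged", cid)
    }
  }
  list(kept = kept,
       consensus = if (length(cons_rows)) do.call(rbind, cons_rows)
                   else data.frame(record_id = character(0), seq = character(0),
                                   members = character(0)),
       log = do.call(rbind, c(log_rows, make.row.names = FALSE)))
}
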