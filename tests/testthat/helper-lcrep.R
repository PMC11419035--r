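# shared fixtures and independent oracles, all built in code

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# small in-code reference: n_v V genes per locus (length v_len) and one J per
# locus (length j_len); optionally a paralog pair on IGK
make_test_reference <- function(n_v = 2L, v_len = 100L, j_len = 20L,
                                paralog = FALSE, seed = 101L,
                                cdr_windows = default_cdr_windows()) {
  withr::local_seed(seed)
  rows <- list()
  for (loc in c("IGK", "IGL")) {
    for (i in seq_len(n_v)) {
      id <- sprintf("%sV%d-%d", loc, i, i * 10 + 1)
      rows[[id]] <- data.frame(gene_id = id, locus = loc, segment = "V",
                               functional = TRUE, paralog_canonical = id,
                               aa_seq = random_aa(v_len),
                               stringsAsFactors = FALSE)
    }
    jid <- paste0(loc, "J1")
    rows[[jid]] <- data.frame(gene_id = jid, locus = loc, segment = "J",
                              functional = TRUE, paralog_canonical = jid,
                              aa_seq = random_aa(j_len),
                              stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (paralog) {
    canon <- genes$gene_id[genes$segment == "V" & genes$locus == "IGK"][1]
    dup <- genes[genes$gene_id == canon, ]
    dup$gene_id <- sub("V1-", "V1D-", canon)
    dup$paralog_canonical <- canon
    genes <- rbind(genes, dup)
  }
  reference_set(genes, cdr_windows)
}

germline_of <- function(ref, v_id, j_id) {
  g <- ref$genes
  paste0(g$aa_seq[g$gene_id == v_id], g$aa_seq[g$gene_id == j_id])
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# independent maximum-likelihood logistic fit: per-gene indicator predictor,
# weighted binomial glm; returns the exponentiated coefficient
glm_or_oracle <- function(a, A, b, B) {
  d <- data.frame(case = c(1, 1, 0, 0), gene = c(1, 0, 1, 0),
                  w = c(a, A - a, b, B - b))
  fit <- stats::glm(case ~ gene, family = stats::binomial(), data = d,
                    weights = d$w,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  exp(unname(stats::coef(fit)["gene"]))
}

# brute-force BH by definition: q_i = smallest FDR level at which p_i would
# be rejected by the step-up rule, i.e. min over thresholds t >= p_i of
# m * t / #{p <= t}, clipped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(m * ts / vapply(ts, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

# multinomial count-level usage table for two cohorts
sim_usage_table <- function(p_case, p_ctrl, n_case, n_ctrl) {
  genes <- names(p_case)
  tab <- data.frame(
    v_gene = genes,
    case = as.integer(stats::rmultinom(1, n_case, p_case)),
    ctrl = as.integer(stats::rmultinom(1, n_ctrl, p_ctrl)),
    stringsAsFactors = FALSE)
  structure(tab, totals = c(case = n_case, ctrl = n_ctrl),
            class = c("GeneUsageTable", "data.frame"))
}
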