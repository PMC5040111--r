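# Independent oracles used across test files. These deliberately recompute
# quantities by a different route than the package implementation.

# All 2^n sign-flip |mean| statistics via an explicit sign matrix.
oracle_signflip_pvalue <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_stats <- abs(signs %*% d) / n
  obs <- abs(mean(d))
  tol <- 1e-10 * (obs + max(abs(d), 1e-300))
  mean(null_stats >= obs - tol)
}

# Spreadsheet-style per-block factorial effects: separate pass over rows.
oracle_effects <- function(table, variable) {
  blocks <- sort(unique(table$block))
  get_cell <- function(b, w, cl) {
    table[[variable]][table$block == b & table$warmed == w &
                        table$clipped == cl]
  }
  per <- t(sapply(blocks, function(b) {
    uu <- get_cell(b, 0, 0)
    w <- 100 * (get_cell(b, 1, 0) - uu) / uu
    c <- 100 * (get_cell(b, 0, 1) - uu) / uu
    oe <- 100 * (get_cell(b, 1, 1) - uu) / uu
    c(W = w, C = c, OE = oe, PE = w + c, OE_minus_PE = oe - (w + c))
  }))
  colMeans(per)
}

# Rule-by-rule enumeration of the gene/probe detection filters.
oracle_detection_filter <- function(records, designed, min_frac = 0.333,
                                    min_probes = 2, min_reps = 2) {
  keep_probe <- vapply(unique(records$probe_id), function(p) {
    length(unique(records$sample_id[records$probe_id == p])) >= min_reps
  }, logical(1))
  surviving_probes <- unique(records$probe_id)[keep_probe]
  r <- records[records$probe_id %in% surviving_probes, ]
  keep_gene <- vapply(unique(r$gene_id), function(g) {
    det <- length(unique(r$probe_id[r$gene_id == g]))
    des <- designed$designed_probes[designed$gene_id == g]
    det / des >= min_frac * (1 - 1e-9) && det >= min_probes
  }, logical(1))
  surviving_genes <- unique(r$gene_id)[keep_gene]
  r[r$gene_id %in% surviving_genes, ]
}

# Classical one-way ANOVA F for two groups of univariate data.
oracle_anova_f <- function(x, groups) {
  unname(summary(stats::aov(x ~ factor(groups)))[[1]]$`F value`[1])
}

# All permutations of 1..n, built independently of the package internals.
oracle_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
          sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
  }))
}

# Small well-formed probe record data frame for hand-built cases.
make_records <- function(...) {
  rows <- list(...)
  defaults <- list(slide_id = "s1", sample_id = "a", subgrid = 1L,
                   probe_id = "p1", gene_id = "g1", category = "cat",
                   signal = 100, background = 10, background_sd = 2,
                   flag = 0L)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, r), stringsAsFactors = FALSE)
  }))
}
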