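# Factorial effect estimation and interaction-direction classification.
#
# For each block, with that block's untreated cell (UU) as denominator:
#   W  = 100 * (UW - UU) / UU      warming effect alone
#   C  = 100 * (CU - UU) / UU      clipping effect alone
#   OE = 100 * (CW - UU) / UU      observed effect of the combined treatment
#   PE = W + C                     predicted additive effect
# The interaction is additive when OE does not differ significantly from PE,
# synergistic when OE is significantly above PE, antagonistic when below.

check_property_table <- function(table) {
  if (!is.data.frame(table)) stop("property table must be a data frame")
  need <- c("block", "warmed", "clipped")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("property table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(table$warmed %in% c(0, 1)) || !all(table$clipped %in% c(0, 1))) {
    stop("`warmed` and `clipped` must be binary flags")
  }
  cells <- table(table$block, paste0(table$warmed, table$clipped))
  if (!all(dim(cells) == c(length(unique(table$block)), 4L)) ||
      any(cells != 1L)) {
    stop("each block must contain exactly one observation per treatment cell")
  }
  invisible(table)
}

#' Per-block factorial effects of warming and clipping
#'
#' Computes, for one variable, per-block percent effects with each block's own
#' UU value as denominator, and their arithmetic means across blocks. The
#' identities `PE = W + C` and `OE_minus_PE = OE - PE` hold exactly per block
#' and in the means.
#'
#' @param table property table: data frame with columns `block`, `warmed`,
#'   `clipped` (binary) and one column per measured variable; one row per
#'   block x treatment cell.
#' @param variable name of the variable column to analyse.
#' @return An `effect_estimate`: list with `variable`, `n_blocks`,
#'   `per_block` (data frame of block-level `W`, `C`, `OE`, `PE`,
#'   `OE_minus_PE`) and `means` (named vector of the same five quantities).
#' @examples
#' tab <- generate_factorial_properties(
#'   factorial_design(6),
#'   list(x = effect_spec(10, warming_pct = 10, seed = 7)))
#' compute_effects(tab, "x")$means
#' @export
compute_effects <- function(table, variable) {
  check_property_table(table)
  if (!variable %in% names(table)) {
    stop("variable '", variable, "' not found in property table")
  }
  v <- table[[variable]]
  if (any(!is.finite(v))) stop("non-finite values for variable '", variable, "'")
  blocks <- sort(unique(table$block))
  cell <- function(w, cl) {
    idx <- table$warmed == w & table$clipped == cl
    v[idx][match(blocks, table$block[idx])]
  }
  uu <- cell(0, 0); uw <- cell(1, 0); cu <- cell(0, 1); cw <- cell(1, 1)
  if (any(uu == 0)) {
    stop("UU value is zero in block ", blocks[which(uu == 0)[1]],
         ": percent effects undefined")
  }
  W <- 100 * (uw - uu) / uu
  C <- 100 * (cu - uu) / uu
  OE <- 100 * (cw - uu) / uu
  PE <- W + C
  per_block <- data.frame(block = blocks, W = W, C = C, OE = OE, PE = PE,
                          OE_minus_PE = OE - PE)
  means <- c(W = mean(W), C = mean(C), OE = mean(OE), PE = mean(PE),
             OE_minus_PE = mean(OE - PE))
  structure(
    list(variable = variable, n_blocks = length(blocks),
         per_block = per_block, means = means),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect_estimate for '%s' (%d blocks)\n", x$variable, x$n_blocks))
  print(round(x$means, 2))
  invisible(x)
}

#' Classical two-tailed paired t test
#'
#' @param x,y paired numeric vectors of equal length `n >= 2`.
#' @return list with `statistic` (t), `p_value` (two-tailed), `df`,
#'   `mean_diff`. All differences zero returns `t = 0, p = 1`; zero variance
#'   with nonzero mean difference is an error (t undefined).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) stop("paired t test needs n >= 2 pairs (df = n - 1 > 0)")
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite differences")
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) {
      return(list(statistic = 0, p_value = 1, df = n - 1, mean_diff = 0))
    }
    stop("zero variance of differences with nonzero mean: t undefined")
  }
  t_stat <- m / (s / sqrt(n))
  list(statistic = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 1),
       df = n - 1, mean_diff = m)
}

# All 2^n sign-flipped sums of d, by recursive doubling (no 2^n x n matrix).
all_signflip_sums <- function(d) {
  sums <- 0
  for (di in d) sums <- c(sums + di, sums - di)
  sums
}

#' Two-tailed sign-flip permutation paired t test
#'
#' The null distribution is generated by flipping the signs of the paired
#' differences; the test statistic is `|mean(d)|` (for fixed magnitudes this
#' orders assignments like `|t|`). The identity assignment is counted in both
#' numerator and denominator, so the smallest attainable two-sided p is
#' `2 / 2^n` under exact enumeration. All `2^n` assignments are enumerated
#' when `n <= max_exact_n`; otherwise `n_perm` Monte-Carlo sign flips are
#' drawn and `p = (count + 1) / (n_perm + 1)`.
#'
#' @param x,y paired numeric vectors, `n >= 2`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed seed for the Monte-Carlo branch (ignored when exact).
#' @param max_exact_n largest n for exhaustive enumeration (default 20).
#' @return list with `p_value`, `statistic` (observed `|mean(d)|`), `exact`
#'   (logical), `n_used` (number of null assignments).
#' @export
permutation_paired_t_test <- function(x, y, n_perm = 9999, seed = 1L,
                                      max_exact_n = 20L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) stop("permutation paired t test needs n >= 2 pairs")
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite differences")
  obs <- abs(mean(d))
  tol <- 1e-10 * (obs + max(abs(d), 1e-300))
  if (n <= max_exact_n) {
    null_stats <- abs(all_signflip_sums(d)) / n
    p <- mean(null_stats >= obs - tol)
    list(p_value = p, statistic = obs, exact = TRUE, n_used = 2L^n)
  } else {
    count <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        if (abs(mean(s * d)) >= obs - tol) hits <- hits + 1L
      }
      hits
    })
    list(p_value = (count + 1) / (n_perm + 1), statistic = obs,
         exact = FALSE, n_used = as.integer(n_perm))
  }
}

#' Classify the warming x clipping interaction direction
#'
#' Tests the per-block OE against PE vectors as a paired comparison and labels
#' the interaction `additive` (p > alpha), `synergistic` (p <= alpha and
#' mean OE > mean PE) or `antagonistic` (p <= alpha and mean OE < mean PE).
#' With `test = "auto"`, the sign-flip permutation test is chosen when a
#' Shapiro-Wilk test rejects normality of the OE - PE differences at
#' `normality_alpha` (or when the differences are degenerate); otherwise the
#' classical paired t test is used. The significance tier is `significant`
#' (p <= alpha), `marginal` (p <= marginal_alpha) or `none`.
#'
#' @param est an `effect_estimate` from [compute_effects()].
#' @param alpha significance level for the interaction label (default 0.05).
#' @param marginal_alpha marginal significance level (default 0.10).
#' @param normality_alpha level of the normality pre-test (default 0.05).
#' @param test `"auto"`, or force `"paired_t"` / `"permutation"`.
#' @param n_perm,seed passed to [permutation_paired_t_test()].
#' @return An `interaction_call`: list with `variable`, `label`, `p_value`,
#'   `test_used`, `tier`, `mean_OE`, `mean_PE`, `mean_OE_minus_PE`.
#' @export
classify_interaction <- function(est, alpha = 0.05, marginal_alpha = 0.10,
                                 normality_alpha = 0.05,
                                 test = c("auto", "paired_t", "permutation"),
                                 n_perm = 9999, seed = 1L) {
  stopifnot(inherits(est, "effect_estimate"))
  test <- match.arg(test)
  oe <- est$per_block$OE
  pe <- est$per_block$PE
  d <- oe - pe

  if (test == "auto") {
    test <- if (all(d == d[1])) {
      # constant differences: Shapiro-Wilk is undefined; the permutation test
      # still has a valid (conservative) answer
      if (d[1] == 0) "paired_t" else "permutation"
    } else if (shapiro.test(d)$p.value < normality_alpha) {
      "permutation"
    } else {
      "paired_t"
    }
  }
  res <- if (test == "paired_t") {
    paired_t_test(oe, pe)
  } else {
    permutation_paired_t_test(oe, pe, n_perm = n_perm, seed = seed)
  }
  p <- res$p_value
  label <- if (p > alpha) {
    "additive"
  } else if (mean(oe) > mean(pe)) {
    "synergistic"
  } else {
    "antagonistic"
  }
  tier <- if (p <= alpha) "significant" else if (p <= marginal_alpha) "marginal" else "none"
  structure(
    list(variable = est$variable, label = label, p_value = p,
         test_used = if (test == "paired_t") "paired_t" else "permutation_paired_t",
         tier = tier, mean_OE = mean(oe), mean_PE = mean(pe),
         mean_OE_minus_PE = mean(d)),
    class = "interaction_call"
  )
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("%s: %s (OE-PE = %.2f, p = %.4f, %s, tier: %s)\n",
              x$variable, x$label, x$mean_OE_minus_PE, x$p_value,
              x$test_used, x$tier))
  invisible(x)
}

#' Effect table for all variables of a property table
#'
#' Convenience wrapper running [compute_effects()] and
#' [classify_interaction()] on every variable column.
#'
#' @inheritParams compute_effects
#' @inheritParams classify_interaction
#' @return data frame with one row per variable: the five mean effects, the
#'   interaction p value, test used, tier and label.
#' @export
effects_table <- function(table, alpha = 0.05, marginal_alpha = 0.10,
                          normality_alpha = 0.05,
                          test = c("auto", "paired_t", "permutation"),
                          n_perm = 9999, seed = 1L) {
  test <- match.arg(test)
  vars <- setdiff(names(table), c("block", "warmed", "clipped"))
  rows <- lapply(vars, function(v) {
    est <- compute_effects(table, v)
    call <- classify_interaction(est, alpha = alpha,
                                 marginal_alpha = marginal_alpha,
                                 normality_alpha = normality_alpha,
                                 test = test, n_perm = n_perm, seed = seed)
    data.frame(variable = v, W = est$means["W"], C = est$means["C"],
               OE = est$means["OE"], PE = est$means["PE"],
               OE_minus_PE = est$means["OE_minus_PE"],
               p_value = call$p_value, test_used = call$test_used,
               tier = call$tier, interaction = call$label,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Category-level treatment effects on gene abundances
#'
#' For one functional category, pairs probe-level (default) or gene-level
#' abundances across treatments within block and reports, per treatment
#' contrast (W: UW vs UU, C: CU vs UU, `W+C`: CW vs UU), the percent change of
#' the mean signal and a two-tailed sign-flip permutation paired t test
#' p value. The number of paired observations is
#' `n = n_blocks x (probes in category)` at probe level, matching the
#' "n = blocks x gene probe number" convention of array studies.
#'
#' Percent changes are computed on the linear (amplified relative abundance)
#' signal scale by default; `scale = "log"` uses the ln(x+1)-transformed
#' values instead.
#'
#' @param matrix a `gene_signal_matrix` from the preprocessing pipeline.
#' @param design a [factorial_design()] whose `sample_id`s match the matrix
#'   columns.
#' @param category functional category label to analyse.
#' @param level `"probe"` (default) or `"gene"` observations.
#' @param scale `"linear"` (default) or `"log"` signal scale.
#' @param n_perm,seed passed to [permutation_paired_t_test()].
#' @return data frame with one row per treatment contrast: `category`,
#'   `treatment`, `pct_change`, `n`, `p_value`.
#' @export
gene_category_effects <- function(matrix, design, category,
                                  level = c("probe", "gene"),
                                  scale = c("linear", "log"),
                                  n_perm = 9999, seed = 1L) {
  stopifnot(inherits(matrix, "gene_signal_matrix"),
            inherits(design, "factorial_design"))
  level <- match.arg(level)
  scale <- match.arg(scale)
  if (level == "probe") {
    vals <- if (scale == "linear") matrix$probe_rescaled else matrix$probe_values
    in_cat <- matrix$probe_map$category == category
  } else {
    vals <- if (scale == "linear") matrix$gene_rescaled else matrix$values
    in_cat <- matrix$genes$category == category
  }
  if (!any(in_cat)) stop("category '", category, "' has no detected members")
  vals <- vals[in_cat, , drop = FALSE]

  tab <- design$table
  missing <- setdiff(tab$sample_id, colnames(vals))
  if (length(missing)) {
    stop("design sample(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  blocks <- sort(unique(tab$block))
  col_by_trt <- function(trt) {
    ids <- tab$sample_id[tab$treatment == trt][
      match(blocks, tab$block[tab$treatment == trt])]
    vals[, ids, drop = FALSE]
  }
  uu <- col_by_trt("UU")
  contrasts <- c(W = "UW", C = "CU", `W+C` = "CW")
  rows <- lapply(names(contrasts), function(lbl) {
    trt <- col_by_trt(contrasts[[lbl]])
    x <- as.vector(trt)   # feature x block, paired with uu entrywise
    y <- as.vector(uu)
    pct <- 100 * (mean(x) - mean(y)) / mean(y)
    p <- permutation_paired_t_test(x, y, n_perm = n_perm, seed = seed)$p_value
    data.frame(category = category, treatment = lbl, pct_change = pct,
               n = length(x), p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
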