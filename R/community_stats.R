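# Dissimilarity-based community statistics: Morisita-Horn dissimilarity,
# pairwise permutational MANOVA (Adonis), Mantel tests, alpha diversity.

check_abundance_matrix <- function(m, min_samples = 2) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("abundance matrix must be a numeric matrix (samples x features)")
  }
  if (nrow(m) < min_samples) stop("need at least ", min_samples, " samples")
  if (any(m < 0)) stop("negative abundances")
  invisible(m)
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square")
  }
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

#' Morisita-Horn (or Horn 1966) dissimilarity matrix
#'
#' Default is the abundance-based Morisita-Horn index, bounded in \[0, 1\] and
#' invariant to per-sample rescaling:
#' `d(x, y) = 1 - 2*sum(x*y) / ((sum(x^2)/X^2 + sum(y^2)/Y^2) * X * Y)`
#' with `X = sum(x)`, `Y = sum(y)`. `variant = "horn1966"` gives the
#' information-theoretic Horn overlap
#' `R0 = (H(x+y)-terms) / ((X+Y)ln(X+Y) - X ln X - Y ln Y)`, as `1 - R0`.
#'
#' @param m abundance matrix, samples as rows (nonnegative; every sample must
#'   have a positive total).
#' @param variant `"morisita"` (default) or `"horn1966"`.
#' @return symmetric samples x samples dissimilarity matrix with zero
#'   diagonal.
#' @export
horn_dissimilarity_matrix <- function(m, variant = c("morisita", "horn1966")) {
  check_abundance_matrix(m)
  variant <- match.arg(variant)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample: ",
         paste(rownames(m)[totals == 0], collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  xlnx <- function(v) sum(ifelse(v > 0, v * log(v), 0))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      x <- m[i, ]; y <- m[j, ]
      X <- totals[i]; Y <- totals[j]
      dij <- if (variant == "morisita") {
        1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
      } else {
        overlap <- (xlnx(x + y) - xlnx(x) - xlnx(y)) /
          ((X + Y) * log(X + Y) - X * log(X) - Y * log(Y))
        1 - overlap
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# Between/within sum-of-squares partition of a distance matrix for a one-way
# grouping (the Gower-centered partition expressed through pairwise
# distances): SS_T = sum_{i<j} d_ij^2 / N, SS_W = sum_g sum_{i<j in g}
# d_ij^2 / n_g.
adonis_pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  a <- length(lev)
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

#' Pairwise permutational MANOVA (Adonis) on a distance matrix
#'
#' Partitions the squared distances into between- and within-group sums of
#' squares and tests the pseudo-F statistic by permuting group labels. On
#' univariate data with Euclidean distances the pseudo-F equals the classical
#' one-way ANOVA F. All distinct label assignments are enumerated (identity
#' included; `p = count(F >= F_obs) / total`) when their number is at most
#' `max_exact`; otherwise `n_perm` Monte-Carlo permutations with
#' `p = (count + 1) / (n_perm + 1)`. With `strata`, labels are permuted only
#' within strata levels (always Monte-Carlo).
#'
#' @param d distance matrix (square symmetric, zero diagonal).
#' @param groups group label per sample; exactly two levels with at least two
#'   samples each.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed RNG seed for the permutations.
#' @param strata optional stratification factor (e.g. block) restricting
#'   permutations.
#' @param max_exact enumeration cutoff on the number of distinct assignments.
#' @return An `adonis_result`: list with `pseudo_F`, `p_value`,
#'   `n_permutations`, `exact`.
#' @export
adonis_pairwise <- function(d, groups, n_perm = 999, seed = 1L,
                            strata = NULL, max_exact = 10000) {
  check_distance_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("`groups` length must match matrix size")
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two group labels required")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group with fewer than 2 samples: ", names(sizes)[sizes < 2][1])
  }
  d2 <- d^2
  f_obs <- adonis_pseudo_f(d2, groups)
  n <- nrow(d)
  n1 <- sum(groups == lev[1])

  if (is.null(strata) && choose(n, n1) <= max_exact) {
    combos <- combn(n, n1)
    f_perm <- apply(combos, 2, function(idx) {
      g <- rep(lev[2], n)
      g[idx] <- lev[1]
      adonis_pseudo_f(d2, g)
    })
    p <- mean(f_perm >= f_obs - 1e-12 * abs(f_obs))
    return(structure(list(pseudo_F = f_obs, p_value = p,
                          n_permutations = ncol(combos), exact = TRUE),
                     class = "adonis_result"))
  }
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- permute_indices(n, strata)
      if (adonis_pseudo_f(d2, groups[perm]) >= f_obs - 1e-12 * abs(f_obs)) {
        hits <- hits + 1L
      }
    }
    hits
  })
  structure(list(pseudo_F = f_obs, p_value = (count + 1) / (n_perm + 1),
                 n_permutations = n_perm, exact = FALSE),
            class = "adonis_result")
}

#' @export
print.adonis_result <- function(x, ...) {
  cat(sprintf("adonis: pseudo-F = %.3f, p = %.4f (%s, %d permutations)\n",
              x$pseudo_F, x$p_value, if (x$exact) "exact" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

permute_indices <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the lower-triangle entries; the p value
#' is obtained by jointly permuting the row/column order of the second matrix
#' (one-sided, large positive `r`). All `n!` relabelings are enumerated when
#' `n! <= max_exact` (identity included); otherwise Monte-Carlo with
#' `p = (count + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 distance matrices over the same samples (size >= 3).
#' @param n_perm Monte-Carlo permutation count.
#' @param seed RNG seed.
#' @param max_exact enumeration cutoff on `n!`.
#' @return list with `r`, `p_value`, `exact`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L, max_exact = 10000) {
  check_distance_matrix(d1)
  check_distance_matrix(d2)
  n <- nrow(d1)
  if (nrow(d2) != n) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("distance matrices have mismatched sample labels")
  }
  if (n < 3) stop("need at least 3 samples")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (sd(v1) == 0 || sd(d2[lt]) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  r_obs <- cor(v1, d2[lt])

  r_for <- function(perm) cor(v1, d2[perm, perm][lt])
  if (factorial(n) <= max_exact) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, r_for, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    return(list(r = r_obs, p_value = p, exact = TRUE,
                n_permutations = length(perms)))
  }
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (r_for(sample.int(n)) >= r_obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(r = r_obs, p_value = (count + 1) / (n_perm + 1), exact = FALSE,
       n_permutations = n_perm)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Per-sample alpha diversity indices
#'
#' Richness (nonzero features), Shannon `H = -sum(p log p)`, Simpson
#' concentration `D = sum(p^2)`, inverse Simpson `1/D`, and Pielou evenness
#' `H / log(richness)` (undefined, `NA`, when richness is 1).
#'
#' @param m abundance matrix, samples as rows with positive totals.
#' @return data frame with one row per sample: `sample`, `richness`,
#'   `shannon`, `simpson`, `inv_simpson`, `evenness`.
#' @export
alpha_diversity <- function(m) {
  check_abundance_matrix(m, min_samples = 1)
  totals <- rowSums(m)
  if (any(totals <= 0)) stop("sample with nonpositive total abundance")
  res <- t(apply(m, 1, function(x) {
    p <- x / sum(x)
    p <- p[p > 0]
    richness <- length(p)
    h <- -sum(p * log(p))
    d <- sum(p^2)
    c(richness = richness, shannon = h, simpson = d, inv_simpson = 1 / d,
      evenness = if (richness > 1) h / log(richness) else NA_real_)
  }))
  data.frame(sample = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
             res, row.names = NULL, stringsAsFactors = FALSE)
}
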