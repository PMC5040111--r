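# Probe-to-gene preprocessing chain for functional gene array data:
# QC filtering -> three-level normalization -> detection filters ->
# relative-abundance rescaling and ln(x+1) transform.

PROBE_COLUMNS <- c("slide_id", "sample_id", "subgrid", "probe_id", "gene_id",
                   "category", "signal", "background", "background_sd", "flag")

check_probe_records <- function(records, require_rows = TRUE) {
  if (!is.data.frame(records)) stop("probe records must be a data frame")
  missing <- setdiff(PROBE_COLUMNS, names(records))
  if (length(missing)) {
    stop("probe records missing column(s): ", paste(missing, collapse = ", "))
  }
  if (require_rows && nrow(records) == 0) stop("probe records are empty")
  if (nrow(records) > 0) {
    if (any(!is.finite(records$signal)) || any(!is.finite(records$background))) {
      stop("non-finite signal or background in probe records")
    }
  }
  invisible(records)
}

#' Quality-control filter on probe records
#'
#' Removes spots flagged 1 or 3 by the image quantification software and spots
#' with a signal-to-noise ratio below 2.0. A spot with SNR exactly 2.0 is
#' retained (the removal rule is "less than 2.0"). SNR is, by default, the
#' array convention `(signal - background) / background_sd`; set
#' `snr_mode = "ratio"` for the plain `signal / background` variant.
#'
#' @param records probe record data frame (see [load_probe_table()] for the
#'   canonical columns).
#' @param snr_threshold removal threshold; spots with SNR strictly below it
#'   are dropped.
#' @param flags_removed integer flag codes to drop.
#' @param snr_mode `"subtract"` (default) or `"ratio"`.
#' @return The retained records (a subset of the input rows).
#' @export
qc_filter_probes <- function(records, snr_threshold = 2,
                             flags_removed = c(1L, 3L),
                             snr_mode = c("subtract", "ratio")) {
  check_probe_records(records)
  snr_mode <- match.arg(snr_mode)
  bad_sd <- which(records$background_sd <= 0)
  if (length(bad_sd)) {
    stop("background_sd <= 0 for probe ", records$probe_id[bad_sd[1]],
         " (slide ", records$slide_id[bad_sd[1]], ")")
  }
  snr <- if (snr_mode == "subtract") {
    (records$signal - records$background) / records$background_sd
  } else {
    records$signal / records$background
  }
  keep <- !(records$flag %in% flags_removed) & snr >= snr_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-level normalization of probe signals
#'
#' Stage 1 rescales each subgrid within a slide so the subgrid mean signal
#' equals the slide mean (mean-ratio scaling; preserves relative ordering
#' within a subgrid). Stage 2 averages technical replicates of the same
#' sample x probe; after this stage a record represents one sample and
#' `slide_id` is set to the `sample_id`. Stage 3 rescales each sample so its
#' total intensity equals the across-sample mean total.
#'
#' A subgrid whose signals are all zero has an undefined scale factor; it is
#' left unscaled with a warning.
#'
#' @param records QC-filtered probe records.
#' @return Normalized records, one row per sample x probe.
#' @export
normalize_probes <- function(records) {
  check_probe_records(records)
  r <- records

  # stage 1: subgrid -> slide mean, within each slide
  slide_mean <- tapply(r$signal, r$slide_id, mean)
  sub_key <- paste(r$slide_id, r$subgrid, sep = "\r")
  sub_mean <- tapply(r$signal, sub_key, mean)
  fac <- as.numeric(slide_mean[r$slide_id]) / as.numeric(sub_mean[sub_key])
  undef <- !is.finite(fac)
  if (any(undef)) {
    warning("subgrid with all-zero signals left unscaled (",
            sum(undef), " record(s))")
    fac[undef] <- 1
  }
  r$signal <- r$signal * fac

  # stage 2: average technical replicates of the same sample x probe
  key <- paste(r$sample_id, r$probe_id, sep = "\r")
  first <- !duplicated(key)
  mean_by <- function(x) as.numeric(tapply(x, key, mean)[key[first]])
  out <- r[first, , drop = FALSE]
  out$signal <- mean_by(r$signal)
  out$background <- mean_by(r$background)
  out$background_sd <- mean_by(r$background_sd)
  out$slide_id <- out$sample_id
  out$flag <- 0L

  # stage 3: sample total -> across-sample mean total
  totals <- tapply(out$signal, out$sample_id, sum)
  target <- mean(totals)
  fac3 <- target / as.numeric(totals[out$sample_id])
  undef3 <- !is.finite(fac3)
  if (any(undef3)) {
    warning("sample with zero total signal left unscaled")
    fac3[undef3] <- 1
  }
  out$signal <- out$signal * fac3
  rownames(out) <- NULL
  out
}

#' Detection filters on genes and probes
#'
#' A probe is retained only if it was detected (present post-QC) in at least
#' `min_probe_replicates` distinct samples ("removing probes appearing in only
#' one replicate"). A gene is then retained iff its number of detected
#' positive probes is at least `min_gene_fraction` of its designed probe
#' number (with a relative tolerance so 1/3 passes a 33.3% threshold) and at
#' least `min_gene_probes`.
#'
#' @param records normalized probe records.
#' @param designed data frame `gene_id`, `designed_probes` covering every gene
#'   present in `records`.
#' @param min_gene_fraction minimum detected/designed probe fraction
#'   (default 0.333, i.e. the 33.3% rule).
#' @param min_gene_probes minimum number of detected positive probes per gene.
#' @param min_probe_replicates minimum number of samples a probe must appear
#'   in.
#' @return The retained records.
#' @export
filter_genes_and_probes <- function(records, designed,
                                    min_gene_fraction = 0.333,
                                    min_gene_probes = 2L,
                                    min_probe_replicates = 2L) {
  check_probe_records(records)
  if (!is.data.frame(designed) ||
      !all(c("gene_id", "designed_probes") %in% names(designed))) {
    stop("`designed` must have columns gene_id, designed_probes")
  }
  absent <- setdiff(unique(records$gene_id), designed$gene_id)
  if (length(absent)) {
    stop("gene(s) absent from designed probe counts: ",
         paste(absent, collapse = ", "))
  }

  # probe rule: detected in >= min_probe_replicates distinct samples
  n_samples_per_probe <- tapply(records$sample_id, records$probe_id,
                                function(s) length(unique(s)))
  keep_probe <- names(n_samples_per_probe)[
    n_samples_per_probe >= min_probe_replicates]
  r <- records[records$probe_id %in% keep_probe, , drop = FALSE]

  # gene rule on surviving probes
  det <- tapply(r$probe_id, r$gene_id, function(p) length(unique(p)))
  des <- designed$designed_probes[match(names(det), designed$gene_id)]
  frac_ok <- det / des >= min_gene_fraction * (1 - 1e-9)
  keep_gene <- names(det)[frac_ok & det >= min_gene_probes]
  out <- r[r$gene_id %in% keep_gene, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescale to amplified relative abundance and ln(x+1)-transform
#'
#' Per sample, each probe's relative abundance is its signal divided by the
#' sample's total signal. The across-sample mean of the totals multiplies the
#' relative abundance ("amplified relative abundance"), and the stored value
#' is `ln(rescaled + 1)`. A probe undetected in a sample contributes 0. The
#' gene-level value is the mean over the gene's retained probes.
#'
#' @param records filtered, normalized probe records.
#' @param designed optional designed probe counts carried into the result.
#' @return A `gene_signal_matrix`: list with `values` (genes x samples matrix
#'   of ln-transformed abundances), `genes` (data frame `gene_id`,
#'   `category`), `samples`, `probe_values` (probes x samples, ln scale),
#'   `probe_rescaled` / `gene_rescaled` (the linear amplified
#'   relative-abundance values before the log transform, used for percent
#'   effect estimation), `probe_map` (data frame `probe_id`, `gene_id`,
#'   `category`) and `designed_probe_counts`.
#' @export
rescale_log_transform <- function(records, designed = NULL) {
  check_probe_records(records)
  samples <- sort(unique(records$sample_id))
  probes <- sort(unique(records$probe_id))
  m <- matrix(0, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(records$probe_id, probes),
          match(records$sample_id, samples))] <- records$signal
  sums <- colSums(m)
  if (any(sums == 0)) {
    stop("sample with zero total signal: ", samples[which(sums == 0)[1]])
  }
  rescaled <- sweep(m, 2, sums, "/") * mean(sums)
  probe_values <- log(rescaled + 1)

  first <- !duplicated(records$probe_id)
  ord <- match(probes, records$probe_id[first])
  probe_map <- data.frame(probe_id = probes,
                          gene_id = records$gene_id[first][ord],
                          category = records$category[first][ord],
                          stringsAsFactors = FALSE)
  genes <- sort(unique(probe_map$gene_id))
  gidx <- match(probe_map$gene_id, genes)
  n_per_gene <- as.vector(table(gidx))
  values <- rowsum(probe_values, gidx) / n_per_gene
  gene_rescaled <- rowsum(rescaled, gidx) / n_per_gene
  rownames(values) <- rownames(gene_rescaled) <- genes
  gene_cat <- probe_map$category[match(genes, probe_map$gene_id)]

  structure(
    list(values = values,
         genes = data.frame(gene_id = genes, category = gene_cat,
                            stringsAsFactors = FALSE),
         samples = samples,
         probe_values = probe_values,
         probe_rescaled = rescaled,
         gene_rescaled = gene_rescaled,
         probe_map = probe_map,
         designed_probe_counts = designed),
    class = "gene_signal_matrix"
  )
}

#' @export
print.gene_signal_matrix <- function(x, ...) {
  cat(sprintf("gene_signal_matrix: %d genes (%d probes) x %d samples\n",
              nrow(x$values), nrow(x$probe_values), length(x$samples)))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' QC filter, three-level normalization, gene/probe detection filters,
#' rescaling and ln(x+1) transform, in that order.
#'
#' @inheritParams qc_filter_probes
#' @inheritParams filter_genes_and_probes
#' @return A `gene_signal_matrix` (see [rescale_log_transform()]).
#' @export
geochip_pipeline <- function(records, designed, snr_threshold = 2,
                             snr_mode = c("subtract", "ratio")) {
  snr_mode <- match.arg(snr_mode)
  r <- qc_filter_probes(records, snr_threshold = snr_threshold,
                        snr_mode = snr_mode)
  r <- normalize_probes(r)
  r <- filter_genes_and_probes(r, designed)
  rescale_log_transform(r, designed = designed)
}

#' Read / write the canonical probe table
#'
#' UTF-8 TSV with header columns exactly
#' `slide_id sample_id subgrid probe_id gene_id category signal background
#' background_sd flag`. `write_probe_table()` followed by
#' `load_probe_table()` round-trips losslessly.
#'
#' @param path file path.
#' @return `load_probe_table()`: probe record data frame (possibly 0 rows).
#' @export
load_probe_table <- function(path) {
  records <- read_tsv(path)
  missing <- setdiff(PROBE_COLUMNS, names(records))
  if (length(missing)) {
    stop("probe table ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  records <- records[, PROBE_COLUMNS]
  if (nrow(records) > 0) {
    for (col in c("signal", "background", "background_sd")) {
      v <- records[[col]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
        stop("non-numeric ", col, " in ", path, " at data line ", bad)
      }
    }
    if (!is.numeric(records$flag)) {
      stop("non-numeric flag column in ", path)
    }
  } else {
    for (col in c("signal", "background", "background_sd")) {
      records[[col]] <- numeric(0)
    }
  }
  records$subgrid <- as.integer(records$subgrid)
  records$flag <- as.integer(records$flag)
  for (col in c("slide_id", "sample_id", "probe_id", "gene_id", "category")) {
    records[[col]] <- as.character(records[[col]])
  }
  records
}

#' @rdname load_probe_table
#' @param records probe record data frame.
#' @export
write_probe_table <- function(records, path) {
  check_probe_records(records, require_rows = FALSE)
  write_tsv(records[, PROBE_COLUMNS], path)
}

#' Write a gene signal matrix as TSV
#'
#' Genes as rows: `gene_id`, `category`, then one column per sample.
#'
#' @param x a `gene_signal_matrix`.
#' @param path output path.
#' @export
write_gene_matrix <- function(x, path) {
  stopifnot(inherits(x, "gene_signal_matrix"))
  out <- cbind(x$genes, as.data.frame(x$values, check.names = FALSE))
  write_tsv(out, path)
}
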