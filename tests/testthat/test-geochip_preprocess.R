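# Preprocessing chain: QC boundaries, the three normalization stages, the
# detection filters against a rule-by-rule oracle, rescaling arithmetic, and
# the file round-trip.

test_that("QC removes flagged spots and SNR < 2, keeps the boundary", {
  recs <- make_records(
    list(probe_id = "p1", flag = 1L, signal = 1000),          # flagged: out
    list(probe_id = "p2", flag = 3L, signal = 1000),          # flagged: out
    list(probe_id = "p3", flag = 0L, signal = 10 + 1.99 * 2), # SNR 1.99: out
    list(probe_id = "p4", flag = 0L, signal = 10 + 2.00 * 2), # SNR 2.00: in
    list(probe_id = "p5", flag = 2L, signal = 1000)           # other flag: in
  )
  kept <- qc_filter_probes(recs)
  expect_setequal(kept$probe_id, c("p4", "p5"))

  # identity on an all-clean table
  clean <- make_records(list(probe_id = "p1"), list(probe_id = "p2"))
  expect_identical(qc_filter_probes(clean), clean)

  # ratio mode: SNR = signal / background
  ratio <- make_records(list(probe_id = "lo", signal = 19, background = 10),
                        list(probe_id = "hi", signal = 21, background = 10))
  expect_equal(qc_filter_probes(ratio, snr_mode = "ratio")$probe_id, "hi")

  bad <- make_records(list(probe_id = "pX", background_sd = 0))
  expect_error(qc_filter_probes(bad), "pX")
})

test_that("normalization: subgrid scaling, replicate averaging, sum equalization", {
  # single slide, single subgrid: stage 1 is the identity on signals
  one <- make_records(list(probe_id = "p1", signal = 4),
                      list(probe_id = "p2", signal = 8))
  expect_equal(normalize_probes(one)$signal, c(4, 8))

  # technical replicates 4 and 6 average to 5
  reps <- make_records(
    list(slide_id = "s1", sample_id = "a", probe_id = "p1", signal = 4),
    list(slide_id = "s2", sample_id = "a", probe_id = "p1", signal = 6))
  out <- normalize_probes(reps)
  expect_equal(nrow(out), 1L)
  expect_equal(out$signal, 5)
  expect_equal(out$slide_id, "a")

  # stage 1 makes subgrid means equal within a slide, preserving order
  sg <- make_records(
    list(subgrid = 1L, probe_id = "p1", signal = 10),
    list(subgrid = 1L, probe_id = "p2", signal = 30),
    list(subgrid = 2L, probe_id = "p3", signal = 100),
    list(subgrid = 2L, probe_id = "p4", signal = 300))
  nsg <- normalize_probes(sg)
  m1 <- mean(nsg$signal[nsg$subgrid == 1]); m2 <- mean(nsg$signal[nsg$subgrid == 2])
  expect_equal(m1, m2)
  expect_true(nsg$signal[nsg$probe_id == "p2"] > nsg$signal[nsg$probe_id == "p1"])

  # after stage 3 all sample totals equal the across-sample mean total
  design <- factorial_design(3)
  spec <- array_fixture_spec(n_genes = 5, probes_per_gene = 2, n_subgrids = 2,
                             n_tech_reps = 2, seed = 21)
  norm <- normalize_probes(qc_filter_probes(generate_geochip_fixture(spec, design)))
  totals <- tapply(norm$signal, norm$sample_id, sum)
  expect_equal(max(totals) - min(totals), 0, tolerance = 1e-9)

  # all-zero subgrid is left unscaled, with a warning
  zero_sg <- make_records(
    list(subgrid = 1L, probe_id = "p1", signal = 0),
    list(subgrid = 2L, probe_id = "p2", signal = 10))
  expect_warning(nz <- normalize_probes(zero_sg), "unscaled")
  expect_equal(nz$signal[nz$probe_id == "p1"], 0)
})

test_that("detection filters match the rule-by-rule enumeration oracle", {
  # hand case: gene with 1/10 designed probes detected is removed
  designed <- data.frame(gene_id = c("g1", "g2"),
                         designed_probes = c(10L, 3L))
  recs <- make_records(
    list(gene_id = "g1", probe_id = "g1p1", sample_id = "a"),
    list(gene_id = "g1", probe_id = "g1p1", sample_id = "b"),
    list(gene_id = "g2", probe_id = "g2p1", sample_id = "a"),
    list(gene_id = "g2", probe_id = "g2p1", sample_id = "b"),
    list(gene_id = "g2", probe_id = "g2p2", sample_id = "a"),
    list(gene_id = "g2", probe_id = "g2p2", sample_id = "b"))
  out <- filter_genes_and_probes(recs, designed)
  expect_setequal(unique(out$gene_id), "g2")  # 2/3 = 66.7% and 2 >= 2

  # a probe in one sample only is dropped even for a retained gene
  recs2 <- rbind(recs, make_records(
    list(gene_id = "g2", probe_id = "g2p3", sample_id = "a")))
  out2 <- filter_genes_and_probes(recs2, designed)
  expect_false("g2p3" %in% out2$probe_id)

  # the 33.3% threshold admits exactly 1/3
  designed3 <- data.frame(gene_id = "g3", designed_probes = 3L)
  recs3 <- make_records(
    list(gene_id = "g3", probe_id = "g3p1", sample_id = "a"),
    list(gene_id = "g3", probe_id = "g3p1", sample_id = "b"))
  expect_equal(nrow(filter_genes_and_probes(recs3, designed3,
                                            min_gene_probes = 1L)), 2L)

  # oracle agreement on a stochastic fixture with dropouts
  design <- factorial_design(3)
  spec <- array_fixture_spec(n_genes = 12, probes_per_gene = 4,
                             flag_rate = 0.3, low_snr_rate = 0.3, seed = 31)
  qc <- qc_filter_probes(generate_geochip_fixture(spec, design))
  designed_f <- designed_probe_counts(spec)
  mine <- filter_genes_and_probes(qc, designed_f)
  oracle <- oracle_detection_filter(qc, designed_f)
  expect_setequal(unique(mine$gene_id), unique(oracle$gene_id))
  expect_setequal(unique(mine$probe_id), unique(oracle$probe_id))
  expect_equal(nrow(mine), nrow(oracle))

  # filters are monotone and idempotent
  expect_true(nrow(mine) <= nrow(qc))
  expect_equal(filter_genes_and_probes(mine, designed_f), mine)

  expect_error(filter_genes_and_probes(recs, designed[1, , drop = FALSE]),
               "absent")
})

test_that("rescaling arithmetic and the log transform", {
  # two samples with sums 100 and 300; rel. abundance 0.5 -> ln(101)
  recs <- make_records(
    list(sample_id = "a", probe_id = "p1", signal = 50),
    list(sample_id = "a", probe_id = "p2", signal = 50),
    list(sample_id = "b", probe_id = "p1", signal = 150),
    list(sample_id = "b", probe_id = "p2", signal = 150))
  recs$slide_id <- recs$sample_id
  recs$signal[recs$sample_id == "b" & recs$probe_id == "p2"] <- 150
  gm <- rescale_log_transform(recs)
  expect_equal(gm$probe_values["p1", "a"], log(101))
  # before the log, every sample sums to the mean of sums
  expect_equal(unname(colSums(gm$probe_rescaled)), c(200, 200))
  # a probe undetected in one sample stores ln(0 + 1) = 0
  recs2 <- recs[-4, ]
  gm2 <- rescale_log_transform(recs2)
  expect_equal(gm2$probe_values["p2", "b"], 0)

  zero <- make_records(list(sample_id = "z", signal = 0))
  expect_error(rescale_log_transform(zero), "zero total")
})

test_that("full pipeline: reduction property and bit-reproducibility", {
  design <- factorial_design(2)
  # no flags, one subgrid, one replicate: output must equal the closed-form
  # ln(relative abundance * mean-of-sums + 1) of the raw signals
  spec <- array_fixture_spec(n_genes = 4, probes_per_gene = 3, n_subgrids = 1,
                             seed = 41)
  recs <- generate_geochip_fixture(spec, design)
  gm <- geochip_pipeline(recs, designed_probe_counts(spec))
  sums <- tapply(recs$signal, recs$sample_id, sum)
  expected <- log(recs$signal / as.numeric(sums[recs$sample_id]) *
                    mean(sums) + 1)
  got <- gm$probe_values[cbind(recs$probe_id, recs$sample_id)]
  expect_equal(unname(got), expected)

  # determinism of the full chain
  spec2 <- array_fixture_spec(n_genes = 6, probes_per_gene = 3,
                              flag_rate = 0.1, low_snr_rate = 0.1,
                              n_tech_reps = 2, seed = 42)
  recs2 <- generate_geochip_fixture(spec2, design)
  expect_identical(geochip_pipeline(recs2, designed_probe_counts(spec2)),
                   geochip_pipeline(recs2, designed_probe_counts(spec2)))
})

test_that("probe table write -> load round-trips losslessly", {
  design <- factorial_design(2)
  spec <- array_fixture_spec(n_genes = 3, probes_per_gene = 2,
                             flag_rate = 0.2, seed = 51)
  recs <- generate_geochip_fixture(spec, design)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_probe_table(recs, path)
  back <- load_probe_table(path)
  expect_equal(back, recs)

  # empty body -> empty record collection
  write_probe_table(recs[0, ], path)
  expect_equal(nrow(load_probe_table(path)), 0L)

  # missing column is an error
  broken <- recs[, setdiff(names(recs), "signal")]
  write_tsv(broken, path)
  expect_error(load_probe_table(path), "signal")
})
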