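test_that("simulation_spec validates its stated world", {
  spec <- simulation_spec()
  expect_equal(spec$n_transcripts, 20000L)
  expect_equal(spec$group_sizes, c(group1 = 400L))
  expect_equal(spec$baseline_density, 0.0037)
  expect_equal(spec$group_multiplier, 1.5)
  expect_error(simulation_spec(group_sizes = c(g = 0L)), "positive")
  expect_error(simulation_spec(baseline_density = 0.9,
                               group_multiplier = 2), "<= 1")
  expect_error(simulation_spec(n_transcripts = 10, group_sizes = c(g = 20L)),
               "exceed")
})

test_that("simulate_annotation: determinism, degenerate mixture, sizing", {
  spec <- small_sim_spec(seed = 7L)
  a1 <- simulate_annotation(spec)
  a2 <- simulate_annotation(spec)
  expect_identical(a1$transcripts, a2$transcripts)
  expect_identical(a1$truth$assignment, a2$truth$assignment)

  # group assignment counts match the spec
  expect_equal(sum(a1$truth$assignment$group == "grp"), 60L)

  # all records pass their own invariants
  t <- a1$transcripts
  expect_true(all(t$tx_start >= 0 & t$tx_start < t$tx_end))
  expect_true(all(t$tx_start <= t$cds_start & t$cds_start <= t$cds_end &
                    t$cds_end <= t$tx_end))
  expect_true(all(t$cds_start < t$cds_end))  # coding by construction

  # degenerate mixture: point mass 1 at zero-length 5'UTR
  z <- simulate_annotation(small_sim_spec(seed = 3L, utr5_zero_weight = 1))
  expect_true(all(utr5_length(z$transcripts) == 0L))

  # transcripts that cannot fit are a sizing error
  expect_error(
    simulate_annotation(
      simulation_spec(chromosome_length = 5000L,
                      transcript_length_range = c(1000L, 10000L),
                      n_transcripts = 10L, group_sizes = c(g = 2L))),
    "cannot fit")
})

test_that("zero-5'UTR fraction concentrates at its weight", {
  spec <- simulation_spec(n_chromosomes = 2L, chromosome_length = 10000000L,
                          n_transcripts = 20000L, group_sizes = c(g = 400L),
                          transcript_length_range = c(1000L, 20000L),
                          utr5_zero_weight = 0.05, seed = 21L)
  ann <- simulate_annotation(spec)
  n_zero <- sum(utr5_length(ann$transcripts) == 0L)
  bound <- 3 * sqrt(20000 * 0.05 * 0.95)
  expect_lt(abs(n_zero - 1000), bound)
})

test_that("simulate_snps: determinism, zero rate, null multiplier", {
  spec <- small_sim_spec(seed = 5L)
  ann <- simulate_annotation(spec)
  s1 <- simulate_snps(ann$transcripts, ann$truth, spec)
  s2 <- simulate_snps(ann$transcripts, ann$truth, spec)
  expect_identical(s1, s2)
  expect_true(all(s1$variant_class == "single"))
  expect_true(!is.unsorted(s1$pos[s1$chrom == "1"]))
  expect_equal(anyDuplicated(paste(s1$chrom, s1$pos)), 0L)
  expect_equal(nrow(filter_snps(s1)), nrow(s1))

  zero <- small_sim_spec(seed = 5L, baseline_density = 0)
  annz <- simulate_annotation(zero)
  expect_equal(nrow(simulate_snps(annz$transcripts, annz$truth, zero)), 0L)

  # rho = 1: group and non-group mean contents agree within sampling error
  null_spec <- simulation_spec(n_chromosomes = 2L,
                               chromosome_length = 5000000L,
                               n_transcripts = 4000L,
                               group_sizes = c(g = 800L),
                               group_multiplier = 1, seed = 13L)
  ann0 <- simulate_annotation(null_spec)
  snp0 <- simulate_snps(ann0$transcripts, ann0$truth, null_spec)
  tab <- build_content_table(ann0$transcripts, snp0, case_spec("TSS", 500))
  grp <- ann0$truth$assignment$group[match(tab$accession,
                                           ann0$truth$assignment$accession)]
  m1 <- mean(tab$snp_content[grp == "g"])
  m2 <- mean(tab$snp_content[grp == "background"])
  se <- sqrt(1.85 / 800 + 1.85 / 3200)  # Poisson-scale SE of the difference
  expect_lt(abs(m1 - m2), 4 * se)
})

test_that("non-group mean content matches the Binomial(500, 0.0037) oracle", {
  spec <- simulation_spec(n_chromosomes = 4L, chromosome_length = 10000000L,
                          n_transcripts = 20000L, group_sizes = c(g = 400L),
                          transcript_length_range = c(1000L, 20000L),
                          seed = 17L)
  ann <- simulate_annotation(spec)
  snps <- simulate_snps(ann$transcripts, ann$truth, spec)
  tab <- build_content_table(ann$transcripts, snps, case_spec("TSS", 500))
  grp <- ann$truth$assignment$group[match(tab$accession,
                                          ann$truth$assignment$accession)]
  bg <- tab$snp_content[grp == "background" & tab$effective_length == 500L]
  mu <- 500 * 0.0037          # 1.85
  se <- sqrt(mu / length(bg)) # Poisson-scale standard error
  expect_lt(abs(mean(bg) - mu), 3 * se)
})

test_that("make_fixture regenerates byte-identical packaged files", {
  dir <- withr::local_tempdir()
  paths <- make_fixture(dir)
  for (nm in names(paths)) {
    expect_identical(
      readBin(paths[[nm]], "raw", file.size(paths[[nm]])),
      readBin(fixture_path(basename(paths[[nm]])), "raw",
              file.size(fixture_path(basename(paths[[nm]])))),
      label = basename(paths[[nm]])
    )
  }
  # and twice in a row
  dir2 <- withr::local_tempdir()
  paths2 <- make_fixture(dir2)
  expect_identical(readLines(paths[["manifest"]]),
                   readLines(paths2[["manifest"]]))
})
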