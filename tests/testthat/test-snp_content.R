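test_that("filter_snps keeps class+flag matches, order preserved", {
  snps <- data.frame(
    chrom = "1", pos = c(10L, 20L, 30L, 40L),
    rsid = paste0("rs", 1:4),
    variant_class = c("single", "single", "single", "deletion"),
    validation_flags = c("by-1000genomes", "By_1000Genomes,by-cluster",
                         "by-frequency", "by-1000genomes"),
    stringsAsFactors = FALSE
  )
  out <- filter_snps(snps)
  expect_equal(out$rsid, c("rs1", "rs2"))  # casing/underscore tolerated
  expect_equal(nrow(filter_snps(snps[0, ])), 0L)
  all_ok <- snps[1:2, ]
  expect_equal(filter_snps(all_ok)$rsid, all_ok$rsid)
})

test_that("window counting uses half-open boundaries", {
  snps <- data.frame(
    chrom = "1", pos = c(9499L, 9500L, 9999L, 10000L),
    rsid = paste0("rs", 1:4), variant_class = "single",
    validation_flags = "by-1000genomes", stringsAsFactors = FALSE
  )
  expect_equal(count_snps_in_window(snps, list(chrom = "1", start = 9500L,
                                               end = 10000L)), 2L)
  expect_equal(count_snps_in_window(snps, list(chrom = "7", start = 0L,
                                               end = 100000L)), 0L)
})

test_that("binary-search counts equal the naive scan on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    inst <- random_instance(n_chrom = sample(1:4, 1),
                            n_snps = sample(50:500, 1))
    for (w in 1:10) {
      ch <- sample(unique(inst$snps$chrom), 1)
      start <- sample.int(90000, 1) - 1L
      end <- start + sample.int(5000, 1)
      expect_identical(
        count_snps_in_window(inst$snps,
                             list(chrom = ch, start = start, end = end)),
        as.integer(naive_window_count(inst$snps, ch, start, end))
      )
    }
  }
})

test_that("build_content_table matches the fixture manifest on all six cases", {
  man <- read_fixture_manifest()
  transcripts <- read_transcript_table(fixture_path("tiny_refgene.tsv"))
  snps <- filter_snps(read_snp_table(fixture_path("tiny_snps.tsv")))
  expect_equal(nrow(snps), man$snp_table$n_qualifying)
  kept <- filter_transcripts(transcripts)$kept
  for (cl in names(man$contents)) {
    parts <- strsplit(cl, "_", fixed = TRUE)[[1]]
    cs <- case_spec(parts[2], as.integer(parts[3]),
                    if (parts[1] == "utrge0") "any" else "positive")
    tab <- build_content_table(kept, snps, cs)
    got <- contents_by_accession(tab)
    expect_equal(got, lapply(man$contents[[cl]], as.integer), info = cl)
    # clipped-window effective length
    exc <- man$effective_length_exceptions
    for (acc in tab$accession) {
      expected_len <- if (acc %in% names(exc)) as.integer(exc[[acc]])
                      else cs$window_length
      expect_equal(tab$effective_length[tab$accession == acc], expected_len,
                   info = paste(cl, acc))
    }
    expect_true(all(tab$snp_content <= tab$effective_length))
  }
})

test_that("degenerate content tables: empty SNPs, all-zero 5'UTRs", {
  inst <- random_instance()
  cs <- case_spec("TSS", 500)
  tab <- build_content_table(inst$transcripts, inst$snps[0, ], cs)
  expect_true(all(tab$snp_content == 0L))

  zero_utr <- inst$transcripts
  zero_utr$cds_start <- ifelse(zero_utr$strand == "+", zero_utr$tx_start,
                               zero_utr$cds_start)
  zero_utr$cds_end <- ifelse(zero_utr$strand == "-", zero_utr$tx_end,
                             zero_utr$cds_end)
  tab2 <- build_content_table(zero_utr, inst$snps,
                              case_spec("TSS", 500, "positive"))
  expect_equal(nrow(tab2), 0L)
})

test_that("snp_rich_subset thresholds and orders correctly", {
  tab <- data.frame(
    accession = c("NM_4", "NM_1", "NM_2", "NM_3"),
    gene_symbol = c("D", "A", "B", "C"),
    snp_content = c(0L, 5L, 6L, 53L),
    stringsAsFactors = FALSE
  )
  rich <- snp_rich_subset(tab, 6)
  expect_equal(rich$accession, c("NM_3", "NM_2"))  # 53 first
  expect_equal(nrow(snp_rich_subset(tab, 0)), 4L)
  expect_equal(snp_rich_subset(tab, 1)$accession, c("NM_3", "NM_2", "NM_1"))
  expect_error(snp_rich_subset(tab, -1), "non-negative")

  man <- read_fixture_manifest()
  transcripts <- read_transcript_table(fixture_path("tiny_refgene.tsv"))
  snps <- filter_snps(read_snp_table(fixture_path("tiny_snps.tsv")))
  kept <- filter_transcripts(transcripts)$kept
  tss500 <- build_content_table(kept, snps, case_spec("TSS", 500, "any"))
  expect_equal(nrow(snp_rich_subset(tss500, 6)),
               length(man$snp_rich$min_6))
  expect_equal(snp_rich_subset(tss500, 2)$accession,
               unlist(man$snp_rich$min_2))
})

test_that("additivity: counts on disjoint SNP halves sum to the union count", {
  set.seed(7)
  inst <- random_instance(n_snps = 800)
  cs <- case_spec("TSS", 1000)
  half <- sample(c(TRUE, FALSE), nrow(inst$snps), replace = TRUE)
  a <- build_content_table(inst$transcripts, inst$snps[half, ], cs)
  b <- build_content_table(inst$transcripts, inst$snps[!half, ], cs)
  full <- build_content_table(inst$transcripts, inst$snps, cs)
  expect_equal(a$snp_content + b$snp_content, full$snp_content)
})

test_that("mirror-coordinate symmetry preserves SNP contents", {
  set.seed(11)
  inst <- random_instance(n_snps = 600)
  # shift everything away from 0 so no window clips on either side
  shift <- 2000L
  inst$transcripts[c("tx_start", "tx_end", "cds_start", "cds_end")] <-
    inst$transcripts[c("tx_start", "tx_end", "cds_start", "cds_end")] + shift
  inst$snps$pos <- inst$snps$pos + shift
  C <- 200000L
  mt <- inst$transcripts
  mirrored <- data.frame(
    accession = mt$accession, gene_symbol = mt$gene_symbol,
    chrom = mt$chrom, strand = ifelse(mt$strand == "+", "-", "+"),
    tx_start = C - mt$tx_end, tx_end = C - mt$tx_start,
    cds_start = C - mt$cds_end, cds_end = C - mt$cds_start,
    stringsAsFactors = FALSE
  )
  ms <- inst$snps
  ms$pos <- C - 1L - ms$pos
  ms <- ms[order(ms$chrom, ms$pos), ]
  for (cs in list(case_spec("TSS", 500), case_spec("CRS", 1000))) {
    orig <- build_content_table(inst$transcripts, inst$snps, cs)
    mirr <- build_content_table(mirrored, ms, cs)
    expect_equal(
      mirr$snp_content[match(orig$accession, mirr$accession)],
      orig$snp_content
    )
    expect_equal(
      mirr$effective_length[match(orig$accession, mirr$accession)],
      orig$effective_length
    )
  }
})
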