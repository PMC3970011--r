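# Shared helpers: independent oracles and small random-instance generators.

# Naive per-record window count: the oracle against binary-search counting.
naive_window_count <- function(snps, chrom, start, end) {
  sum(snps$chrom == chrom & snps$pos >= start & snps$pos < end)
}

# Exact hypergeometric upper tail by direct enumeration with choose();
# independent of stats::phyper.
hyper_tail_oracle <- function(k_from, n, K, N_bg) {
  lo <- max(k_from, 0)
  hi <- min(n, K)
  if (lo > hi) return(0)
  i <- lo:hi
  sum(choose(K, i) * choose(N_bg - K, n - i)) / choose(N_bg, n)
}

# Random small instance: transcripts + SNPs on a few chromosomes.
random_instance <- function(n_chrom = 3, n_transcripts = 30, n_snps = 500,
                            chrom_len = 100000) {
  chroms <- as.character(seq_len(n_chrom))
  tlen <- sample(500:5000, n_transcripts, replace = TRUE)
  tx_start <- vapply(tlen, function(l) sample.int(chrom_len - l, 1), integer(1))
  utr <- sample(0:300, n_transcripts, replace = TRUE)
  utr <- pmin(utr, tlen - 1)
  strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)
  transcripts <- data.frame(
    accession = sprintf("NM_T%04d", seq_len(n_transcripts)),
    gene_symbol = sprintf("G%04d", seq_len(n_transcripts)),
    chrom = sample(chroms, n_transcripts, replace = TRUE),
    strand = strand,
    tx_start = tx_start, tx_end = tx_start + tlen,
    cds_start = ifelse(strand == "+", tx_start + utr, tx_start),
    cds_end = ifelse(strand == "+", tx_start + tlen, tx_start + tlen - utr),
    stringsAsFactors = FALSE
  )
  pos <- sample.int(chrom_len, n_snps, replace = TRUE) - 1L
  snps <- data.frame(
    chrom = sample(chroms, n_snps, replace = TRUE),
    pos = pos,
    rsid = sprintf("rsR%06d", seq_len(n_snps)),
    variant_class = "single",
    validation_flags = "by-1000genomes",
    stringsAsFactors = FALSE
  )
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  list(transcripts = transcripts, snps = snps)
}

# Contents of a content table as a named list in accession order (the
# manifest's ordering), independent of the table's positional row order.
contents_by_accession <- function(tab) {
  x <- stats::setNames(tab$snp_content, tab$accession)
  as.list(x[order(names(x))])
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "promvar", mustWork = TRUE)
}

read_fixture_manifest <- function() {
  jsonlite::read_json(fixture_path("tiny_manifest.json"),
                      simplifyVector = FALSE)
}

# Small simulation spec used by fast (non-acceptance) tests.
small_sim_spec <- function(seed = 1L, ...) {
  simulation_spec(n_chromosomes = 2L, chromosome_length = 2000000L,
                  n_transcripts = 1500L, group_sizes = c(grp = 60L),
                  seed = seed, ...)
}
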