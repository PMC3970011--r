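normalize_flag_token <- function(x) {
  gsub("_", "-", tolower(trimws(x)), fixed = TRUE)
}

#' Filter SNPs by class and validation flag
#'
#' Keeps records whose `variant_class` equals `required_class` and whose
#' comma-separated `validation_flags` contain `required_flag` as a token.
#' Token matching is case-insensitive and equates hyphens with underscores
#' (UCSC releases are inconsistent about both), so `"by-1000genomes"`
#' matches `"By_1000Genomes"`.
#'
#' @param snps A SNP table (as from [read_snp_table()]).
#' @param required_class Variant class to keep (default `"single"`).
#' @param required_flag Validation token that must be present (default
#'   `"by-1000genomes"`).
#' @return The filtered SNP table, input order preserved.
#' @export
filter_snps <- function(snps, required_class = "single",
                        required_flag = "by-1000genomes") {
  if (nrow(snps) == 0L) return(snps)
  want <- normalize_flag_token(required_flag)
  has_flag <- vapply(
    strsplit(snps$validation_flags, ",", fixed = TRUE),
    function(tok) want %in% normalize_flag_token(tok),
    logical(1)
  )
  out <- snps[snps$variant_class == required_class & has_flag, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Split SNP positions by chromosome once; each element is a sorted integer
# vector. Counting a window is then two binary searches (findInterval).
split_snp_positions <- function(snps) {
  pos <- split(snps$pos, snps$chrom)
  lapply(pos, function(p) sort(as.integer(p)))
}

count_in_sorted <- function(sorted_pos, start, end) {
  # number of values v with start <= v < end, by binary search
  findInterval(end - 0.5, sorted_pos) - findInterval(start - 0.5, sorted_pos)
}

#' Count SNPs in one genomic window
#'
#' Counts SNP records with `chrom == window$chrom` and `start <= pos < end`
#' by binary search over the per-chromosome sorted position vector
#' (O(log n) per window after the one-off sort).
#'
#' @param snps A SNP table sorted by (chrom, pos).
#' @param window A one-row data frame (or list) with `chrom`, `start`,
#'   `end`.
#' @return A non-negative integer count.
#' @export
count_snps_in_window <- function(snps, window) {
  sorted <- split_snp_positions(snps)
  p <- sorted[[as.character(window$chrom)]]
  if (is.null(p)) return(0L)
  as.integer(count_in_sorted(p, window$start, window$end))
}

#' Build the per-transcript SNP-content table for one analysis case
#'
#' For every transcript satisfying the case's 5'UTR requirement, computes
#' the strand-aware upstream window ([upstream_window()]) and its SNP
#' content (the number of qualifying SNPs inside the window). Transcripts
#' are assumed already filtered ([filter_transcripts()]) and SNPs already
#' filtered ([filter_snps()]).
#'
#' @param transcripts A filtered transcript table.
#' @param snps A filtered SNP table.
#' @param case A [case_spec()].
#' @return A data frame with columns `accession`, `gene_symbol`, `chrom`,
#'   `strand`, `window_start`, `window_end`, `effective_length`,
#'   `snp_content`, carrying the case as attribute `case`.
#' @export
build_content_table <- function(transcripts, snps, case) {
  stopifnot(inherits(case, "case_spec"))
  if (case$utr_requirement == "positive") {
    transcripts <- transcripts[utr5_length(transcripts) > 0L, , drop = FALSE]
  }
  win <- upstream_window(transcripts, case)
  content <- integer(nrow(transcripts))
  if (nrow(transcripts) > 0L && nrow(snps) > 0L) {
    sorted <- split_snp_positions(snps)
    for (ch in unique(win$chrom)) {
      p <- sorted[[ch]]
      sel <- which(win$chrom == ch)
      if (is.null(p) || length(sel) == 0L) next
      content[sel] <- findInterval(win$end[sel] - 0.5, p) -
        findInterval(win$start[sel] - 0.5, p)
    }
  }
  out <- data.frame(
    accession = transcripts$accession,
    gene_symbol = transcripts$gene_symbol,
    chrom = win$chrom, strand = transcripts$strand,
    window_start = win$start, window_end = win$end,
    effective_length = win$effective_length,
    snp_content = as.integer(content),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "case") <- case
  out
}

#' SNP-rich transcripts
#'
#' Transcripts whose upstream window holds at least `min_content` SNPs —
#' with the conventional default of 6 in the 500-bp TSS window this is the
#' "SNP-rich" subset. Rows are ordered by decreasing SNP content, ties by
#' accession.
#'
#' @param table A SNP-content table from [build_content_table()].
#' @param min_content Non-negative integer threshold (default 6).
#' @return A data frame with columns `accession`, `gene_symbol`,
#'   `snp_content`.
#' @export
snp_rich_subset <- function(table, min_content = 6L) {
  min_content <- as.integer(min_content)
  if (is.na(min_content) || min_content < 0L) {
    stop("min_content must be a non-negative integer", call. = FALSE)
  }
  sel <- table$snp_content >= min_content
  out <- table[sel, c("accession", "gene_symbol", "snp_content"),
               drop = FALSE]
  out <- out[order(-out$snp_content, out$accession, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
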