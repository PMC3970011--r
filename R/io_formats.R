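#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr1"` and `"1"` refer to the
#' same chromosome internally. Idempotent.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX", "chrM"))
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# Columns of the pipeline's native transcript representation. Coordinates are
# 0-based half-open throughout (the UCSC storage convention).
transcript_cols <- c(
  "accession", "gene_symbol", "chrom", "strand",
  "tx_start", "tx_end", "cds_start", "cds_end"
)

empty_transcript_table <- function() {
  data.frame(
    accession = character(0), gene_symbol = character(0),
    chrom = character(0), strand = character(0),
    tx_start = integer(0), tx_end = integer(0),
    cds_start = integer(0), cds_end = integer(0),
    stringsAsFactors = FALSE
  )
}

empty_snp_table <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), rsid = character(0),
    variant_class = character(0), validation_flags = character(0),
    stringsAsFactors = FALSE
  )
}

new_parse_report <- function(row = integer(0), reason = character(0)) {
  data.frame(row = as.integer(row), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' Retrieve the parse report attached to a parsed table
#'
#' Readers never silently drop malformed rows: every skipped row is recorded
#' with its 1-based line number and a reason. `parse_report()` returns that
#' record.
#'
#' @param x A table returned by [read_transcript_table()], [read_snp_table()]
#'   or [read_gene_sets()].
#' @return A data frame with columns `row` and `reason` (may have 0 rows).
#' @export
parse_report <- function(x) {
  rep <- attr(x, "parse_report")
  if (is.null(rep)) new_parse_report() else rep
}

read_tsv_rows <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       line_no = which(keep))
}

#' Read a transcript annotation table
#'
#' Parses a UCSC genePred-dialect transcript table into the pipeline's native
#' 8-column representation (`accession`, `gene_symbol`, `chrom`, `strand`,
#' `tx_start`, `tx_end`, `cds_start`, `cds_end`; coordinates 0-based
#' half-open). Two dialects are supported:
#'
#' * `"minimal-8col"` — the native format, columns in the order above;
#' * `"refgene-16col"` — the full UCSC refGene table (bin, name, chrom,
#'   strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#'   exonEnds, score, name2, cdsStartStat, cdsEndStat, exonFrames). Exon
#'   structure is discarded; it plays no role in upstream-window counting.
#'
#' Chromosome names are normalized with [normalize_chrom()]. Rows with the
#' wrong column count, a strand other than `+`/`-`, non-numeric coordinates,
#' or coordinates violating `0 <= tx_start < tx_end` and
#' `tx_start <= cds_start <= cds_end <= tx_end` are collected in the parse
#' report (see [parse_report()]) and excluded from the output.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` and
#'   blank lines are ignored.
#' @param dialect `"minimal-8col"` (default) or `"refgene-16col"`.
#' @param strict If `TRUE`, any malformed row is a fatal error instead of a
#'   report entry.
#' @return A data frame of transcript records with a `parse_report`
#'   attribute.
#' @export
read_transcript_table <- function(path,
                                  dialect = c("minimal-8col", "refgene-16col"),
                                  strict = FALSE) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_rows(path)
  ncol_expect <- if (dialect == "minimal-8col") 8L else 16L
  nf <- lengths(raw$fields)

  bad_rows <- integer(0)
  bad_why <- character(0)
  note_bad <- function(i, why) {
    if (strict) {
      stop("malformed row ", raw$line_no[i], " in ", path, ": ", why,
           call. = FALSE)
    }
    bad_rows <<- c(bad_rows, raw$line_no[i])
    bad_why <<- c(bad_why, why)
  }

  ok <- nf == ncol_expect
  for (i in which(!ok)) {
    note_bad(i, sprintf("expected %d columns, found %d", ncol_expect, nf[i]))
  }

  if (!any(ok)) {
    out <- empty_transcript_table()
    attr(out, "parse_report") <- new_parse_report(bad_rows, bad_why)
    return(out)
  }

  m <- do.call(rbind, raw$fields[ok])
  if (dialect == "minimal-8col") {
    df <- data.frame(
      accession = m[, 1], gene_symbol = m[, 2],
      chrom = normalize_chrom(m[, 3]), strand = m[, 4],
      tx_start = suppressWarnings(as.integer(m[, 5])),
      tx_end = suppressWarnings(as.integer(m[, 6])),
      cds_start = suppressWarnings(as.integer(m[, 7])),
      cds_end = suppressWarnings(as.integer(m[, 8])),
      stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(
      accession = m[, 2], gene_symbol = m[, 13],
      chrom = normalize_chrom(m[, 3]), strand = m[, 4],
      tx_start = suppressWarnings(as.integer(m[, 5])),
      tx_end = suppressWarnings(as.integer(m[, 6])),
      cds_start = suppressWarnings(as.integer(m[, 7])),
      cds_end = suppressWarnings(as.integer(m[, 8])),
      stringsAsFactors = FALSE
    )
  }
  idx <- which(ok)

  valid_strand <- df$strand %in% c("+", "-")
  numeric_ok <- !(is.na(df$tx_start) | is.na(df$tx_end) |
                    is.na(df$cds_start) | is.na(df$cds_end))
  coord_ok <- numeric_ok &
    df$tx_start >= 0L & df$tx_start < df$tx_end &
    df$tx_start <= df$cds_start & df$cds_start <= df$cds_end &
    df$cds_end <= df$tx_end

  for (j in which(!valid_strand)) {
    note_bad(idx[j], sprintf("invalid strand '%s'", df$strand[j]))
  }
  for (j in which(valid_strand & !numeric_ok)) {
    note_bad(idx[j], "non-numeric coordinate")
  }
  for (j in which(valid_strand & numeric_ok & !coord_ok)) {
    note_bad(idx[j], "coordinate invariant violated")
  }

  keep <- valid_strand & coord_ok
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parse_report") <- new_parse_report(bad_rows, bad_why)
  out
}

#' Read a UCSC-dialect SNP table
#'
#' Parses a tab-separated SNP track in the UCSC common-SNPs dialect:
#' `chrom`, `chromStart`, `chromEnd`, `rsID`, `class`, `validationFlags`
#' (BED-like 0-based starts). The output is sorted by (chrom, pos) —
#' chromosomes in lexicographic order — and exact duplicate
#' (chrom, pos, rsid) triples are collapsed to one record; the number of
#' collapsed duplicates is available as `attr(x, "duplicates_collapsed")`.
#'
#' Class `"single"` records are expected to span exactly one base
#' (`chromEnd == chromStart + 1`); violations are kept but flagged in the
#' parse report.
#'
#' @param path Path to a tab-separated SNP file.
#' @param strict If `TRUE`, malformed rows are fatal.
#' @return A data frame with columns `chrom`, `pos`, `rsid`, `variant_class`,
#'   `validation_flags`, sorted by (chrom, pos), with attributes
#'   `parse_report` and `duplicates_collapsed`.
#' @export
read_snp_table <- function(path, strict = FALSE) {
  raw <- read_tsv_rows(path)
  nf <- lengths(raw$fields)

  bad_rows <- integer(0)
  bad_why <- character(0)
  note_bad <- function(i, why) {
    if (strict) {
      stop("malformed row ", raw$line_no[i], " in ", path, ": ", why,
           call. = FALSE)
    }
    bad_rows <<- c(bad_rows, raw$line_no[i])
    bad_why <<- c(bad_why, why)
  }

  ok <- nf == 6L
  for (i in which(!ok)) {
    note_bad(i, sprintf("expected 6 columns, found %d", nf[i]))
  }

  if (!any(ok)) {
    out <- empty_snp_table()
    attr(out, "parse_report") <- new_parse_report(bad_rows, bad_why)
    attr(out, "duplicates_collapsed") <- 0L
    return(out)
  }

  m <- do.call(rbind, raw$fields[ok])
  idx <- which(ok)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  df <- data.frame(
    chrom = normalize_chrom(m[, 1]), pos = start, rsid = m[, 4],
    variant_class = m[, 5], validation_flags = m[, 6],
    stringsAsFactors = FALSE
  )

  numeric_ok <- !(is.na(start) | is.na(end)) & start >= 0L & end > start
  for (j in which(!numeric_ok)) {
    note_bad(idx[j], "invalid coordinates")
  }
  # "single" records must be 1 bp; flagged but retained
  span_bad <- numeric_ok & df$variant_class == "single" & (end - start) != 1L
  for (j in which(span_bad)) {
    note_bad(idx[j], sprintf("class 'single' record spans %d bp",
                             end[j] - start[j]))
  }

  df <- df[numeric_ok, , drop = FALSE]
  o <- order(df$chrom, df$pos, df$rsid, method = "radix")
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "pos", "rsid")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL

  attr(df, "parse_report") <- new_parse_report(bad_rows, bad_why)
  attr(df, "duplicates_collapsed") <- n_dup
  df
}

#' Read SNPs from a VCF file (optional ingestion route)
#'
#' Minimal plain-text VCF ingestion for single-nucleotide records: keeps only
#' rows whose REF and every comma-separated ALT are single bases, maps the
#' 1-based `POS` to the internal 0-based `pos = POS - 1`, and labels the
#' records class `"single"`. The `validation_flags` field is filled with
#' `flag` for every record (VCFs carry no UCSC-style validation tokens), so
#' the result passes [filter_snps()] with the default flag.
#'
#' @param path Path to an uncompressed VCF file.
#' @param flag Validation token to assign (default `"by-1000genomes"`).
#' @return A SNP table as from [read_snp_table()].
#' @export
read_snp_vcf <- function(path, flag = "by-1000genomes") {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    out <- empty_snp_table()
    attr(out, "parse_report") <- new_parse_report()
    attr(out, "duplicates_collapsed") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(fields) >= 8L
  m <- do.call(rbind, lapply(fields[keep], `[`, 1:5))
  ref <- m[, 4]
  alt_single <- vapply(strsplit(m[, 5], ",", fixed = TRUE),
                       function(a) all(nchar(a) == 1L) && all(a %in% c("A", "C", "G", "T")),
                       logical(1))
  snv <- nchar(ref) == 1L & alt_single
  df <- data.frame(
    chrom = normalize_chrom(m[snv, 1]),
    pos = as.integer(m[snv, 2]) - 1L,
    rsid = m[snv, 3],
    variant_class = "single",
    validation_flags = flag,
    stringsAsFactors = FALSE
  )
  o <- order(df$chrom, df$pos, df$rsid, method = "radix")
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "pos", "rsid")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "parse_report") <- new_parse_report()
  attr(df, "duplicates_collapsed") <- n_dup
  df
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then one or more member symbols,
#' tab-separated. Member symbols are uppercased; duplicate members within a
#' set are collapsed.
#'
#' @param path Path to a GMT file.
#' @param strict If `TRUE`, a row with no members is fatal; otherwise it is
#'   skipped and recorded in the parse report.
#' @return A named list of character vectors of gene symbols, with
#'   attributes `descriptions` (named character) and `parse_report`.
#' @export
read_gene_sets <- function(path, strict = FALSE) {
  raw <- read_tsv_rows(path)
  nf <- lengths(raw$fields)

  bad_rows <- integer(0)
  bad_why <- character(0)

  sets <- list()
  descs <- character(0)
  for (i in seq_along(raw$fields)) {
    f <- raw$fields[[i]]
    if (nf[i] < 3L || all(!nzchar(f[-(1:2)]))) {
      if (strict) {
        stop("gene set row ", raw$line_no[i], " in ", path,
             " has no members", call. = FALSE)
      }
      bad_rows <- c(bad_rows, raw$line_no[i])
      bad_why <- c(bad_why, "gene set with no members")
      next
    }
    members <- unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])]))
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  attr(sets, "parse_report") <- new_parse_report(bad_rows, bad_why)
  sets
}

#' Write a result table as TSV
#'
#' Writes any tabular result as a tab-separated file with a header row and
#' locale-independent numeric formatting. If the table carries a `case`
#' attribute (see [case_spec()]), it is serialized as a leading `# case:`
#' comment line so that [read_content_table()] can restore it.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  cs <- attr(rows, "case")
  con <- file(path, open = "wt")
  ok <- FALSE
  tryCatch({
    if (!is.null(cs)) {
      writeLines(sprintf("# case: anchor=%s window=%d utr=%s",
                         cs$anchor, cs$window_length, cs$utr_requirement), con)
    }
    close(con)
    con <- NULL
    data.table::fwrite(rows, path, sep = "\t", quote = FALSE,
                       append = !is.null(cs), col.names = TRUE,
                       logical01 = FALSE)
    ok <- TRUE
  }, finally = {
    if (!is.null(con)) close(con)
    if (!ok && file.exists(path)) invisible(NULL)
  })
  invisible(path)
}

#' Read back a SNP-content table written by [write_table()]
#'
#' Restores the data frame and, when present, the `# case:` header as a
#' [case_spec()] attribute.
#'
#' @param path Path to a TSV written by [write_table()].
#' @return A data frame; attribute `case` holds the analysis case if one was
#'   serialized.
#' @export
read_content_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  cs <- NULL
  if (length(first) == 1L && startsWith(first, "# case:")) {
    kv <- regmatches(first, gregexpr("[a-z]+=[^ ]+", first))[[1]]
    vals <- sub("^[a-z]+=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    cs <- case_spec(anchor = vals[["anchor"]],
                    window_length = as.integer(vals[["window"]]),
                    utr_requirement = vals[["utr"]])
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", skip = if (is.null(cs)) 0L else 1L,
                                        header = TRUE))
  if (!is.null(cs)) attr(df, "case") <- cs
  df
}
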