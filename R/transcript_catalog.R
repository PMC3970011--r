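#' Define an analysis case
#'
#' An analysis case fixes three choices: the window anchor (TSS, the
#' transcription start site, or CRS, the coding region start), the upstream
#' window length in bases, and whether transcripts with a zero-length 5'UTR
#' (TSS == CRS) are admitted (`"any"`, i.e. 5'UTR >= 0) or excluded
#' (`"positive"`, 5'UTR > 0).
#'
#' @param anchor `"TSS"` or `"CRS"`.
#' @param window_length Positive integer window length in bases (500 and
#'   1000 are the conventional choices; any positive integer is accepted).
#' @param utr_requirement `"any"` or `"positive"`.
#' @return An object of class `case_spec`.
#' @examples
#' case_spec("TSS", 500, "any")
#' @export
case_spec <- function(anchor = c("TSS", "CRS"), window_length = 500L,
                      utr_requirement = c("any", "positive")) {
  anchor <- match.arg(anchor)
  utr_requirement <- match.arg(utr_requirement)
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length <= 0L) {
    stop("window_length must be a positive integer", call. = FALSE)
  }
  structure(list(anchor = anchor, window_length = window_length,
                 utr_requirement = utr_requirement),
            class = "case_spec")
}

#' @export
format.case_spec <- function(x, ...) {
  sprintf("5'UTR%s_(-%d;%s)",
          if (x$utr_requirement == "any") ">=0" else ">0",
          x$window_length, x$anchor)
}

#' @export
print.case_spec <- function(x, ...) {
  cat("<case_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Filename-safe label for an analysis case
#'
#' @param case A [case_spec()].
#' @return A string such as `"utrge0_TSS_500"`.
#' @export
case_label <- function(case) {
  stopifnot(inherits(case, "case_spec"))
  sprintf("%s_%s_%d",
          if (case$utr_requirement == "any") "utrge0" else "utrgt0",
          case$anchor, case$window_length)
}

#' The six default analysis cases
#'
#' The default case matrix: (5'UTR>=0, TSS, 500), (5'UTR>=0, TSS, 1000),
#' (5'UTR>=0, CRS, 500), (5'UTR>0, TSS, 500), (5'UTR>0, CRS, 500),
#' (5'UTR>0, CRS, 1000). The full 2x2x2 matrix is available via `full =
#' TRUE`.
#'
#' @param full If `TRUE`, return all eight anchor x length x requirement
#'   combinations.
#' @return A named list of [case_spec()] objects, named by [case_label()].
#' @export
default_cases <- function(full = FALSE) {
  combos <- if (full) {
    expand.grid(utr = c("any", "positive"), anchor = c("TSS", "CRS"),
                len = c(500L, 1000L), stringsAsFactors = FALSE)
  } else {
    data.frame(
      utr = c("any", "any", "any", "positive", "positive", "positive"),
      anchor = c("TSS", "TSS", "CRS", "TSS", "CRS", "CRS"),
      len = c(500L, 1000L, 500L, 500L, 500L, 1000L),
      stringsAsFactors = FALSE
    )
  }
  cases <- lapply(seq_len(nrow(combos)), function(i) {
    case_spec(combos$anchor[i], combos$len[i], combos$utr[i])
  })
  names(cases) <- vapply(cases, case_label, character(1))
  cases
}

#' 5'UTR length of each transcript
#'
#' The 5'UTR length is the distance between the transcription start site and
#' the coding region start: `cds_start - tx_start` on the `+` strand,
#' `tx_end - cds_end` on the `-` strand. Zero encodes a transcript whose TSS
#' and CRS coincide (no annotated 5'UTR).
#'
#' @param records A transcript table.
#' @return Integer vector of non-negative 5'UTR lengths, one per record.
#' @export
utr5_length <- function(records) {
  ifelse(records$strand == "+",
         records$cds_start - records$tx_start,
         records$tx_end - records$cds_end)
}

#' Anchor boundary coordinate of each transcript
#'
#' Returns the half-open boundary coordinate such that the transcript body
#' lies on its downstream side: on the `+` strand the TSS boundary is
#' `tx_start` and the CRS boundary `cds_start`; on the `-` strand they are
#' `tx_end` and `cds_end` respectively.
#'
#' @param records A transcript table.
#' @param anchor `"TSS"` or `"CRS"`.
#' @return Integer vector of boundary coordinates.
#' @export
anchor_position <- function(records, anchor = c("TSS", "CRS")) {
  anchor <- match.arg(anchor)
  if (anchor == "TSS") {
    ifelse(records$strand == "+", records$tx_start, records$tx_end)
  } else {
    ifelse(records$strand == "+", records$cds_start, records$cds_end)
  }
}

#' Strand-aware upstream window of each transcript
#'
#' For a window of length L anchored at boundary b, the window is `[b - L,
#' b)` on the `+` strand and `[b, b + L)` on the `-` strand — strictly
#' upstream, so a SNP at the boundary itself is downstream on the `+` strand
#' and not counted. Windows running past position 0 are clipped, and the
#' bases actually covered are reported as `effective_length`.
#'
#' @param records A transcript table.
#' @param case A [case_spec()] (only `anchor` and `window_length` are used).
#' @return A data frame with columns `chrom`, `start`, `end`,
#'   `effective_length`.
#' @export
upstream_window <- function(records, case) {
  stopifnot(inherits(case, "case_spec"))
  b <- anchor_position(records, case$anchor)
  L <- case$window_length
  plus <- records$strand == "+"
  start <- ifelse(plus, pmax(0L, b - L), b)
  end <- ifelse(plus, b, b + L)
  data.frame(chrom = records$chrom,
             start = as.integer(start), end = as.integer(end),
             effective_length = as.integer(end - start),
             stringsAsFactors = FALSE)
}

#' Apply the curated-transcript selection criteria
#'
#' Keeps transcripts that (a) carry a curated accession (prefix `"NM_"` by
#' default), (b) map to a canonical chromosome (1-22, X, Y by default), (c)
#' are protein coding (`cds_start < cds_end`; `cds_start == cds_end` encodes
#' a non-coding annotation), and (d) have a unique TSS: when two or more
#' transcripts share the same (chrom, strand, TSS boundary) key only one is
#' analyzed — the one with the lexicographically smallest accession. Filters
#' are applied in that order, each counting the rows it removes; the
#' non-coding filter runs before TSS deduplication.
#'
#' @param records A transcript table (as from [read_transcript_table()]).
#' @param accession_prefix Accession prefix identifying curated transcripts.
#' @param chromosomes Character vector of admissible (normalized)
#'   chromosome names.
#' @param dedup_strand If `TRUE` (default) the TSS-dedup key includes
#'   strand; if `FALSE` transcripts on opposite strands sharing a TSS
#'   coordinate also collide.
#' @return A list with elements `kept` (transcript table) and `report`
#'   (class `filter_report`): counts removed by each criterion plus totals
#'   kept, kept with 5'UTR > 0, and kept with 5'UTR == 0.
#' @export
filter_transcripts <- function(records,
                               accession_prefix = "NM_",
                               chromosomes = c(as.character(1:22), "X", "Y"),
                               dedup_strand = TRUE) {
  n_input <- nrow(records)

  is_curated <- startsWith(records$accession, accession_prefix)
  removed_accession <- sum(!is_curated)
  records <- records[is_curated, , drop = FALSE]

  on_canonical <- records$chrom %in% chromosomes
  removed_chromosome <- sum(!on_canonical)
  records <- records[on_canonical, , drop = FALSE]

  coding <- records$cds_start < records$cds_end
  removed_noncoding <- sum(!coding)
  records <- records[coding, , drop = FALSE]

  if (nrow(records) > 0L) {
    tss <- anchor_position(records, "TSS")
    key <- if (dedup_strand) {
      paste(records$chrom, records$strand, tss, sep = "\r")
    } else {
      paste(records$chrom, tss, sep = "\r")
    }
    o <- order(key, records$accession, method = "radix")
    records <- records[o, , drop = FALSE]
    dup <- duplicated(key[o])
    removed_duplicate_tss <- sum(dup)
    records <- records[!dup, , drop = FALSE]
    # restore a stable, position-based ordering
    records <- records[order(records$chrom, records$tx_start,
                             records$accession, method = "radix"), ,
                       drop = FALSE]
  } else {
    removed_duplicate_tss <- 0L
  }
  rownames(records) <- NULL

  utr <- utr5_length(records)
  report <- structure(list(
    n_input = n_input,
    removed_accession = removed_accession,
    removed_chromosome = removed_chromosome,
    removed_noncoding = removed_noncoding,
    removed_duplicate_tss = removed_duplicate_tss,
    kept = nrow(records),
    kept_utr_positive = sum(utr > 0L),
    kept_utr_zero = sum(utr == 0L)
  ), class = "filter_report")

  list(kept = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Transcript filter report\n")
  cat("  input:                 ", x$n_input, "\n")
  cat("  removed (accession):   ", x$removed_accession, "\n")
  cat("  removed (chromosome):  ", x$removed_chromosome, "\n")
  cat("  removed (non-coding):  ", x$removed_noncoding, "\n")
  cat("  removed (dup. TSS):    ", x$removed_duplicate_tss, "\n")
  cat("  kept:                  ", x$kept,
      sprintf(" (5'UTR>0: %d, 5'UTR==0: %d)\n",
              x$kept_utr_positive, x$kept_utr_zero))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(criterion = names(unclass(x)),
             count = unlist(unclass(x), use.names = FALSE),
             stringsAsFactors = FALSE)
}
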