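#' Histogram and survival counts of SNP contents
#'
#' Tabulates how many transcripts carry each SNP-content value, plus the
#' cumulative "at least N" transform for N = 1..max(content).
#'
#' @param table A SNP-content table from [build_content_table()].
#' @return A list with `counts` (named integer vector, names are content
#'   values observed) and `at_least` (named integer vector over N =
#'   1..max(content); empty if no transcript has a SNP).
#' @export
content_histogram <- function(table) {
  x <- table$snp_content
  if (length(x) == 0L) {
    return(list(counts = integer(0), at_least = integer(0)))
  }
  counts <- table(x)
  counts <- stats::setNames(as.integer(counts), names(counts))
  mx <- max(x)
  if (mx < 1L) {
    at_least <- integer(0)
  } else {
    at_least <- vapply(1:mx, function(n) sum(x >= n), integer(1))
    names(at_least) <- as.character(1:mx)
  }
  list(counts = counts, at_least = at_least)
}

#' Angular (arcsine square root) transformation of a proportion
#'
#' The variance-stabilizing transform for proportions,
#' `y = 2 * asin(sqrt(p))`, mapping `[0, 1]` onto `[0, pi]`. After the
#' transform, a proportion estimated from n trials has variance
#' approximately `1/n` regardless of p.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return `2 * asin(sqrt(p))`, in radians.
#' @examples
#' angular_transform(c(0, 0.25, 1)) # 0, pi/3, pi
#' @export
angular_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  2 * asin(sqrt(p))
}

#' Two-proportion test on the angular scale
#'
#' Compares the proportion `x1/n1` (group) against `x2/n2` (background)
#' after the angular transform: `z = (y1 - y2) / sqrt(1/n1 + 1/n2)`, where
#' `y_i = 2 * asin(sqrt(x_i/n_i))`. Because the transformed proportion has
#' the known variance `1/n`, no variance is estimated and the statistic is
#' referred to the standard normal by default; a finite-df mode (df = n1 +
#' n2 - 2) is available for sensitivity analysis. Output labels keep the
#' conventional "t-test for arcsine transformed proportions" framing.
#'
#' @param x1,n1 Group successes and trials.
#' @param x2,n2 Background successes and trials.
#' @param sidedness `"greater"` (one-sided, group > background; default) or
#'   `"two-sided"`.
#' @param df `Inf` (standard normal, default) or a finite number of degrees
#'   of freedom; `NULL` selects `n1 + n2 - 2`.
#' @param N Optional threshold label carried into the result.
#' @return A one-row data frame of class `comparison_result` with columns
#'   `N`, `n1`, `x1`, `p1`, `y1`, `n2`, `x2`, `p2`, `y2`, `z_stat`,
#'   `p_value`, `sidedness`.
#' @export
compare_proportions <- function(x1, n1, x2, n2,
                                sidedness = c("greater", "two-sided"),
                                df = Inf, N = NA_integer_) {
  sidedness <- match.arg(sidedness)
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  if (is.null(df)) df <- n1 + n2 - 2
  p1 <- x1 / n1
  p2 <- x2 / n2
  y1 <- angular_transform(p1)
  y2 <- angular_transform(p2)
  z <- (y1 - y2) / sqrt(1 / n1 + 1 / n2)
  tail <- function(q) {
    if (is.infinite(df)) stats::pnorm(q, lower.tail = FALSE)
    else stats::pt(q, df = df, lower.tail = FALSE)
  }
  p_value <- if (sidedness == "greater") tail(z) else 2 * tail(abs(z))
  p_value <- min(p_value, 1)
  out <- data.frame(N = as.integer(N), n1 = n1, x1 = x1, p1 = p1, y1 = y1,
                    n2 = n2, x2 = x2, p2 = p2, y2 = y2,
                    z_stat = z, p_value = p_value, sidedness = sidedness,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

same_case <- function(a, b) {
  !is.null(a) && !is.null(b) &&
    identical(a$anchor, b$anchor) &&
    identical(a$window_length, b$window_length) &&
    identical(a$utr_requirement, b$utr_requirement)
}

#' Threshold sweep: group vs background over N = 1..20
#'
#' For each threshold N, forms the tail proportions p1 = (group transcripts
#' with SNP content >= N) / n1 and p2 likewise for the background, and runs
#' [compare_proportions()]. Both content tables must have been built under
#' the same analysis case. The background is conventionally the
#' whole-genome table and may include the group's transcripts; pass a
#' pre-subtracted background for a disjoint comparison.
#'
#' @param group_table,background_table SNP-content tables from
#'   [build_content_table()] built under the same [case_spec()].
#' @param n_range Integer thresholds to sweep (default `1:20`).
#' @param sidedness,df Passed to [compare_proportions()].
#' @param group_name Optional label stored as an attribute.
#' @return A data frame of class `sweep_table`, one row per N, carrying
#'   attributes `case` and `group_name`.
#' @export
threshold_sweep <- function(group_table, background_table, n_range = 1:20,
                            sidedness = c("greater", "two-sided"), df = Inf,
                            group_name = NULL) {
  sidedness <- match.arg(sidedness)
  ca <- attr(group_table, "case")
  cb <- attr(background_table, "case")
  if (!is.null(ca) || !is.null(cb)) {
    if (!same_case(ca, cb)) {
      stop("group and background content tables were built under different ",
           "analysis cases", call. = FALSE)
    }
  }
  n1 <- nrow(group_table)
  n2 <- nrow(background_table)
  if (n1 == 0L || n2 == 0L) {
    stop("both content tables must be non-empty", call. = FALSE)
  }
  n_range <- sort(unique(as.integer(n_range)))
  rows <- lapply(n_range, function(N) {
    compare_proportions(sum(group_table$snp_content >= N), n1,
                        sum(background_table$snp_content >= N), n2,
                        sidedness = sidedness, df = df, N = N)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  attr(out, "case") <- ca
  attr(out, "group_name") <- group_name
  out
}

#' Run the full group x case analysis matrix
#'
#' Builds, for every analysis case, the whole-genome SNP-content table and
#' each group's sub-table (matched by uppercased gene symbol), then runs
#' [threshold_sweep()] for every (group, case) combination. Symbols in a
#' group definition that match no transcript are counted and reported with
#' a warning.
#'
#' @param transcripts A filtered transcript table ([filter_transcripts()]).
#' @param snps A filtered SNP table ([filter_snps()]).
#' @param groups Named list of character vectors of gene symbols.
#' @param cases Named list of [case_spec()] objects (default
#'   [default_cases()]).
#' @param n_range,sidedness,df Passed to [threshold_sweep()].
#' @return A nested list `result[[group]][[case_label]]` of `sweep_table`s,
#'   with attribute `unmatched` (named integer vector of unmatched-symbol
#'   counts per group).
#' @export
run_case_matrix <- function(transcripts, snps, groups,
                            cases = default_cases(), n_range = 1:20,
                            sidedness = c("greater", "two-sided"), df = Inf) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.list(groups), !is.null(names(groups)))
  catalog_symbols <- toupper(transcripts$gene_symbol)
  unmatched <- vapply(groups, function(g) {
    sum(!(unique(toupper(g)) %in% catalog_symbols))
  }, integer(1))
  for (g in names(groups)) {
    if (unmatched[[g]] > 0L) {
      warning(sprintf("group '%s': %d symbol(s) not found in the catalog",
                      g, unmatched[[g]]), call. = FALSE)
    }
  }
  bg_tables <- lapply(cases, function(cs) {
    build_content_table(transcripts, snps, cs)
  })
  out <- lapply(names(groups), function(g) {
    members <- unique(toupper(groups[[g]]))
    res <- lapply(names(cases), function(cl) {
      bg <- bg_tables[[cl]]
      grp <- bg[toupper(bg$gene_symbol) %in% members, , drop = FALSE]
      attr(grp, "case") <- cases[[cl]]
      threshold_sweep(grp, bg, n_range = n_range, sidedness = sidedness,
                      df = df, group_name = g)
    })
    names(res) <- names(cases)
    res
  })
  names(out) <- names(groups)
  attr(out, "unmatched") <- unmatched
  out
}
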