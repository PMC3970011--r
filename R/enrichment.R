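#' Fold enrichment of a gene set in a query list
#'
#' The ratio of two proportions: the share of the query list annotated by
#' the set, `k/n`, over the share of the background annotated by it,
#' `K/N_bg`. Values above 1 indicate over-representation; 1.5 is the
#' conventional "interesting" cut-off.
#'
#' @param k Query genes in the set.
#' @param n Query list size.
#' @param K Background genes in the set.
#' @param N_bg Background size.
#' @return `(k/n) / (K/N_bg)`; `NA` where `K == 0` (undefined).
#' @export
fold_enrichment <- function(k, n, K, N_bg) {
  if (any(n <= 0) || any(N_bg <= 0)) {
    stop("n and N_bg must be positive", call. = FALSE)
  }
  ifelse(K == 0, NA_real_, (k / n) / (K / N_bg))
}

check_contingency <- function(k, n, K, N_bg) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N_bg <= 0) ||
      any(k > n) || any(k > K) || any(n > N_bg) || any(K > N_bg)) {
    stop("impossible contingency table: need 0 <= k <= min(n, K) and ",
         "n, K <= N_bg", call. = FALSE)
  }
}

#' One-sided Fisher exact p-value (hypergeometric upper tail)
#'
#' The probability of observing at least `k` query genes in the set when
#' `n` genes are drawn without replacement from a background of `N_bg`
#' genes of which `K` are in the set.
#'
#' @inheritParams fold_enrichment
#' @return P(X >= k) under Hypergeometric(n, K, N_bg). Vectorized.
#' @export
fisher_score <- function(k, n, K, N_bg) {
  check_contingency(k, n, K, N_bg)
  stats::phyper(k - 1, K, N_bg - K, n, lower.tail = FALSE)
}

#' EASE score: the conservative variant of the Fisher exact test
#'
#' The one-sided Fisher exact p-value computed after removing one gene from
#' the query overlap: the hypergeometric upper tail from `max(k - 1, 0)`.
#' Decrementing the overlap penalizes sets supported by very few genes, so
#' `ease_score >= fisher_score` always.
#'
#' @inheritParams fold_enrichment
#' @return P(X >= max(k - 1, 0)) under Hypergeometric(n, K, N_bg).
#'   Vectorized.
#' @export
ease_score <- function(k, n, K, N_bg) {
  check_contingency(k, n, K, N_bg)
  stats::phyper(pmax(k - 1, 0) - 1, K, N_bg - K, n, lower.tail = FALSE)
}

#' Gene-set enrichment of a query list
#'
#' Scores every gene set against a query list and a background universe.
#' Symbols are uppercased before matching. Following the annotation-tool
#' convention, the effective query size `n` and background size `N_bg`
#' count only genes annotated by at least one set in the collection; a set
#' contributes a record when it overlaps the query in at least one gene.
#' Records are ordered by increasing EASE score. A record `passes` the
#' reporting screen when `k >= count_threshold` and
#' `ease_p <= ease_threshold`; significance at `sig_level` is a separate
#' derived column.
#'
#' @param query Character vector of query gene symbols.
#' @param sets A gene-set collection from [read_gene_sets()] (named list of
#'   symbol vectors).
#' @param background Character vector of background gene symbols; must
#'   contain the query (query symbols outside it are dropped with a
#'   warning).
#' @param count_threshold Minimum overlap for `passes` (default 2).
#' @param ease_threshold Maximum EASE score for `passes` (default 0.1).
#' @param sig_level Level for the `significant` flag (default 0.05).
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted EASE column
#'   `ease_bh`.
#' @return A data frame with columns `set_name`, `k`, `n`, `K`, `N_bg`,
#'   `fold_enrichment`, `ease_p`, `fisher_p`, `significant`, `passes`
#'   (and optionally `ease_bh`), sorted by `ease_p`.
#' @export
enrich_gene_list <- function(query, sets, background,
                             count_threshold = 2L, ease_threshold = 0.1,
                             sig_level = 0.05, fdr = FALSE) {
  if (length(background) == 0L) {
    stop("background gene list is empty", call. = FALSE)
  }
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  stray <- setdiff(query, background)
  if (length(stray) > 0L) {
    warning(length(stray), " query symbol(s) absent from the background ",
            "were dropped", call. = FALSE)
    query <- intersect(query, background)
  }
  sets <- lapply(sets, function(s) unique(toupper(s)))

  annotated <- unique(unlist(sets, use.names = FALSE))
  universe <- intersect(background, annotated)
  query_ann <- intersect(query, universe)
  n <- length(query_ann)
  N_bg <- length(universe)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    k <- length(intersect(query_ann, members))
    K <- length(members)
    if (k < 1L) return(NULL)
    data.frame(set_name = nm, k = k, n = n, K = K, N_bg = N_bg,
               fold_enrichment = fold_enrichment(k, n, K, N_bg),
               ease_p = ease_score(k, n, K, N_bg),
               fisher_p = fisher_score(k, n, K, N_bg),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(set_name = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N_bg = integer(0),
                      fold_enrichment = numeric(0), ease_p = numeric(0),
                      fisher_p = numeric(0), significant = logical(0),
                      passes = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$ease_p < sig_level
  out$passes <- out$k >= count_threshold & out$ease_p <= ease_threshold
  if (fdr) out$ease_bh <- stats::p.adjust(out$ease_p, method = "BH")
  out <- out[order(out$ease_p, out$set_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
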