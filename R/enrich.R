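#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` genes from a background of `N` that contains
#' `K` term-annotated genes; computed through the stable distribution-function
#' implementation in stats.
#'
#' @param k observed term-annotated candidates
#' @param n number of candidate genes
#' @param K term-annotated genes in the background
#' @param N background size
#' @return the tail probability
#' @export
hypergeom_upper <- function(k, n, K, N) {
  if (!(is_count(k) && is_count(n) && is_count(K) && is_count(N))) {
    stop_input("k, n, K, N must be non-negative integers")
  }
  if (k > n || n > N || K > N || k > K) {
    stop_input("impossible draw: need k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test of candidate genes
#'
#' One-sided over-representation test of a candidate gene set against a
#' term-to-gene map, one test per term with at least one candidate gene.
#' Candidates outside the background and term-map genes outside the background
#' are dropped (counts recorded in attributes). The default significance call
#' uses the raw p-value at `alpha` (no correction); Bonferroni multiplies by
#' the number of tested terms.
#'
#' @param candidates,background character gene-id vectors (candidates must lie
#'   in the background; violations are dropped with a message)
#' @param term_map data.frame with columns term, gene
#' @param alpha significance level, default 0.05
#' @param correction "none" (default) or "bonferroni"
#' @return data.frame of class `enrichment_result`, sorted by `p_raw`:
#'   term, k, n, K, N, p_raw, p_bonferroni, significant
#' @export
enrich <- function(candidates, background, term_map, alpha = 0.05,
                   correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  background <- unique(as.character(background))
  if (length(background) == 0L) stop_input("empty background")
  candidates <- unique(as.character(candidates))
  dropped_cand <- setdiff(candidates, background)
  if (length(dropped_cand)) {
    message(sprintf("dropping %d candidate gene(s) not in the background", length(dropped_cand)))
    candidates <- intersect(candidates, background)
  }
  tm <- unique(term_map[term_map$gene %in% background, c("term", "gene")])
  dropped_tm <- nrow(unique(term_map[, c("term", "gene")])) - nrow(tm)
  N <- length(background)
  n <- length(candidates)
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), significant = logical(0))
  if (n == 0L || nrow(tm) == 0L) {
    class(empty) <- c("enrichment_result", class(empty))
    return(empty)
  }
  K_all <- table(tm$term)
  k_all <- table(tm$term[tm$gene %in% candidates])
  terms <- names(k_all)[k_all > 0]           # terms with >= 1 candidate gene
  if (length(terms) == 0L) {
    class(empty) <- c("enrichment_result", class(empty))
    return(empty)
  }
  k <- as.integer(k_all[terms])
  K <- as.integer(K_all[terms])
  p_raw <- vapply(seq_along(terms), function(i) hypergeom_upper(k[i], n, K[i], N),
                  numeric(1))
  p_bonf <- pmin(1, p_raw * length(terms))
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, p_bonferroni = p_bonf,
                    significant = (if (correction == "none") p_raw else p_bonf) < alpha)
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_candidates") <- length(dropped_cand)
  attr(out, "dropped_term_rows") <- dropped_tm
  class(out) <- c("enrichment_result", class(out))
  out
}
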