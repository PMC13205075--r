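#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` features from
#' a universe of `N` of which `K` belong to the term, the probability of at
#' least `k` term members in the draw. The standard over-representation
#' test p-value.
#'
#' @param N Universe size.
#' @param K Term size within the universe.
#' @param n Selected-set size.
#' @param k Observed overlap.
#' @return A probability in (0, 1].
#' @export
hypergeom_upper <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || K < 0 || K > N || n < 0 || n > N ||
      k < 0 || k > min(n, K)) {
    stop_input("need integers with 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a selected feature set
#'
#' One hypergeometric test per term against the analysis universe. Term
#' memberships are intersected with the universe first; terms with zero
#' overlap are dropped before BH adjustment (they carry p = 1 and only
#' dilute the correction). Adjustment is applied within each namespace.
#'
#' @param selected Character vector of selected features (subset of
#'   `universe`), e.g. the upregulated mRNAs.
#' @param terms Term tibble as from [read_gmt()].
#' @param universe Character vector: all features eligible for selection
#'   (typically every tested feature of the class).
#' @param direction_label Label stored in the output (e.g. `"up"`).
#' @return A tibble ordered by (namespace, p, term_id): `term_id`,
#'   `term_name`, `namespace`, `direction`, `k`, `n`, `K`, `N`,
#'   `gene_ratio`, `p`, `p_adj`.
#' @export
enrich_terms <- function(selected, terms, universe,
                         direction_label = "selected") {
  universe <- unique(universe)
  if (!length(universe)) stop_input("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    stop_input("selected features must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(selected)
  rec <- purrr::pmap_dfr(
    list(terms$term_id, terms$term_name, terms$namespace, terms$members),
    function(id, nm, ns, members) {
      members <- intersect(members, universe)
      k <- length(intersect(members, selected))
      if (k == 0) return(NULL)
      K <- length(members)
      tibble(term_id = id, term_name = nm, namespace = ns,
             direction = direction_label, k = k, n = n, K = K, N = N,
             gene_ratio = k / n, p = hypergeom_upper(N, K, n, k))
    })
  if (!nrow(rec)) {
    return(tibble(term_id = character(), term_name = character(),
                  namespace = character(), direction = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  gene_ratio = numeric(), p = numeric(), p_adj = numeric()))
  }
  rec |>
    group_by(.data$namespace) |>
    mutate(p_adj = bh_adjust(.data$p)) |>
    ungroup() |>
    arrange(.data$namespace, .data$p, .data$term_id)
}

#' Top terms by gene ratio
#'
#' Within each namespace, ranks by gene ratio descending (ties: smaller p
#' first, then term id) and keeps the namespace's limit: by default the top
#' 10 per GO category and the top 20 pathways.
#'
#' @param records Tibble from [enrich_terms()].
#' @param limits Named integer vector of per-namespace limits.
#' @return The truncated tibble, ranked within namespace.
#' @export
top_terms <- function(records,
                      limits = c(BP = 10, MF = 10, CC = 10, pathway = 20)) {
  records |>
    arrange(.data$namespace, dplyr::desc(.data$gene_ratio), .data$p,
            .data$term_id) |>
    group_by(.data$namespace) |>
    mutate(.limit = unname(limits[.data$namespace])) |>
    filter(dplyr::row_number() <= .data$.limit) |>
    ungroup() |>
    select(-".limit")
}
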