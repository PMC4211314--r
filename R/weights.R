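#' Half-sigmoid link weight
#'
#' Maps an accumulated link count to a weight in `[0, 1)` through a rescaled
#' logistic, `phi(l) = 2 / (1 + exp(-l / C)) - 1`. A link that has never been
#' observed has weight 0, the weight grows strictly with the count, and 1 is
#' approached only in the limit of infinitely many co-occurrences. The slope
#' constant `C` stretches the curve: a larger `C` gives a smaller weight at
#' any fixed count, which delays saturation of frequently repeated links.
#'
#' @param count Non-negative accumulated co-occurrence count(s); vectorized.
#' @param C Positive slope constant (default 10).
#' @return Numeric vector of weights in `[0, 1)`.
#' @examples
#' link_weight(0)            # 0
#' link_weight(10, C = 10)   # 2 / (1 + exp(-1)) - 1
#' @export
link_weight <- function(count, C = 10) {
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C <= 0)
    stop("`C` must be a single positive number", call. = FALSE)
  if (!is.numeric(count) || any(is.na(count)) || any(count < 0))
    stop("`count` must be non-negative", call. = FALSE)
  2 / (1 + exp(-count / C)) - 1
}

#' Edge-capacity bound of an anchored hypernetwork
#'
#' Counts the position-anchored hyperedges of fixed order `k` that are
#' representable over given per-attribute alphabet sizes, together with the
#' size of the full instance space and their ratio. With ring anchoring there
#' is one contiguous edge window per attribute position (indices wrapping
#' modulo `d`), so the bound is `sum_t prod_{i=t}^{t+k-1} C_i`; a line
#' truncates the windows at the last position instead. In the uniform case
#' `C_i = C` the ring ratio collapses to `d * C^(k - d)`, which is below 1
#' whenever `k < d` and `C^(d-k) > d` — the regime in which the edge store
#' grows much more slowly than the instance space.
#'
#' @param category_counts Positive integer vector of per-attribute alphabet
#'   sizes (length `d`).
#' @param k Edge order, `1 <= k <= d`.
#' @param topology `"ring"` (default) or `"line"` anchoring.
#' @return A one-row tibble with columns `edge_bound`, `instance_count`, and
#'   `ratio = edge_bound / instance_count`.
#' @examples
#' capacity_bound(rep(3, 4), k = 2)   # 36 edges over 81 instances
#' @export
capacity_bound <- function(category_counts, k, topology = c("ring", "line")) {
  topology <- match.arg(topology)
  d <- length(category_counts)
  if (d < 1L || any(is.na(category_counts)) || any(category_counts < 1))
    stop("`category_counts` must be positive", call. = FALSE)
  if (length(k) != 1L || is.na(k) || k < 1 || k > d)
    stop("`k` must lie in [1, d]", call. = FALSE)
  cc <- as.numeric(category_counts)
  anchors <- if (topology == "ring") seq_len(d) else seq_len(d - k + 1L)
  edge_bound <- sum(vapply(anchors, function(t) {
    idx <- ((t - 1L + seq_len(k) - 1L) %% d) + 1L
    prod(cc[idx])
  }, numeric(1)))
  instance_count <- prod(cc)
  tibble::tibble(
    edge_bound = edge_bound,
    instance_count = instance_count,
    ratio = edge_bound / instance_count
  )
}
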