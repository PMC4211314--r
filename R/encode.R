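#' Sample anchored hyperedges from an instance
#'
#' Subsamples an event instance into position-anchored hyperedges under an
#' [edge_config()]. With a ring topology there is one edge per attribute
#' position, covering a window that wraps around the attribute circle; a
#' line stops at the last position a window fits into, giving `d - k + 1`
#' edges for fixed order `k`. Random modes re-draw the per-anchor order on
#' every call, so repeated calls on the same instance generally differ
#' unless the RNG seed is fixed.
#'
#' Missing values are carried through into the sampled edges (this is how
#' partial probes are built); [encode()] itself refuses incomplete
#' instances.
#'
#' @param instance Character vector of attribute values (`NA` = missing).
#' @param config An [edge_config()].
#' @param topology `"ring"` or `"line"`.
#' @return A tibble with one row per edge: `anchor` (1-based), `order`, and
#'   list-columns `attrs` (1-based attribute indices) and `values`.
#' @examples
#' sample_edges(c("1", "2", "3", "4"), edge_config("fixed", k = 2))
#' @export
sample_edges <- function(instance, config, topology = c("ring", "line")) {
  topology <- match.arg(topology)
  instance <- as.character(instance)
  d <- length(instance)
  validate_config(config, d)
  cc <- config_code(config)
  # stateless positional coding: edge values are read back off the instance
  codes <- ifelse(is.na(instance), NA_integer_, seq_len(d))
  es <- hn_sample_edges(codes, d, topology == "ring", cc[1], cc[2], cc[2], cc[3])
  tibble::tibble(
    anchor = vapply(es, function(e) e$anchor + 1L, integer(1)),
    order = vapply(es, function(e) length(e$attrs), integer(1)),
    attrs = lapply(es, function(e) e$attrs + 1L),
    values = lapply(es, function(e) instance[e$attrs + 1L])
  )
}

#' Encode events into a hypernetwork
#'
#' Runs the sampling–connecting–weighting cycle for each complete event, in
#' row order: the instance is subsampled into anchored hyperedges
#' (`config$repetitions` independent passes), new edges are deduplicated
#' against the store by identity (anchor, attribute set, values), and the
#' link count of every adjacent-anchor pair in the pass is incremented — the
#' link weight follows via [link_weight()]. The store only ever grows; there
#' is no decay or deletion, which is what makes the model's
#' no-false-negative guarantee exact.
#'
#' The network is modified in place (it is a reference object); the returned
#' report is per-event bookkeeping.
#'
#' @param network A [hypernetwork()].
#' @param events A data frame of complete events (one row each, no `NA`), or
#'   a single character vector of length `d`.
#' @param config An [edge_config()].
#' @return A tibble with one row per event: `new_edges`, `new_links`.
#' @examples
#' net <- hypernetwork(4)
#' encode(net, c("1", "2", "3", "4"), edge_config("fixed", k = 2))
#' @export
encode <- function(network, events, config) {
  stopifnot(inherits(network, "hypernetwork"))
  validate_config(config, network$d)
  if (!is.data.frame(events)) {
    m <- matrix(as_instance(network, events), nrow = 1L)
  } else {
    m <- instance_matrix(network, events)
  }
  if (anyNA(m))
    stop("cannot encode events with missing values", call. = FALSE)
  codes <- code_matrix(network, m, register = TRUE)
  cc <- config_code(config)
  n <- nrow(codes)
  new_edges <- integer(n)
  new_links <- integer(n)
  for (i in seq_len(n)) {
    rep_i <- hn_encode(network$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
                       config$repetitions)
    new_edges[i] <- rep_i$new_edges
    new_links[i] <- rep_i$new_links
  }
  tibble::tibble(new_edges = new_edges, new_links = new_links)
}
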