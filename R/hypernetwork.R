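#' Create an empty hypernetwork memory
#'
#' A hypernetwork is the layered store that accumulates position-anchored
#' hyperedges from encoded event instances, together with weighted links
#' between edges at adjacent anchors. It behaves like a reference object
#' (similar to an external model handle): [encode()] grows it in place,
#' while [judge()] and [complete_pattern()] are strictly read-only.
#'
#' @param attributes Either a character vector of attribute names (its length
#'   sets the dimension `d`) or a single integer `d` (names become
#'   `a1 ... ad`).
#' @param topology `"ring"` links the anchored edges into a closed cycle
#'   (contextual data with no serial order); `"line"` leaves an open chain
#'   (serial data). The choice fixes both how edges are anchored and which
#'   adjacent pairs are linked.
#' @param C Positive slope constant of the half-sigmoid [link_weight()].
#' @return An object of class `hypernetwork`.
#' @examples
#' net <- hypernetwork(c("time", "place", "person", "action"))
#' net
#' @export
hypernetwork <- function(attributes, topology = c("ring", "line"), C = 10) {
  topology <- match.arg(topology)
  if (is.numeric(attributes) && length(attributes) == 1L) {
    d <- as.integer(attributes)
    attributes <- paste0("a", seq_len(d))
  } else {
    attributes <- as.character(attributes)
    d <- length(attributes)
  }
  if (d < 2L) stop("a hypernetwork needs at least 2 attributes", call. = FALSE)
  if (anyDuplicated(attributes))
    stop("attribute names must be unique", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C <= 0)
    stop("`C` must be a single positive number", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$levels <- rep(list(character()), d)
  env$C <- C
  structure(
    list(ptr = hn_new(d, topology == "ring", C),
         d = d, attribute_names = attributes, topology = topology, env = env),
    class = "hypernetwork"
  )
}

#' @export
print.hypernetwork <- function(x, ...) {
  info <- hn_info(x$ptr)
  cat("<hypernetwork> d = ", x$d, " (", x$topology, "), C = ", x$env$C, "\n",
      "  edges: ", format(info$n_edges, big.mark = ","),
      "  links: ", format(info$n_links, big.mark = ","),
      "  encoded instances: ", format(info$n_encoded, big.mark = ","),
      "  connectivity: ", signif(connectivity(x), 4), "\n", sep = "")
  invisible(x)
}

#' Network connectivity
#'
#' Total number of links divided by the total number of edges — the density
#' proxy that drives the judgment/completion tradeoff. Defined as 0 for an
#' empty network.
#'
#' @param network A [hypernetwork()].
#' @return A single non-negative number.
#' @export
connectivity <- function(network) {
  stopifnot(inherits(network, "hypernetwork"))
  info <- hn_info(network$ptr)
  if (info$n_edges == 0) return(0)
  info$n_links / info$n_edges
}

#' @describeIn hypernetwork One row per stored hyperedge: `edge_id`, `anchor`
#'   (1-based), `order`, and list-columns `attrs` (1-based attribute indices)
#'   and `values` (decoded tokens).
#' @param x,network A `hypernetwork`.
#' @param ... Unused.
#' @method tidy hypernetwork
#' @export
tidy.hypernetwork <- function(x, ...) {
  dump <- hn_dump(x$ptr)
  ed <- dump$edges
  lv <- x$env$levels
  n <- length(ed$anchor)
  attrs <- lapply(ed$attrs, function(a) a + 1L)
  values <- vector("list", n)
  for (i in seq_len(n)) {
    a <- attrs[[i]]
    v <- ed$vals[[i]]
    values[[i]] <- vapply(seq_along(a), function(j) lv[[a[j]]][v[j]], character(1))
  }
  tibble::tibble(
    edge_id = seq_len(n),
    anchor = ed$anchor + 1L,
    order = ed$order,
    attrs = attrs,
    values = values
  )
}

#' @describeIn hypernetwork One-row summary: dimension, topology, `C`, edge,
#'   link and instance counts, and connectivity.
#' @method glance hypernetwork
#' @export
glance.hypernetwork <- function(x, ...) {
  info <- hn_info(x$ptr)
  tibble::tibble(
    d = x$d, topology = x$topology, C = x$env$C,
    n_edges = info$n_edges, n_links = info$n_links,
    n_encoded = info$n_encoded,
    connectivity = if (info$n_edges > 0) info$n_links / info$n_edges else 0
  )
}

#' Stored links of a hypernetwork
#'
#' @param network A [hypernetwork()].
#' @return A tibble with one row per stored link: `from` and `to` edge ids
#'   (matching `edge_id` in [tidy.hypernetwork()]), the accumulated `count`,
#'   and the derived `weight`.
#' @export
network_links <- function(network) {
  stopifnot(inherits(network, "hypernetwork"))
  dump <- hn_dump(network$ptr)
  lk <- dump$links
  out <- tibble::tibble(
    from = lk$from + 1L, to = lk$to + 1L, count = lk$count,
    weight = link_weight(lk$count, network$env$C)
  )
  dplyr::arrange(out, .data$from, .data$to)
}

#' Content digest of a hypernetwork
#'
#' An order-independent hash of the stored edges, link counts and instance
#' registry. Two networks with identical content give identical digests, and
#' read-only operations (judgment, completion) leave the digest unchanged.
#'
#' @param network A [hypernetwork()].
#' @return A 16-character hexadecimal string.
#' @export
network_digest <- function(network) {
  stopifnot(inherits(network, "hypernetwork"))
  hn_digest(network$ptr)
}

#' Exact-match registry lookup
#'
#' Reports whether a complete instance has previously been encoded into the
#' network. This is bookkeeping for ground truth in experiments; the
#' judgment mechanism itself never consults it.
#'
#' @param network A [hypernetwork()].
#' @param instance A complete instance (character vector of length `d`, or a
#'   one-row data frame).
#' @return `TRUE` or `FALSE`.
#' @export
was_encoded <- function(network, instance) {
  stopifnot(inherits(network, "hypernetwork"))
  v <- code_instance(network, as_instance(network, instance), register = FALSE)
  if (anyNA(v)) stop("instance has missing values", call. = FALSE)
  hn_has_instance(network$ptr, v)
}

# ---- internal: token coding -------------------------------------------

# Accept a character vector of length d or a 1-row data frame; returns the
# character vector in attribute order.
as_instance <- function(network, instance) {
  if (is.data.frame(instance)) {
    if (nrow(instance) != 1L) stop("expected a single instance", call. = FALSE)
    m <- instance_matrix(network, instance)
    return(m[1L, ])
  }
  instance <- as.character(instance)
  if (length(instance) != network$d)
    stop("instance length ", length(instance), " does not match d = ",
         network$d, call. = FALSE)
  instance
}

# Align a data frame of events to the network's attribute order; returns a
# character matrix (rows = events). Matches by name when all attribute
# columns are present, otherwise positionally (dot-prefixed metadata columns
# are dropped first).
instance_matrix <- function(network, data) {
  stopifnot(is.data.frame(data))
  nm <- network$attribute_names
  if (all(nm %in% names(data))) {
    data <- data[nm]
  } else {
    data <- data[!startsWith(names(data), ".")]
    if (ncol(data) != network$d)
      stop("event data has ", ncol(data), " attribute columns; expected ",
           network$d, call. = FALSE)
  }
  m <- as.matrix(data)
  mode(m) <- "character"
  m
}

# Integer codes for one instance; unseen tokens become -1 (never matching)
# unless register = TRUE, which appends them to the per-attribute alphabets.
code_instance <- function(network, values, register = FALSE) {
  lv <- network$env$levels
  out <- integer(network$d)
  for (i in seq_len(network$d)) {
    v <- values[i]
    if (is.na(v)) { out[i] <- NA_integer_; next }
    idx <- match(v, lv[[i]])
    if (is.na(idx)) {
      if (register) {
        lv[[i]] <- c(lv[[i]], v)
        idx <- length(lv[[i]])
      } else idx <- -1L
    }
    out[i] <- idx
  }
  if (register) network$env$levels <- lv
  out
}

# Code a whole character matrix at once. With register = TRUE, levels are
# assigned in order of first appearance (identical to row-by-row coding).
code_matrix <- function(network, m, register = FALSE) {
  lv <- network$env$levels
  out <- matrix(NA_integer_, nrow(m), ncol(m))
  for (i in seq_len(network$d)) {
    col <- m[, i]
    if (register) {
      new <- unique(col[!is.na(col) & !(col %in% lv[[i]])])
      lv[[i]] <- c(lv[[i]], new)
    }
    idx <- match(col, lv[[i]])
    idx[!is.na(col) & is.na(idx)] <- -1L
    out[, i] <- idx
  }
  if (register) network$env$levels <- lv
  out
}

# Decode an integer-coded matrix back to tokens.
decode_matrix <- function(network, m) {
  lv <- network$env$levels
  out <- matrix(NA_character_, nrow(m), ncol(m))
  for (i in seq_len(network$d)) out[, i] <- lv[[i]][m[, i]]
  colnames(out) <- network$attribute_names
  out
}
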