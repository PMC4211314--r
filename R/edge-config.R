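#' Hyperedge sampling configuration
#'
#' Describes how an event instance is subsampled into anchored hyperedges.
#' Three modes are supported:
#'
#' * `"fixed"` — every anchor draws a contiguous window of exactly `k`
#'   attributes (sampling is deterministic);
#' * `"random_order"` — each anchor independently draws its window length
#'   uniformly from `order_range = c(r1, r2)` on every sampling call, both
#'   when encoding and when probing;
#' * `"random_combination"` — the window length is drawn as in
#'   `random_order`, but instead of a contiguous window the edge holds the
#'   anchor attribute plus `k - 1` further attributes drawn uniformly
#'   without replacement.
#'
#' `repetitions` controls how many independent sampling passes one call to
#' [encode()] performs per instance (the "study duration" on the encoding
#' side); `observations` is the default number of repeated judgments used by
#' [judge()] (the retrieval side). Both default to 1.
#'
#' @param mode One of `"fixed"`, `"random_order"`, `"random_combination"`.
#' @param k Edge order for `"fixed"` mode, `2 <= k <= d - 1`.
#' @param order_range Integer pair `c(r1, r2)` for the random modes,
#'   `2 <= r1 <= r2 <= d - 1`.
#' @param repetitions Encoding passes per instance (>= 1).
#' @param observations Repeated judgments per probe (>= 1).
#' @return An object of class `edge_config`.
#' @examples
#' edge_config("fixed", k = 2)
#' edge_config("random_order", order_range = c(2, 5))
#' @export
edge_config <- function(mode = c("fixed", "random_order", "random_combination"),
                        k = NULL, order_range = NULL,
                        repetitions = 1L, observations = 1L) {
  mode <- match.arg(mode)
  repetitions <- as.integer(repetitions)
  observations <- as.integer(observations)
  if (is.na(repetitions) || repetitions < 1L)
    stop("`repetitions` must be a positive integer", call. = FALSE)
  if (is.na(observations) || observations < 1L)
    stop("`observations` must be a positive integer", call. = FALSE)
  if (mode == "fixed") {
    if (is.null(k) || length(k) != 1L || is.na(k))
      stop("fixed mode requires a single `k`", call. = FALSE)
    k <- as.integer(k)
    if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
    order_range <- c(k, k)
  } else {
    if (is.null(order_range) || length(order_range) != 2L || any(is.na(order_range)))
      stop("random modes require `order_range = c(r1, r2)`", call. = FALSE)
    order_range <- as.integer(order_range)
    if (order_range[1] < 2L || order_range[1] > order_range[2])
      stop("`order_range` must satisfy 2 <= r1 <= r2", call. = FALSE)
    k <- NULL
  }
  structure(
    list(mode = mode, k = k, order_range = order_range,
         repetitions = repetitions, observations = observations),
    class = "edge_config"
  )
}

#' @export
print.edge_config <- function(x, ...) {
  rng <- if (x$mode == "fixed") paste0("k = ", x$k)
         else paste0("orders ", x$order_range[1], "..", x$order_range[2])
  cat("<edge_config> ", x$mode, ", ", rng,
      ", repetitions = ", x$repetitions,
      ", observations = ", x$observations, "\n", sep = "")
  invisible(x)
}

# validate against a network dimension; returns the config unchanged
validate_config <- function(config, d) {
  if (!inherits(config, "edge_config"))
    stop("`config` must be created with edge_config()", call. = FALSE)
  r2 <- config$order_range[2]
  if (r2 > d - 1L)
    stop("edge order ", r2, " outside [2, d-1] for d = ", d, call. = FALSE)
  config
}

# integer triplet (mode, r1, r2) for the compiled core
config_code <- function(config) {
  mode <- match(config$mode, c("fixed", "random_order", "random_combination")) - 1L
  c(mode, config$order_range[1], config$order_range[2])
}
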