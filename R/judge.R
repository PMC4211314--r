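#' Old/new familiarity judgment
#'
#' Judges whether each complete probe is familiar to the memory. A probe is
#' subsampled into anchored hyperedges under `config` (random modes re-draw
#' the orders per observation), each probe edge activates the stored edges
#' at its anchor that share at least one value and conflict on none, and the
#' probe is judged *old* exactly when some selection of one activated edge
#' per anchor is connected by stored links into a full chain — closed
#' around the ring, or spanning the line. The attached similarity is the
#' weight-sum score: the sum of link weights along the best closed route
#' when old, and along the best open chain (unlinked adjacencies scoring
#' zero) otherwise.
#'
#' With `observations > 1` (or `config$observations > 1`) the judgment is
#' repeated and the verdicts are combined conservatively: the probe counts
#' as old only if *every* observation says old. A truly encoded probe is
#' always judged old under any edge configuration, so repeated observation
#' can only retract false alarms, never introduce misses.
#'
#' Judgment never mutates the network.
#'
#' @param network A [hypernetwork()].
#' @param probes Data frame of complete probes, or one character vector.
#' @param config An [edge_config()].
#' @param observations Repeated judgments per probe; defaults to
#'   `config$observations`.
#' @param n_m Activation match threshold: a stored edge activates only if
#'   strictly more than `n_m` of its values match the probe edge (default 0).
#' @param max_routes Cap on enumerated closed routes per observation; a
#'   warning-level `capped` flag is set when hit.
#' @return A tibble with one row per probe: `old` (logical), `verdict`
#'   (`"old"`/`"new"`), `similarity`, `n_routes`, `capped`.
#' @export
judge <- function(network, probes, config, observations = NULL, n_m = 0L,
                  max_routes = 10000L) {
  stopifnot(inherits(network, "hypernetwork"))
  validate_config(config, network$d)
  if (is.null(observations)) observations <- config$observations
  observations <- as.integer(observations)
  stopifnot(observations >= 1L)
  if (!is.data.frame(probes)) {
    m <- matrix(as_instance(network, probes), nrow = 1L)
  } else {
    m <- instance_matrix(network, probes)
  }
  if (anyNA(m))
    stop("probes contain missing values; use complete_pattern()", call. = FALSE)
  codes <- code_matrix(network, m, register = FALSE)
  cc <- config_code(config)
  n <- nrow(codes)
  old <- logical(n); sim <- numeric(n); nr <- numeric(n); capped <- logical(n)
  for (i in seq_len(n)) {
    o <- TRUE; s <- 0; routes <- 0; cp <- FALSE
    for (obs in seq_len(observations)) {
      r <- hn_judge(network$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
                    n_m, max_routes, FALSE)
      o <- o && r$old
      s <- max(s, r$similarity)
      routes <- max(routes, r$n_routes)
      cp <- cp || r$capped
    }
    old[i] <- o; sim[i] <- s; nr[i] <- routes; capped[i] <- cp
  }
  tibble::tibble(old = old, verdict = ifelse(old, "old", "new"),
                 similarity = sim, n_routes = nr, capped = capped)
}

#' Detailed single-probe judgment
#'
#' Like [judge()] for one probe, but additionally returns the activated
#' memory edges per anchor and the enumerated closed routes (up to 1000),
#' referencing `edge_id` in [tidy.hypernetwork()]. Probe edges may be
#' supplied explicitly (e.g. from [sample_edges()]); otherwise they are
#' sampled under `config`.
#'
#' @inheritParams judge
#' @param probe One complete or partial probe (character vector or one-row
#'   data frame).
#' @param probe_edges Optional tibble from [sample_edges()] to use instead
#'   of sampling internally.
#' @return A list with `old`, `similarity`, `n_routes`, `capped`,
#'   `activated` (list of integer edge-id vectors per probe edge) and
#'   `routes` (list of integer edge-id chains).
#' @export
judgment_details <- function(network, probe, config = NULL, probe_edges = NULL,
                             n_m = 0L, max_routes = 10000L) {
  stopifnot(inherits(network, "hypernetwork"))
  v <- code_instance(network, as_instance(network, probe), register = FALSE)
  if (is.null(probe_edges)) {
    if (is.null(config)) stop("supply `config` or `probe_edges`", call. = FALSE)
    validate_config(config, network$d)
    cc <- config_code(config)
    es <- hn_sample_edges(v, network$d, network$topology == "ring",
                          cc[1], cc[2], cc[2], cc[3])
  } else {
    es <- lapply(seq_len(nrow(probe_edges)), function(i) {
      attrs <- probe_edges$attrs[[i]] - 1L
      list(anchor = probe_edges$anchor[i] - 1L, attrs = attrs,
           vals = v[attrs + 1L])
    })
  }
  r <- hn_judge_edges(network$ptr, es, v, n_m, max_routes, TRUE)
  list(
    old = r$old,
    similarity = r$similarity,
    n_routes = r$n_routes,
    capped = r$capped,
    activated = lapply(r$activated, function(a) a + 1L),
    routes = lapply(r$routes, function(a) a + 1L)
  )
}

#' Pattern completion from partial probes
#'
#' Reconstructs complete instances consistent with a partial probe. The
#' probe (at least one observed and one missing attribute per row) is
#' subsampled into edges that carry their missing slots; activation uses the
#' partial-data rule (more than `n_m` matched values, none mismatched,
#' missing slots not compared), and every consistent fully linked route
#' through the activated edges yields a completion: the observed values plus
#' the values read off the selected memory edges. Selected edges must agree
#' with each other and with the probe on every attribute they cover.
#'
#' Two summary flags follow the completeness-versus-expectation distinction:
#' `complete` records whether any completion exists, and — when ground truth
#' is supplied — `expected` records whether the true original instance is
#' among the completions.
#'
#' @inheritParams judge
#' @param probes Data frame of partial probes (`NA` = missing), or one
#'   character vector with at least one `NA`.
#' @param truth Optional data frame (or single instance) of the original
#'   complete instances, row-aligned with `probes`.
#' @return A tibble with one row per probe: `complete`, `expected` (`NA`
#'   without truth), `n_completions`, `n_routes`, `capped`, and a
#'   list-column `completions` of character matrices (columns = attributes).
#' @export
complete_pattern <- function(network, probes, config, truth = NULL, n_m = 0L,
                             max_routes = 10000L) {
  stopifnot(inherits(network, "hypernetwork"))
  validate_config(config, network$d)
  if (!is.data.frame(probes)) {
    m <- matrix(as_instance(network, probes), nrow = 1L)
  } else {
    m <- instance_matrix(network, probes)
  }
  tm <- NULL
  if (!is.null(truth)) {
    tm <- if (is.data.frame(truth)) instance_matrix(network, truth)
          else matrix(as_instance(network, truth), nrow = 1L)
    if (nrow(tm) != nrow(m))
      stop("`truth` must align row-wise with `probes`", call. = FALSE)
  }
  codes <- code_matrix(network, m, register = FALSE)
  tcodes <- if (!is.null(tm)) code_matrix(network, tm, register = FALSE)
  cc <- config_code(config)
  n <- nrow(codes)
  complete <- logical(n); expected <- rep(NA, n)
  n_comp <- integer(n); nr <- numeric(n); capped <- logical(n)
  comps <- vector("list", n)
  for (i in seq_len(n)) {
    tv <- if (!is.null(tm)) tcodes[i, ] else NULL
    r <- hn_complete(network$ptr, codes[i, ], cc[1], cc[2], cc[2], cc[3],
                     n_m, max_routes, tv)
    complete[i] <- nrow(r$completions) > 0L
    if (!is.null(tm)) expected[i] <- r$expected
    n_comp[i] <- nrow(r$completions)
    nr[i] <- r$n_routes
    capped[i] <- r$capped
    comps[[i]] <- decode_matrix(network, r$completions)
  }
  tibble::tibble(complete = complete, expected = expected,
                 n_completions = n_comp, n_routes = nr, capped = capped,
                 completions = comps)
}
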