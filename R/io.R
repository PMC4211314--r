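#' Read an event stream from TSV/CSV
#'
#' One row per event, header row of attribute names; `"NA"` and empty
#' fields are parsed as missing. The delimiter is taken from the file
#' extension (`.csv` = comma, anything else = tab).
#'
#' @param path File path.
#' @return A tibble of character columns.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # parsing problems are escalated to errors below; silence readr's warning
  out <- suppressWarnings(readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), show_col_types = FALSE, progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0)
    stop("malformed stream file (", nrow(probs), " parsing problems, first: ",
         probs$expected[1], " / got ", probs$actual[1], ")", call. = FALSE)
  if (nrow(out) == 0L) stop("empty stream file", call. = FALSE)
  nm <- names(out)[!startsWith(names(out), ".")]
  if (anyDuplicated(nm)) stop("duplicate attribute names", call. = FALSE)
  out
}

#' Write an event stream to TSV/CSV
#'
#' Missing values are written as `"NA"`. When the stream carries a
#' generator spec (as produced by [generate_stream()]) and
#' `sidecar = TRUE`, a `<path>.json` sidecar with the spec and the section
#' start indices is written alongside.
#'
#' @param stream Data frame of events.
#' @param path Output path (`.csv` = comma-separated, else tab).
#' @param sidecar Write the spec sidecar if available.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, sidecar = TRUE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(stream, path, delim = delim, na = "NA", progress = FALSE)
  spec <- attr(stream, "spec")
  if (sidecar && !is.null(spec)) {
    meta <- unclass(spec)
    meta$section_starts <- attr(stream, "section_starts")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

HM_SCHEMA_VERSION <- 1L

#' Save a hypernetwork snapshot as JSON
#'
#' Writes a canonical JSON snapshot: edges in insertion order, links and the
#' instance registry sorted, link *counts* only (weights are derived state
#' and recomputed on load). Saving, loading and saving again is
#' byte-stable.
#'
#' @param network A [hypernetwork()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "hypernetwork"))
  dump <- hn_dump(network$ptr)
  lk <- dump$links
  ord <- order(lk$from, lk$to)
  insts <- dump$instances
  if (length(insts)) {
    ik <- vapply(insts, paste, character(1), collapse = ",")
    insts <- insts[order(ik)]
  }
  snap <- list(
    schema_version = HM_SCHEMA_VERSION,
    d = network$d,
    topology = network$topology,
    C = network$env$C,
    attribute_names = network$attribute_names,
    levels = network$env$levels,
    edges = list(anchor = dump$edges$anchor + 1L,
                 attrs = lapply(dump$edges$attrs, function(a) a + 1L),
                 vals = dump$edges$vals),
    links = list(from = lk$from[ord] + 1L, to = lk$to[ord] + 1L,
                 count = lk$count[ord]),
    instances = insts,
    n_encoded = dump$n_encoded
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a hypernetwork snapshot
#'
#' Reconstructs the store exactly (edges, link counts, instance registry);
#' link weights are recomputed from the counts under `C` — supplying a
#' different `C` than the saved one re-weights the whole network without
#' touching the counts.
#'
#' @param path Snapshot path written by [save_network()].
#' @param C Optional override of the sigmoid slope constant.
#' @return A [hypernetwork()].
#' @export
load_network <- function(path, C = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(snap$schema_version) || snap$schema_version != HM_SCHEMA_VERSION)
    stop("unsupported or missing snapshot schema version", call. = FALSE)
  d <- as.integer(snap$d)
  C_use <- if (is.null(C)) as.numeric(snap$C) else C
  net <- hypernetwork(as.character(snap$attribute_names),
                      topology = snap$topology, C = C_use)
  levels <- snap$levels
  if (is.matrix(levels)) levels <- lapply(seq_len(d), function(i) levels[i, ])
  net$env$levels <- lapply(levels, as.character)
  to_intlist <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) as.integer(x[i, ]))
    else lapply(x, as.integer)
  }
  edges <- list(anchor = as.integer(snap$edges$anchor) - 1L,
                attrs = lapply(to_intlist(snap$edges$attrs),
                               function(a) a - 1L),
                vals = to_intlist(snap$edges$vals))
  links <- list(from = as.integer(snap$links$from) - 1L,
                to = as.integer(snap$links$to) - 1L,
                count = as.integer(snap$links$count))
  insts <- if (length(snap$instances)) to_intlist(snap$instances) else list()
  net$ptr <- hn_restore(d, snap$topology == "ring", C_use, edges, links,
                        insts, as.numeric(snap$n_encoded))
  net
}

#' Read a run configuration (JSON)
#'
#' A run configuration mirrors [edge_config()] plus the network-level
#' parameters: fields `mode`, `k` or `order_range`, `repetitions`,
#' `observations`, `topology`, `C`, `n_m`, `seed` and any experiment
#' parameters (`section_size`, `n_missing`, `update_interval`, ...).
#'
#' @param path JSON file path.
#' @return A list with `config` (an [edge_config()]) and the remaining
#'   fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mode <- raw$mode %||% "fixed"
  config <- if (mode == "fixed") {
    edge_config("fixed", k = raw$k %||% 2,
                repetitions = raw$repetitions %||% 1,
                observations = raw$observations %||% 1)
  } else {
    edge_config(mode, order_range = raw$order_range %||% c(2, 3),
                repetitions = raw$repetitions %||% 1,
                observations = raw$observations %||% 1)
  }
  list(config = config,
       topology = raw$topology %||% "ring",
       C = raw$C %||% 10,
       n_m = raw$n_m %||% 0,
       seed = raw$seed %||% 1,
       extra = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
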