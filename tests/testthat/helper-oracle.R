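# Independent pure-R reference implementations used as oracles. They work
# only from the public tabular views (tidy(), network_links()) and never
# touch the compiled route search.

# Brute-force old/new verdict: enumerate ALL selections of one admissible
# memory edge per probe-edge anchor and test that consecutive selections
# (plus the wrap pair on a ring) are connected by stored links.
oracle_judge <- function(net, probe, probe_edges) {
  edges <- tidy(net)
  links <- network_links(net)
  lset <- paste(links$from, links$to)
  pv <- as.character(probe)
  A <- lapply(seq_len(nrow(probe_edges)), function(i) {
    pa <- probe_edges$attrs[[i]]
    obs <- !is.na(pv[pa])
    cand <- edges[edges$anchor == probe_edges$anchor[i], , drop = FALSE]
    if (!any(obs)) return(cand$edge_id)  # evidence-free anchor
    keep <- vapply(seq_len(nrow(cand)), function(j) {
      ma <- cand$attrs[[j]]
      mv <- cand$values[[j]]
      shared <- intersect(ma, pa[obs])
      if (length(shared) == 0L) return(FALSE)
      all(mv[match(shared, ma)] == pv[shared])
    }, logical(1))
    cand$edge_id[keep]
  })
  sizes <- vapply(A, length, integer(1))
  if (any(sizes == 0L)) return(FALSE)
  sel <- as.matrix(expand.grid(A, KEEP.OUT.ATTRS = FALSE))
  n_anchor <- ncol(sel)
  ring <- net$topology == "ring"
  for (r in seq_len(nrow(sel))) {
    ids <- sel[r, ]
    from <- ids[seq_len(n_anchor - 1L)]
    to <- ids[seq_len(n_anchor - 1L) + 1L]
    if (ring) {
      from <- c(from, ids[n_anchor])
      to <- c(to, ids[1L])
    }
    if (all(paste(from, to) %in% lset)) return(TRUE)
  }
  FALSE
}

# O(n^2) pairwise exact-match reference for old/new ground truth.
oracle_truth_labels <- function(stream) {
  m <- as.matrix(stream[!startsWith(names(stream), ".")])
  n <- nrow(m)
  out <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (all(m[i, ] == m[j, ])) { out[i] <- TRUE; break }
    }
  }
  out
}

# Random complete instances as a character tibble, tokens "v1".."valphabet".
random_instances <- function(n, d, alphabet = 3) {
  m <- matrix(paste0("v", sample.int(alphabet, n * d, replace = TRUE)), n, d)
  colnames(m) <- paste0("a", seq_len(d))
  tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
}

# Small default-shaped stream for experiment tests.
small_stream <- function(n, seed, ...) {
  generate_stream(stream_spec(n = n, seed = seed, ...))
}
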