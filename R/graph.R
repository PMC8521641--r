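# Bidirected sparse de Bruijn graph. Nodes are 128-bit hashes of canonical
# minimizer k-mers; an edge is added whenever two minimizers are adjacent in
# a read, with HPC-space overlap k - (pos_to - pos_from). Each edge and its
# mirror (reverse both endpoints, swap direction) are one object, stored
# under the lexicographically smaller of the two keys; overlap is part of the
# key, so distinct overlaps between the same oriented pair are distinct
# edges. Construction accumulates per-read chains and aggregates once, so
# the finished graph is invariant under read input order and strand.

orient_digit <- function(fwd) ifelse(fwd, "0", "1")

#' Create a graph builder
#'
#' @param k K-mer size in HPC bases, >= 2.
#' @param w Window size, `1 <= w <= k - 1`.
#' @return A mutable builder environment; feed it with [thread_chain()] or
#'   [dbg_add_read()] and turn it into a graph with [dbg_finalize()].
#' @export
dbg_new <- function(k, w) {
  k <- as.integer(k)
  w <- as.integer(w)
  if (k < 2L) stop("k must be >= 2")
  if (w < 1L || w > k - 1L) stop("w must satisfy 1 <= w <= k - 1")
  b <- new.env(parent = emptyenv())
  b$k <- k
  b$w <- w
  b$chains <- list()
  b$runs <- list()
  b$n_reads <- 0L
  b$n_skipped <- 0L
  b$hpc_bases <- 0
  class(b) <- "sdbg_builder"
  b
}

#' Thread one minimizer chain into the graph builder
#'
#' Each selected k-mer inserts-or-updates its node (coverage +1, run lengths
#' at its k offsets added to the node's tallies, offsets mirrored when the
#' observed orientation is not the canonical one), and each consecutive chain
#' pair adds one bidirected edge with overlap `k - (pos_to - pos_from)` and
#' coverage +1, oriented so the edge spells the read. Updates become visible
#' in the graph returned by [dbg_finalize()].
#'
#' @param builder From [dbg_new()].
#' @param chain A `minimizer_chain` from [select_minimizers()].
#' @param hpc The `hpc_seq` the chain was selected from.
#' @return The builder, invisibly.
#' @export
thread_chain <- function(builder, chain, hpc) {
  stopifnot(inherits(builder, "sdbg_builder"),
            inherits(chain, "minimizer_chain"))
  builder$hpc_bases <- builder$hpc_bases + length(hpc$run_lengths)
  if (length(chain$positions) == 0L) {
    builder$n_skipped <- builder$n_skipped + 1L
    return(invisible(builder))
  }
  i <- builder$n_reads + 1L
  builder$chains[[i]] <- chain
  builder$runs[[i]] <- hpc$run_lengths
  builder$n_reads <- i
  invisible(builder)
}

#' Compress, winnow and thread one read
#'
#' @param builder From [dbg_new()].
#' @param sequence Read sequence (A/C/G/T). Reads whose HPC form is shorter
#'   than `k` contribute nothing.
#' @param read_id Optional identifier.
#' @return The builder, invisibly.
#' @export
dbg_add_read <- function(builder, sequence, read_id = NULL) {
  h <- hpc_compress(sequence, origin = read_id)
  ch <- select_minimizers(h, builder$k, builder$w)
  thread_chain(builder, ch, h)
}

#' Finalize a builder into a sparse de Bruijn graph
#'
#' Aggregates all threaded chains into the node, edge and run-length tally
#' stores. Node ids are assigned in sorted hash order, so the result is
#' independent of read order.
#'
#' @param builder From [dbg_new()].
#' @param min_node_cov,min_edge_cov Coverage pre-filters applied by
#'   [drop_low_coverage()]; the defaults of 1 keep everything.
#' @return An object of class `sparse_dbg`: list with `k`, `w`, `nodes`
#'   (data.table: `id`, `hash`, `kmer`, `coverage`), `edges` (data.table:
#'   `eid`, `from`, `from_fwd`, `to`, `to_fwd`, `overlap`, `coverage`) and
#'   `tallies` (data.table: `node`, `offset` 0-based canonical, `runlen`,
#'   `n`).
#' @export
dbg_finalize <- function(builder, min_node_cov = 1L, min_edge_cov = 1L) {
  stopifnot(inherits(builder, "sdbg_builder"))
  chains <- builder$chains
  if (length(chains) == 0L) stop("no usable reads: every read was shorter than k in HPC space")
  k <- builder$k

  occ <- data.table::rbindlist(lapply(chains, function(ch) {
    data.table::data.table(hash = ch$hash, kmer = ch$kmer)
  }))
  nodes <- occ[, .(coverage = .N, kmer = kmer[1L]), by = hash]
  data.table::setorder(nodes, hash)
  nodes[, id := .I]
  data.table::setcolorder(nodes, c("id", "hash", "kmer", "coverage"))

  # edges from consecutive chain pairs, canonicalized with their mirrors
  epl <- lapply(chains, function(ch) {
    m <- length(ch$positions)
    if (m < 2L) return(NULL)
    i <- seq_len(m - 1L)
    ov <- k - diff(ch$positions)
    if (any(ov < 1L)) stop("internal error: non-positive edge overlap")
    data.table::data.table(h1 = ch$hash[i], f1 = ch$forward[i],
                           h2 = ch$hash[i + 1L], f2 = ch$forward[i + 1L],
                           overlap = ov)
  })
  eraw <- data.table::rbindlist(epl)
  if (nrow(eraw) > 0L) {
    eraw[, key1 := paste0(h1, orient_digit(f1), h2, orient_digit(f2))]
    eraw[, key2 := paste0(h2, orient_digit(!f2), h1, orient_digit(!f1))]
    swap <- eraw$key2 < eraw$key1
    ecan <- data.table::data.table(
      fh = ifelse(swap, eraw$h2, eraw$h1),
      ff = ifelse(swap, !eraw$f2, eraw$f1),
      th = ifelse(swap, eraw$h1, eraw$h2),
      tf = ifelse(swap, !eraw$f1, eraw$f2),
      overlap = eraw$overlap)
    edges <- ecan[, .(coverage = .N), by = .(fh, ff, th, tf, overlap)]
    edges[, from := nodes[match(edges$fh, nodes$hash), id]]
    edges[, to := nodes[match(edges$th, nodes$hash), id]]
    edges <- edges[, .(from, from_fwd = ff, to, to_fwd = tf, overlap, coverage)]
    data.table::setorder(edges, from, from_fwd, to, to_fwd, overlap)
    edges[, eid := .I]
    data.table::setcolorder(edges, c("eid", "from", "from_fwd", "to",
                                     "to_fwd", "overlap", "coverage"))
  } else {
    edges <- data.table::data.table(eid = integer(0), from = integer(0),
                                    from_fwd = logical(0), to = integer(0),
                                    to_fwd = logical(0), overlap = integer(0),
                                    coverage = integer(0))
  }

  # run-length tallies per node offset, in canonical orientation
  off <- 0:(k - 1L)
  tpl <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    rl <- builder$runs[[i]]
    m <- length(ch$positions)
    offv <- rep(off, times = m)
    shift <- ifelse(rep(ch$forward, each = k), offv, k - 1L - offv)
    data.table::data.table(
      node = rep(nodes[match(ch$hash, nodes$hash), id], each = k),
      offset = offv,
      runlen = pmin(rl[rep(ch$positions, each = k) + shift + 1L], 255L))
  })
  tallies <- data.table::rbindlist(tpl)[, .(n = .N), by = .(node, offset, runlen)]
  data.table::setorder(tallies, node, offset, runlen)

  g <- structure(list(k = k, w = builder$w, nodes = nodes, edges = edges,
                      tallies = tallies),
                 class = "sparse_dbg")
  drop_low_coverage(g, min_node_cov, min_edge_cov)
}

#' Build a sparse de Bruijn graph from sequences
#'
#' Convenience wrapper: compresses, winnows and threads every sequence, then
#' finalizes.
#'
#' @param sequences Character vector of read sequences (A/C/G/T).
#' @param k,w Graph parameters, see [select_minimizers()].
#' @param min_node_cov,min_edge_cov Passed to [dbg_finalize()].
#' @return A `sparse_dbg` object.
#' @export
dbg_build <- function(sequences, k, w, min_node_cov = 1L, min_edge_cov = 1L) {
  b <- dbg_new(k, w)
  for (i in seq_along(sequences)) dbg_add_read(b, sequences[[i]], read_id = i)
  dbg_finalize(b, min_node_cov, min_edge_cov)
}

#' @export
print.sparse_dbg <- function(x, ...) {
  cat(sprintf("sparse de Bruijn graph: k=%d w=%d, %d nodes, %d edges\n",
              x$k, x$w, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Oriented arc table: every stored edge in both traversal directions.
# Mirror-identical arcs (hairpin edges) are deduplicated so degrees count
# traversal options, not storage artifacts.
dbg_arcs <- function(g) {
  e <- g$edges
  a <- data.table::rbindlist(list(
    e[, .(u = from, uo = from_fwd, v = to, vo = to_fwd, ov = overlap,
          cov = coverage, eid)],
    e[, .(u = to, uo = !to_fwd, v = from, vo = !from_fwd, ov = overlap,
          cov = coverage, eid)]))
  unique(a, by = c("u", "uo", "v", "vo", "ov", "eid"))
}

#' Remove error-induced transitive edges
#'
#' A read that loses one minimizer occurrence to a sequencing error connects
#' the two flanking minimizers directly, creating a low-coverage edge that
#' bypasses a well-covered two-edge path. An edge `e = u -> v` is removed iff
#' (a) some oriented 2-path `u -> m -> v` (not using `e` itself) has both leg
#' coverages >= `coverage(e)`, and (b) `coverage(e) <=
#' max(1, floor(t * min(leg coverages)))` for the detour maximizing that
#' minimum. The relative threshold keeps genuine repeat-induced triangles,
#' whose direct edge is as well covered as the detour. All removals are
#' decided against the pre-cleaning graph in one simultaneous pass.
#'
#' @param g A `sparse_dbg`.
#' @param t Relative coverage fraction in (0, 1], default 0.25.
#' @return List with `graph` (cleaned) and `removed` (edge count).
#' @export
clean_transitive_edges <- function(g, t = 0.25) {
  stopifnot(inherits(g, "sparse_dbg"), t > 0, t <= 1)
  if (nrow(g$edges) == 0L) return(list(graph = g, removed = 0L))
  A <- dbg_arcs(g)
  a1 <- A[, .(u, uo, mid = v, mo = vo, c1 = cov, e1 = eid)]
  a2 <- A[, .(mid = u, mo = uo, v, vo, c2 = cov, e2 = eid)]
  two <- merge(a1, a2, by = c("mid", "mo"), allow.cartesian = TRUE)
  if (nrow(two) == 0L) return(list(graph = g, removed = 0L))
  cand <- merge(A[, .(u, uo, v, vo, cov, eid)],
                two[, .(u, uo, v, vo, c1, c2, e1, e2)],
                by = c("u", "uo", "v", "vo"), allow.cartesian = TRUE)
  cand <- cand[e1 != eid & e2 != eid & c1 >= cov & c2 >= cov]
  if (nrow(cand) == 0L) return(list(graph = g, removed = 0L))
  best <- cand[, .(best = max(pmin(c1, c2)), cov = cov[1L]), by = eid]
  rm_ids <- unique(best[cov <= pmax(1L, as.integer(floor(t * best))), eid])
  g$edges <- g$edges[!eid %in% rm_ids]
  list(graph = g, removed = length(rm_ids))
}

#' Drop low-coverage nodes and edges
#'
#' Optional pre-filter: nodes below `min_node_cov` are removed together with
#' their incident edges, then edges below `min_edge_cov` are removed. The
#' defaults of 1 keep everything (the method itself has no abundance filter).
#'
#' @param g A `sparse_dbg`.
#' @param min_node_cov,min_edge_cov Integer thresholds >= 1.
#' @return The filtered graph.
#' @export
drop_low_coverage <- function(g, min_node_cov = 1L, min_edge_cov = 1L) {
  stopifnot(min_node_cov >= 1L, min_edge_cov >= 1L)
  if (min_node_cov > 1L) {
    keep <- g$nodes[coverage >= min_node_cov, id]
    g$nodes <- g$nodes[id %in% keep]
    g$edges <- g$edges[from %in% keep & to %in% keep]
    g$tallies <- g$tallies[node %in% keep]
  }
  if (min_edge_cov > 1L) g$edges <- g$edges[coverage >= min_edge_cov]
  g
}

#' Order- and strand-invariant structural summary of a graph
#'
#' Maps internal ids back to hashes and sorts, producing a representation
#' that is identical for graphs built from the same reads in any order or
#' orientation. Useful for comparing graphs.
#'
#' @param g A `sparse_dbg`.
#' @param coverage Include coverage columns (set `FALSE` for purely
#'   topological comparison).
#' @return List of two data.tables, `nodes` and `edges`.
#' @export
graph_signature <- function(g, coverage = TRUE) {
  nodes <- g$nodes[, .(hash, coverage)]
  data.table::setorder(nodes, hash)
  edges <- g$edges[, .(
    from_hash = g$nodes[match(from, g$nodes$id), hash],
    from_or = ifelse(from_fwd, "+", "-"),
    to_hash = g$nodes[match(to, g$nodes$id), hash],
    to_or = ifelse(to_fwd, "+", "-"),
    overlap, coverage)]
  data.table::setorder(edges, from_hash, from_or, to_hash, to_or, overlap)
  if (!coverage) {
    nodes[, coverage := NULL]
    edges[, coverage := NULL]
  }
  list(nodes = nodes[], edges = edges[])
}
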