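# Unitig condensation: maximal non-branching oriented paths of the bidirected
# graph, spelled in HPC space and expanded to base space by per-position
# run-length consensus over the pooled tallies of their constituent nodes.

okey <- function(id, fwd) paste0(id, ifelse(fwd, "+", "-"))

node_hash <- function(g, ids) g$nodes[match(ids, g$nodes$id), hash]
node_kmer <- function(g, ids) g$nodes[match(ids, g$nodes$id), kmer]

oriented_kmer <- function(g, id, fwd) {
  km <- node_kmer(g, id)
  if (fwd) km else cpp_revcomp(km)
}

# ov_after: overlap following each node (length m-1 linear, m circular where
# the last entry closes the cycle).
flip_path <- function(p) {
  m <- length(p$ids)
  ids <- rev(p$ids)
  fwds <- rev(!p$fwds)
  if (p$circular) {
    ov <- if (m > 1L) c(rev(p$ov_after[seq_len(m - 1L)]), p$ov_after[m]) else p$ov_after
  } else {
    ov <- rev(p$ov_after)
  }
  list(ids = ids, fwds = fwds, ov_after = ov, circular = p$circular)
}

rotate_path <- function(p, r) {
  if (r == 1L) return(p)
  m <- length(p$ids)
  idx <- c(r:m, seq_len(r - 1L))
  list(ids = p$ids[idx], fwds = p$fwds[idx], ov_after = p$ov_after[idx],
       circular = p$circular)
}

spell_path <- function(g, p) {
  k <- g$k
  m <- length(p$ids)
  s <- oriented_kmer(g, p$ids[1L], p$fwds[1L])
  if (m > 1L) {
    for (j in 2:m) {
      ov <- p$ov_after[j - 1L]
      nxt <- oriented_kmer(g, p$ids[j], p$fwds[j])
      if (substr(s, nchar(s) - ov + 1L, nchar(s)) != substr(nxt, 1L, ov))
        stop("internal error: overlap mismatch while spelling unitig")
      s <- paste0(s, substr(nxt, ov + 1L, k))
    }
  }
  if (p$circular) {
    closing <- p$ov_after[m]
    L <- nchar(s) - closing
    if (closing > 0L &&
        substr(s, L + 1L, L + closing) != substr(s, 1L, closing))
      stop("internal error: closing overlap mismatch on circular unitig")
    s <- substr(s, 1L, L)
  }
  s
}

# Pool node tallies onto unitig positions. Overlap positions receive the
# tallies of every node covering them; circular coordinates wrap.
pool_tallies <- function(g, p, L) {
  k <- g$k
  m <- length(p$ids)
  between <- if (p$circular) {
    if (m > 1L) p$ov_after[seq_len(m - 1L)] else integer(0)
  } else p$ov_after
  starts <- c(0L, cumsum(k - between))
  map <- data.table::data.table(node = p$ids, fwd = p$fwds, start = starts)
  tt <- merge(map, g$tallies, by = "node", allow.cartesian = TRUE)
  tt[, upos := ifelse(fwd, start + offset, start + (k - 1L) - offset)]
  if (p$circular) tt[, upos := upos %% L]
  pooled <- tt[, .(n = sum(n)), by = .(upos, runlen)]
  data.table::setorder(pooled, upos, runlen)
  pooled[]
}

make_unitig <- function(g, p) {
  # canonical orientation: circular paths start at the smallest constituent
  # hash in forward orientation; linear paths keep the lexicographically
  # smaller of the two spellings.
  if (p$circular) {
    hashes <- node_hash(g, p$ids)
    j <- order(hashes, method = "radix")[1L]
    if (!p$fwds[j]) {
      p <- flip_path(p)
      j <- order(node_hash(g, p$ids), method = "radix")[1L]
    }
    p <- rotate_path(p, j)
    s <- spell_path(g, p)
  } else {
    s <- spell_path(g, p)
    rc <- cpp_revcomp(s)
    if (rc < s) {
      p <- flip_path(p)
      s <- rc
      stopifnot(identical(spell_path(g, p), s))
    }
  }
  L <- nchar(s)
  pooled <- pool_tallies(g, p, L)
  cons <- consensus_table(pooled, "upos")
  if (nrow(cons) != L)
    stop("internal error: tally pooling left unitig positions uncovered")
  data.table::setorder(cons, upos)
  runs <- cons$runlen
  structure(list(
    name = NA_character_,
    path = data.table::data.table(id = p$ids, fwd = p$fwds),
    ov_after = p$ov_after,
    circular = p$circular,
    closing_overlap = if (p$circular) p$ov_after[length(p$ov_after)] else 0L,
    hpc_seq = s,
    tallies = pooled,
    runs = runs,
    seq = cpp_hpc_expand(s, runs),
    avg_coverage = mean(g$nodes[match(p$ids, g$nodes$id), coverage])),
    class = "sdbg_unitig")
}

#' Condense a graph into unitigs
#'
#' Partitions the nodes into maximal non-branching oriented paths. A path
#' extends through a junction iff the junction has exactly one outgoing edge
#' and its successor exactly one incoming edge (in the bidirected sense);
#' parallel edges with different overlaps count separately. An isolated,
#' everywhere-non-branching cycle becomes one circular unitig, broken at its
#' smallest node hash in forward orientation. Each unitig is spelled in HPC
#' space, its constituent node tallies are pooled per position (overlap
#' positions pool both adjacent nodes), and base-space sequence is restored
#' by per-position run-length consensus. Circular unitigs are spelled as
#' exactly one traversal of the cycle (the closing overlap is not repeated).
#'
#' Unitigs are returned sorted (longest expanded sequence first; ties by
#' sequence, then by first node hash) and named `utg0000001`, `utg0000002`,
#' ... so output is deterministic for a given graph.
#'
#' @param g A cleaned `sparse_dbg`.
#' @return List of `sdbg_unitig` objects, each with elements `name`, `path`
#'   (node ids + orientations), `circular`, `hpc_seq`, `runs` (consensus run
#'   length per HPC position), `seq` (expanded base-space sequence),
#'   `tallies` and `avg_coverage`.
#' @export
condense_unitigs <- function(g) {
  stopifnot(inherits(g, "sparse_dbg"))
  arcs <- dbg_arcs(g)
  outidx <- if (nrow(arcs) > 0L) {
    split(seq_len(nrow(arcs)), paste0(arcs$u, ifelse(arcs$uo, "+", "-")))
  } else list()
  outdeg <- function(id, fwd) {
    ix <- outidx[[okey(id, fwd)]]
    if (is.null(ix)) 0L else length(ix)
  }
  nvisited <- max(g$nodes$id)
  visited <- rep(FALSE, nvisited)
  order_ids <- g$nodes[order(hash), id]
  unitigs <- list()

  walk <- function(start_id, start_fwd, stop_at_start) {
    ids <- integer(0); fwds <- logical(0); ovs <- integer(0)
    circular <- FALSE
    cur_id <- start_id; cur_f <- start_fwd
    repeat {
      ix <- outidx[[okey(cur_id, cur_f)]]
      if (is.null(ix) || length(ix) != 1L) break
      a <- arcs[ix]
      if (outdeg(a$v, !a$vo) != 1L) break
      if (a$v == start_id && a$vo == stop_at_start) {
        circular <- TRUE
        ovs <- c(ovs, a$ov)
        break
      }
      if (visited[a$v]) break
      ids <- c(ids, a$v); fwds <- c(fwds, a$vo); ovs <- c(ovs, a$ov)
      visited[a$v] <<- TRUE
      cur_id <- a$v; cur_f <- a$vo
    }
    list(ids = ids, fwds = fwds, ovs = ovs, circular = circular)
  }

  for (nid in order_ids) {
    if (visited[nid]) next
    visited[nid] <- TRUE
    fw <- walk(nid, TRUE, stop_at_start = TRUE)
    if (fw$circular) {
      p <- list(ids = c(nid, fw$ids), fwds = c(TRUE, fw$fwds),
                ov_after = fw$ovs, circular = TRUE)
    } else {
      bw <- walk(nid, FALSE, stop_at_start = FALSE)
      p <- list(ids = c(rev(bw$ids), nid, fw$ids),
                fwds = c(rev(!bw$fwds), TRUE, fw$fwds),
                ov_after = c(rev(bw$ovs), fw$ovs),
                circular = FALSE)
    }
    unitigs[[length(unitigs) + 1L]] <- make_unitig(g, p)
  }

  lens <- vapply(unitigs, function(u) nchar(u$seq), 0)
  seqs <- vapply(unitigs, function(u) u$hpc_seq, "")
  first_hash <- vapply(unitigs, function(u) node_hash(g, u$path$id[1L]), "")
  o <- order(-lens, seqs, first_hash)
  unitigs <- unitigs[o]
  for (i in seq_along(unitigs)) unitigs[[i]]$name <- sprintf("utg%07d", i)
  unitigs
}

#' Assembly statistics of a unitig set
#'
#' Lengths are measured on expanded (base-space) sequences. N50 is the length
#' at which the running sum of descending-sorted lengths first reaches half
#' the total.
#'
#' @param unitigs List of `sdbg_unitig` from [condense_unitigs()].
#' @return List with `count`, `total_length` and `n50` (all in bp).
#' @export
assembly_stats <- function(unitigs) {
  if (length(unitigs) == 0L) stop("assembly_stats: no unitigs")
  lens <- sort(vapply(unitigs, function(u) nchar(u$seq), 0), decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1L]]
  list(count = length(lens), total_length = total, n50 = n50)
}
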