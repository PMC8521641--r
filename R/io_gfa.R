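# GFA 1.0 output: one S record per unitig (expanded sequence plus a dp:f:
# average read coverage tag) and one L record per bidirected link between
# unitig-terminal nodes, with the overlap as a single match operation in
# expanded coordinates. Records are sorted so output is byte-stable across
# runs and read orderings.

oriented_runs <- function(u, sign) if (sign == "+") u$runs else rev(u$runs)
oriented_seq <- function(u, sign) if (sign == "+") u$seq else cpp_revcomp(u$seq)

#' Derive links between unitigs from graph edges
#'
#' Every remaining graph edge joins terminal nodes of (possibly the same)
#' unitigs; each such edge becomes one bidirected link, reported once with
#' its mirror suppressed. The link overlap is converted from HPC space to
#' expanded bases by summing the source unitig's consensus run lengths over
#' the overlapping positions; the target side is validated to spell the same
#' bases. If the two sides disagree (possible when sequencing errors leave
#' conflicting tallies at a junction), the overlap is shrunk to the longest
#' length over which suffix and prefix agree, with a warning. The closing
#' link of a circular unitig gets overlap 0, since its segment already
#' represents exactly one traversal of the cycle.
#'
#' @param g The cleaned `sparse_dbg` the unitigs were condensed from.
#' @param unitigs List of `sdbg_unitig` from [condense_unitigs()].
#' @return data.table with columns `from`, `from_or`, `to`, `to_or`,
#'   `overlap_hpc`, `overlap_exp`.
#' @export
unitig_links <- function(g, unitigs) {
  by_name <- stats::setNames(unitigs, vapply(unitigs, `[[`, "", "name"))
  startmap <- new.env(parent = emptyenv())
  endmap <- new.env(parent = emptyenv())
  for (u in unitigs) {
    m <- nrow(u$path)
    id1 <- u$path$id[1L]; f1 <- u$path$fwd[1L]
    idm <- u$path$id[m]; fm <- u$path$fwd[m]
    startmap[[okey(id1, f1)]] <- c(u$name, "+")
    endmap[[okey(idm, fm)]] <- c(u$name, "+")
    startmap[[okey(idm, !fm)]] <- c(u$name, "-")
    endmap[[okey(id1, !f1)]] <- c(u$name, "-")
  }
  arcs <- dbg_arcs(g)
  rows <- list()
  for (i in seq_len(nrow(arcs))) {
    a <- arcs[i]
    src <- endmap[[okey(a$u, a$uo)]]
    dst <- startmap[[okey(a$v, a$vo)]]
    if (is.null(src) || is.null(dst)) next
    rows[[length(rows) + 1L]] <-
      data.table::data.table(from = src[1L], from_or = src[2L],
                             to = dst[1L], to_or = dst[2L],
                             overlap_hpc = a$ov)
  }
  if (length(rows) == 0L)
    return(data.table::data.table(from = character(0), from_or = character(0),
                                  to = character(0), to_or = character(0),
                                  overlap_hpc = integer(0),
                                  overlap_exp = integer(0)))
  lk <- data.table::rbindlist(rows)
  # suppress mirrors: keep the lexicographically smaller representation
  # (orientations encoded as digits so comparison is locale-independent)
  flip <- function(x) ifelse(x == "+", "-", "+")
  odig <- function(x) ifelse(x == "+", "0", "1")
  lk[, key1 := paste(from, odig(from_or), to, odig(to_or), overlap_hpc)]
  lk[, key2 := paste(to, odig(flip(to_or)), from, odig(flip(from_or)), overlap_hpc)]
  swap <- lk$key2 < lk$key1
  lk <- data.table::data.table(
    from = ifelse(swap, lk$to, lk$from),
    from_or = ifelse(swap, flip(lk$to_or), lk$from_or),
    to = ifelse(swap, lk$from, lk$to),
    to_or = ifelse(swap, flip(lk$from_or), lk$to_or),
    overlap_hpc = lk$overlap_hpc)
  lk <- unique(lk)

  lk[, overlap_exp := NA_integer_]
  for (i in seq_len(nrow(lk))) {
    ua <- by_name[[lk$from[i]]]
    ub <- by_name[[lk$to[i]]]
    if (identical(lk$from[i], lk$to[i]) &&
        identical(lk$from_or[i], lk$to_or[i]) && ua$circular) {
      lk$overlap_exp[i] <- 0L
      next
    }
    ov <- lk$overlap_hpc[i]
    ra <- oriented_runs(ua, lk$from_or[i])
    rb <- oriented_runs(ub, lk$to_or[i])
    n1 <- sum(utils::tail(ra, ov))
    n2 <- sum(utils::head(rb, ov))
    sa <- oriented_seq(ua, lk$from_or[i])
    sb <- oriented_seq(ub, lk$to_or[i])
    n <- if (n1 == n2 &&
             substr(sa, nchar(sa) - n1 + 1L, nchar(sa)) == substr(sb, 1L, n1)) {
      n1
    } else {
      l <- min(n1, n2, nchar(sa), nchar(sb))
      while (l > 0L &&
             substr(sa, nchar(sa) - l + 1L, nchar(sa)) != substr(sb, 1L, l)) {
        l <- l - 1L
      }
      warning("link ", lk$from[i], lk$from_or[i], " -> ", lk$to[i],
              lk$to_or[i], ": expanded overlap disagrees between sides, ",
              "shrunk to ", l, " bases")
      l
    }
    lk$overlap_exp[i] <- as.integer(n)
  }
  data.table::setorder(lk, from, from_or, to, to_or, overlap_exp)
  lk[]
}

#' Write unitigs and links as GFA 1.0
#'
#' Emits an `H VN:Z:1.0` header, one `S` line per unitig carrying the
#' expanded sequence and an average read coverage tag (`dp:f:`, two decimal
#' places), and one `L` line per link with the overlap CIGAR `<n>M` in
#' expanded bases. Segments are sorted by name and links lexicographically,
#' so the file is byte-identical across runs and input read orderings. Every
#' link's suffix/prefix agreement is validated before writing.
#'
#' @param unitigs List of `sdbg_unitig` from [condense_unitigs()].
#' @param links data.table from [unitig_links()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gfa <- function(unitigs, links, path) {
  names_u <- vapply(unitigs, `[[`, "", "name")
  by_name <- stats::setNames(unitigs, names_u)
  s_lines <- vapply(unitigs[order(names_u)], function(u) {
    sprintf("S\t%s\t%s\tdp:f:%.2f", u$name, u$seq, u$avg_coverage)
  }, "")
  l_lines <- character(0)
  if (nrow(links) > 0L) {
    if (!all(links$from %in% names_u) || !all(links$to %in% names_u))
      stop("write_gfa: link references unknown segment")
    for (i in seq_len(nrow(links))) {
      n <- links$overlap_exp[i]
      sa <- oriented_seq(by_name[[links$from[i]]], links$from_or[i])
      sb <- oriented_seq(by_name[[links$to[i]]], links$to_or[i])
      if (n > 0L &&
          substr(sa, nchar(sa) - n + 1L, nchar(sa)) != substr(sb, 1L, n))
        stop("write_gfa: link overlap does not spell identically from both sides")
      l_lines[[length(l_lines) + 1L]] <-
        sprintf("L\t%s\t%s\t%s\t%s\t%dM", links$from[i], links$from_or[i],
                links$to[i], links$to_or[i], n)
    }
    l_lines <- sort(l_lines, method = "radix")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), con, sep = "\n")
  invisible(path)
}

#' Write unitig sequences as FASTA contigs
#'
#' One record per unitig, named exactly like the GFA segments, with sequence
#' lines wrapped at 80 columns.
#'
#' @inheritParams write_gfa
#' @return Invisibly, `path`.
#' @export
write_fasta_contigs <- function(unitigs, path) {
  names_u <- vapply(unitigs, `[[`, "", "name")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (u in unitigs[order(names_u)]) {
    writeLines(paste0(">", u$name), con)
    s <- u$seq
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}
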