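# FASTA/FASTQ input. Streaming, connection-based: memory is bounded by the
# line-buffer chunk plus one record, never by file size, so arbitrarily large
# read sets can be threaded through the graph builder. gzip input is handled
# transparently by gzfile(). FASTQ records are the standard 4-line form.

IUPAC_TO_N <- "RYSWKMBDHVryswkmbdhv"

normalize_seq <- function(s) {
  s <- toupper(s)
  s <- chartr(IUPAC_TO_N, strrep("N", nchar(IUPAC_TO_N)), s)
  s
}

# Split a normalized sequence at N runs into maximal N-free segments.
split_at_n <- function(s) {
  if (!grepl("N", s, fixed = TRUE)) return(s)
  segs <- strsplit(s, "N+")[[1]]
  segs[nzchar(segs)]
}

detect_format <- function(con, path) {
  first <- ""
  while (TRUE) {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("empty input file: ", path)
    if (nzchar(trimws(ln))) {
      first <- trimws(ln)
      break
    }
  }
  c1 <- substr(first, 1L, 1L)
  fmt <- if (c1 == ">") "fasta" else if (c1 == "@") "fastq" else
    stop("cannot detect FASTA/FASTQ format of ", path,
         " (first record starts with '", c1, "')")
  list(format = fmt, first_line = first)
}

#' Stream normalized reads from FASTA/FASTQ files
#'
#' Reads each file record by record (plain or gzip-compressed; format
#' auto-detected from the first record character), normalizes sequences, and
#' calls `callback` once per emitted record. Normalization: sequences are
#' uppercased (soft-masking is ignored), IUPAC ambiguity codes other than N
#' become N, and each read is split at N runs so that every maximal N-free
#' segment becomes its own record (ids of split reads get `/1`, `/2`, ...
#' suffixes). Quality strings are discarded. Duplicate ids are disambiguated
#' by appending `_<source_index>`.
#'
#' @param paths Character vector of file paths, streamed in order.
#' @param callback Function called as `callback(record)` with a list carrying
#'   `read_id`, `sequence` (non-empty, A/C/G/T only) and `source_index`
#'   (0-based ordinal of the emitted record across all files).
#' @return Invisibly, the number of records emitted.
#' @export
stream_reads <- function(paths, callback) {
  emitted <- 0L
  seen <- new.env(parent = emptyenv())
  emit <- function(id, seq) {
    seq <- normalize_seq(seq)
    if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
    segs <- split_at_n(seq)
    had_n <- grepl("N", seq, fixed = TRUE)
    for (i in seq_along(segs)) {
      rid <- if (had_n) paste0(id, "/", i) else id
      if (!is.null(seen[[rid]])) rid <- paste0(rid, "_", emitted)
      seen[[rid]] <- TRUE
      callback(list(read_id = rid, sequence = segs[[i]],
                    source_index = emitted))
      emitted <<- emitted + 1L
    }
  }
  for (path in paths) {
    if (!file.exists(path)) stop("input file does not exist: ", path)
    stream_one_file(path, emit)
  }
  invisible(emitted)
}

stream_one_file <- function(path, emit) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  fmt <- detect_format(con, path)
  if (fmt$format == "fasta") {
    cur_id <- sub("^>", "", fmt$first_line)
    cur_id <- sub("\\s.*$", "", cur_id)
    buf <- character(0)
    repeat {
      lines <- readLines(con, n = 10000L)
      if (length(lines) == 0L) break
      for (ln in lines) {
        if (startsWith(ln, ">")) {
          emit(cur_id, paste(buf, collapse = ""))
          cur_id <- sub("\\s.*$", "", sub("^>", "", ln))
          buf <- character(0)
        } else if (nzchar(trimws(ln))) {
          buf[[length(buf) + 1L]] <- trimws(ln)
        }
      }
    }
    emit(cur_id, paste(buf, collapse = ""))
  } else {
    lineno <- 1L
    hdr <- fmt$first_line
    repeat {
      block <- readLines(con, n = 3L)
      if (length(block) < 3L)
        stop("truncated FASTQ record '", hdr, "' at line ", lineno,
             " of ", path)
      seq <- trimws(block[[1L]])
      plus <- block[[2L]]
      qual <- trimws(block[[3L]])
      if (!startsWith(plus, "+"))
        stop("malformed FASTQ record '", hdr, "' at line ", lineno + 2L,
             " of ", path, ": expected '+' separator")
      if (nchar(qual) != nchar(seq))
        stop("FASTQ length mismatch for record '", hdr, "' at line ",
             lineno + 3L, " of ", path)
      id <- sub("\\s.*$", "", sub("^@", "", hdr))
      emit(id, seq)
      nxt <- readLines(con, n = 1L)
      if (length(nxt) == 0L) break
      if (!startsWith(nxt, "@"))
        stop("malformed FASTQ header at line ", lineno + 4L, " of ", path)
      hdr <- nxt
      lineno <- lineno + 4L
    }
  }
  invisible(NULL)
}

#' Read all sequences from FASTA/FASTQ files into a data frame
#'
#' Convenience wrapper around [stream_reads()] collecting every record.
#'
#' @inheritParams stream_reads
#' @return `data.frame` with columns `read_id`, `sequence`, `source_index`.
#' @export
read_seqs <- function(paths) {
  acc <- vector("list", 256L)
  i <- 0L
  stream_reads(paths, function(rec) {
    i <<- i + 1L
    if (i > length(acc)) acc[[2L * i]] <<- NULL  # grow
    acc[[i]] <<- rec
  })
  acc <- acc[seq_len(i)]
  data.frame(read_id = vapply(acc, `[[`, "", "read_id"),
             sequence = vapply(acc, `[[`, "", "sequence"),
             source_index = vapply(acc, `[[`, 0L, "source_index"),
             stringsAsFactors = FALSE)
}
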