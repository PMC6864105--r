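# Strict text-format readers/writers for the pipeline's three dialects:
# multi-record FASTA, 12-column BLAST tabular (outfmt 6, no header), and
# 4-column BedGraph (no track lines). Parsers are total: every input row
# maps to one record or one error carrying its line/row number.

.FASTA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on ingest and validated against the alphabet
#' `A,C,G,T,N`. Record ids (first whitespace-delimited token of the header)
#' must be unique and non-empty; every record must carry at least one base.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`, one row
#'   per record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 a contig", "acgt", ">c2", "GGNN"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(path))
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("FASTA format error at line ", lineno[1L],
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  ids <- character(0)
  descs <- character(0)
  seqs <- character(0)
  header_lines <- integer(0)
  rec <- 0L
  chunks <- list()
  for (i in seq_along(lines)) {
    if (is_header[i]) {
      header <- sub("^>", "", lines[i])
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) {
        stop("FASTA format error at line ", lineno[i],
             ": header has an empty id", call. = FALSE)
      }
      desc <- sub("^\\S*\\s*", "", header)
      rec <- rec + 1L
      ids[rec] <- id
      descs[rec] <- desc
      header_lines[rec] <- lineno[i]
      chunks[[rec]] <- character(0)
    } else {
      sq <- toupper(gsub("\\s", "", lines[i]))
      bad <- setdiff(unique(strsplit(sq, "", fixed = TRUE)[[1L]]),
                     .FASTA_ALPHABET)
      if (length(bad)) {
        stop("FASTA format error at line ", lineno[i],
             ": invalid sequence character(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      chunks[[rec]] <- c(chunks[[rec]], sq)
    }
  }
  seqs <- vapply(chunks, paste, character(1L), collapse = "")
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA format error at line ", header_lines[which(empty)[1L]],
         ": record '", ids[which(empty)[1L]], "' has an empty sequence",
         call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("FASTA format error: duplicate record id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, description = descs, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description` (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", header[i]), con)
    sq <- records$sequence[i]
    starts <- seq(1L, nchar(sq), by = width)
    writeLines(substring(sq, starts, pmin(starts + width - 1L, nchar(sq))), con)
  }
  invisible(path)
}

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read 12-column tabular alignments (BLAST outfmt 6 dialect)
#'
#' Each row must have exactly 12 tab-separated fields. Subject coordinates
#' are kept exactly as given (`sstart > send` denotes a minus-strand match);
#' use [subject_ranges()] for the normalized 0-based half-open view.
#'
#' @param path Path to a headerless tab-separated alignment file.
#' @return A data frame with the standard columns `qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.empty_alignments())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("alignment format error at row ", bad, ": expected 12 columns, got ",
         nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  bad_pid <- which(is.na(out$pident) | out$pident < 0 | out$pident > 100)
  if (length(bad_pid)) {
    stop("alignment format error at row ", bad_pid[1L],
         ": pident must lie in [0, 100]", call. = FALSE)
  }
  bad_len <- which(is.na(out$length) | out$length < 1L)
  if (length(bad_len)) {
    stop("alignment format error at row ", bad_len[1L],
         ": aligned length must be >= 1", call. = FALSE)
  }
  bad_coord <- which(out$qstart < 1L | out$qend < 1L |
                       out$sstart < 1L | out$send < 1L)
  if (length(bad_coord)) {
    stop("alignment format error at row ", bad_coord[1L],
         ": coordinates must be >= 1", call. = FALSE)
  }
  out
}

#' Write tabular alignments in the outfmt-6 dialect
#'
#' @param alignments Data frame with the 12 standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(alignments, path) {
  stopifnot(all(.BLAST_COLS %in% names(alignments)))
  df <- alignments[, .BLAST_COLS]
  df$pident <- .fmt_num(df$pident)
  df$evalue <- .fmt_num(df$evalue, sci_ok = TRUE)
  df$bitscore <- .fmt_num(df$bitscore)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalized subject intervals of tabular alignments
#'
#' Converts BLAST's 1-based inclusive subject coordinates (where
#' `sstart > send` marks the minus strand) into the single internal
#' convention: 0-based half-open intervals plus an explicit strand flag.
#'
#' @param alignments Data frame as from [read_blast_tab()].
#' @return A data frame with columns `contig`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`"+"`/`"-"`), one row per alignment.
#' @examples
#' aln <- data.frame(sseqid = "c1", sstart = 300, send = 201)
#' subject_ranges(aln)  # [200, 300) on the minus strand
#' @export
subject_ranges <- function(alignments) {
  data.frame(
    contig = alignments$sseqid,
    start = pmin(alignments$sstart, alignments$send) - 1L,
    end = pmax(alignments$sstart, alignments$send),
    strand = ifelse(alignments$send >= alignments$sstart, "+", "-"),
    stringsAsFactors = FALSE
  )
}

#' Read a 4-column BedGraph file
#'
#' Intervals are 0-based half-open. Per contig they must be sorted and
#' non-overlapping (the dialect emitted by `genomecov -bga`).
#'
#' @param path Path to a BedGraph file without track lines.
#' @return Data frame with columns `contig`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) {
    stop("BedGraph file not found: ", path, call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), depth = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1L]
    stop("BedGraph format error at row ", bad, ": expected 4 columns, got ",
         nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  out <- data.frame(contig = m[, 1L], start = as.integer(m[, 2L]),
                    end = as.integer(m[, 3L]), depth = as.numeric(m[, 4L]),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0L |
                 out$start >= out$end)
  if (length(bad)) {
    stop("BedGraph format error at row ", bad[1L],
         ": start must be >= 0 and < end", call. = FALSE)
  }
  if (any(is.na(out$depth) | out$depth < 0)) {
    bad <- which(is.na(out$depth) | out$depth < 0)[1L]
    stop("BedGraph format error at row ", bad,
         ": depth must be a number >= 0", call. = FALSE)
  }
  for (ctg in unique(out$contig)) {
    sel <- out[out$contig == ctg, , drop = FALSE]
    if (nrow(sel) > 1L && any(sel$start[-1L] < sel$end[-nrow(sel)])) {
      stop("BedGraph format error: intervals for contig '", ctg,
           "' overlap or are unsorted", call. = FALSE)
    }
  }
  out
}

#' Write depth intervals as BedGraph
#'
#' Writes the canonical dialect read back by [read_bedgraph()]; a
#' write/read/write cycle is byte-identical.
#'
#' @param tracks Data frame with columns `contig`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(tracks)))
  lines <- paste(tracks$contig, tracks$start, tracks$end,
                 .fmt_num(tracks$depth), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' The simulator does not model base qualities, so a constant quality
#' character is emitted.
#'
#' @param reads Data frame with columns `read_id` and `sequence`.
#' @param path Output path.
#' @param qual Single quality character recycled over each read.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  quals <- vapply(nchar(reads$sequence),
                  function(n) strrep(qual, n), character(1L))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", quals)), path)
  invisible(path)
}

.empty_alignments <- function() {
  data.frame(qseqid = character(), sseqid = character(),
             pident = numeric(), length = integer(),
             mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

# Stable plain-decimal formatting so numeric round-trips are byte-identical.
.fmt_num <- function(x, sci_ok = FALSE) {
  if (sci_ok) {
    return(vapply(x, function(v) format(v, trim = TRUE), character(1L)))
  }
  vapply(x, function(v) {
    format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  }, character(1L))
}
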