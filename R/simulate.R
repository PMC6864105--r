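# Synthetic community generator with complete ground truth: reference
# genomes, sister clades at chosen divergence, shotgun reads with lineage
# substitutions and sequencing error, a truth-based gapless aligner, and
# marker-gene hit extraction. The mutation model has no indels, so the truth
# aligner is exact and identities are Hamming-based.

.BASE_RAW <- charToRaw("ACGT")
.BASE_CODE <- local({
  m <- rep(NA_integer_, 256L)
  m[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  m[as.integer(charToRaw("acgt")) + 1L] <- 0:3
  m
})

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Substitute each A/C/G/T byte with probability `rate`, uniformly over the
# three alternatives; returns the mutated raw vector.
.mutate_raw <- function(r, rate) {
  if (rate <= 0) return(r)
  hit <- which(runif(length(r)) < rate)
  if (!length(hit)) return(r)
  code <- .BASE_CODE[as.integer(r[hit]) + 1L]
  ok <- !is.na(code)
  hit <- hit[ok]
  code <- code[ok]
  if (!length(hit)) return(r)
  newcode <- (code + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  r[hit] <- .BASE_RAW[newcode + 1L]
  r
}

#' Generate a random genome sequence
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`, emitted as a single contig.
#'
#' @param length Genome length in bp (>= 10000).
#' @param gc GC content as a fraction in (0, 1).
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @param id Contig/genome identifier.
#' @return A one-row genome data frame (`id`, `description`, `sequence`).
#' @export
sim_genome <- function(length, gc = 0.5, seed = NULL, id = "genome") {
  if (length < 10000) stop("genome length must be >= 10000 bp", call. = FALSE)
  if (!(gc > 0 && gc < 1)) stop("gc must lie in (0, 1)", call. = FALSE)
  with_seed(seed, {
    at <- (1 - gc) / 2
    idx <- sample.int(4L, length, replace = TRUE,
                      prob = c(at, gc / 2, gc / 2, at))
    data.frame(id = id, description = "synthetic genome",
               sequence = rawToChar(.BASE_RAW[idx]),
               stringsAsFactors = FALSE)
  })
}

#' Derive a relative genome at a chosen divergence
#'
#' Substitutes each base independently with probability `divergence`,
#' uniformly over the three alternatives (Jukes-Cantor-like, no indels), to
#' create sister clades at a target ANI of roughly `100 * (1 - divergence)`.
#' N bases are left untouched.
#'
#' @param genome Genome data frame.
#' @param divergence Per-base substitution probability in (0, 0.3).
#' @param seed Optional RNG seed.
#' @param id Identifier of the derived genome.
#' @return A genome data frame with the same contig structure and lengths.
#' @export
sim_relative <- function(genome, divergence, seed = NULL,
                         id = paste0(genome$id[1L], "_rel")) {
  if (!(divergence >= 0 && divergence < 0.3)) {
    stop("divergence must lie in [0, 0.3)", call. = FALSE)
  }
  with_seed(seed, {
    out <- genome
    out$sequence <- vapply(genome$sequence, function(sq) {
      rawToChar(.mutate_raw(charToRaw(sq), divergence))
    }, character(1L), USE.NAMES = FALSE)
    out$id <- if (nrow(out) == 1L) id else paste0(id, "_", seq_len(nrow(out)))
    out$description <- paste0("derived at divergence ", divergence)
    out
  })
}

#' Fragment a single-contig genome into several contigs
#'
#' Splits the sequence at uniformly random internal boundaries; total length
#' and base content are preserved. Used to exercise multi-contig depth and
#' TAD behaviour.
#'
#' @param genome One-row genome data frame.
#' @param n_contigs Number of contigs to produce.
#' @param seed Optional RNG seed.
#' @return A genome data frame with `n_contigs` rows (`<id>_c1`, ...).
#' @export
fragment_genome <- function(genome, n_contigs, seed = NULL) {
  stopifnot(nrow(genome) == 1L, n_contigs >= 1L)
  L <- nchar(genome$sequence)
  if (n_contigs > L) stop("more contigs than bases", call. = FALSE)
  with_seed(seed, {
    cuts <- sort(sample.int(L - 1L, n_contigs - 1L))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    data.frame(id = paste0(genome$id, "_c", seq_len(n_contigs)),
               description = genome$description,
               sequence = substring(genome$sequence, starts, ends),
               stringsAsFactors = FALSE)
  })
}

#' Build a synthetic community with ground truth
#'
#' Takes a population specification and materializes one reference genome per
#' population (independent random genomes, or sister clades derived from
#' another population at a stated divergence) plus a single-copy marker locus
#' of fixed length placed uniformly at random within each genome — the
#' stand-in for a universal rpoB-style gene.
#'
#' @param spec Data frame with one row per population and columns: `id`,
#'   `genome_length` (bp), `gc` (fraction), `abundance` (fractions summing to
#'   1), `divergence` (intra-population per-base substitution probability,
#'   <= 0.02); optional `marker_length` (default 4000 bp), `parent` (id of
#'   the population this genome is derived from; `NA` for independent) and
#'   `parent_divergence` (divergence from the parent genome).
#' @param seed Optional RNG seed.
#' @return A `community`: list with `populations` (the spec plus marker
#'   coordinates `marker_start`/`marker_end`, 1-based inclusive, and the
#'   contig id) and `genomes` (named list of genome data frames).
#' @export
sim_community <- function(spec, seed = NULL) {
  stopifnot(is.data.frame(spec),
            all(c("id", "genome_length", "gc", "abundance", "divergence")
                %in% names(spec)))
  if (abs(sum(spec$abundance) - 1) > 1e-8) {
    stop("population abundances must sum to 1", call. = FALSE)
  }
  if (any(spec$divergence < 0 | spec$divergence > 0.02)) {
    stop("intra-population divergence must lie in [0, 0.02]", call. = FALSE)
  }
  if (anyDuplicated(spec$id)) {
    stop("population ids must be unique", call. = FALSE)
  }
  if (is.null(spec$marker_length)) spec$marker_length <- 4000L
  if (is.null(spec$parent)) spec$parent <- NA_character_
  if (is.null(spec$parent_divergence)) spec$parent_divergence <- NA_real_
  with_seed(seed, {
    genomes <- list()
    indep <- which(is.na(spec$parent))
    for (i in indep) {
      genomes[[spec$id[i]]] <- sim_genome(spec$genome_length[i], spec$gc[i],
                                          id = spec$id[i])
    }
    derived <- which(!is.na(spec$parent))
    for (i in derived) {
      parent <- spec$parent[i]
      if (is.null(genomes[[parent]])) {
        stop("population '", spec$id[i], "' derives from unknown parent '",
             parent, "'", call. = FALSE)
      }
      genomes[[spec$id[i]]] <- sim_relative(genomes[[parent]],
                                            spec$parent_divergence[i],
                                            id = spec$id[i])
    }
    spec$contig <- spec$id
    spec$marker_start <- vapply(seq_len(nrow(spec)), function(i) {
      sample.int(spec$genome_length[i] - spec$marker_length[i] + 1L, 1L)
    }, integer(1L))
    spec$marker_end <- spec$marker_start + spec$marker_length - 1L
    structure(list(populations = spec, genomes = genomes),
              class = "community")
  })
}

#' Simulate shotgun reads from a community
#'
#' Read counts per population are multinomial with weights proportional to
#' `abundance * genome_length`; origins are uniform; each read first receives
#' lineage substitutions at its population's intra-population divergence
#' (delta), then sequencing errors at `error_rate` (epsilon). The expected
#' read identity against the population reference is approximately
#' `100 * (1 - delta - epsilon)`.
#'
#' @param community A [sim_community()] object.
#' @param n_reads Total number of reads.
#' @param read_length Read length in bp.
#' @param error_rate Per-base sequencing error probability.
#' @param seed Optional RNG seed.
#' @return A `sim_reads` object: list with `reads` (data frame `read_id`,
#'   `population`, `sequence`), `truth` (per-read provenance: `read_id`,
#'   `population`, `contig`, `start`, `end` 1-based inclusive, `mismatches`
#'   vs the population reference), `community`, `read_length`, `error_rate`.
#' @export
sim_reads <- function(community, n_reads, read_length = 150L,
                      error_rate = 0.001, seed = NULL) {
  stopifnot(inherits(community, "community"), n_reads >= 1L)
  pops <- community$populations
  if (any(pops$genome_length < read_length)) {
    stop("read length exceeds a genome length", call. = FALSE)
  }
  with_seed(seed, {
    w <- pops$abundance * pops$genome_length
    counts <- as.vector(rmultinom(1L, n_reads, w))
    reads <- vector("list", nrow(pops))
    truth <- vector("list", nrow(pops))
    for (i in seq_len(nrow(pops))) {
      n <- counts[i]
      if (n == 0L) next
      refseq <- community$genomes[[pops$id[i]]]$sequence
      L <- pops$genome_length[i]
      starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
      ends <- starts + read_length - 1L
      orig <- charToRaw(paste(substring(refseq, starts, ends), collapse = ""))
      mut <- .mutate_raw(orig, pops$divergence[i])
      mut <- .mutate_raw(mut, error_rate)
      diff_idx <- which(mut != orig)
      mism <- tabulate((diff_idx - 1L) %/% read_length + 1L, nbins = n)
      big <- rawToChar(mut)
      off <- (seq_len(n) - 1L) * read_length
      seqs <- substring(big, off + 1L, off + read_length)
      ids <- sprintf("%s.r%06d", pops$id[i], seq_len(n))
      reads[[i]] <- data.frame(read_id = ids, population = pops$id[i],
                               sequence = seqs, stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(read_id = ids, population = pops$id[i],
                               contig = pops$contig[i], start = starts,
                               end = ends, mismatches = mism,
                               stringsAsFactors = FALSE)
    }
    structure(list(reads = do.call(rbind, reads),
                   truth = do.call(rbind, truth),
                   community = community,
                   read_length = as.integer(read_length),
                   error_rate = error_rate),
              class = "sim_reads")
  })
}

#' Truth-based gapless alignment of simulated reads
#'
#' Emits one gapless alignment per read at its true origin, against the
#' population's own reference or, for cross-recruitment experiments, against
#' a sister population's genome (same coordinates: derived genomes are
#' colinear with their parent). Percent identity is computed by direct
#' base-by-base comparison, so the output is exact rather than
#' heuristic-mapper dependent, while staying in the 12-column tabular
#' dialect.
#'
#' @param sim A [sim_reads()] object.
#' @param reference_map Optional named character vector mapping population id
#'   to the id of the genome its reads should be aligned against; defaults to
#'   each population's own genome.
#' @return A tabular alignment data frame (see [read_blast_tab()]).
#' @export
truth_align <- function(sim, reference_map = NULL) {
  stopifnot(inherits(sim, "sim_reads"))
  pops <- sim$community$populations
  rl <- sim$read_length
  out <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    pop <- pops$id[i]
    target <- if (!is.null(reference_map) && pop %in% names(reference_map)) {
      reference_map[[pop]]
    } else {
      pop
    }
    ref <- sim$community$genomes[[target]]
    if (is.null(ref)) {
      stop("reference genome '", target, "' not found for population '",
           pop, "'", call. = FALSE)
    }
    sel <- sim$truth$population == pop
    if (!any(sel)) next
    tr <- sim$truth[sel, , drop = FALSE]
    if (any(tr$end > nchar(ref$sequence[1L]))) {
      stop("read origin exceeds reference '", target, "' bounds",
           call. = FALSE)
    }
    refraw <- charToRaw(paste(substring(ref$sequence[1L], tr$start, tr$end),
                              collapse = ""))
    rdraw <- charToRaw(paste(sim$reads$sequence[sel], collapse = ""))
    diff_idx <- which(refraw != rdraw)
    mism <- tabulate((diff_idx - 1L) %/% rl + 1L, nbins = nrow(tr))
    matches <- rl - mism
    out[[i]] <- data.frame(
      qseqid = tr$read_id, sseqid = ref$id[1L],
      pident = round(100 * matches / rl, 4),
      length = rl, mismatch = mism, gapopen = 0L,
      qstart = 1L, qend = rl, sstart = tr$start, send = tr$end,
      evalue = 0, bitscore = round(2 * matches, 1),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Extract marker-gene hits from simulated reads
#'
#' Returns exactly the reads whose true origin interval overlaps their
#' population's marker locus, re-expressed as alignments to the pooled
#' marker references (`<population>_marker`, one per population). The
#' reported aligned interval is clipped to the read/locus overlap, so summed
#' aligned bases estimate marker depth without edge inflation. This mirrors
#' an upstream classifier that has already isolated bona fide marker reads.
#'
#' @param sim A [sim_reads()] object.
#' @return A tabular alignment data frame with attribute `reference_lengths`
#'   (named marker gene lengths, bp).
#' @export
emit_marker_hits <- function(sim) {
  stopifnot(inherits(sim, "sim_reads"))
  pops <- sim$community$populations
  rl <- sim$read_length
  out <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    pop <- pops$id[i]
    ms <- pops$marker_start[i]
    me <- pops$marker_end[i]
    if (is.na(ms)) next
    sel <- which(sim$truth$population == pop &
                   sim$truth$start <= me & sim$truth$end >= ms)
    if (!length(sel)) next
    tr <- sim$truth[sel, , drop = FALSE]
    os <- pmax(tr$start, ms)
    oe <- pmin(tr$end, me)
    refseq <- sim$community$genomes[[pop]]$sequence[1L]
    olen <- oe - os + 1L
    qs <- os - tr$start + 1L
    qe <- oe - tr$start + 1L
    refraw <- charToRaw(paste(substring(refseq, os, oe), collapse = ""))
    rdraw <- charToRaw(paste(substring(sim$reads$sequence[sel], qs, qe),
                             collapse = ""))
    grp <- rep(seq_along(sel), times = olen)
    mism <- tabulate(grp[refraw != rdraw], nbins = length(sel))
    matches <- olen - mism
    out[[i]] <- data.frame(
      qseqid = tr$read_id, sseqid = paste0(pop, "_marker"),
      pident = round(100 * matches / olen, 4),
      length = olen, mismatch = mism, gapopen = 0L,
      qstart = qs, qend = qe,
      sstart = os - ms + 1L, send = oe - ms + 1L,
      evalue = 0, bitscore = round(2 * matches, 1),
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- .empty_alignments()
  attr(hits, "reference_lengths") <- setNames(pops$marker_length, pops$id)
  hits
}
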