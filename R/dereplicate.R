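# Genome quality scoring, MinHash ANI estimation, and greedy dereplication
# at an ANI threshold with best-representative selection.

#' Genome quality score from completeness and contamination
#'
#' `completeness - 4 * contamination`: the score used to admit genome bins
#' into dereplication (bins scoring at least 50 pass the standard filter,
#' boundary included).
#'
#' @param completeness Completeness percent in `[0, 100]`.
#' @param contamination Contamination percent, >= 0.
#' @return Numeric score(s); at most `completeness`.
#' @examples
#' quality_score(88.5, 3.8)  # 73.3
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness must lie in [0, 100]", call. = FALSE)
  }
  if (any(contamination < 0)) {
    stop("contamination must be >= 0", call. = FALSE)
  }
  completeness - 4 * contamination
}

#' Filter genome bins by quality score
#'
#' @param qualities Data frame with columns `completeness` and
#'   `contamination` (and any id columns, preserved).
#' @param min_score Inclusive minimum score (default 50).
#' @return The rows whose [quality_score()] is `>= min_score`, in input
#'   order, with a `score` column appended.
#' @export
quality_filter <- function(qualities, min_score = 50) {
  stopifnot(is.data.frame(qualities),
            all(c("completeness", "contamination") %in% names(qualities)))
  score <- quality_score(qualities$completeness, qualities$contamination)
  out <- qualities
  out$score <- score
  out[score >= min_score, , drop = FALSE]
}

#' MinHash sketch of a genome
#'
#' The `s` smallest distinct 64-bit hash values over the genome's canonical
#' k-mers (lexicographic minimum of each k-mer and its reverse complement,
#' 2-bit encoded; k-mers containing N are skipped). The hash function is a
#' fixed splitmix64-style mixer, so sketches are deterministic across runs
#' and machines.
#'
#' @param genome Genome data frame (see [read_fasta()]) or a character vector
#'   of sequences.
#' @param k K-mer size (default 21).
#' @param s Sketch size (default 5000).
#' @param id Genome identifier stored in the sketch.
#' @return A `minhash_sketch`: list with `genome_id`, `k`, `s`, `hashes`
#'   (sorted ascending, distinct) and `total_length`.
#' @export
minhash_sketch <- function(genome, k = 21L, s = 5000L, id = NULL) {
  seqs <- if (is.data.frame(genome)) genome$sequence else as.character(genome)
  if (is.null(id)) {
    id <- if (is.data.frame(genome) && nrow(genome) > 0L) {
      genome$id[1L]
    } else {
      NA_character_
    }
  }
  total <- sum(nchar(seqs))
  if (total < k) {
    stop("genome (", total, " bp) is shorter than k = ", k, call. = FALSE)
  }
  structure(list(genome_id = id, k = as.integer(k), s = as.integer(s),
                 hashes = .minhash_hashes(seqs, as.integer(k), as.integer(s)),
                 total_length = total),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat("<minhash_sketch>", x$genome_id, "\n  k =", x$k, " s =", x$s,
      " |sketch| =", length(x$hashes), "\n")
  invisible(x)
}

#' ANI estimate between two MinHash sketches
#'
#' The Jaccard index `j` of the two sketches is estimated on the merged
#' bottom-s hash set and converted through the Mash distance
#' `D = -ln(2j / (1 + j)) / k` to `ANI = 100 * (1 - D)`. Sketches with no
#' shared hashes are below the resolution of the estimator; `NA` is returned
#' as the sentinel rather than a number.
#'
#' @param a,b `minhash_sketch` objects with matching `k` and `s`.
#' @return Estimated ANI in percent, or `NA` when `j = 0`.
#' @export
ani_estimate <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k || a$s != b$s) {
    stop("sketches have mismatched parameters (k: ", a$k, " vs ", b$k,
         "; s: ", a$s, " vs ", b$s, ")", call. = FALSE)
  }
  u <- sort(unique(c(a$hashes, b$hashes)))
  merged <- u[seq_len(min(a$s, length(u)))]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- shared / length(merged)
  if (j == 0) {
    return(NA_real_)  # below resolution: no k-mer overlap in the sketches
  }
  d <- -log(2 * j / (1 + j)) / a$k
  100 * (1 - d)
}

#' Greedy dereplication of genomes at an ANI threshold
#'
#' Genomes are visited in descending quality score (ties broken by larger
#' total length, then lexicographic id). Each genome joins the existing
#' cluster representative with the highest estimated ANI meeting the
#' threshold, or founds a new cluster; representatives therefore maximize
#' the quality score within their cluster by construction.
#'
#' @param genomes Named list of genome data frames (see [read_fasta()]) or of
#'   precomputed `minhash_sketch` objects.
#' @param qualities Data frame with columns `genome`, `completeness`,
#'   `contamination` covering every genome.
#' @param ani_threshold ANI threshold in percent (default 95).
#' @param inclusive If `TRUE` (default) a genome at exactly the threshold
#'   joins the cluster (`>=`); if `FALSE` the comparison is strict.
#' @param k,s Sketch parameters, used when `genomes` holds sequences.
#' @return A `cluster_set`: data frame with columns `genome`, `cluster`
#'   (representative id), `representative` (logical), `score`,
#'   `ani_to_representative`; attributes `ani_threshold` and `hash`
#'   (the fixed hash function identifier, for run metadata).
#' @export
greedy_cluster <- function(genomes, qualities, ani_threshold = 95,
                           inclusive = TRUE, k = 21L, s = 5000L) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  ids <- names(genomes)
  missing <- setdiff(ids, qualities$genome)
  if (length(missing)) {
    stop("qualities missing for genome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sketches <- lapply(ids, function(g) {
    x <- genomes[[g]]
    if (inherits(x, "minhash_sketch")) x else minhash_sketch(x, k, s, id = g)
  })
  names(sketches) <- ids
  qual <- qualities[match(ids, qualities$genome), ]
  score <- quality_score(qual$completeness, qual$contamination)
  len <- vapply(sketches, function(x) x$total_length, numeric(1L))
  ord <- order(-score, -len, ids)

  cluster <- setNames(character(length(ids)), ids)
  ani_rep <- setNames(rep(NA_real_, length(ids)), ids)
  reps <- character(0)
  for (i in ord) {
    g <- ids[i]
    best <- NA_character_
    best_ani <- -Inf
    for (r in reps) {
      ani <- ani_estimate(sketches[[g]], sketches[[r]])
      if (is.na(ani)) next
      hit <- if (inclusive) ani >= ani_threshold else ani > ani_threshold
      if (hit && ani > best_ani) {
        best <- r
        best_ani <- ani
      }
    }
    if (is.na(best)) {
      reps <- c(reps, g)
      cluster[g] <- g
      ani_rep[g] <- 100
    } else {
      cluster[g] <- best
      ani_rep[g] <- best_ani
    }
  }
  out <- data.frame(genome = ids, cluster = cluster[ids],
                    representative = ids == cluster[ids],
                    score = score,
                    ani_to_representative = ani_rep[ids],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, ani_threshold = ani_threshold,
            hash = "splitmix64/53-bit canonical k-mer",
            class = c("cluster_set", "data.frame"))
}
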