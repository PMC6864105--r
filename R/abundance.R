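# Marker-gene depth normalization, relative abundance, detection,
# prevalence, and size-fraction enrichment summaries.

#' Community sequencing depth from single-copy marker-gene hits
#'
#' Pools the aligned bases of reads hitting a universal single-copy marker
#' gene (rpoB-style) and divides by the mean reference gene length. Because
#' the marker occurs once per genome, this depth proxies the summed
#' sequencing depth of all genomes in the sample and is the denominator that
#' turns a genome's TAD into a community fraction.
#'
#' @param hits Tabular alignments already filtered to bona fide marker reads
#'   (see [filter_marker_hits()] for a plain threshold filter).
#' @param reference_lengths Lengths (bp) of the marker reference genes.
#' @param sample Optional sample identifier.
#' @return A `marker_depth`: list with `sample`, `bases` (total aligned bp),
#'   `ref_length` (mean reference length) and `depth`.
#' @examples
#' hits <- data.frame(pident = rep(99, 4), length = rep(100, 4))
#' marker_depth(hits, reference_lengths = 4000)$depth  # 0.1
#' @export
marker_depth <- function(hits, reference_lengths, sample = NA_character_) {
  if (length(reference_lengths) == 0L) {
    stop("empty marker reference set", call. = FALSE)
  }
  if (any(reference_lengths <= 0)) {
    stop("marker reference lengths must be positive", call. = FALSE)
  }
  bases <- if (nrow(hits) == 0L) 0 else sum(as.numeric(hits$length))
  if (bases == 0) {
    warning("no marker hits: marker depth is 0 and abundances are undefined",
            call. = FALSE)
  }
  structure(list(sample = sample, bases = bases,
                 ref_length = mean(reference_lengths),
                 depth = bases / mean(reference_lengths)),
            class = "marker_depth")
}

#' @export
print.marker_depth <- function(x, ...) {
  cat("<marker_depth>", if (!is.na(x$sample)) x$sample else "", "\n  ",
      format(x$bases, big.mark = ","), "aligned bp /",
      format(x$ref_length, big.mark = ","), "bp mean reference =",
      format(x$depth, digits = 4), "x\n")
  invisible(x)
}

#' Threshold filter for marker-gene hits
#'
#' A plain bitscore/identity filter standing where a trained read classifier
#' would sit in a production pipeline; input order is preserved.
#'
#' @param hits Tabular alignments.
#' @param min_bitscore,min_pident Inclusive minimum thresholds.
#' @return The subset of `hits` passing both thresholds.
#' @export
filter_marker_hits <- function(hits, min_bitscore = 0, min_pident = 0) {
  if (min_bitscore < 0 || min_pident < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  hits[hits$bitscore >= min_bitscore & hits$pident >= min_pident, ,
       drop = FALSE]
}

#' Relative abundance of a genome in a sample
#'
#' The quotient of the genome's truncated average depth and the sample's
#' marker-gene depth: the fraction of the community the population
#' represents.
#'
#' @param tad_value TAD of the genome in the sample (see [tad()]).
#' @param marker A `marker_depth` object or a bare positive depth.
#' @return Abundance as a fraction (0.0001 corresponds to 0.01%).
#' @export
relative_abundance <- function(tad_value, marker) {
  depth <- if (inherits(marker, "marker_depth")) marker$depth else marker
  if (is.na(depth) || depth <= 0) {
    stop("marker depth is 0: relative abundance is undefined", call. = FALSE)
  }
  if (tad_value < 0) stop("TAD must be >= 0", call. = FALSE)
  tad_value / depth
}

#' Detection call for an abundance estimate
#'
#' Strictly greater than the threshold: the default 0.0001 (0.01% of the
#' community) corresponds to roughly 2x genome coverage in the samples this
#' rule was designed for.
#'
#' @param abundance Abundance fraction(s), >= 0.
#' @param threshold Detection threshold (fraction).
#' @return Logical vector, `TRUE` where `abundance > threshold`.
#' @export
is_detected <- function(abundance, threshold = 1e-4) {
  if (any(abundance < 0)) stop("abundance must be >= 0", call. = FALSE)
  abundance > threshold
}

#' Prevalence of genomes across a set of samples
#'
#' Percent of the chosen samples in which each genome is detected, reported
#' to one decimal by truncation (so 25 detections in 38 samples reports
#' 65.7).
#'
#' @param detections Logical matrix, genomes in rows, samples in columns
#'   (column names are sample ids).
#' @param subset Sample ids to evaluate; defaults to all columns.
#' @return Named numeric vector of prevalence percentages per genome.
#' @export
prevalence <- function(detections, subset = NULL) {
  stopifnot(is.matrix(detections) || is.data.frame(detections))
  detections <- as.matrix(detections)
  samples <- colnames(detections)
  if (is.null(subset)) subset <- samples
  if (length(subset) == 0L) {
    stop("cannot compute prevalence over an empty sample subset",
         call. = FALSE)
  }
  missing <- setdiff(subset, samples)
  if (length(missing)) {
    stop("subset sample(s) not in the detection matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- rowSums(detections[, subset, drop = FALSE])
  pct <- 100 * counts / length(subset)
  trunc(round(pct * 10, 9)) / 10
}

#' Size-fraction enrichment of features from paired count tables
#'
#' Reimplements a threshold log-ratio readout for comparing feature counts
#' between two filter size fractions. Counts are normalized per sample to
#' proportions, averaged within each fraction, stabilized with a pseudocount
#' (half the smallest nonzero proportion observed across both tables, unless
#' a numeric pseudocount is given), and compared as
#' `log2FC = log2((mean_small + p) / (mean_large + p))`. Features with
#' `log2FC > log2_small_threshold` are `small_enriched` (default > 2: more
#' than 4-fold higher in the small fraction), features with
#' `log2FC < log2_large_threshold` are `large_enriched` (default < -1), the
#' rest `neutral`.
#'
#' @param counts_small,counts_large Matrices (features x samples) with
#'   identical feature sets (row names).
#' @param pseudocount `"half_min_nonzero"` or a positive number.
#' @param log2_small_threshold,log2_large_threshold Classification bounds.
#' @return Data frame with columns `feature`, `mean_small`, `mean_large`,
#'   `log2fc`, `class`.
#' @export
fraction_enrichment <- function(counts_small, counts_large,
                                pseudocount = "half_min_nonzero",
                                log2_small_threshold = 2,
                                log2_large_threshold = -1) {
  counts_small <- as.matrix(counts_small)
  counts_large <- as.matrix(counts_large)
  if (is.null(rownames(counts_small)) || is.null(rownames(counts_large)) ||
      !setequal(rownames(counts_small), rownames(counts_large))) {
    stop("the two count tables must share one feature set (row names)",
         call. = FALSE)
  }
  counts_large <- counts_large[rownames(counts_small), , drop = FALSE]
  norm <- function(m) {
    tot <- colSums(m)
    if (any(tot <= 0)) {
      stop("sample with zero total counts cannot be normalized",
           call. = FALSE)
    }
    sweep(m, 2L, tot, "/")
  }
  ps <- norm(counts_small)
  pl <- norm(counts_large)
  p <- if (is.numeric(pseudocount)) {
    pseudocount
  } else {
    nz <- c(ps[ps > 0], pl[pl > 0])
    if (length(nz) == 0L) stop("all counts are zero", call. = FALSE)
    min(nz) / 2
  }
  m_s <- rowMeans(ps)
  m_l <- rowMeans(pl)
  lfc <- log2((m_s + p) / (m_l + p))
  cls <- ifelse(lfc > log2_small_threshold, "small_enriched",
                ifelse(lfc < log2_large_threshold, "large_enriched",
                       "neutral"))
  data.frame(feature = rownames(counts_small), mean_small = m_s,
             mean_large = m_l, log2fc = lfc, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
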