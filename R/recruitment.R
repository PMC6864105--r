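# Depth profiles, truncated average depth (TAD), depth-by-identity
# histograms, automated sequence-discrete population cutoff detection, and
# read-based ANI (ANIr) from recruited alignments.

#' Per-base sequencing depth of a genome from recruited alignments
#'
#' Depth at a base is the number of alignments whose (strand-normalized)
#' subject interval contains it, as `genomecov -bga` would report for the
#' corresponding mapping.
#'
#' @param alignments Tabular alignments (see [read_blast_tab()]) recruited to
#'   `genome`.
#' @param genome Genome as a data frame of contigs (see [read_fasta()]).
#' @param id Optional genome identifier stored in the profile.
#' @return A `depth_profile`: list with `genome_id`, `depth` (named list of
#'   per-contig numeric vectors) and `length` (total bp).
#' @export
compute_depth <- function(alignments, genome, id = NA_character_) {
  stopifnot(is.data.frame(genome), all(c("id", "sequence") %in% names(genome)))
  lens <- setNames(nchar(genome$sequence), genome$id)
  rng <- subject_ranges(alignments)
  unknown <- setdiff(unique(rng$contig), names(lens))
  if (length(unknown)) {
    stop("alignment(s) to unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  over <- which(rng$end > lens[rng$contig])
  if (length(over)) {
    i <- over[1L]
    stop("alignment interval [", rng$start[i], ", ", rng$end[i],
         ") exceeds contig '", rng$contig[i], "' of length ",
         lens[rng$contig[i]], call. = FALSE)
  }
  depth <- lapply(names(lens), function(ctg) {
    sel <- rng$contig == ctg
    cov <- IRanges::coverage(
      IRanges::IRanges(start = rng$start[sel] + 1L, end = rng$end[sel]),
      width = lens[[ctg]]
    )
    as.numeric(cov)
  })
  names(depth) <- names(lens)
  structure(list(genome_id = id, depth = depth,
                 length = sum(lens)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile>", if (!is.na(x$genome_id)) x$genome_id else "",
      "\n  contigs:", length(x$depth), " total length:", x$length, "bp\n",
      " mean depth:", format(mean(unlist(x$depth)), digits = 4), "\n")
  invisible(x)
}

#' Convert a depth profile to BedGraph intervals
#'
#' Runs of equal depth are collapsed to 0-based half-open intervals,
#' including zero-depth runs (the `-bga` convention).
#'
#' @param profile A `depth_profile` from [compute_depth()].
#' @return Data frame with columns `contig`, `start`, `end`, `depth`.
#' @export
depth_to_bedgraph <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  out <- lapply(names(profile$depth), function(ctg) {
    r <- rle(profile$depth[[ctg]])
    ends <- cumsum(r$lengths)
    data.frame(contig = ctg, start = c(0L, ends[-length(ends)]),
               end = ends, depth = r$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Truncated average sequencing depth (TAD)
#'
#' Per-base depths of all contigs are concatenated (zero-depth positions
#' included), sorted, and `floor(((1 - central_fraction)/2) * L)` positions
#' are dropped from each tail before taking the arithmetic mean. The default
#' `central_fraction = 0.8` (TAD80) discards the top and bottom 10% of
#' positions, damping conserved-region pile-ups and contig-edge artifacts.
#'
#' @param profile A `depth_profile`, or a bare numeric vector of depths.
#' @param central_fraction Fraction of central positions kept, in (0, 1].
#' @return Mean depth of the retained positions.
#' @examples
#' tad(c(0, 0, 1, 1, 1, 1, 1, 1, 100, 100))  # 13.25
#' @export
tad <- function(profile, central_fraction = 0.8) {
  v <- if (inherits(profile, "depth_profile")) {
    unlist(profile$depth, use.names = FALSE)
  } else {
    as.numeric(profile)
  }
  if (length(v) < 1L) {
    stop("cannot compute TAD of an empty depth profile", call. = FALSE)
  }
  if (!(central_fraction > 0 && central_fraction <= 1)) {
    stop("central_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- length(v)
  # guard the floor against floating-point representation of the fraction
  drop <- floor(round(((1 - central_fraction) / 2) * n, 9))
  v <- sort(v)
  mean(v[(drop + 1L):(n - drop)])
}

#' Depth-by-identity histogram of recruited alignments
#'
#' Each alignment contributes its aligned length (bases) to the identity bin
#' containing its percent identity; per-bin depth is contributed bases
#' divided by genome length. Bins are half-open `[lower, lower + w)`; a
#' percent identity exactly on an edge belongs to the upper bin and 100%
#' belongs to the top bin. Alignments below the histogram domain are ignored.
#'
#' @param alignments Tabular alignments.
#' @param genome_length Genome length in bp (>= 1).
#' @param bin_width Bin width in percent identity; must divide the domain span.
#' @param lower,upper Histogram domain (default `[70, 100]`).
#' @return An `identity_histogram`: data frame with columns `lower`, `upper`,
#'   `depth`, with attributes `bin_width` and `genome_length`.
#' @export
identity_histogram <- function(alignments, genome_length, bin_width = 0.5,
                               lower = 70, upper = 100) {
  if (genome_length < 1) stop("genome_length must be >= 1", call. = FALSE)
  span <- upper - lower
  nbin <- span / bin_width
  if (abs(nbin - round(nbin)) > 1e-9) {
    stop("bin_width must divide the [", lower, ", ", upper, "] span",
         call. = FALSE)
  }
  nbin <- as.integer(round(nbin))
  pid <- alignments$pident
  if (any(pid < 0 | pid > 100)) {
    stop("percent identity outside [0, 100]", call. = FALSE)
  }
  edges <- lower + bin_width * (0:nbin)
  depth <- numeric(nbin)
  keep <- pid >= lower & pid <= upper
  if (any(keep)) {
    idx <- pmin(floor((pid[keep] - lower) / bin_width) + 1L, nbin)
    agg <- tapply(alignments$length[keep], idx, sum)
    depth[as.integer(names(agg))] <- agg / genome_length
  }
  structure(
    data.frame(lower = edges[-(nbin + 1L)], upper = edges[-1L], depth = depth),
    bin_width = bin_width, genome_length = genome_length,
    class = c("identity_histogram", "data.frame")
  )
}

#' Detect the sequence-discrete population identity cutoff
#'
#' Automates the visual rule used on recruitment plots: a sequence-discrete
#' population shows a high-identity depth peak separated from lower-identity
#' background by a coverage gap of several orders of magnitude. Scanning from
#' the peak bin toward lower identity, the gap opens at the first run of at
#' least `min_gap_bins` consecutive bins whose depth falls below
#' `peak * 10^-drop_orders`; a discontinuity is declared only when depth
#' re-emerges to at least that threshold on the far (lower identity) side of
#' the gap, i.e. when the gap actually separates the population from
#' background recruitment. The cutoff is then the lower edge of the last
#' above-threshold bin before the gap. When recruitment simply decays to
#' nothing (single population, no co-recruiting background) no discontinuity
#' is declared and the configured floor is returned.
#'
#' Requiring the gap to span more than one bin keeps isolated empty bins —
#' which arise structurally when fixed-length gapless reads produce a lattice
#' of achievable identities coarser than the bin width — from being read as a
#' population boundary; a genuine sequence-discrete gap spans several percent
#' identity.
#'
#' @param hist An [identity_histogram()].
#' @param drop_orders Orders of magnitude defining the coverage gap.
#' @param floor Cutoff (percent identity) returned when no discontinuity is
#'   found.
#' @param min_gap_bins Minimum number of consecutive below-threshold bins
#'   constituting a gap.
#' @param manual Optional user-supplied cutoff overriding detection (the
#'   fidelity escape hatch for visually chosen cutoffs); when given,
#'   `discontinuity_found` is `NA`.
#' @return A `population_cutoff`: list with `cutoff`, `discontinuity_found`,
#'   `peak_depth` and `drop_ratio` (peak depth over depth in the first gap
#'   bin; `Inf` for an empty gap bin).
#' @export
detect_cutoff <- function(hist, drop_orders = 3, floor = 95,
                          min_gap_bins = 2L, manual = NULL) {
  stopifnot(inherits(hist, "identity_histogram"))
  if (!is.null(manual)) {
    return(structure(list(cutoff = manual, discontinuity_found = NA,
                          peak_depth = max(hist$depth), drop_ratio = NA_real_),
                     class = "population_cutoff"))
  }
  if (nrow(hist) == 0L || sum(hist$depth) <= 0) {
    stop("cannot detect a cutoff on an all-zero identity histogram",
         call. = FALSE)
  }
  peak <- which.max(hist$depth)
  pd <- hist$depth[peak]
  thr <- pd * 10^(-drop_orders)
  sub <- hist$depth < thr
  # top bin of the first run of >= min_gap_bins sub-threshold bins, scanning
  # from the peak toward lower identity (a run may continue past bin 1)
  gap <- NA_integer_
  run <- 0L
  for (i in rev(seq_len(peak - 1L))) {
    if (sub[i]) {
      run <- run + 1L
      if (run >= min_gap_bins || (run >= 1L && i == 1L)) {
        gap <- i + run - 1L
        break
      }
    } else {
      run <- 0L
    }
  }
  res <- list(cutoff = floor, discontinuity_found = FALSE,
              peak_depth = pd, drop_ratio = NA_real_)
  if (!is.na(gap)) {
    res$drop_ratio <- pd / hist$depth[gap]   # Inf when the gap bin is empty
    below_gap <- seq_len(gap - run)
    background <- length(below_gap) > 0L && any(hist$depth[below_gap] >= thr)
    if (background) {
      res$cutoff <- hist$lower[gap + 1L]
      res$discontinuity_found <- TRUE
    }
  } else {
    res$drop_ratio <- pd / min(hist$depth[seq_len(peak)])
  }
  structure(res, class = "population_cutoff")
}

#' @export
print.population_cutoff <- function(x, ...) {
  cat("<population_cutoff> ",
      if (isTRUE(x$discontinuity_found)) {
        sprintf("%.1f%% (coverage discontinuity, drop ratio %.3g)",
                x$cutoff, x$drop_ratio)
      } else if (is.na(x$discontinuity_found)) {
        sprintf("%.1f%% (manual override)", x$cutoff)
      } else {
        sprintf("%.1f%% (floor; no discontinuity found)", x$cutoff)
      }, "\n", sep = "")
  invisible(x)
}

#' Read-based average nucleotide identity (ANIr)
#'
#' Mean percent identity of alignments at or above the population cutoff; a
#' proxy for intra-population sequence diversity. The default weights each
#' alignment by its aligned length (base-weighted mean); `per_read` takes the
#' unweighted mean over qualifying alignments.
#'
#' @param alignments Tabular alignments recruited to one genome.
#' @param cutoff Identity cutoff in percent; alignments with
#'   `pident >= cutoff` qualify.
#' @param weighting `"aligned_bases"` (default) or `"per_read"`.
#' @return ANIr in percent, in `[cutoff, 100]`.
#' @export
anir <- function(alignments, cutoff = 98,
                 weighting = c("aligned_bases", "per_read")) {
  weighting <- match.arg(weighting)
  keep <- alignments$pident >= cutoff
  if (!any(keep)) {
    stop("no recruited reads at or above the ", cutoff, "% identity cutoff",
         call. = FALSE)
  }
  pid <- alignments$pident[keep]
  if (weighting == "aligned_bases") {
    len <- alignments$length[keep]
    sum(pid * len) / sum(len)
  } else {
    mean(pid)
  }
}

#' Recruitment matrix (position x identity)
#'
#' The 2D summary behind a recruitment plot: aligned bases binned by genome
#' position (alignment midpoint, contigs concatenated in genome order) and by
#' percent identity. Its identity marginal equals the
#' [identity_histogram()] scaled by genome length.
#'
#' @param alignments Tabular alignments.
#' @param genome Genome data frame (see [read_fasta()]).
#' @param position_bin Position bin width in bp.
#' @param identity_bin Identity bin width in percent.
#' @param lower,upper Identity domain.
#' @return A `recruitment_matrix`: list with `matrix` (position bins x
#'   identity bins, aligned bases), `position_edges` (bp) and
#'   `identity_edges` (percent).
#' @export
recruitment_matrix <- function(alignments, genome, position_bin = 1000,
                               identity_bin = 0.5, lower = 70, upper = 100) {
  lens <- setNames(nchar(genome$sequence), genome$id)
  offsets <- setNames(c(0, cumsum(as.numeric(lens)))[seq_along(lens)],
                      names(lens))
  total <- sum(lens)
  rng <- subject_ranges(alignments)
  unknown <- setdiff(unique(rng$contig), names(lens))
  if (length(unknown)) {
    stop("alignment(s) to unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(rng$end > lens[rng$contig])) {
    stop("alignment interval exceeds contig bounds", call. = FALSE)
  }
  npos <- max(1L, as.integer(ceiling(total / position_bin)))
  nid <- as.integer(round((upper - lower) / identity_bin))
  m <- matrix(0, nrow = npos, ncol = nid)
  pid <- alignments$pident
  if (any(pid < 0 | pid > 100)) {
    stop("percent identity outside [0, 100]", call. = FALSE)
  }
  keep <- pid >= lower & pid <= upper
  if (any(keep)) {
    mid <- (rng$start[keep] + rng$end[keep]) / 2 + offsets[rng$contig[keep]]
    pi_ <- pmin(as.integer(floor(mid / position_bin)) + 1L, npos)
    ii <- pmin(as.integer(floor((pid[keep] - lower) / identity_bin)) + 1L, nid)
    lenk <- alignments$length[keep]
    for (r in seq_along(pi_)) {
      m[pi_[r], ii[r]] <- m[pi_[r], ii[r]] + lenk[r]
    }
  }
  structure(list(matrix = m,
                 position_edges = position_bin * (0:npos),
                 identity_edges = lower + identity_bin * (0:nid)),
            class = "recruitment_matrix")
}
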