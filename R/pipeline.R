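# One-call workflow: depth -> TAD -> marker depth -> relative abundance ->
# identity histogram -> cutoff -> ANIr for every (genome, sample) pair, with
# a run manifest for provenance.

#' Run the population-statistics pipeline over genomes and samples
#'
#' For every sample the marker-gene hits are pooled into a community depth,
#' and for every genome the recruited alignments are turned into per-base
#' depth, TAD, relative abundance, a depth-by-identity histogram, the
#' detected (or configured) population cutoff, and ANIr. Per-sample and
#' combined TSV tables plus a YAML run manifest (tool version, config
#' snapshot, input checksums, seed, timestamps) are written to `outdir`.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{genomes}{named list of FASTA paths.}
#'     \item{samples}{list of per-sample entries: `id`, `alignments` (named
#'       list genome id -> tabular alignment path), `marker_hits` (path).}
#'     \item{marker_lengths}{numeric vector of marker reference lengths (bp).}
#'     \item{options}{optional: `central_fraction` (0.8), `bin_width` (0.5),
#'       `drop_orders` (3), `floor` (95), `cutoff` (`"auto"` or a number),
#'       `detection_threshold` (1e-4), `anir_weighting`
#'       (`"aligned_bases"`).}
#'     \item{seed}{optional integer recorded in the manifest.}
#'   }
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the combined data frame (one row per genome/sample)
#'   with columns `sample`, `genome`, `n_alignments`, `tad`, `marker_depth`,
#'   `abundance`, `detected`, `cutoff`, `discontinuity`, `anir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$genomes),
            !is.null(config$samples), !is.null(config$marker_lengths))
  opts <- .pipeline_options(config$options)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed for ", what, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  t0 <- Sys.time()
  genomes <- lapply(names(config$genomes), function(g) {
    stage("read_genome", paste0("genome '", g, "'"),
          read_fasta(config$genomes[[g]]))
  })
  names(genomes) <- names(config$genomes)

  rows <- list()
  for (smp in config$samples) {
    sid <- smp$id
    message(sprintf("[magpop] sample %s: marker depth", sid))
    mhits <- stage("read_marker_hits", paste0("sample '", sid, "'"),
                   read_blast_tab(smp$marker_hits))
    md <- stage("marker_depth", paste0("sample '", sid, "'"),
                marker_depth(mhits, config$marker_lengths, sample = sid))
    sample_rows <- list()
    for (g in names(genomes)) {
      path <- smp$alignments[[g]]
      if (is.null(path)) {
        stop("pipeline stage 'read_alignments' failed for sample '", sid,
             "': no alignment file configured for genome '", g, "'",
             call. = FALSE)
      }
      aln <- stage("read_alignments",
                   paste0("sample '", sid, "', genome '", g, "'"),
                   read_blast_tab(path))
      prof <- stage("depth", paste0("sample '", sid, "', genome '", g, "'"),
                    compute_depth(aln, genomes[[g]], id = g))
      tv <- stage("tad", paste0("sample '", sid, "', genome '", g, "'"),
                  tad(prof, opts$central_fraction))
      ab <- stage("abundance", paste0("sample '", sid, "', genome '", g, "'"),
                  relative_abundance(tv, md))
      hist <- stage("identity_histogram",
                    paste0("sample '", sid, "', genome '", g, "'"),
                    identity_histogram(aln, prof$length, opts$bin_width))
      cut <- if (identical(opts$cutoff, "auto")) {
        if (sum(hist$depth) > 0) {
          stage("cutoff", paste0("sample '", sid, "', genome '", g, "'"),
                detect_cutoff(hist, opts$drop_orders, opts$floor))
        } else {
          structure(list(cutoff = opts$floor, discontinuity_found = FALSE,
                         peak_depth = 0, drop_ratio = NA_real_),
                    class = "population_cutoff")
        }
      } else {
        detect_cutoff(hist, manual = opts$cutoff)
      }
      av <- if (any(aln$pident >= cut$cutoff)) {
        stage("anir", paste0("sample '", sid, "', genome '", g, "'"),
              anir(aln, cut$cutoff, opts$anir_weighting))
      } else {
        NA_real_   # population not recruited in this sample
      }
      sample_rows[[g]] <- data.frame(
        sample = sid, genome = g, n_alignments = nrow(aln),
        tad = tv, marker_depth = md$depth, abundance = ab,
        detected = is_detected(ab, opts$detection_threshold),
        cutoff = cut$cutoff,
        discontinuity = isTRUE(cut$discontinuity_found),
        anir = av, stringsAsFactors = FALSE
      )
    }
    sdf <- do.call(rbind, sample_rows)
    write.table(sdf, file.path(outdir, paste0(sid, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rows[[sid]] <- sdf
  }
  combined <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(combined, file.path(outdir, "combined.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  inputs <- c(unlist(config$genomes),
              unlist(lapply(config$samples, function(s)
                c(unlist(s$alignments), s$marker_hits))))
  manifest <- list(
    tool = "magpop",
    version = as.character(packageVersion("magpop")),
    seed = config$seed,
    options = opts,
    inputs = as.list(tools::md5sum(inputs)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(combined)
}

.pipeline_options <- function(options) {
  opts <- list(central_fraction = 0.8, bin_width = 0.5, drop_orders = 3,
               floor = 95, cutoff = "auto", detection_threshold = 1e-4,
               anir_weighting = "aligned_bases")
  for (nm in names(options)) {
    if (!nm %in% names(opts)) {
      stop("unknown pipeline option: ", nm, call. = FALSE)
    }
    opts[[nm]] <- options[[nm]]
  }
  opts
}
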