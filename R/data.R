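#' Genome statistics for eleven representative coastal archaeal MAGs
#'
#' The published summary table of the eleven representative archaeal
#' metagenome-assembled genomes recovered from Helgoland (southern North
#' Sea) surface-water metagenomes: genome length, contig and gene counts,
#' GC content, completeness and contamination, and sampling date, with the
#' MGIIa/MGIIb/Thaumarchaeota/Woesearchaeota group labels. Shipped as the
#' worked real-data input for quality scoring and group summaries.
#'
#' @return Data frame with columns `mag`, `phylum`, `group`, `length_mbp`,
#'   `n_contigs`, `n_genes`, `gc_pct`, `completeness`, `contamination`,
#'   `sampling_date`.
#' @examples
#' mags <- helgoland_mags()
#' quality_score(mags$completeness, mags$contamination)
#' @export
helgoland_mags <- function() {
  path <- system.file("extdata", "helgoland_archaeal_mags.tsv",
                      package = "magpop", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
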