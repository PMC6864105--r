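# Shared simulated fixtures, built once per test run and memoised. All seeds
# are fixed so the suite is deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Single clonal population at ~60x depth, 150 bp reads: the ANIr regime.
clonal_sim <- function() {
  fixture("clonal_sim", function() {
    spec <- data.frame(id = "pop1", genome_length = 40000, gc = 0.5,
                       abundance = 1, divergence = 0.004)
    comm <- sim_community(spec, seed = 101)
    sim <- sim_reads(comm, n_reads = 16000, read_length = 150,
                     error_rate = 0.001, seed = 102)
    list(sim = sim, aln = truth_align(sim))
  })
}

# Primary population plus a co-occurring sister clade at 92% ANI, equal
# abundance, 400 bp reads, all cross-recruited to the primary reference.
sister_sim <- function() {
  fixture("sister_sim", function() {
    spec <- data.frame(id = c("prim", "sist"), genome_length = 40000,
                       gc = 0.5, abundance = c(0.5, 0.5), divergence = 0.004,
                       parent = c(NA, "prim"), parent_divergence = c(NA, 0.08))
    comm <- sim_community(spec, seed = 201)
    sim <- sim_reads(comm, n_reads = 50000, read_length = 400,
                     error_rate = 0.001, seed = 202)
    list(sim = sim,
         aln = truth_align(sim, reference_map = c(prim = "prim",
                                                  sist = "prim")))
  })
}

# Same geometry without the sister: the no-discontinuity control.
single_sim_400 <- function() {
  fixture("single_sim_400", function() {
    spec <- data.frame(id = "prim", genome_length = 40000, gc = 0.5,
                       abundance = 1, divergence = 0.004)
    comm <- sim_community(spec, seed = 201)
    sim <- sim_reads(comm, n_reads = 25000, read_length = 400,
                     error_rate = 0.001, seed = 202)
    list(sim = sim, aln = truth_align(sim))
  })
}

# Five-population community with known proportions and embedded markers,
# >= 100x pooled marker depth.
five_pop_sim <- function() {
  fixture("five_pop_sim", function() {
    spec <- data.frame(id = paste0("pop", 1:5), genome_length = 40000,
                       gc = c(0.50, 0.45, 0.55, 0.40, 0.38),
                       abundance = c(0.40, 0.30, 0.15, 0.10, 0.05),
                       divergence = 0.004, marker_length = 4000)
    comm <- sim_community(spec, seed = 301)
    sim <- sim_reads(comm, n_reads = 30000, read_length = 150,
                     error_rate = 0.001, seed = 302)
    list(comm = comm, sim = sim, aln = truth_align(sim),
         marker = emit_marker_hits(sim))
  })
}

# Ten genomes in three truth groups: within-group ANI >= 99.5 (d = 0.003),
# between groups unrelated random genomes.
derep_genomes <- function() {
  fixture("derep_genomes", function() {
    bases <- lapply(1:3, function(i) {
      sim_genome(60000, gc = 0.45 + 0.05 * i, seed = 400 + i,
                 id = paste0("base", i))
    })
    members <- list(c(1, 1, 1, 1), c(2, 2, 2), c(3, 3, 3))
    genomes <- list()
    truth <- character(0)
    n <- 0
    for (grp in 1:3) {
      for (j in seq_along(members[[grp]])) {
        n <- n + 1
        id <- sprintf("g%02d", n)
        genomes[[id]] <- if (j == 1) {
          g <- bases[[grp]]
          g$id <- id
          g
        } else {
          sim_relative(bases[[grp]], 0.003, seed = 500 + n, id = id)
        }
        truth[id] <- paste0("grp", grp)
      }
    }
    qualities <- data.frame(genome = names(genomes),
                            completeness = c(96.2, 88.5, 92.3, 80.8, 96.2,
                                             88.5, 50, 92.3, 96.2, 85.0),
                            contamination = c(0, 3.8, 0, 0, 0,
                                              0, 0, 1.0, 0.5, 0))
    list(genomes = genomes, qualities = qualities, truth = truth)
  })
}

expect_alignment_frame <- function(aln) {
  expect_true(is.data.frame(aln))
  expect_named(aln, c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore"))
}
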