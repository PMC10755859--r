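# Shared fixtures, built in code at test time.

# A small catalog + genomes pair used across typing tests.
tiny_world <- function(seed = 101, n_genes = 20,
                       length_range = c(300, 600), ...) {
  catalog <- simulate_catalog(n_genes, length_range, seed = seed)
  genomes <- simulate_strain_genomes(catalog, seed = seed + 1, ...)
  list(catalog = catalog, genomes = genomes)
}

# Single-position pileup row in interchange shape.
pileup_row <- function(sample_id = "s1", gene_id = "gene0001", pos = 0,
                       nA = 0, nC = 0, nG = 0, nT = 0) {
  data.frame(sample_id = sample_id, gene_id = gene_id, pos = pos,
             nA = nA, nC = nC, nG = nG, nT = nT,
             stringsAsFactors = FALSE)
}

# Random small trajectory table with arbitrary categories.
random_trajectories <- function(n = 40, seed = 1) {
  cats <- c("LMG11588", "OtherInfantis", "UntypedLow", "UntypedHet",
            "NotDetected", NA)
  withr::with_seed(seed, {
    tr <- data.frame(
      infant_id = sprintf("I%03d", seq_len(n)),
      arm = sample(c("CG", "Lo-EG", "Hi-EG"), n, replace = TRUE),
      feeding = sample(c("EBF", "mixed", "formula"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (v in c("V1", "V2", "V3", "V4")) {
      tr[[v]] <- sample(cats, n, replace = TRUE)
    }
    class(tr) <- c("infant_trajectories", "data.frame")
    attr(tr, "visits") <- c("V1", "V2", "V3", "V4")
    tr
  })
}
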