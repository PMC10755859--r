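#' Simulate a signature-gene catalog
#'
#' Generates a random gene catalog standing in for the 100-gene
#' *B. infantis* signature-gene set used for abundance profiling and
#' SNV-based strain typing. Sequences are uniform random DNA; gene
#' lengths are drawn uniformly from `length_range`.
#'
#' @param n_genes number of genes (default 100).
#' @param length_range integer vector of length 2, min and max gene
#'   length in bp (default `c(300, 1500)`; lengths below 300 bp are not
#'   allowed since signature genes are full-length CDS-scale sequences).
#' @param seed integer seed for reproducibility.
#' @return An object of class `gene_catalog`: a list with `genes`
#'   (data.frame of `gene_id`, `length`, `offset` of the gene's first
#'   position in the concatenated coordinate system), `seq` (integer
#'   vector over the concatenated catalog, 1..4 = A,C,G,T), and
#'   `total_length`.
#' @export
simulate_catalog <- function(n_genes = 100, length_range = c(300, 1500),
                             seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    sf_stop("`length_range` must be positive and non-decreasing",
            class = "strainflow_invalid_argument")
  }
  with_seed(seed, {
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n_genes)
    } else {
      sample(seq(length_range[1], length_range[2]), n_genes, replace = TRUE)
    }
    total <- sum(lens)
    catalog <- list(
      genes = data.frame(
        gene_id = sprintf("gene%04d", seq_len(n_genes)),
        length = as.integer(lens),
        offset = as.integer(cumsum(c(0L, lens[-n_genes]))),
        stringsAsFactors = FALSE
      ),
      seq = sample.int(4L, total, replace = TRUE),
      total_length = as.integer(total)
    )
    class(catalog) <- "gene_catalog"
    catalog
  })
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes, %d bp total (%d-%d bp per gene)\n",
              nrow(x$genes), x$total_length,
              min(x$genes$length), max(x$genes$length)))
  invisible(x)
}

#' Map concatenated catalog positions to (gene_id, within-gene position)
#' @noRd
catalog_gene_of <- function(catalog) {
  rep(catalog$genes$gene_id, catalog$genes$length)
}

#' @noRd
catalog_pos_within <- function(catalog) {
  unlist(lapply(catalog$genes$length, function(l) seq_len(l) - 1L),
         use.names = FALSE)
}

#' Mutate a sequence at a fixed per-site substitution rate
#' @noRd
mutate_seq <- function(s, rate) {
  n <- length(s)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  # draw a uniformly random *different* base at each mutated site
  shift <- sample.int(3L, k, replace = TRUE)
  s[pos] <- ((s[pos] - 1L + shift) %% 4L) + 1L
  s
}

#' Simulate strain genomes over a gene catalog
#'
#' Builds a set of strain sequences emulating the population structure
#' observed for *B. infantis* in infant cohorts: a probiotic clade with
#' negligible internal variability (the supplemented strain and a few
#' near-identical variants) plus a diverse autochthonous clade with
#' stable subclade structure, and a distant outgroup (standing in for
#' *B. longum* subsp. *longum*). Each lineage is mutated at half the
#' nominal rate from its ancestor so that the expected *pairwise* SNV
#' distance between two strains equals rate x total length.
#'
#' @param catalog a [simulate_catalog()] result; the probiotic reference
#'   equals the catalog sequence.
#' @param n_autoch_subclades number of autochthonous subclades.
#' @param snv_rate_between per-site SNV rate between autochthonous
#'   subclades (and between the probiotic and autochthonous clades);
#'   default 0.005.
#' @param snv_rate_within_probiotic per-site SNV rate between members of
#'   the probiotic clade; default 1e-4.
#' @param n_probiotic_variants number of probiotic-clade variant genomes
#'   (colonized infants carry one of these).
#' @param outgroup_rate per-site rate separating the outgroup.
#' @param seed integer seed.
#' @return Object of class `strain_genomes`: list with `seqs` (named list
#'   of integer base vectors; names `"LMG11588"`, `"LMG11588_v*"`,
#'   `"auto*"`, `"outgroup"`), `snv_truth` (named list of planted SNV
#'   positions, 1-based concatenated coordinates, relative to the
#'   probiotic reference), and the rates used.
#' @export
simulate_strain_genomes <- function(catalog,
                                    n_autoch_subclades = 5,
                                    snv_rate_between = 0.005,
                                    snv_rate_within_probiotic = 1e-4,
                                    n_probiotic_variants = 8,
                                    outgroup_rate = 0.03,
                                    seed = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  check_fraction(snv_rate_between, "snv_rate_between", 0, 0.05)
  check_fraction(snv_rate_within_probiotic, "snv_rate_within_probiotic",
                 0, 0.05)
  if (snv_rate_within_probiotic > snv_rate_between) {
    sf_stop("probiotic within-clade rate must not exceed the between rate",
            class = "strainflow_invalid_argument")
  }
  n_autoch_subclades <- check_count(n_autoch_subclades, "n_autoch_subclades")
  n_probiotic_variants <- check_count(n_probiotic_variants,
                                      "n_probiotic_variants", min = 1L)
  with_seed(seed, {
    ref <- catalog$seq
    seqs <- list(LMG11588 = ref)
    for (i in seq_len(n_probiotic_variants)) {
      seqs[[sprintf("LMG11588_v%d", i)]] <-
        mutate_seq(ref, snv_rate_within_probiotic / 2)
    }
    ancestor <- mutate_seq(ref, snv_rate_between / 2)
    for (i in seq_len(n_autoch_subclades)) {
      seqs[[sprintf("auto%d", i)]] <- mutate_seq(ancestor, snv_rate_between / 2)
    }
    seqs[["outgroup"]] <- mutate_seq(ref, outgroup_rate)
    out <- list(
      seqs = seqs,
      snv_truth = lapply(seqs, function(s) which(s != ref)),
      rates = list(between = snv_rate_between,
                   within_probiotic = snv_rate_within_probiotic,
                   outgroup = outgroup_rate),
      catalog_total_length = catalog$total_length
    )
    class(out) <- "strain_genomes"
    out
  })
}

#' @export
print.strain_genomes <- function(x, ...) {
  cat(sprintf("<strain_genomes> %d strains over %d bp (between-rate %g)\n",
              length(x$seqs), x$catalog_total_length, x$rates$between))
  invisible(x)
}
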