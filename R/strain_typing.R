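#' Strain-typing parameters
#'
#' Thresholds of the SNV-based typing procedure. Defaults follow the
#' published filters: a position is called when its major allele reaches
#' 90% frequency (inclusive), samples require at least 250 reads mapping
#' to at least 10 signature genes, a gene is excluded when more than 20%
#' of its covered positions have major-allele frequency below 90%, and
#' *B. infantis* below 0.16% relative abundance is left untyped.
#' `min_depth` (4 reads), `het_max` (0.2% heterogeneous positions,
#' where a heterogeneous position has major-allele frequency below the
#' calling threshold with at least two reads on a second allele),
#' `probiotic_radius` (0.1% of shared positions) and `min_shared`
#' (1000 shared called positions) are this package's own operating
#' choices, exposed here and reported in every output. The `het_max`
#' default sits an order of magnitude above the error-driven
#' heterogeneity of pure single-strain profiles and below the ~0.5% of
#' positions at which two strain lineages typically differ, so 50/50
#' strain mixtures are flagged while pure profiles are not.
#'
#' @param af_threshold consensus allele-frequency threshold (inclusive).
#' @param min_depth minimum depth for a position to be callable.
#' @param min_reads,min_genes sample-level typing filter.
#' @param gene_low_af_max gene excluded if its fraction of low-AF
#'   covered positions is strictly greater than this.
#' @param low_abund relative-abundance bound below which detected
#'   *B. infantis* is left untyped.
#' @param het_max maximum heterogeneity fraction before a profile is
#'   considered a potential strain mixture.
#' @param probiotic_radius normalized SNV distance to the probiotic
#'   reference within which a sample is assigned to the probiotic clade.
#' @param min_shared minimum shared called positions for a defined
#'   pairwise distance.
#' @return list of class `typing_params`.
#' @export
typing_params <- function(af_threshold = 0.90, min_depth = 4,
                          min_reads = 250, min_genes = 10,
                          gene_low_af_max = 0.20, low_abund = 0.0016,
                          het_max = 0.002, probiotic_radius = 0.001,
                          min_shared = 1000) {
  check_fraction(af_threshold, "af_threshold", 0.5, 1)
  check_count(min_depth, "min_depth")
  p <- as.list(environment())
  class(p) <- "typing_params"
  p
}

# Tolerance making >=/<= threshold comparisons robust to float division
.AF_EPS <- 1e-9

#' Consensus-call one sample's pileup
#'
#' A position is called to base `b` iff depth >= `min_depth` and
#' `count_b / depth >= af_threshold` (inclusive, so a 90/100 major
#' allele is called at the default 0.90 threshold). Positions failing
#' either condition remain uncalled.
#'
#' @param counts one sample's allele counts: a data.frame/data.table
#'   with `gene_id`, `pos` (0-based within gene), `nA`, `nC`, `nG`,
#'   `nT`. An empty table yields an all-uncalled profile.
#' @param catalog the [simulate_catalog()]-shaped catalog the counts
#'   refer to.
#' @param params a [typing_params()].
#' @param read_counts optional data.frame with `gene_id`, `reads` for
#'   this sample; if absent, read totals are estimated from summed depth
#'   assuming 100 bp reads.
#' @return object of class `strain_profile`: `calls` (integer vector
#'   over the concatenated catalog, 0 = uncalled, 1..4 = A,C,G,T),
#'   `gene_stats` (per-gene covered / low-AF position counts),
#'   `heterogeneity_fraction`, `total_signature_reads`,
#'   `genes_with_reads`, plus `genes_retained`/`retained_genes` filled
#'   by [exclude_noisy_genes()].
#' @export
call_consensus <- function(counts, catalog, params = typing_params(),
                           read_counts = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  L <- catalog$total_length
  calls <- integer(L)
  gene_stats <- data.frame(gene_id = catalog$genes$gene_id,
                           covered = 0L, low_af = 0L,
                           stringsAsFactors = FALSE)
  covered_total <- 0L
  low_total <- 0L
  depth_sum <- 0
  genes_cov <- character(0)
  if (!is.null(counts) && nrow(counts) > 0) {
    cm <- as.matrix(counts[, c("nA", "nC", "nG", "nT")])
    depth <- rowSums(cm)
    off <- catalog$genes$offset[match(counts$gene_id,
                                      catalog$genes$gene_id)]
    if (anyNA(off)) {
      sf_stop("pileup contains gene ids absent from the catalog",
              class = "strainflow_missing_reference")
    }
    if (any(counts$pos < 0) ||
        any(counts$pos >=
            catalog$genes$length[match(counts$gene_id,
                                       catalog$genes$gene_id)])) {
      sf_stop("pileup positions outside gene bounds",
              class = "strainflow_invalid_argument")
    }
    idx <- off + counts$pos + 1L
    maxc <- pmax(cm[, 1], cm[, 2], cm[, 3], cm[, 4])
    major <- max.col(cm, ties.method = "first")
    cov <- depth >= params$min_depth
    called <- cov & (maxc / depth >= params$af_threshold - .AF_EPS)
    low <- cov & !called
    # heterogeneity requires >= 2 reads on a second allele, so isolated
    # sequencing errors at low depth do not mimic a strain mixture
    het <- low & (depth - maxc >= 2L)
    calls[idx[called]] <- major[called]
    covg <- tapply(as.integer(cov), counts$gene_id, sum)
    lowg <- tapply(as.integer(low), counts$gene_id, sum)
    m <- match(gene_stats$gene_id, names(covg))
    gene_stats$covered <- ifelse(is.na(m), 0L, as.integer(covg[m]))
    m2 <- match(gene_stats$gene_id, names(lowg))
    gene_stats$low_af <- ifelse(is.na(m2), 0L, as.integer(lowg[m2]))
    covered_total <- sum(cov)
    low_total <- sum(het)
    depth_sum <- sum(depth)
    genes_cov <- unique(counts$gene_id[depth > 0])
  }
  if (!is.null(read_counts) && nrow(read_counts) > 0) {
    total_reads <- sum(read_counts$reads)
    genes_with_reads <- sum(read_counts$reads > 0)
  } else {
    total_reads <- as.integer(ceiling(depth_sum / 100))
    genes_with_reads <- length(genes_cov)
  }
  structure(list(
    calls = calls,
    gene_stats = gene_stats,
    covered_positions = as.integer(covered_total),
    heterogeneity_fraction = if (covered_total > 0)
      low_total / covered_total else 0,
    total_signature_reads = total_reads,
    genes_with_reads = as.integer(genes_with_reads),
    genes_retained = NA_integer_,
    retained_genes = NULL
  ), class = "strain_profile")
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf(paste0("<strain_profile> %d called positions, het %.3f, ",
                     "%d reads over %d genes\n"),
              sum(x$calls > 0), x$heterogeneity_fraction,
              x$total_signature_reads, x$genes_with_reads))
  invisible(x)
}

#' Sample-level typing filter
#'
#' A sample enters strain typing only with at least `min_reads` reads
#' mapping to at least `min_genes` signature genes (both inclusive).
#'
#' @param profile a [call_consensus()] profile.
#' @param min_reads,min_genes thresholds (defaults 250 and 10).
#' @return logical.
#' @export
sample_passes_typing_filter <- function(profile, min_reads = 250,
                                        min_genes = 10) {
  profile$total_signature_reads >= min_reads &&
    profile$genes_with_reads >= min_genes
}

#' Exclude noisy genes from a profile
#'
#' A gene is excluded when strictly more than `max_low_af_fraction` of
#' its covered positions have major-allele frequency below the calling
#' threshold (so exactly 20% low-AF positions retains the gene at the
#' default). Genes with zero covered positions are excluded and flagged
#' `"no-coverage"`.
#'
#' @param profile a [call_consensus()] profile.
#' @param max_low_af_fraction exclusion threshold (default 0.20).
#' @return the profile with excluded genes' positions set uncalled,
#'   `retained_genes` / `genes_retained` filled in, and an
#'   `excluded_flags` attribute naming no-coverage genes.
#' @export
exclude_noisy_genes <- function(profile, max_low_af_fraction = 0.20) {
  gs <- profile$gene_stats
  frac <- ifelse(gs$covered > 0, gs$low_af / gs$covered, NA_real_)
  retained <- !is.na(frac) & (frac <= max_low_af_fraction + .AF_EPS)
  no_cov <- gs$gene_id[gs$covered == 0]
  profile$retained_genes <- gs$gene_id[retained]
  profile$genes_retained <- sum(retained)
  profile$excluded_flags <- setNames(
    rep("no-coverage", length(no_cov)), no_cov)
  profile
}

#' Concatenate called sequences over retained genes
#'
#' Masks all positions of excluded genes so that only retained genes
#' contribute to the comparable position set. Coordinates are preserved
#' (uncalled positions stay 0), so all profiles remain alignable by
#' catalog position without a multiple sequence alignment step.
#'
#' @param profile a profile run through [exclude_noisy_genes()].
#' @param catalog the matching catalog.
#' @return the profile with `calls` masked to retained genes.
#' @export
build_profiles <- function(profile, catalog) {
  if (is.null(profile$retained_genes)) {
    profile <- exclude_noisy_genes(profile)
  }
  keep <- catalog$genes$gene_id %in% profile$retained_genes
  if (!all(keep)) {
    mask <- rep(keep, catalog$genes$length)
    profile$calls[!mask] <- 0L
  }
  profile
}

#' Pairwise SNV distance between two profiles
#'
#' @param a,b profiles on the same catalog (or raw integer call
#'   vectors).
#' @param min_shared minimum number of positions called in both for the
#'   distance to be defined.
#' @return list with `raw` (count of differing shared positions),
#'   `shared` (positions called in both), `normalized` (`raw/shared`,
#'   `NA` when undefined) and `defined`.
#' @export
pairwise_snv_distance <- function(a, b, min_shared = 1000) {
  ca <- if (inherits(a, "strain_profile")) a$calls else a
  cb <- if (inherits(b, "strain_profile")) b$calls else b
  if (length(ca) != length(cb)) {
    sf_stop("profiles are not on the same catalog",
            class = "strainflow_invalid_argument")
  }
  shared <- ca > 0L & cb > 0L
  ns <- sum(shared)
  raw <- sum(ca[shared] != cb[shared])
  list(raw = raw, shared = ns,
       normalized = if (ns >= min_shared) raw / ns else NA_real_,
       defined = ns >= min_shared)
}

#' Reference genomes as error-free profiles
#'
#' @param genomes a [simulate_strain_genomes()] result (or a named list
#'   of integer base vectors).
#' @return named list of full-length call vectors.
#' @export
reference_profiles <- function(genomes) {
  seqs <- if (inherits(genomes, "strain_genomes")) genomes$seqs else genomes
  lapply(seqs, identity)
}

#' Normalized SNV distance matrix over profiles
#'
#' @param profiles named list of profiles or call vectors.
#' @param min_shared per-pair minimum shared positions.
#' @return symmetric matrix of normalized distances (`NA` when a pair
#'   shares fewer than `min_shared` called positions).
#' @export
snv_distance_matrix <- function(profiles, min_shared = 1000) {
  n <- length(profiles)
  nm <- names(profiles) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  calls <- lapply(profiles, function(p)
    if (inherits(p, "strain_profile")) p$calls else p)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      pd <- pairwise_snv_distance(calls[[i]], calls[[j]], min_shared)
      d[i, j] <- d[j, i] <- pd$normalized
    }
  }
  d
}

#' Neighbor-joining strain tree rooted on an outgroup
#'
#' Builds a neighbor-joining tree from normalized SNV distances, clamps
#' any negative NJ branch length to zero (moving the deficit to the
#' sibling branches so tip-to-tip path lengths are preserved), and roots
#' the tree on the outgroup. Branch lengths are in normalized SNV units,
#' so the path length between two tips is proportional to their SNV
#' difference.
#'
#' @param d symmetric distance matrix with tip names (samples plus
#'   references; must include `outgroup`). All entries must be defined.
#' @param outgroup tip label used for rooting.
#' @return an [ape::phylo] tree.
#' @export
build_strain_tree <- function(d, outgroup = "outgroup") {
  if (anyNA(d)) {
    sf_stop("distance matrix contains undefined pairs; place only samples
with defined distances", class = "strainflow_invalid_argument")
  }
  n <- nrow(d)
  if (n < 3) {
    warning("fewer than 3 tips; returning a trivial tree")
    tr <- list(edge = matrix(c(n + 1L, n + 1L, 1L, 2L), 2, 2),
               tip.label = rownames(d),
               edge.length = rep(d[1, 2] / 2, 2), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    sibs <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    tr$edge.length[sibs] <- tr$edge.length[sibs] + deficit
  }
  if (outgroup %in% tr$tip.label) {
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Classify a sample's strain category
#'
#' Applies the categorization rules in fixed order: `NotDetected` when
#' *B. infantis* is absent from the taxonomic profile; `UntypedLow` when
#' detected below the low-abundance bound (strictly less than 0.16% by
#' default); `UntypedHet` when the typing filter failed, the profile is
#' heterogeneous (possible strain mixture), or too few positions are
#' shared with the probiotic reference; `LMG11588` when the normalized
#' distance to the probiotic reference is within `probiotic_radius`;
#' otherwise `OtherInfantis`.
#'
#' @param profile a processed [build_profiles()] profile.
#' @param abundance *B. infantis* relative abundance of the same sample.
#' @param ref_dists named normalized distances to references (must
#'   contain `"LMG11588"`; `NA` means undefined).
#' @param params a [typing_params()].
#' @param filter_pass result of [sample_passes_typing_filter()]; if
#'   `NULL` it is recomputed from the profile.
#' @return list with `category` and the supporting evidence.
#' @export
classify_strain <- function(profile, abundance, ref_dists,
                            params = typing_params(),
                            filter_pass = NULL) {
  if (is.na(abundance) || abundance < 0 || abundance > 1) {
    sf_stop("`abundance` must be in [0, 1]",
            class = "strainflow_invalid_argument")
  }
  filter_pass <- filter_pass %||%
    sample_passes_typing_filter(profile, params$min_reads,
                                params$min_genes)
  d_pro <- ref_dists[["LMG11588"]]
  category <- if (abundance <= 0) {
    "NotDetected"
  } else if (abundance < params$low_abund) {
    "UntypedLow"
  } else if (!filter_pass ||
             profile$heterogeneity_fraction > params$het_max ||
             is.na(d_pro)) {
    "UntypedHet"
  } else if (d_pro <= params$probiotic_radius) {
    "LMG11588"
  } else {
    "OtherInfantis"
  }
  list(category = category, abundance = abundance,
       dist_probiotic = d_pro,
       heterogeneity_fraction = profile$heterogeneity_fraction,
       filter_pass = filter_pass,
       called_positions = sum(profile$calls > 0L))
}

#' Type all samples of a cohort
#'
#' Runs consensus calling, sample/gene filters and categorization for
#' every sample in `abundances`, streaming one sample at a time so large
#' cohorts stay within memory.
#'
#' @param pileups a `pileup_set` (see [simulate_pileups()]) or a bare
#'   allele-count data.table.
#' @param abundances data.frame with `sample_id` and `abundance`
#'   (*B. infantis* relative abundance).
#' @param genomes references as [simulate_strain_genomes()] output or a
#'   named list of call vectors (must include `LMG11588`).
#' @param catalog the catalog.
#' @param params a [typing_params()].
#' @return data.frame with one row per sample: category, abundance,
#'   distance to the probiotic reference, nearest reference and its
#'   distance, QC metrics.
#' @export
type_strains <- function(pileups, abundances, genomes, catalog,
                         params = typing_params()) {
  counts <- if (inherits(pileups, "pileup_set")) pileups$counts
            else data.table::as.data.table(pileups)
  read_counts <- if (inherits(pileups, "pileup_set")) pileups$read_counts
                 else NULL
  refs <- reference_profiles(genomes)
  refs <- refs[setdiff(names(refs), "outgroup")]
  if (!"LMG11588" %in% names(refs)) {
    sf_stop("references must include 'LMG11588'",
            class = "strainflow_missing_reference")
  }
  data.table::setkey(counts, sample_id)
  if (!is.null(read_counts)) data.table::setkey(read_counts, sample_id)
  out <- vector("list", nrow(abundances))
  for (i in seq_len(nrow(abundances))) {
    sid <- abundances$sample_id[i]
    cs <- counts[list(sid), nomatch = NULL]
    rs <- if (!is.null(read_counts))
      read_counts[list(sid), nomatch = NULL] else NULL
    prof <- call_consensus(cs, catalog, params, read_counts = rs)
    prof <- exclude_noisy_genes(prof, params$gene_low_af_max)
    prof <- build_profiles(prof, catalog)
    dists <- vapply(refs, function(rf)
      pairwise_snv_distance(prof$calls, rf, params$min_shared)$normalized,
      numeric(1))
    cl <- classify_strain(prof, abundances$abundance[i], dists, params)
    others <- dists[setdiff(names(dists), "LMG11588")]
    nearest <- if (all(is.na(dists))) NA_character_
               else names(dists)[which.min(dists)]
    out[[i]] <- data.frame(
      sample_id = sid, category = cl$category,
      abundance = cl$abundance,
      dist_probiotic = cl$dist_probiotic,
      nearest_ref = nearest,
      dist_nearest = if (all(is.na(dists))) NA_real_
                     else min(dists, na.rm = TRUE),
      dist_best_other = if (all(is.na(others))) NA_real_
                        else min(others, na.rm = TRUE),
      heterogeneity_fraction = prof$heterogeneity_fraction,
      total_signature_reads = prof$total_signature_reads,
      genes_with_reads = prof$genes_with_reads,
      genes_retained = prof$genes_retained,
      called_positions = cl$called_positions,
      filter_pass = cl$filter_pass,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  attr(res, "params") <- params
  res
}
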