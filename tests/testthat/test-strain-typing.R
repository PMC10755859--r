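test_that("consensus calling matches a brute-force recount", {
  # random pileup over >= 1e5 positions; oracle recomputes every call
  # from first principles, the implementation must agree exactly
  world <- tiny_world(seed = 41, n_genes = 100,
                      length_range = c(900, 1200))
  withr::with_seed(42, {
    catalog <- world$catalog
    n <- catalog$total_length
    expect_gte(n, 1e5)
    depth <- rpois(n, 6)
    cm <- t(vapply(depth, function(d) rmultinom(1, d, c(0.6, 0.2, 0.1,
                                                        0.1))[, 1],
                   integer(4)))
    counts <- data.frame(sample_id = "s",
                         gene_id = rep(catalog$genes$gene_id,
                                       catalog$genes$length),
                         pos = unlist(lapply(catalog$genes$length,
                                             function(l) 0:(l - 1))),
                         nA = cm[, 1], nC = cm[, 2], nG = cm[, 3],
                         nT = cm[, 4])
    prm <- typing_params(af_threshold = 0.9, min_depth = 4)
    prof <- call_consensus(counts, catalog, prm)

    # oracle: slow per-position recount
    oracle <- integer(n)
    for (i in seq_len(n)) {
      d <- sum(cm[i, ])
      if (d >= 4) {
        mx <- which.max(cm[i, ])
        if (cm[i, mx] / d >= 0.9) oracle[i] <- mx
      }
    }
    expect_identical(prof$calls, oracle)
  })
})

test_that("allele-frequency threshold is inclusive at 90%", {
  catalog <- simulate_catalog(1, c(300, 300), seed = 1)
  prm <- typing_params()
  p95 <- call_consensus(pileup_row(nA = 95, nG = 5), catalog, prm)
  expect_equal(p95$calls[1], 1L)
  p89 <- call_consensus(pileup_row(nA = 89, nG = 11), catalog, prm)
  expect_equal(p89$calls[1], 0L)
  p90 <- call_consensus(pileup_row(nA = 90, nG = 10), catalog, prm)
  expect_equal(p90$calls[1], 1L)
  # empty pileup: all-uncalled profile, not an error
  empty <- call_consensus(NULL, catalog, prm)
  expect_true(all(empty$calls == 0L))
})

test_that("sample typing filter boundaries are inclusive", {
  prof <- structure(list(total_signature_reads = 250,
                         genes_with_reads = 10),
                    class = "strain_profile")
  expect_true(sample_passes_typing_filter(prof))
  prof$total_signature_reads <- 249
  prof$genes_with_reads <- 50
  expect_false(sample_passes_typing_filter(prof))
  prof$total_signature_reads <- 10000
  prof$genes_with_reads <- 9
  expect_false(sample_passes_typing_filter(prof))
})

test_that("gene exclusion uses a strict majority of low-AF positions", {
  mk <- function(covered, low) {
    structure(list(gene_stats = data.frame(
      gene_id = "g", covered = covered, low_af = low), calls = integer(0)),
      class = "strain_profile")
  }
  expect_equal(exclude_noisy_genes(mk(100, 20))$genes_retained, 1L)
  expect_equal(exclude_noisy_genes(mk(100, 21))$genes_retained, 0L)
  expect_equal(exclude_noisy_genes(mk(100, 0))$genes_retained, 1L)
  nocov <- exclude_noisy_genes(mk(0, 0))
  expect_equal(nocov$genes_retained, 0L)
  expect_equal(unname(nocov$excluded_flags["g"]), "no-coverage")
})

test_that("profiles concatenate retained genes and keep coordinates", {
  world <- tiny_world(seed = 51, n_genes = 3, length_range = c(300, 300))
  truth <- data.frame(sample_id = "s1", strain = "auto1",
                      strain2 = NA_character_, mix_prop = 1,
                      abundance = 0.05)
  pp <- simulate_pileups(truth, world$genomes, world$catalog,
                         depth_per_unit_abundance = 2000, error_rate = 0,
                         seed = 6)
  prof <- call_consensus(pp$counts, world$catalog)
  prof <- exclude_noisy_genes(prof)
  prof <- build_profiles(prof, world$catalog)
  covered <- prof$calls > 0
  # error-free: called positions equal the strain's sequence exactly
  expect_identical(prof$calls[covered],
                   world$genomes$seqs$auto1[covered])
  expect_length(prof$calls, world$catalog$total_length)

  # masking one gene removes its positions from the comparable set
  prof2 <- prof
  prof2$retained_genes <- setdiff(prof$retained_genes, "gene0001")
  prof2 <- build_profiles(prof2, world$catalog)
  expect_true(all(prof2$calls[1:300] == 0L))
})

test_that("pairwise distances count planted SNVs and are symmetric", {
  world <- tiny_world(seed = 61, n_genes = 40, length_range = c(500, 700))
  a <- world$genomes$seqs$auto1
  b <- world$genomes$seqs$auto2
  k <- sum(a != b)
  d <- pairwise_snv_distance(a, b, min_shared = 100)
  expect_equal(d$raw, k)
  expect_equal(d$shared, length(a))
  expect_equal(d$normalized, k / length(a))
  d_rev <- pairwise_snv_distance(b, a, min_shared = 100)
  expect_equal(d_rev$raw, d$raw)

  same <- pairwise_snv_distance(a, a, min_shared = 100)
  expect_equal(same$raw, 0)
  expect_equal(same$normalized, 0)

  # disjoint called sets: flagged undefined, not zero
  x <- a; x[1:(length(a) / 2)] <- 0L
  y <- a; y[(length(a) / 2 + 1):length(a)] <- 0L
  dis <- pairwise_snv_distance(x, y, min_shared = 10)
  expect_false(dis$defined)
  expect_true(is.na(dis$normalized))
})

test_that("raising the AF threshold never increases called positions", {
  world <- tiny_world(seed = 71, n_genes = 10)
  withr::with_seed(8, {
    for (rep in 1:5) {
      truth <- data.frame(sample_id = "s", strain = "auto1",
                          strain2 = if (rep %% 2) "auto2" else NA,
                          mix_prop = 0.7, abundance = runif(1, 0.01, 0.1))
      pp <- simulate_pileups(truth, world$genomes, world$catalog,
                             error_rate = 0.01, seed = rep)
      called <- vapply(c(0.6, 0.75, 0.9, 0.95, 1), function(af) {
        prm <- typing_params(af_threshold = af)
        sum(call_consensus(pp$counts, world$catalog, prm)$calls > 0)
      }, numeric(1))
      expect_true(all(diff(called) <= 0))
    }
  })
})

test_that("NJ tree groups the probiotic clade and roots on the outgroup", {
  # additive 4-point configuration + outgroup
  world <- tiny_world(seed = 81, n_genes = 50, length_range = c(500, 700),
                      n_autoch_subclades = 2, n_probiotic_variants = 2)
  profs <- reference_profiles(world$genomes)
  profs <- profs[c("LMG11588_v1", "LMG11588_v2", "auto1", "auto2",
                   "outgroup")]
  d <- snv_distance_matrix(profs, min_shared = 100)
  tr <- build_strain_tree(d, outgroup = "outgroup")
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
  # probiotic variants are siblings: their MRCA contains only them
  pro_tips <- c("LMG11588_v1", "LMG11588_v2")
  mrca <- ape::getMRCA(tr, pro_tips)
  clade <- ape::extract.clade(tr, mrca)
  expect_setequal(clade$tip.label, pro_tips)

  # degenerate all-equal distances: star-like, no crash
  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  expect_s3_class(build_strain_tree(eq, outgroup = "a"), "phylo")

  expect_warning(build_strain_tree(eq[1:2, 1:2], outgroup = "a"),
                 "trivial")
})

test_that("classification follows the rule order", {
  prof <- structure(list(calls = rep(1L, 5000),
                         heterogeneity_fraction = 0,
                         total_signature_reads = 1000,
                         genes_with_reads = 50, genes_retained = 50),
                    class = "strain_profile")
  prm <- typing_params()
  dists <- c(LMG11588 = 0, auto1 = 0.004)

  expect_equal(classify_strain(prof, 0, dists, prm)$category,
               "NotDetected")
  expect_equal(classify_strain(prof, 0.0015, dists, prm)$category,
               "UntypedLow")
  expect_equal(classify_strain(prof, 0.0016, dists, prm)$category,
               "LMG11588")
  far <- c(LMG11588 = 0.004, auto1 = 0.0001)
  expect_equal(classify_strain(prof, 0.01, far, prm)$category,
               "OtherInfantis")
  prof_het <- prof
  prof_het$heterogeneity_fraction <- 0.01
  expect_equal(classify_strain(prof_het, 0.01, dists, prm)$category,
               "UntypedHet")
  expect_equal(classify_strain(prof, 0.01, dists, prm,
                               filter_pass = FALSE)$category,
               "UntypedHet")
  undef <- c(LMG11588 = NA_real_)
  expect_equal(classify_strain(prof, 0.01, undef, prm)$category,
               "UntypedHet")
  expect_error(classify_strain(prof, 1.5, dists, prm),
               class = "strainflow_invalid_argument")
})

test_that("a simulated 50/50 mixture at depth is flagged heterogeneous", {
  world <- tiny_world(seed = 91, n_genes = 40, length_range = c(500, 700))
  truth <- data.frame(sample_id = "mix", strain = "auto1",
                      strain2 = "auto2", mix_prop = 0.5, abundance = 0.04)
  pp <- simulate_pileups(truth, world$genomes, world$catalog,
                         depth_per_unit_abundance = 5000,
                         error_rate = 0.002, seed = 12)
  cl <- type_strains(pp, data.frame(sample_id = "mix", abundance = 0.04),
                     world$genomes, world$catalog,
                     typing_params(min_shared = 500))
  expect_equal(cl$category, "UntypedHet")
})

test_that("typing recovers truth and agrees with the tree on a cohort", {
  cfg <- cohort_config(n_per_arm = 5, n_genes = 30,
                       gene_length_range = c(400, 700), error_rate = 0,
                       dropout_prob = 0, seed = 19)
  co <- simulate_cohort(cfg)
  present <- co$truth$samples[!co$truth$samples$missing, ]
  prm <- typing_params(min_shared = 500)
  cl <- type_strains(co$pileups, present[, c("sample_id", "abundance")],
                     co$genomes, co$catalog, prm)
  m <- match(cl$sample_id, present$sample_id)
  hi <- present$abundance[m] >= 0.005
  expect_gte(mean(cl$category[hi] == present$true_category[m][hi]), 0.95)
  pro_truth <- startsWith(ifelse(is.na(present$strain[m]), "",
                                 present$strain[m]), "LMG")
  expect_equal(sum(cl$category[pro_truth] == "OtherInfantis"), 0)

  # tree/threshold concordance on error-free profiles: every sample
  # typed LMG11588 by radius is inside the minimal probiotic clade
  placed <- cl$sample_id[cl$category %in% c("LMG11588", "OtherInfantis")]
  if (length(placed) >= 3) {
    profs <- list()
    counts <- co$pileups$counts
    data.table::setkey(counts, sample_id)
    for (sid in placed) {
      pr <- call_consensus(counts[list(sid), nomatch = NULL], co$catalog,
                           prm)
      pr <- build_profiles(exclude_noisy_genes(pr), co$catalog)
      profs[[sid]] <- pr$calls
    }
    refs <- reference_profiles(co$genomes)
    d <- snv_distance_matrix(c(profs, refs), min_shared = 500)
    ok <- !apply(is.na(d), 1, any)
    d <- d[ok, ok]
    tr <- build_strain_tree(d, outgroup = "outgroup")
    # every sample typed LMG11588 by radius must sit on the probiotic
    # side of the tree: patristically closer to a probiotic reference
    # than to any autochthonous reference
    coph <- ape::cophenetic.phylo(tr)
    pro_tips <- intersect(rownames(d),
                          c("LMG11588", paste0("LMG11588_v", 1:8)))
    auto_tips <- intersect(rownames(d), paste0("auto", 1:5))
    typed_pro <- intersect(cl$sample_id[cl$category == "LMG11588"],
                           rownames(d))
    for (sid in typed_pro) {
      expect_lt(min(coph[sid, pro_tips]), min(coph[sid, auto_tips]))
    }
  }
})
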