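test_that("catalog simulation respects sizes and is deterministic", {
  cat1 <- simulate_catalog(100, c(300, 1500), seed = 1)
  expect_equal(nrow(cat1$genes), 100)
  expect_gte(cat1$total_length, 30000)
  expect_lte(cat1$total_length, 150000)

  single <- simulate_catalog(1, c(300, 300), seed = 7)
  expect_equal(single$total_length, 300L)
  expect_equal(single$genes$length, 300L)

  cat2 <- simulate_catalog(100, c(300, 1500), seed = 1)
  expect_identical(cat1, cat2)

  expect_error(simulate_catalog(0), class = "strainflow_invalid_argument")
  expect_error(simulate_catalog(10, c(-5, 10)),
               class = "strainflow_invalid_argument")
})

test_that("planted SNV distances match their binomial expectations", {
  # pairwise autochthonous distance ~ between_rate x L over many seeds
  world <- tiny_world(seed = 5, n_genes = 100, length_range = c(900, 1100))
  L <- world$catalog$total_length
  rate <- 0.005
  dists <- c()
  for (s in 1:20) {
    g <- simulate_strain_genomes(world$catalog, n_autoch_subclades = 3,
                                 snv_rate_between = rate, seed = s)
    pairs <- combn(paste0("auto", 1:3), 2)
    for (j in seq_len(ncol(pairs))) {
      dists <- c(dists, sum(g$seqs[[pairs[1, j]]] != g$seqs[[pairs[2, j]]]))
    }
  }
  expected <- rate * L
  # mean over 60 pairs; allow 4 sigma of the binomial spread plus the
  # small deficit from coincident mutations
  expect_lt(abs(mean(dists) - expected),
            4 * sqrt(expected) / sqrt(length(dists)) + 0.01 * expected)

  # probiotic clade members differ by ~ within_rate x L (Poisson scale)
  pro <- c()
  for (s in 1:20) {
    g <- simulate_strain_genomes(world$catalog, n_probiotic_variants = 2,
                                 snv_rate_within_probiotic = 1e-4,
                                 seed = 100 + s)
    pro <- c(pro, sum(g$seqs$LMG11588_v1 != g$seqs$LMG11588_v2))
  }
  expect_lt(abs(mean(pro) - 1e-4 * L), 4 * sqrt(1e-4 * L / 20) + 1)

  # zero rate: identical to the reference
  g0 <- simulate_strain_genomes(world$catalog, snv_rate_between = 0,
                                snv_rate_within_probiotic = 0, seed = 3)
  expect_identical(g0$seqs$auto1, world$catalog$seq)
  expect_identical(g0$seqs$LMG11588_v1, world$catalog$seq)

  expect_error(simulate_strain_genomes(world$catalog,
                                       snv_rate_between = 0.2),
               class = "strainflow_invalid_argument")
})

test_that("pileups follow the depth/error model", {
  world <- tiny_world(seed = 11)
  # zero abundance: no counts at all
  t0 <- data.frame(sample_id = "s0", strain = "auto1",
                   strain2 = NA_character_, mix_prop = 1, abundance = 0)
  p0 <- simulate_pileups(t0, world$genomes, world$catalog, seed = 1)
  expect_equal(nrow(p0$counts), 0)

  # noiseless single strain: every covered position is 100% strain base
  t1 <- data.frame(sample_id = "s1", strain = "auto1",
                   strain2 = NA_character_, mix_prop = 1, abundance = 0.02)
  p1 <- simulate_pileups(t1, world$genomes, world$catalog,
                         depth_per_unit_abundance = 5000, error_rate = 0,
                         seed = 2)
  cm <- as.matrix(p1$counts[, c("nA", "nC", "nG", "nT")])
  depth <- rowSums(cm)
  off <- world$catalog$genes$offset[match(p1$counts$gene_id,
                                          world$catalog$genes$gene_id)]
  truth_base <- world$genomes$seqs$auto1[off + p1$counts$pos + 1]
  expect_true(all(cm[cbind(seq_len(nrow(cm)), truth_base)] == depth))

  # 50/50 mixture: allele frequency ~50% at planted SNV sites
  t2 <- data.frame(sample_id = "s2", strain = "auto1", strain2 = "auto2",
                   mix_prop = 0.5, abundance = 0.05)
  p2 <- simulate_pileups(t2, world$genomes, world$catalog,
                         depth_per_unit_abundance = 5000, error_rate = 0,
                         seed = 3)
  diff_pos <- which(world$genomes$seqs$auto1 != world$genomes$seqs$auto2)
  off2 <- world$catalog$genes$offset[match(p2$counts$gene_id,
                                           world$catalog$genes$gene_id)]
  idx <- off2 + p2$counts$pos + 1
  at_snv <- idx %in% diff_pos
  cm2 <- as.matrix(p2$counts[at_snv, c("nA", "nC", "nG", "nT")])
  d2 <- rowSums(cm2)
  b1 <- world$genomes$seqs$auto1[idx[at_snv]]
  af1 <- cm2[cbind(seq_len(nrow(cm2)), b1)] / d2
  keep <- d2 >= 200
  expect_gt(sum(keep), 10)
  expect_lt(abs(mean(af1[keep]) - 0.5), 0.02)

  expect_error(
    simulate_pileups(data.frame(sample_id = "x", strain = "nope",
                                strain2 = NA, mix_prop = 1,
                                abundance = 0.1),
                     world$genomes, world$catalog),
    class = "strainflow_missing_reference")
})

test_that("total signature reads track B. infantis abundance", {
  world <- tiny_world(seed = 21)
  truth <- data.frame(
    sample_id = sprintf("s%02d", 1:40),
    strain = "auto1", strain2 = NA_character_, mix_prop = 1,
    abundance = exp(seq(log(0.001), log(0.3), length.out = 40))
  )
  pp <- simulate_pileups(truth, world$genomes, world$catalog, seed = 4)
  tot <- tapply(pp$read_counts$reads, pp$read_counts$sample_id, sum)
  tot <- tot[truth$sample_id]
  expect_gte(cor(tot, truth$abundance, method = "spearman"), 0.9)
})

test_that("genus tables reproduce Dirichlet-multinomial moments", {
  prm <- list(alpha = matrix(c(10, 10), 1, 2,
                             dimnames = list(NULL, c("a", "b"))))
  lab <- rep(1L, 400)
  x <- simulate_genus_tables(lab, prm, library_size = 1000, seed = 5)
  props <- x / rowSums(x)
  expect_lt(abs(mean(props[, 1]) - 0.5), 0.02)

  # x100 concentration: same mean, smaller dispersion than the
  # Dirichlet-multinomial variance formula predicts for the diffuse case
  prm2 <- list(alpha = prm$alpha * 100)
  x2 <- simulate_genus_tables(lab, prm2, library_size = 1000, seed = 5)
  props2 <- x2 / rowSums(x2)
  expect_lt(abs(mean(props2[, 1]) - 0.5), 0.02)
  expect_lt(var(props2[, 1]), var(props[, 1]))
  # theoretical variances: p(1-p)(n+A)/(n(1+A))
  v1 <- 0.25 * (1000 + 20) / (1000 * 21)
  v2 <- 0.25 * (1000 + 2000) / (1000 * 2001)
  expect_lt(abs(var(props[, 1]) - v1), 4 * v1 / sqrt(400))
  expect_lt(abs(var(props2[, 1]) - v2), 4 * v2 / sqrt(400))

  x3 <- simulate_genus_tables(rep(1L, 10), prm, library_size = 1, seed = 6)
  expect_true(all(rowSums(x3 > 0) == 1))

  expect_error(simulate_genus_tables(lab, list(alpha = matrix(0, 1, 2))),
               class = "strainflow_invalid_argument")
})

test_that("biomarkers are monotone in abundance and growth matches spec", {
  cfg <- cohort_config(n_per_arm = 20, biomarker_noise_sd = 0, seed = 9)
  truth <- simulate_cohort_truth(cfg, seed = 9)
  bg <- simulate_biomarkers_and_growth(truth$samples, truth$infants, cfg,
                                       seed = 10)
  m <- match(bg$biomarkers$sample_id, truth$samples$sample_id)
  ab <- truth$samples$abundance[m]
  for (v in c("V1", "V2", "V3")) {
    sel <- bg$biomarkers$visit == v & !duplicated(ab[])
    if (sum(sel) > 5 && sd(ab[sel]) > 0) {
      tau_pos <- cor(ab[sel], bg$biomarkers$acetate[sel],
                     method = "kendall")
      tau_neg <- cor(ab[sel], bg$biomarkers$IL8[sel], method = "kendall")
      expect_equal(tau_pos, 1)
      expect_equal(tau_neg, -1)
    }
  }
  # pooled gain SD close to the planted 7.7 over a larger cohort
  cfg2 <- cohort_config(n_per_arm = 400, seed = 2)
  truth2 <- simulate_cohort_truth(cfg2, seed = 2)
  bg2 <- simulate_biomarkers_and_growth(truth2$samples, truth2$infants,
                                        cfg2, seed = 3)
  expect_lt(abs(sd(bg2$growth$weight_gain_gday) - 7.7), 0.45)
})

test_that("cohort simulation is reproducible and emits machine truth", {
  cfg <- cohort_config(n_per_arm = 4, n_genes = 10,
                       gene_length_range = c(300, 400), seed = 33)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))

  out <- tempfile("cohort")
  write_cohort(co1, out)
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_named(truth, c("fct_labels", "strain", "seed"),
               ignore.order = TRUE)
  expect_equal(length(truth$fct_labels),
               sum(!co1$truth$samples$missing))
  unlink(out, recursive = TRUE)
})

test_that("colonization truth hits its planted rates at scale", {
  cfg <- cohort_config(n_per_arm = 500, dropout_prob = 0, seed = 77)
  truth <- simulate_cohort_truth(cfg, seed = 77)
  s <- truth$samples
  v1 <- s[s$visit == "V1", ]
  expect_lt(abs(mean(!is.na(v1$strain)) - 0.16), 0.03)
  # none of the baseline strains are the probiotic
  expect_false(any(startsWith(v1$strain[!is.na(v1$strain)], "LMG")))
  eg <- s[s$arm != "CG" & s$visit %in% c("V2", "V3"), ]
  by_inf <- tapply(!is.na(eg$strain) & startsWith(
    ifelse(is.na(eg$strain), "", eg$strain), "LMG"), eg$infant_id, any)
  expect_lt(abs(mean(by_inf) - 0.787), 0.03)
})
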