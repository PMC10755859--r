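#' Cohort simulation configuration
#'
#' Returns the configuration object for [simulate_cohort()]. Defaults
#' encode the trial design the package targets: three arms (placebo CG
#' and two supplemented arms Lo-EG / Hi-EG) of 76 infants each, four
#' visits (V1 baseline, V2/V3 during supplementation, V4 four weeks
#' after cessation), feeding-mode mix 58% exclusively breastfed / 26%
#' mixed / 16% formula, baseline *B. infantis* prevalence 16%, probiotic
#' acquisition during the intervention 78.7% with feeding-dependent
#' post-cessation persistence (83.9% in EBF, 51.5% otherwise, ~70%
#' pooled), rare probiotic detections in the control arm (2% per visit,
#' emulating horizontal transmission), and a gradual expansion of
#' autochthonous strains.
#'
#' @param n_per_arm infants per arm (default 76).
#' @param arms,visits ordered labels.
#' @param feeding_probs named probabilities over EBF/mixed/formula.
#' @param dropout_prob per-visit probability that a sample is missing.
#' @param baseline_colonization probability of autochthonous
#'   colonization at V1.
#' @param auto_acquisition per-visit acquisition probability of an
#'   autochthonous strain for not-yet-colonized infants.
#' @param auto_persistence per-visit retention probability of an
#'   autochthonous strain.
#' @param probiotic_colonization probability an EG infant carries the
#'   probiotic at V2 and/or V3.
#' @param probiotic_v2_frac among colonized EG infants, probability the
#'   first detection is at V2 (rather than V3).
#' @param probiotic_intra_persistence probability a V2 coloniser is
#'   still colonized at V3.
#' @param persistence_prob named per-feeding-mode probability that an
#'   intervention coloniser is still colonized at V4.
#' @param leakage_prob per-visit probability of probiotic detection in
#'   the control arm during the intervention.
#' @param mixture_prob probability that an autochthonous sample carries
#'   two subclades at 50/50 (triggers the heterogeneous-profile rule).
#' @param abund_meanlog,abund_sdlog lognormal parameters of
#'   *B. infantis* relative abundance in colonized samples.
#' @param n_genes,gene_length_range catalog size passed to
#'   [simulate_catalog()].
#' @param n_autoch_subclades,snv_rate_between,snv_rate_within_probiotic
#'   passed to [simulate_strain_genomes()].
#' @param depth_per_unit_abundance per-position read depth at relative
#'   abundance 1 (default 5000, i.e. 50x coverage at 1% abundance).
#' @param error_rate per-base sequencing substitution error rate.
#' @param library_size genus-table multinomial library size.
#' @param group_effect named per-arm weight-gain shift in g/day
#'   (default 0: the null growth generator).
#' @param gain_mean,gain_sd weight-gain distribution in g/day.
#' @param baseline_weight_mean,baseline_weight_sd baseline weight (kg).
#' @param baseline_slope planted dependence of gain on baseline weight
#'   (g/day per kg); default 0.
#' @param sex_effect planted male-vs-female gain difference (g/day).
#' @param biomarker_noise_sd multiplier on the per-analyte noise SDs.
#' @param fct_nobi_tilt multiplicative tilt of the community-type
#'   mixing weights for infants never colonized by *B. infantis*
#'   (set to 1s for a null generator).
#' @param seed default master seed carried in the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 76,
                          arms = c("CG", "Lo-EG", "Hi-EG"),
                          visits = c("V1", "V2", "V3", "V4"),
                          feeding_probs = c(EBF = 0.58, mixed = 0.26,
                                            formula = 0.16),
                          dropout_prob = 0.02,
                          baseline_colonization = 0.16,
                          auto_acquisition = 0.03,
                          auto_persistence = 0.95,
                          probiotic_colonization = 0.787,
                          probiotic_v2_frac = 0.8,
                          probiotic_intra_persistence = 0.95,
                          persistence_prob = c(EBF = 0.839, mixed = 0.515,
                                               formula = 0.515),
                          leakage_prob = 0.02,
                          mixture_prob = 0.01,
                          abund_meanlog = log(0.02),
                          abund_sdlog = 1.5,
                          n_genes = 100,
                          gene_length_range = c(300, 1500),
                          n_autoch_subclades = 5,
                          snv_rate_between = 0.005,
                          snv_rate_within_probiotic = 1e-4,
                          depth_per_unit_abundance = 5000,
                          error_rate = 0.002,
                          library_size = 10000,
                          group_effect = c(CG = 0, `Lo-EG` = 0, `Hi-EG` = 0),
                          gain_mean = 35,
                          gain_sd = 7.7,
                          baseline_weight_mean = 3.5,
                          baseline_weight_sd = 0.4,
                          baseline_slope = 0,
                          sex_effect = 0,
                          biomarker_noise_sd = 1,
                          fct_nobi_tilt = c(0.7, 0.3, 2.5, 0.8, 2.0, 1.0),
                          seed = 1L) {
  if (abs(sum(feeding_probs) - 1) > 1e-8) {
    sf_stop("`feeding_probs` must sum to 1",
            class = "strainflow_invalid_argument")
  }
  check_count(n_per_arm, "n_per_arm")
  check_fraction(dropout_prob, "dropout_prob")
  check_fraction(probiotic_colonization, "probiotic_colonization")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d infants/arm x %d arms, visits %s\n",
                     "  probiotic colonization %.1f%%, persistence (EBF) ",
                     "%.1f%%, error rate %g\n"),
              x$n_per_arm, length(x$arms), paste(x$visits, collapse = ","),
              100 * x$probiotic_colonization,
              100 * x$persistence_prob[["EBF"]], x$error_rate))
  invisible(x)
}

#' Simulate per-infant colonization truth and metadata
#'
#' Draws the latent colonization process for every infant: feeding mode,
#' sex, delivery, autochthonous subclade dynamics, probiotic acquisition
#' and persistence, per-sample *B. infantis* relative abundance, and
#' missing visits. This is the ground truth every downstream recovery
#' test compares against.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `infants` (one row per infant) and `samples` (one
#'   row per infant x visit, including missing flags, planted strain
#'   identities, mixture flags, abundance, and the true strain category).
#' @export
simulate_cohort_truth <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    arms <- rep(config$arms, each = config$n_per_arm)
    n <- length(arms)
    infant_id <- sprintf("I%03d", seq_len(n))
    feeding <- sample(names(config$feeding_probs), n, replace = TRUE,
                      prob = config$feeding_probs)
    sex <- sample(c("male", "female"), n, replace = TRUE,
                  prob = c(0.53, 0.47))
    delivery <- sample(c("vaginal", "csection"), n, replace = TRUE,
                       prob = c(0.85, 0.15))
    subclade <- sprintf("auto%d",
                        sample.int(config$n_autoch_subclades, n,
                                   replace = TRUE))
    pro_variant <- sprintf("LMG11588_v%d", sample.int(8L, n, replace = TRUE))

    nv <- length(config$visits)
    # autochthonous colonization process (visit x infant logical matrix)
    auto <- matrix(FALSE, n, nv)
    auto[, 1] <- runif(n) < config$baseline_colonization
    for (v in 2:nv) {
      keep <- auto[, v - 1] & (runif(n) < config$auto_persistence)
      gain <- !auto[, v - 1] & (runif(n) < config$auto_acquisition)
      auto[, v] <- keep | gain
    }

    # probiotic process
    pro <- matrix(FALSE, n, nv)
    is_eg <- arms != config$arms[1]
    colonized <- is_eg & (runif(n) < config$probiotic_colonization)
    first_v2 <- runif(n) < config$probiotic_v2_frac
    pro[, 2] <- colonized & first_v2
    pro[, 3] <- colonized &
      ifelse(first_v2, runif(n) < config$probiotic_intra_persistence, TRUE)
    # control-arm leakage during intervention
    leak2 <- !is_eg & (runif(n) < config$leakage_prob)
    leak3 <- !is_eg & (runif(n) < config$leakage_prob)
    pro[, 2] <- pro[, 2] | leak2
    pro[, 3] <- pro[, 3] | leak3
    ever_pro <- pro[, 2] | pro[, 3]
    persist_p <- config$persistence_prob[feeding]
    pro[, 4] <- ever_pro & (runif(n) < persist_p)

    missing <- matrix(runif(n * nv) < config$dropout_prob, n, nv)

    rows <- vector("list", n * nv)
    k <- 0L
    for (i in seq_len(n)) {
      for (v in seq_len(nv)) {
        k <- k + 1L
        strain <- strain2 <- NA_character_
        mix_prop <- 1
        if (pro[i, v]) {
          strain <- pro_variant[i]
        } else if (auto[i, v]) {
          strain <- subclade[i]
          if (runif(1) < config$mixture_prob &&
              config$n_autoch_subclades > 1L) {
            other <- setdiff(sprintf("auto%d",
                                     seq_len(config$n_autoch_subclades)),
                             strain)
            strain2 <- sample(other, 1L)
            mix_prop <- 0.5
          }
        }
        abundance <- if (is.na(strain)) 0 else {
          min(rlnorm(1, config$abund_meanlog, config$abund_sdlog), 0.6)
        }
        rows[[k]] <- data.frame(
          sample_id = sprintf("%s_%s", infant_id[i], config$visits[v]),
          infant_id = infant_id[i], arm = arms[i], feeding = feeding[i],
          sex = sex[i], delivery = delivery[i], visit = config$visits[v],
          visit_index = v, missing = missing[i, v],
          strain = strain, strain2 = strain2, mix_prop = mix_prop,
          abundance = abundance, stringsAsFactors = FALSE
        )
      }
    }
    samples <- do.call(rbind, rows)
    samples$true_category <- true_category(samples,
                                           low_abund = 0.0016)
    list(
      infants = data.frame(infant_id = infant_id, arm = arms,
                           feeding = feeding, sex = sex,
                           delivery = delivery, subclade = subclade,
                           probiotic_variant = pro_variant,
                           stringsAsFactors = FALSE),
      samples = samples
    )
  })
}

#' True strain category implied by the planted truth
#' @noRd
true_category <- function(samples, low_abund = 0.0016) {
  ifelse(is.na(samples$strain), "NotDetected",
    ifelse(samples$abundance < low_abund, "UntypedLow",
      ifelse(!is.na(samples$strain2), "UntypedHet",
        ifelse(startsWith(samples$strain, "LMG11588"), "LMG11588",
               "OtherInfantis"))))
}

#' Simulate per-position allele counts over the signature-gene catalog
#'
#' Emulates the read-mapping output upstream of consensus strain typing.
#' Per-position depth is Poisson with mean
#' `depth_per_unit_abundance x abundance`; read counts per gene are
#' Poisson with mean coverage x length / read_length; base calls follow
#' the colonizing strain's base with uniform substitution errors at
#' `error_rate` (split over the three other bases). Mixture samples draw
#' each position's reads binomially between the two strains. Samples
#' with zero abundance receive no mapped reads.
#'
#' @param truth `samples` data.frame from [simulate_cohort_truth()] (or
#'   any frame with `sample_id`, `strain`, `strain2`, `mix_prop`,
#'   `abundance`); missing samples (column `missing`) are skipped.
#' @param genomes a [simulate_strain_genomes()] result.
#' @param catalog the matching [simulate_catalog()] result.
#' @param depth_per_unit_abundance coverage at abundance 1.
#' @param error_rate per-base substitution error rate, in \[0, 0.1\].
#' @param read_length nominal read length (bp) for the read-count model.
#' @param seed integer seed.
#' @return list of class `pileup_set`: `counts`
#'   (data.table: `sample_id`, `gene_id`, `pos` 0-based, `nA,nC,nG,nT`)
#'   and `read_counts` (data.table: `sample_id`, `gene_id`, `reads`).
#' @export
simulate_pileups <- function(truth, genomes, catalog,
                             depth_per_unit_abundance = 5000,
                             error_rate = 0.002, read_length = 100,
                             seed = NULL) {
  stopifnot(inherits(genomes, "strain_genomes"),
            inherits(catalog, "gene_catalog"))
  check_fraction(error_rate, "error_rate", 0, 0.1)
  if (depth_per_unit_abundance <= 0) {
    sf_stop("`depth_per_unit_abundance` must be positive",
            class = "strainflow_invalid_argument")
  }
  known <- names(genomes$seqs)
  used <- unique(c(truth$strain, truth$strain2))
  used <- used[!is.na(used)]
  if (length(bad <- setdiff(used, known))) {
    sf_stop(paste0("unknown strain id(s) in truth: ",
                   paste(bad, collapse = ", ")),
            class = "strainflow_missing_reference")
  }
  if ("missing" %in% names(truth)) truth <- truth[!truth$missing, ]
  gene_of <- catalog_gene_of(catalog)
  pos_within <- catalog_pos_within(catalog)
  L <- catalog$total_length

  with_seed(seed, {
    count_rows <- list()
    read_rows <- list()
    for (r in seq_len(nrow(truth))) {
      sid <- truth$sample_id[r]
      ab <- truth$abundance[r]
      cov <- depth_per_unit_abundance * ab
      if (is.na(truth$strain[r]) || cov <= 0) next
      depth <- rpois(L, cov)
      idx <- which(depth > 0L)
      if (!length(idx)) next
      d <- depth[idx]
      counts <- matrix(0L, length(idx), 4L)
      b1 <- genomes$seqs[[truth$strain[r]]][idx]
      if (!is.na(truth$strain2[r])) {
        n1 <- rbinom(length(idx), d, truth$mix_prop[r])
        counts <- add_base_counts(counts, b1, n1, error_rate)
        b2 <- genomes$seqs[[truth$strain2[r]]][idx]
        counts <- add_base_counts(counts, b2, d - n1, error_rate)
      } else {
        counts <- add_base_counts(counts, b1, d, error_rate)
      }
      count_rows[[length(count_rows) + 1L]] <- data.table::data.table(
        sample_id = sid, gene_id = gene_of[idx], pos = pos_within[idx],
        nA = counts[, 1], nC = counts[, 2], nG = counts[, 3],
        nT = counts[, 4]
      )
      reads <- rpois(nrow(catalog$genes),
                     cov * catalog$genes$length / read_length)
      read_rows[[length(read_rows) + 1L]] <- data.table::data.table(
        sample_id = sid, gene_id = catalog$genes$gene_id,
        reads = reads
      )
    }
    out <- list(
      counts = if (length(count_rows)) data.table::rbindlist(count_rows)
               else empty_pileup(),
      read_counts = if (length(read_rows)) data.table::rbindlist(read_rows)
                    else data.table::data.table(sample_id = character(),
                                                gene_id = character(),
                                                reads = integer())
    )
    class(out) <- "pileup_set"
    out
  })
}

#' @noRd
empty_pileup <- function() {
  data.table::data.table(sample_id = character(), gene_id = character(),
                         pos = integer(), nA = integer(), nC = integer(),
                         nG = integer(), nT = integer())
}

#' Add n reads of true base `b` (integer 1..4) with uniform errors
#' @noRd
add_base_counts <- function(counts, b, n, error_rate) {
  err <- rbinom(length(n), n, error_rate)
  correct <- n - err
  i <- seq_along(n)
  counts[cbind(i, b)] <- counts[cbind(i, b)] + correct
  if (any(err > 0L)) {
    e1 <- rbinom(length(n), err, 1 / 3)
    e2 <- rbinom(length(n), err - e1, 1 / 2)
    e3 <- err - e1 - e2
    o1 <- (b %% 4L) + 1L
    o2 <- (o1 %% 4L) + 1L
    o3 <- (o2 %% 4L) + 1L
    counts[cbind(i, o1)] <- counts[cbind(i, o1)] + e1
    counts[cbind(i, o2)] <- counts[cbind(i, o2)] + e2
    counts[cbind(i, o3)] <- counts[cbind(i, o3)] + e3
  }
  counts
}

#' Default Dirichlet-multinomial mixture parameters (six community types)
#'
#' Six components over ten genera emulating the community types seen in
#' early infancy: an early skin/facultative-anaerobe type, a
#' *Bifidobacterium*-dominated type, a *Bifidobacterium*+*Escherichia*
#' type, a *Bacteroides*-rich type, an *Escherichia*+*Streptococcus*
#' type and a late diverse Clostridia-rich type. `visit_weights` give
#' each component's prevalence per visit (components are chronologically
#' ordered by construction).
#'
#' @param concentration Dirichlet precision of each component.
#' @return list with `alpha` (K x G matrix), `visit_weights` (V x K) and
#'   `genera`.
#' @export
default_dmm_params <- function(concentration = 35) {
  genera <- c("Bifidobacterium", "Escherichia", "Streptococcus",
              "Staphylococcus", "Klebsiella", "Bacteroides", "Veillonella",
              "Enterococcus", "Clostridium", "Lachnospiraceae_unclassified")
  means <- rbind(
    c(0.10, 0.25, 0.20, 0.20, 0.10, 0.02, 0.05, 0.05, 0.02, 0.01),
    c(0.70, 0.05, 0.05, 0.01, 0.03, 0.03, 0.05, 0.03, 0.03, 0.02),
    c(0.40, 0.35, 0.05, 0.02, 0.05, 0.03, 0.04, 0.03, 0.02, 0.01),
    c(0.20, 0.10, 0.08, 0.02, 0.05, 0.35, 0.08, 0.05, 0.04, 0.03),
    c(0.10, 0.40, 0.30, 0.02, 0.06, 0.03, 0.04, 0.02, 0.02, 0.01),
    c(0.15, 0.10, 0.10, 0.01, 0.05, 0.15, 0.10, 0.05, 0.15, 0.14)
  )
  alpha <- means * concentration
  colnames(alpha) <- genera
  visit_weights <- rbind(
    c(0.40, 0.22, 0.15, 0.10, 0.08, 0.05),
    c(0.08, 0.34, 0.22, 0.14, 0.14, 0.08),
    c(0.03, 0.20, 0.20, 0.18, 0.26, 0.13),
    c(0.01, 0.12, 0.13, 0.16, 0.28, 0.30)
  )
  rownames(visit_weights) <- c("V1", "V2", "V3", "V4")
  list(alpha = alpha, visit_weights = visit_weights, genera = genera)
}

#' Simulate genus-level count tables from a known DMM
#'
#' Inverts the community-typing model: each sample's genus proportions
#' are drawn from the Dirichlet component of its true label and counts
#' from a multinomial at `library_size`.
#'
#' @param labels integer vector of true component labels (one per
#'   sample, values in `1..K`), optionally named by sample id.
#' @param dmm_params list with `alpha`, a K x G matrix of strictly
#'   positive Dirichlet parameters (see [default_dmm_params()]).
#' @param library_size total counts per sample (>= 1).
#' @param seed integer seed.
#' @return integer matrix samples x genera with `labels` kept in
#'   attribute `"true_labels"`.
#' @export
simulate_genus_tables <- function(labels, dmm_params, library_size = 10000,
                                  seed = NULL) {
  alpha <- dmm_params$alpha
  if (is.null(dim(alpha)) || ncol(alpha) < 1L) {
    sf_stop("`dmm_params$alpha` must be a K x G matrix",
            class = "strainflow_invalid_argument")
  }
  if (any(alpha <= 0)) {
    sf_stop("Dirichlet parameters must be strictly positive",
            class = "strainflow_invalid_argument")
  }
  check_count(library_size, "library_size")
  if (any(labels < 1L | labels > nrow(alpha))) {
    sf_stop("labels must index rows of alpha",
            class = "strainflow_invalid_argument")
  }
  with_seed(seed, {
    n <- length(labels)
    counts <- matrix(0L, n, ncol(alpha),
                     dimnames = list(names(labels), colnames(alpha)))
    for (i in seq_len(n)) {
      p <- rdirichlet(1, alpha[labels[i], ])[1, ]
      counts[i, ] <- rmultinom(1, library_size, p)[, 1]
    }
    attr(counts, "true_labels") <- labels
    counts
  })
}

#' Per-analyte assay limits used by the biomarker generator
#' @noRd
biomarker_panel <- function() {
  data.frame(
    analyte = c("acetate", "AAT", "calprotectin", "sIgA",
                "IL1b", "IL8", "IFNg"),
    base = c(60, 0.8, 250, 2.5, 40, 120, 3),
    slope = c(8, 0.12, 35, 0.5, -8, -25, -0.9),
    sd = c(15, 0.25, 80, 1.0, 15, 50, 1.5),
    lld = c(1, 0.05, 10, 0.1, 2, 5, 0.25),
    lod = c(0.5, 0.02, 5, 0.05, 1, 2, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Simulate biomarker and growth outcomes
#'
#' Biomarkers depend monotonically on log10 *B. infantis* abundance with
#' Gaussian noise: acetate, alpha-1-antitrypsin (AAT), calprotectin and
#' sIgA increase with abundance; IL-1b, IL-8 and IFN-g decrease.
#' Weight: baseline ~ N(3.5, 0.4^2) kg and daily gain ~
#' N(35 + group effect, 7.7^2) g/day over the 56-day intervention, with
#' optional planted baseline-weight and sex effects for ANCOVA recovery
#' tests.
#'
#' @param samples sample-level truth (needs `sample_id`, `infant_id`,
#'   `visit`, `abundance`, `missing`).
#' @param infants infant-level frame (needs `infant_id`, `arm`, `sex`).
#' @param config a [cohort_config()] supplying `group_effect`,
#'   `gain_mean`, `gain_sd`, `baseline_weight_*`, `baseline_slope`,
#'   `sex_effect`, `biomarker_noise_sd`.
#' @param seed integer seed.
#' @return list with `biomarkers` (per-sample analyte values),
#'   `limits` (per-analyte LLD/LOD), and `growth` (per-infant baseline
#'   weight, gain in g/day, V3 weight).
#' @export
simulate_biomarkers_and_growth <- function(samples, infants,
                                           config = cohort_config(),
                                           seed = NULL) {
  panel <- biomarker_panel()
  with_seed(seed, {
    keep <- if ("missing" %in% names(samples)) !samples$missing
            else rep(TRUE, nrow(samples))
    s <- samples[keep, , drop = FALSE]
    z <- log10(s$abundance + 1e-5)
    z <- z - mean(z)
    bio <- data.frame(sample_id = s$sample_id, infant_id = s$infant_id,
                      visit = s$visit, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(panel))) {
      noise <- rnorm(nrow(s), 0, panel$sd[j] * config$biomarker_noise_sd)
      val <- panel$base[j] + panel$slope[j] * z + noise
      bio[[panel$analyte[j]]] <- pmax(val, 0)
    }
    ge <- config$group_effect[infants$arm]
    ge[is.na(ge)] <- 0
    baseline <- rnorm(nrow(infants), config$baseline_weight_mean,
                      config$baseline_weight_sd)
    gain <- rnorm(nrow(infants),
                  config$gain_mean + ge +
                    config$baseline_slope *
                      (baseline - config$baseline_weight_mean) +
                    config$sex_effect * (infants$sex == "male"),
                  config$gain_sd)
    growth <- data.frame(
      infant_id = infants$infant_id, arm = infants$arm, sex = infants$sex,
      baseline_weight_kg = baseline,
      weight_gain_gday = gain,
      weight_v3_kg = baseline + gain * 56 / 1000,
      stringsAsFactors = FALSE
    )
    list(biomarkers = bio,
         limits = panel[, c("analyte", "lld", "lod")],
         growth = growth)
  })
}

#' Assign true fecal community types chronologically
#' @noRd
assign_fct_truth <- function(samples, dmm_params, tilt = NULL) {
  vw <- dmm_params$visit_weights
  k <- ncol(vw)
  labels <- integer(nrow(samples))
  # infants never colonized by B. infantis get tilted community mixing
  nobi <- tapply(samples$abundance, samples$infant_id,
                 function(a) all(a == 0))
  for (i in seq_len(nrow(samples))) {
    w <- vw[samples$visit[i], ]
    if (!is.null(tilt) && isTRUE(nobi[[samples$infant_id[i]]])) {
      w <- w * tilt
    }
    labels[i] <- sample.int(k, 1L, prob = w / sum(w))
  }
  names(labels) <- samples$sample_id
  labels
}

#' Simulate a full synthetic trial cohort
#'
#' Orchestrates all generators: catalog, strain genomes, colonization
#' truth, allele-count pileups, genus count tables with true community
#' types, biomarkers and growth. All randomness derives from
#' `config$seed` (or the `seed` argument) via fixed stream offsets, so
#' identical configurations reproduce byte-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed master seed (overrides `config$seed` if given).
#' @param with_pileups set `FALSE` to skip the (largest) pileup stage.
#' @return list of class `synthetic_cohort` with elements `catalog`,
#'   `genomes`, `truth` (infants + samples), `pileups`, `genus_counts`,
#'   `fct_truth`, `biomarkers`, `limits`, `growth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL,
                            with_pileups = TRUE) {
  seed <- seed %||% config$seed
  catalog <- simulate_catalog(config$n_genes, config$gene_length_range,
                              seed = child_seed(seed, 1))
  genomes <- simulate_strain_genomes(
    catalog, n_autoch_subclades = config$n_autoch_subclades,
    snv_rate_between = config$snv_rate_between,
    snv_rate_within_probiotic = config$snv_rate_within_probiotic,
    seed = child_seed(seed, 2)
  )
  truth <- simulate_cohort_truth(config, seed = child_seed(seed, 3))
  pileups <- if (with_pileups) {
    simulate_pileups(truth$samples, genomes, catalog,
                     depth_per_unit_abundance =
                       config$depth_per_unit_abundance,
                     error_rate = config$error_rate,
                     seed = child_seed(seed, 4))
  }
  dmm <- default_dmm_params()
  present <- truth$samples[!truth$samples$missing, ]
  fct_truth <- with_seed(child_seed(seed, 5),
                         assign_fct_truth(present, dmm,
                                          tilt = config$fct_nobi_tilt))
  genus_counts <- simulate_genus_tables(fct_truth, dmm,
                                        library_size = config$library_size,
                                        seed = child_seed(seed, 6))
  bg <- simulate_biomarkers_and_growth(truth$samples, truth$infants, config,
                                       seed = child_seed(seed, 7))
  out <- list(catalog = catalog, genomes = genomes, truth = truth,
              pileups = pileups, genus_counts = genus_counts,
              fct_truth = fct_truth, biomarkers = bg$biomarkers,
              limits = bg$limits, growth = bg$growth, config = config,
              dmm_params = dmm, seed = seed)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d infants, %d samples present, seed %s\n",
    nrow(x$truth$infants), sum(!x$truth$samples$missing),
    format(x$seed)))
  invisible(x)
}
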