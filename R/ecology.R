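#' Aggregate infant-type bifidobacteria
#'
#' Sums the per-sample relative abundances of the four infant-adapted
#' *Bifidobacterium* species: *B. longum* (both subspecies), *B. breve*,
#' *B. bifidum* and *B. scardovii*. Species absent from the table
#' contribute zero (warned once).
#'
#' @param table samples x taxa relative-abundance matrix or data.frame
#'   with taxon columns.
#' @param species character vector of column names to sum; columns whose
#'   name starts with an entry followed by `"_"` (e.g. subspecies
#'   `B.longum_infantis`) are included.
#' @return numeric vector of per-sample summed abundance.
#' @export
aggregate_infant_type_bifido <- function(table,
                                         species = c("B.longum", "B.breve",
                                                     "B.bifidum",
                                                     "B.scardovii")) {
  tab <- as.matrix(table)
  hit <- rep(FALSE, ncol(tab))
  found <- logical(length(species))
  for (i in seq_along(species)) {
    m <- colnames(tab) == species[i] |
      startsWith(colnames(tab), paste0(species[i], "_"))
    found[i] <- any(m)
    hit <- hit | m
  }
  if (any(!found)) {
    warning("species absent from taxonomy (contribute 0): ",
            paste(species[!found], collapse = ", "))
  }
  if (!any(hit)) return(setNames(rep(0, nrow(tab)), rownames(tab)))
  rowSums(tab[, hit, drop = FALSE])
}

#' Alpha diversity (richness and Shannon)
#'
#' @param table samples x taxa abundance matrix (relative or counts).
#' @return data.frame with `richness` (taxa with abundance > 0) and
#'   `shannon` (natural-log Shannon index over nonzero proportions;
#'   all-zero samples get 0 and are flagged).
#' @export
alpha_diversity <- function(table) {
  tab <- as.matrix(table)
  richness <- rowSums(tab > 0)
  shannon <- apply(tab, 1, function(x) {
    s <- sum(x)
    if (s <= 0) return(0)
    p <- x[x > 0] / s
    -sum(p * log(p))
  })
  data.frame(sample_id = rownames(tab) %||% seq_len(nrow(tab)),
             richness = as.integer(richness), shannon = shannon,
             all_zero = rowSums(tab) <= 0,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = 1 - sum(min(a_i, b_i)) / ((sum a + sum b) / 2)`; for
#' rows normalized to 1 this reduces to `1 - sum(min)`. Zero-sum
#' samples yield undefined (`NA`) pairs, flagged with a warning.
#'
#' @param table samples x taxa abundance matrix.
#' @return symmetric matrix of class `dissimilarity_matrix`.
#' @export
bray_curtis <- function(table) {
  tab <- as.matrix(table)
  zero <- rowSums(tab) <= 0
  # vegdist warns on empty rows; we flag them explicitly below
  d <- as.matrix(suppressWarnings(vegan::vegdist(tab, method = "bray")))
  if (any(zero)) {
    warning("zero-sum sample(s); their dissimilarities are undefined")
    d[zero, ] <- NA_real_
    d[, zero] <- NA_real_
    diag(d) <- 0
  }
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' PERMANOVA with marginal terms
#'
#' Permutational multivariate ANOVA on a dissimilarity matrix with
#' 1,000 permutations by default and marginal (`by = "margin"`) effects,
#' i.e. each term assessed in a model containing all other terms. The
#' p-value uses the add-one rule
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so it is never
#' exactly zero.
#'
#' @param dist a dissimilarity matrix (or `dist`).
#' @param metadata data.frame aligned with the rows of `dist`.
#' @param terms character vector of metadata column names.
#' @param n_perm number of permutations (default 1000).
#' @param marginal assess marginal effects (default) or sequential.
#' @param seed integer seed; permutations are reproducible.
#' @return data.frame with one row per term: `df`, `R2`, `F`, `p`.
#' @export
permanova <- function(dist, metadata, terms, n_perm = 1000,
                      marginal = TRUE, seed = NULL) {
  if (!all(terms %in% names(metadata))) {
    sf_stop("terms missing from metadata",
            class = "strainflow_invalid_argument")
  }
  if (anyNA(metadata[, terms, drop = FALSE])) {
    sf_stop("metadata incomplete for the samples in `dist`",
            class = "strainflow_invalid_argument")
  }
  d <- stats::as.dist(dist)
  fml <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  res <- with_seed(seed, vegan::adonis2(
    fml, data = metadata, permutations = n_perm,
    by = if (marginal) "margin" else "terms"))
  keep <- rownames(res) %in% terms
  data.frame(term = rownames(res)[keep], df = res$Df[keep],
             R2 = res$R2[keep], F = res$F[keep],
             p = res$`Pr(>F)`[keep], stringsAsFactors = FALSE)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered dissimilarity matrix; axes
#' sorted by descending eigenvalue and negative eigenvalues reported.
#'
#' @param dist dissimilarity matrix or `dist`.
#' @param k number of axes to return (default all positive).
#' @return list with `coordinates` (n x k), `eigenvalues` (all, sorted
#'   descending) and `relative_eig` over positive eigenvalues.
#' @export
pcoa <- function(dist, k = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  # negative eigenvalues are expected for non-Euclidean dissimilarities
  cm <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- cm$eig
  npos <- sum(eig > 1e-10)
  k <- min(k %||% npos, npos)
  list(coordinates = cm$points[, seq_len(k), drop = FALSE],
       eigenvalues = eig,
       relative_eig = pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' Symmetric Procrustes correlation with permutation test
#'
#' Procrustes superimposition of two ordinations after centering and
#' scaling; the correlation is `sqrt(1 - m2)` where `m2` is the
#' symmetric Procrustes residual sum of squares. Significance by
#' permutation of the rows of `coords_b` (add-one rule).
#'
#' @param coords_a,coords_b matrices with matching rows (same samples).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `correlation`, `m2`, `p`, `n_perm`.
#' @export
procrustes_correlation <- function(coords_a, coords_b, n_perm = 999,
                                   seed = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) {
    sf_stop("coordinate sets must contain the same samples",
            class = "strainflow_invalid_argument")
  }
  if (nrow(a) < 3) {
    sf_stop("Procrustes needs at least 3 samples",
            class = "strainflow_invalid_argument")
  }
  res <- with_seed(seed,
                   vegan::protest(a, b, permutations = n_perm))
  list(correlation = sqrt(1 - res$ss), m2 = res$ss,
       p = res$signif, n_perm = res$permutations)
}

#' Kendall taxon-biomarker association matrix
#'
#' Tau-b rank correlations (tie-corrected) between each retained taxon
#' and each biomarker, with Benjamini-Hochberg adjustment across the
#' full matrix. Taxa are retained when their mean relative abundance is
#' at least `min_mean_abundance` or they are nominated explicitly
#' (e.g. *Bifidobacterium* taxa of interest). Adjusted p-values below
#' 0.1 are marked significant.
#'
#' @param taxa samples x taxa abundance matrix.
#' @param biomarkers samples x analyte matrix/data.frame (numeric),
#'   rows aligned with `taxa`.
#' @param min_mean_abundance retention threshold (default 0.01).
#' @param nominate taxa always retained regardless of abundance.
#' @param sig_level adjusted-p significance band (default 0.1).
#' @return data.frame with `taxon`, `analyte`, `tau`, `p`, `p_adj`,
#'   `significant`; constant vectors give `NA` tau with a flag.
#' @export
kendall_associations <- function(taxa, biomarkers,
                                 min_mean_abundance = 0.01,
                                 nominate = character(0),
                                 sig_level = 0.1) {
  taxa <- as.matrix(taxa)
  bio <- as.matrix(biomarkers)
  keep <- colMeans(taxa) >= min_mean_abundance |
    colnames(taxa) %in% nominate
  taxa <- taxa[, keep, drop = FALSE]
  grid <- expand.grid(taxon = colnames(taxa), analyte = colnames(bio),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- taxa[, grid$taxon[i]]
    y <- bio[, grid$analyte[i]]
    ok <- complete.cases(x, y)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(data.frame(tau = NA_real_, p = NA_real_, constant = TRUE))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "kendall"))
    data.frame(tau = unname(ct$estimate), p = ct$p.value,
               constant = FALSE)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < sig_level
  out
}

#' Pathogen prevalence at sample and infant grain
#'
#' @param detection samples x taxa logical (or 0/1) detection matrix.
#' @param infant_map named vector mapping `sample_id` to `infant_id`.
#' @return data.frame per taxon: positive sample and infant counts and
#'   percentages (an infant is positive if any of its samples is;
#'   infants with zero samples are excluded from the denominator).
#' @export
pathogen_prevalence <- function(detection, infant_map) {
  det <- as.matrix(detection) > 0
  sids <- rownames(det)
  if (is.null(sids)) {
    sf_stop("detection table needs sample_id rownames",
            class = "strainflow_invalid_argument")
  }
  infants <- infant_map[sids]
  n_samples <- nrow(det)
  n_infants <- length(unique(infants[!is.na(infants)]))
  out <- lapply(colnames(det), function(tx) {
    pos_s <- sum(det[, tx])
    pos_i <- length(unique(infants[det[, tx] & !is.na(infants)]))
    data.frame(taxon = tx, positive_samples = pos_s,
               pct_samples = 100 * pos_s / n_samples,
               positive_infants = pos_i,
               pct_infants = 100 * pos_i / n_infants,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
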