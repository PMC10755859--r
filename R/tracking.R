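#' Build per-infant strain trajectories
#'
#' Joins sample-level strain categories with infant metadata into one
#' row per infant with one (possibly missing) category per visit.
#'
#' @param classes data.frame with `sample_id` and `category` (from
#'   [type_strains()] or equivalent).
#' @param meta data.frame with `sample_id`, `infant_id`, `arm`,
#'   `feeding`, `visit` for every collected sample; samples absent from
#'   `classes` (or flagged `missing`) become `NA` visits.
#' @param visits ordered visit labels.
#' @return data.frame of class `infant_trajectories`: `infant_id`,
#'   `arm`, `feeding`, then one category column per visit.
#' @export
track_trajectories <- function(classes, meta,
                               visits = c("V1", "V2", "V3", "V4")) {
  if ("missing" %in% names(meta)) meta <- meta[!meta$missing, ]
  m <- merge(meta[, c("sample_id", "infant_id", "arm", "feeding", "visit")],
             classes[, c("sample_id", "category")],
             by = "sample_id", all.x = TRUE)
  infants <- unique(m[, c("infant_id", "arm", "feeding")])
  infants <- infants[order(infants$infant_id), , drop = FALSE]
  out <- infants
  for (v in visits) {
    mv <- m[m$visit == v, c("infant_id", "category")]
    out[[v]] <- mv$category[match(out$infant_id, mv$infant_id)]
  }
  rownames(out) <- NULL
  class(out) <- c("infant_trajectories", "data.frame")
  attr(out, "visits") <- visits
  out
}

#' Detection rate of a category set at a visit
#'
#' Fraction of infants whose strain category at `visit` lies in
#' `categories`. Infants with a missing sample at that visit are
#' excluded from the denominator by default.
#'
#' @param traj an [track_trajectories()] result.
#' @param visit visit label.
#' @param categories character vector of categories counted as
#'   "detected" (e.g. `c("LMG11588", "OtherInfantis", "UntypedLow",
#'   "UntypedHet")` for any *B. infantis*).
#' @param by optional grouping column (`"arm"` or `"feeding"`).
#' @param include_missing if `TRUE`, missing visits stay in the
#'   denominator.
#' @return data.frame with group (if any), `n` (denominator), `k`
#'   (detected) and `rate`; rate is `NA` for empty groups.
#' @export
detection_rate <- function(traj, visit,
                           categories = c("LMG11588", "OtherInfantis",
                                          "UntypedLow", "UntypedHet"),
                           by = NULL, include_missing = FALSE) {
  if (!visit %in% attr(traj, "visits")) {
    sf_stop(sprintf("unknown visit '%s'", visit),
            class = "strainflow_invalid_argument")
  }
  cat_v <- traj[[visit]]
  usable <- if (include_missing) rep(TRUE, nrow(traj)) else !is.na(cat_v)
  hit <- !is.na(cat_v) & cat_v %in% categories
  grp <- if (is.null(by)) rep("all", nrow(traj)) else traj[[by]]
  agg <- data.frame(group = sort(unique(grp)), stringsAsFactors = FALSE)
  agg$n <- vapply(agg$group, function(g) sum(usable & grp == g), integer(1))
  agg$k <- vapply(agg$group, function(g) sum(hit & usable & grp == g),
                  integer(1))
  agg$rate <- ifelse(agg$n > 0, agg$k / agg$n, NA_real_)
  if (is.null(by)) agg$group <- NULL
  agg
}

#' Probiotic colonization during the intervention
#'
#' `TRUE` iff the infant's category is `LMG11588` at V2 and/or V3;
#' `NA` (excluded from denominators) when both intervention visits are
#' missing.
#'
#' @param traj an [track_trajectories()] result.
#' @return logical vector, one element per infant.
#' @export
colonized_during_intervention <- function(traj) {
  v2 <- traj[["V2"]]
  v3 <- traj[["V3"]]
  hit <- (!is.na(v2) & v2 == "LMG11588") | (!is.na(v3) & v3 == "LMG11588")
  hit[is.na(v2) & is.na(v3)] <- NA
  hit
}

#' Post-cessation persistence rate of the probiotic strain
#'
#' Among infants colonized by the probiotic during the intervention and
#' with a typed V4 sample, the fraction still `LMG11588` at V4 (a V4
#' `OtherInfantis` counts as replacement, i.e. non-persistent).
#'
#' @param traj an [track_trajectories()] result.
#' @return list with `rate`, `n` (eligible infants) and `k`
#'   (persistent); `rate` is `NA` when no infant is eligible.
#' @export
persistence_rate <- function(traj) {
  col <- colonized_during_intervention(traj)
  v4 <- traj[["V4"]]
  eligible <- !is.na(col) & col & !is.na(v4)
  k <- sum(eligible & v4 == "LMG11588")
  n <- sum(eligible)
  list(rate = if (n > 0) k / n else NA_real_, n = n, k = k)
}

#' Strain replacement events between consecutive visits
#'
#' Counts infants with at least one direct transition between typed
#' strain categories on consecutive visits. Untyped or missing visits
#' break adjacency: no event is inferred across them.
#'
#' @param traj an [track_trajectories()] result.
#' @return list with `probiotic_to_other` and `other_to_probiotic`
#'   infant counts.
#' @export
replacement_events <- function(traj) {
  visits <- attr(traj, "visits")
  p2o <- o2p <- 0L
  for (i in seq_len(nrow(traj))) {
    cats <- unlist(traj[i, visits], use.names = FALSE)
    saw_p2o <- saw_o2p <- FALSE
    for (v in seq_len(length(visits) - 1L)) {
      a <- cats[v]; b <- cats[v + 1L]
      if (is.na(a) || is.na(b)) next
      if (a == "LMG11588" && b == "OtherInfantis") saw_p2o <- TRUE
      if (a == "OtherInfantis" && b == "LMG11588") saw_o2p <- TRUE
    }
    p2o <- p2o + saw_p2o
    o2p <- o2p + saw_o2p
  }
  list(probiotic_to_other = p2o, other_to_probiotic = o2p)
}

#' Chi-square test of category x group contingency
#'
#' Pearson chi-square on a category-by-group count table, with an
#' optional Monte-Carlo p-value for sparse tables. Zero-margin rows and
#' columns are dropped with a warning.
#'
#' @param tab matrix of non-negative counts (categories x groups), or a
#'   pair of factors via `table()`.
#' @param monte_carlo use a Monte-Carlo p-value.
#' @param n_mc Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo draw.
#' @return list with `statistic`, `df`, `p`, and `method`.
#' @export
category_group_test <- function(tab, monte_carlo = FALSE, n_mc = 2000,
                                seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) {
    sf_stop("counts must be non-negative",
            class = "strainflow_invalid_argument")
  }
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(statistic = 0, df = 0L, p = 1, method = "degenerate"))
  }
  res <- with_seed(seed, suppressWarnings(
    chisq.test(tab, correct = FALSE, simulate.p.value = monte_carlo,
               B = n_mc)))
  list(statistic = unname(res$statistic),
       df = if (monte_carlo) NA_integer_ else unname(res$parameter),
       p = res$p.value,
       method = if (monte_carlo) "monte-carlo" else "pearson")
}

#' Summarize a cohort's colonization statistics
#'
#' Convenience wrapper reporting the headline tracking quantities:
#' baseline detection of any *B. infantis*, probiotic colonization
#' during the intervention in the supplemented arms, post-cessation
#' persistence, and replacement events.
#'
#' @param traj an [track_trajectories()] result.
#' @param eg_arms labels of the supplemented arms.
#' @return list of rates and counts (denominators included).
#' @export
tracking_summary <- function(traj, eg_arms = c("Lo-EG", "Hi-EG")) {
  baseline <- detection_rate(traj, "V1")
  eg <- traj[traj$arm %in% eg_arms, , drop = FALSE]
  class(eg) <- class(traj)
  attr(eg, "visits") <- attr(traj, "visits")
  col <- colonized_during_intervention(eg)
  pers <- persistence_rate(eg)
  repl <- replacement_events(eg)
  list(
    baseline_detection = baseline,
    intervention_colonization = list(
      rate = mean(col, na.rm = TRUE), n = sum(!is.na(col)),
      k = sum(col, na.rm = TRUE)),
    persistence = pers,
    replacement = repl
  )
}
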