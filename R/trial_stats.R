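#' ANCOVA-adjusted group means with Tukey-adjusted pairwise differences
#'
#' Least-squares fit of `outcome ~ group + covariates`; adjusted means
#' are evaluated at the covariate grand means (least-squares means).
#' Pairwise-difference confidence intervals use the studentized-range
#' (Tukey) quantile at the residual degrees of freedom (Tukey-Kramer
#' for unbalanced designs, as implemented in emmeans); unadjusted
#' standard errors are also returned for one-sided non-inferiority
#' testing against a margin.
#'
#' @param data data.frame.
#' @param outcome,group column names (group is coerced to factor).
#' @param covariates character vector of covariate columns (e.g.
#'   baseline value and sex); rows with missing values are dropped with
#'   a message.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `ancova_fit`: `adjusted_means` (per group:
#'   emmean, SE, CI), `differences` (per pair: estimate, Tukey-adjusted
#'   CI, unadjusted SE, df), `fit` (the `lm`), `n_used`.
#' @export
ancova_adjusted_means <- function(data, outcome, group,
                                  covariates = character(0),
                                  conf_level = 0.95) {
  cols <- c(outcome, group, covariates)
  if (!all(cols %in% names(data))) {
    sf_stop("missing columns in `data`",
            class = "strainflow_invalid_argument")
  }
  cc <- complete.cases(data[, cols, drop = FALSE])
  if (!all(cc)) message(sum(!cc), " row(s) with missing values dropped")
  d <- data[cc, cols, drop = FALSE]
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) < 2) {
    sf_stop("need at least 2 groups", class = "strainflow_invalid_argument")
  }
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    sf_stop(paste0("rank-deficient design; aliased: ",
                   paste(names(coef(fit))[is.na(coef(fit))],
                         collapse = ", ")),
            class = "strainflow_invalid_argument")
  }
  emm <- emmeans::emmeans(fit, specs = group, level = conf_level)
  means <- as.data.frame(emm)
  names(means)[1] <- "group"
  prs <- emmeans::contrast(emm, method = "pairwise")
  tukey <- as.data.frame(stats::confint(prs, level = conf_level,
                                        adjust = "tukey"))
  unadj <- as.data.frame(summary(prs, adjust = "none", infer = TRUE))
  differences <- data.frame(
    comparison = tukey$contrast,
    estimate = tukey$estimate,
    lower = tukey$lower.CL,
    upper = tukey$upper.CL,
    se = unadj$SE,
    df = unadj$df,
    p_unadjusted = unadj$p.value,
    stringsAsFactors = FALSE
  )
  structure(list(adjusted_means = means, differences = differences,
                 fit = fit, n_used = nrow(d), conf_level = conf_level),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("<ancova_fit> n=%d\nAdjusted means:\n", x$n_used))
  print(x$adjusted_means, row.names = FALSE)
  cat("Pairwise differences (Tukey-adjusted CIs):\n")
  print(x$differences, row.names = FALSE)
  invisible(x)
}

#' Non-inferiority decision against a margin
#'
#' Non-inferiority is concluded iff the lower bound of the two-sided
#' 95% confidence interval of the group difference strictly exceeds the
#' margin (default -3.6 g/day); a lower bound exactly at the margin is
#' *not* non-inferior. The one-sided p-value tests H0: difference <=
#' margin using the same fit's estimate and standard error when
#' available (normal approximation from the CI half-width otherwise).
#'
#' @param estimate point estimate of the difference.
#' @param lower,upper two-sided CI bounds.
#' @param margin non-inferiority margin (default -3.6).
#' @param se,df optional standard error and residual df of the estimate
#'   for an exact t-based p-value.
#' @return list with `non_inferior` (logical), `p`, `margin`, `lower`.
#' @export
noninferiority_decision <- function(estimate, lower, upper = NA,
                                    margin = -3.6, se = NULL, df = Inf) {
  decision <- lower > margin
  if (is.null(se)) {
    se <- if (!is.na(upper)) (upper - lower) / (2 * qnorm(0.975))
          else NA_real_
  }
  p <- if (is.na(se) || se <= 0) NA_real_
       else pt((estimate - margin) / se, df, lower.tail = FALSE)
  list(non_inferior = decision, p = p, margin = margin, lower = lower)
}

#' Sample size for a non-inferiority comparison of means
#'
#' `n0 = 2 (z_{1-alpha} + z_{power})^2 sd^2 / margin^2` per group
#' (normal approximation, one-sided alpha), rounded up, then inflated
#' by `1 / (1 - attrition)` and rounded up again.
#'
#' @param margin non-inferiority margin (nonzero, same units as sd).
#' @param sd outcome standard deviation.
#' @param alpha one-sided type-I error (default 0.025).
#' @param power target power.
#' @param attrition expected attrition fraction.
#' @return list with `n_raw` and `n_per_group` (inflated).
#' @export
sample_size_noninferiority <- function(margin, sd, alpha = 0.025,
                                       power = 0.80, attrition = 0) {
  if (margin == 0) {
    sf_stop("`margin` must be nonzero",
            class = "strainflow_invalid_argument")
  }
  if (sd <= 0 || power <= 0 || power >= 1) {
    sf_stop("invalid sd or power", class = "strainflow_invalid_argument")
  }
  check_fraction(attrition, "attrition", 0, 0.99)
  n0 <- ceiling(2 * (qnorm(1 - alpha) + qnorm(power))^2 * sd^2 / margin^2)
  list(n_raw = n0, n_per_group = ceiling(n0 / (1 - attrition)))
}

#' Relative risk with log-normal confidence interval
#'
#' `RR = (a/n1) / (b/n2)` with
#' `CI = exp(log RR +/- z sqrt(1/a - 1/n1 + 1/b - 1/n2))`. When either
#' event count is zero, a 0.5 continuity correction is applied to all
#' four cells and flagged.
#'
#' @param a,n1 events and total in the exposed group.
#' @param b,n2 events and total in the reference group.
#' @param conf_level confidence level.
#' @return list with `rr`, `lower`, `upper`, `continuity_corrected`.
#' @export
relative_risk <- function(a, n1, b, n2, conf_level = 0.95) {
  if (n1 <= 0 || n2 <= 0) {
    sf_stop("group sizes must be positive",
            class = "strainflow_invalid_argument")
  }
  corrected <- a == 0 || b == 0
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 0.5; n2 <- n2 + 0.5
  }
  rr <- (a / n1) / (b / n2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  list(rr = rr, lower = rr * exp(-z * se), upper = rr * exp(z * se),
       continuity_corrected = corrected)
}

#' Freeman-Halton exact test for r x c contingency tables
#'
#' Generalization of Fisher's exact test: the p-value sums the
#' conditional (fixed-margins, multivariate hypergeometric)
#' probabilities of all tables no more probable than the observed one.
#' Tables are enumerated exactly when the candidate count is within
#' `max_tables` (<= 1e6 by default); otherwise a Monte-Carlo estimate
#' with Patefield-sampled margin-fixed tables and the add-one rule is
#' used.
#'
#' @param tab matrix of non-negative integer counts.
#' @param n_mc Monte-Carlo table draws (used only when enumeration is
#'   infeasible, or when `force_mc = TRUE`).
#' @param seed integer seed for the Monte-Carlo path.
#' @param max_tables enumeration budget.
#' @param force_mc always use Monte-Carlo.
#' @return list with `p`, `method` (`"exact"`/`"monte-carlo"`), and
#'   `n_tables` (enumerated or sampled). Degenerate margins give p = 1.
#' @export
freeman_halton_test <- function(tab, n_mc = 10000, seed = NULL,
                                max_tables = 1e6, force_mc = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    sf_stop("counts must be non-negative integers",
            class = "strainflow_invalid_argument")
  }
  rm_ <- rowSums(tab); cm_ <- colSums(tab)
  rm_ <- rm_[rm_ > 0]; cm_ <- cm_[cm_ > 0]
  if (length(rm_) < 2 || length(cm_) < 2) {
    return(list(p = 1, method = "degenerate", n_tables = 1L))
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  logp_obs <- fh_log_prob(tab, rm_, cm_)
  # crude upper bound on the number of candidate tables (free cells)
  bound <- prod(pmin(outer(rm_[-length(rm_)], cm_[-length(cm_)], pmin) + 1,
                     Inf))
  if (!force_mc && is.finite(bound) && bound <= max_tables) {
    probs <- fh_enumerate(rm_, cm_)
    p <- sum(exp(probs[probs <= logp_obs + 1e-7]))
    list(p = min(p, 1), method = "exact", n_tables = length(probs))
  } else {
    p <- with_seed(seed, {
      draws <- r2dtable(n_mc, rm_, cm_)
      hits <- vapply(draws, function(t_)
        fh_log_prob(t_, rm_, cm_) <= logp_obs + 1e-7, logical(1))
      (1 + sum(hits)) / (1 + n_mc)
    })
    list(p = p, method = "monte-carlo", n_tables = n_mc)
  }
}

#' Log conditional probability of a table given its margins
#' @noRd
fh_log_prob <- function(tab, rm_, cm_) {
  sum(lgamma(rm_ + 1)) + sum(lgamma(cm_ + 1)) -
    lgamma(sum(rm_) + 1) - sum(lgamma(tab + 1))
}

#' Enumerate log probabilities of all tables with the given margins
#' @noRd
fh_enumerate <- function(rm_, cm_) {
  r <- length(rm_); cc <- length(cm_)
  probs <- numeric(0)
  cells <- matrix(0L, r, cc)
  const <- sum(lgamma(rm_ + 1)) + sum(lgamma(cm_ + 1)) -
    lgamma(sum(rm_) + 1)
  rec <- function(i, j, row_left, col_left) {
    if (i == r) {
      # last row fully determined by column remainders
      if (any(col_left < 0)) return()
      cells[r, ] <<- col_left
      probs[length(probs) + 1L] <<- const - sum(lgamma(cells + 1))
      return()
    }
    hi <- min(row_left, col_left[j])
    if (j == cc - 1L) {
      # last free cell in the row: remainder goes to the last column
      for (x in 0:hi) {
        rest <- row_left - x
        if (rest > col_left[cc]) next
        cells[i, j] <<- x
        cells[i, cc] <<- rest
        nl <- col_left
        nl[j] <- nl[j] - x
        nl[cc] <- nl[cc] - rest
        rec(i + 1L, 1L, if (i + 1L <= r) rm_[i + 1L] else 0L, nl)
      }
    } else {
      for (x in 0:hi) {
        cells[i, j] <<- x
        nl <- col_left
        nl[j] <- nl[j] - x
        rec(i, j + 1L, row_left - x, nl)
      }
    }
  }
  if (r == 1L) {
    probs <- const - sum(lgamma(cm_ + 1))
  } else {
    rec(1L, 1L, rm_[1L], cm_)
  }
  probs
}

#' Apply LLD/LOD censoring rules to biomarker values
#'
#' When more than 50% of values fall below the limit of detection
#' (LOD), the analyte is flagged `"no-model"` and left unmodified (no
#' ANCOVA should be run). Otherwise, when less than 10% of values fall
#' below the lower limit of detection (LLD), those values are replaced
#' by the LLD itself and modeling proceeds. Fractions below LLD in the
#' \[10%, 50%\] gap pass through unmodified with a `"caution"` flag.
#'
#' @param values numeric vector.
#' @param lld,lod detection limits.
#' @return list with `values`, `flag` (`"ok"`, `"caution"`,
#'   `"no-model"`), `frac_below_lld`, `frac_below_lod`.
#' @export
apply_censoring <- function(values, lld, lod) {
  frac_lld <- mean(values < lld, na.rm = TRUE)
  frac_lod <- mean(values < lod, na.rm = TRUE)
  if (frac_lod > 0.5) {
    flag <- "no-model"
  } else if (frac_lld < 0.10) {
    values[!is.na(values) & values < lld] <- lld
    flag <- "ok"
  } else {
    flag <- "caution"
  }
  list(values = values, flag = flag, frac_below_lld = frac_lld,
       frac_below_lod = frac_lod)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; `NA` inputs are propagated
#' and flagged via an attribute.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (capped at 1), attribute `"had_na"`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    sf_stop("p-values must be in [0, 1]",
            class = "strainflow_invalid_argument")
  }
  out <- p.adjust(p, method = "BH")
  attr(out, "had_na") <- anyNA(p)
  out
}

#' Full non-inferiority growth analysis
#'
#' Convenience driver reproducing the trial's primary analysis shape:
#' ANCOVA of daily weight gain on group, baseline weight and sex;
#' Tukey-adjusted pairwise CIs; non-inferiority decisions of each
#' supplemented arm versus the reference against the margin.
#'
#' @param growth data.frame with `weight_gain_gday`, `arm`,
#'   `baseline_weight_kg`, `sex`.
#' @param margin non-inferiority margin in g/day (default -3.6).
#' @param reference reference (control) arm label.
#' @return list with the `ancova_fit` and a `decisions` data.frame.
#' @export
growth_noninferiority <- function(growth, margin = -3.6,
                                  reference = "CG") {
  fit <- ancova_adjusted_means(growth, "weight_gain_gday", "arm",
                               c("baseline_weight_kg", "sex"))
  diffs <- fit$differences
  diffs$comparison <- gsub("[()]", "", diffs$comparison)
  # orient every contrast as (arm - reference)
  sides <- strsplit(diffs$comparison, " - ", fixed = TRUE)
  rows <- vapply(sides, function(s) reference %in% s, logical(1))
  decisions <- lapply(which(rows), function(i) {
    est <- diffs$estimate[i]; lo <- diffs$lower[i]; hi <- diffs$upper[i]
    if (sides[[i]][1] == reference) {
      est <- -est
      tmp <- lo; lo <- -hi; hi <- -tmp
      lab <- paste(sides[[i]][2], "vs.", reference)
    } else {
      lab <- paste(sides[[i]][1], "vs.", reference)
    }
    dec <- noninferiority_decision(est, lo, hi, margin = margin,
                                   se = diffs$se[i], df = diffs$df[i])
    data.frame(comparison = lab, estimate = est, lower = lo, upper = hi,
               non_inferior = dec$non_inferior, p = dec$p,
               stringsAsFactors = FALSE)
  })
  list(fit = fit, decisions = do.call(rbind, decisions), margin = margin)
}
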