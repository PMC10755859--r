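#' Dirichlet-multinomial log density
#'
#' Log probability mass of count vectors under a Dirichlet-multinomial
#' (multivariate Polya) distribution, including the multinomial
#' coefficient:
#' `log DM(x | a) = log(N!) - sum(log x_j!) + lgamma(A) - lgamma(N + A)
#'  + sum_j [lgamma(x_j + a_j) - lgamma(a_j)]`, with `A = sum(a)`.
#'
#' @param x integer count vector, or an n x G matrix of counts (rows are
#'   samples).
#' @param alpha Dirichlet parameter vector (length G, strictly
#'   positive).
#' @return numeric vector of per-row log densities.
#' @export
ddirmult <- function(x, alpha) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(alpha)) {
    sf_stop("`alpha` length must match the number of taxa",
            class = "strainflow_invalid_argument")
  }
  if (any(alpha <= 0)) {
    sf_stop("`alpha` must be strictly positive",
            class = "strainflow_invalid_argument")
  }
  n_i <- rowSums(x)
  a_sum <- sum(alpha)
  const <- lgamma(n_i + 1) - rowSums(lgamma(x + 1))
  const + lgamma(a_sum) - lgamma(n_i + a_sum) +
    rowSums(lgamma(sweep(x, 2, alpha, "+"))) - sum(lgamma(alpha))
}

#' Moment-matching Dirichlet initialization for one cluster
#' @noRd
moment_match_alpha <- function(props, floor = 1e-2) {
  m <- colMeans(props)
  m <- pmax(m, 1e-4)
  m <- m / sum(m)
  v <- apply(props, 2, var)
  ok <- v > 1e-10 & m > 1e-4 & m < 1 - 1e-4
  s <- if (any(ok)) {
    est <- m[ok] * (1 - m[ok]) / v[ok] - 1
    max(stats::median(est), 1)
  } else 10
  pmax(m * s, floor)
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Expectation-maximization on the DM mixture likelihood: the E-step
#' computes responsibilities proportional to `pi_k * DM(x | alpha_k)`;
#' the M-step updates the weights by responsibility means and each
#' `alpha_k` by Minka's fixed-point ascent on the responsibility-
#' weighted DM log-likelihood (monotone in the likelihood). The best of
#' `n_restarts` random restarts (k-means partitions of the proportion
#' vectors with moment-matched Dirichlet starts) is returned, together
#' with the Laplace, AIC and BIC model-choice criteria (all on a
#' "smaller is better" scale; the Laplace term uses a block-diagonal
#' analytic Hessian per component).
#'
#' @param counts n x G matrix of non-negative integer counts; every row
#'   must have a positive total.
#' @param K number of mixture components (>= 1).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param alpha_floor lower bound on Dirichlet parameters (prevents
#'   boundary divergence).
#' @return object of class `dmm_model`: `K`, `pi`, `alpha` (K x G),
#'   `resp` (n x K responsibilities), `loglik`, `loglik_trace`,
#'   `laplace`, `aic`, `bic`, `p` (free parameters `K*G + K - 1`),
#'   `converged`, `n_iter`.
#' @export
fit_dmm <- function(counts, K, n_restarts = 10, seed = NULL,
                    tol = 1e-6, max_iter = 200, alpha_floor = 1e-6) {
  counts <- as.matrix(counts)
  K <- check_count(K, "K")
  if (any(counts < 0) || any(rowSums(counts) <= 0)) {
    sf_stop("counts must be non-negative with positive row sums",
            class = "strainflow_invalid_argument")
  }
  n <- nrow(counts); G <- ncol(counts)
  props <- counts / rowSums(counts)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- dmm_init(props, K)
      fit <- dmm_em(counts, init$alpha, init$pi, tol, max_iter,
                    alpha_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    p <- K * G + (K - 1)
    best$p <- p
    best$aic <- -2 * best$loglik + 2 * p
    best$bic <- -2 * best$loglik + p * log(n)
    best$laplace <- dmm_laplace(counts, best)
    best$K <- K
    best$n <- n
    best$G <- G
    if (!is.null(rownames(counts))) rownames(best$resp) <- rownames(counts)
    colnames(best$alpha) <- colnames(counts)
    class(best) <- "dmm_model"
    best
  })
}

#' @noRd
dmm_init <- function(props, K) {
  n <- nrow(props)
  cl <- if (K == 1L) {
    rep(1L, n)
  } else {
    km <- tryCatch(
      kmeans(props, centers = K, nstart = 1, iter.max = 30)$cluster,
      error = function(e) sample.int(K, n, replace = TRUE))
    # guard against empty clusters from degenerate data
    if (length(unique(km)) < K) km <- sample.int(K, n, replace = TRUE)
    km
  }
  alpha <- t(vapply(seq_len(K), function(k) {
    rows <- props[cl == k, , drop = FALSE]
    if (nrow(rows) < 2) rows <- props[sample.int(n, max(2, n %/% K)), ,
                                      drop = FALSE]
    moment_match_alpha(rows)
  }, numeric(ncol(props))))
  pi0 <- tabulate(cl, K) / n
  pi0 <- pmax(pi0, 1e-3); pi0 <- pi0 / sum(pi0)
  list(alpha = alpha, pi = pi0)
}

#' @noRd
dmm_em <- function(counts, alpha, pi, tol, max_iter, alpha_floor) {
  n <- nrow(counts); K <- nrow(alpha)
  n_i <- rowSums(counts)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  resp <- matrix(1, n, 1)
  for (iter in seq_len(max_iter)) {
    logp <- vapply(seq_len(K), function(k) ddirmult(counts, alpha[k, ]),
                   numeric(n))
    logp <- sweep(matrix(logp, n, K), 2, log(pi), "+")
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logp - lse)
    if (is.finite(prev) && abs(ll - prev) <= tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
    prev <- ll
    pi <- pmax(colMeans(resp), 1e-10)
    pi <- pi / sum(pi)
    for (k in seq_len(K)) {
      alpha[k, ] <- minka_update(counts, n_i, resp[, k], alpha[k, ],
                                 alpha_floor, inner = 5)
    }
  }
  list(pi = pi, alpha = alpha, resp = resp, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged, n_iter = length(trace))
}

#' Minka fixed-point update of one component's Dirichlet parameters
#' @noRd
minka_update <- function(counts, n_i, w, alpha, alpha_floor, inner = 5) {
  ws <- sum(w)
  if (ws < 1e-8) return(alpha)
  for (it in seq_len(inner)) {
    num <- colSums(w * (digamma(sweep(counts, 2, alpha, "+")))) -
      ws_digamma(alpha, w)
    den <- sum(w * (digamma(n_i + sum(alpha)))) - ws * digamma(sum(alpha))
    if (!is.finite(den) || den <= 0) break
    alpha_new <- alpha * pmax(num, 0) / den
    alpha_new <- pmax(alpha_new, alpha_floor)
    if (max(abs(alpha_new - alpha)) < 1e-8 * max(alpha)) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  alpha
}

#' @noRd
ws_digamma <- function(alpha, w) sum(w) * digamma(alpha)

#' Laplace model-choice criterion (block-diagonal Hessian in log space)
#'
#' The model evidence is approximated per component from the Hessian of
#' the responsibility-weighted negative DM log-likelihood with respect
#' to log(alpha) (the scale the parameters are optimized on), exploiting
#' its diagonal-plus-rank-one structure. Ill-conditioned blocks (e.g.
#' starved components whose parameters sit at the floor) fall back to a
#' BIC-style penalty so that degenerate fits are never rewarded.
#' @noRd
dmm_laplace <- function(counts, fit) {
  K <- nrow(fit$alpha); G <- ncol(fit$alpha)
  n_i <- rowSums(counts)
  logdet <- 0
  for (k in seq_len(K)) {
    w <- fit$resp[, k]
    a <- fit$alpha[k, ]
    a_sum <- sum(a)
    ws <- sum(w)
    # H_alpha = D + c * 11' (weighted observed information)
    c_term <- sum(w * (trigamma(n_i + a_sum) - trigamma(a_sum)))
    d_diag <- colSums(w * (-trigamma(sweep(counts, 2, a, "+")))) +
      ws * trigamma(a)
    # gradient of the weighted negative log-likelihood (nonzero at floor)
    grad <- -(colSums(w * digamma(sweep(counts, 2, a, "+"))) -
                ws * digamma(a) +
                ws * digamma(a_sum) - sum(w * digamma(n_i + a_sum)))
    # log-space Hessian: diag(a) H diag(a) + diag(a * grad)
    dd <- a^2 * d_diag + a * grad
    det_ok <- all(dd > 0) && (1 + c_term * sum(a^2 / dd)) > 0
    block <- if (det_ok) {
      sum(log(dd)) + log1p(c_term * sum(a^2 / dd))
    } else {
      NA_real_
    }
    # never let a degenerate block reward extra components
    bic_style <- G * log(max(ws, 2))
    logdet <- logdet + if (is.na(block)) bic_style else max(block, bic_style)
  }
  p_alpha <- K * G
  -(fit$loglik - 0.5 * logdet + 0.5 * p_alpha * log(2 * pi))
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf(paste0("<dmm_model> K=%d, logL=%.2f, Laplace=%.2f, ",
                     "AIC=%.2f, BIC=%.2f, %sconverged (%d iter)\n"),
              x$K, x$loglik, x$laplace, x$aic, x$bic,
              if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Fit DMM models over a range of K and select the best
#'
#' Fits `K = 1..k_max` and reports the minimizing K under each of the
#' Laplace, AIC and BIC criteria. The Laplace criterion is the primary
#' choice; all three are always reported.
#'
#' @param counts samples x taxa count matrix.
#' @param k_max largest component count (default 15).
#' @param n_restarts,seed,... passed to [fit_dmm()].
#' @return list of class `dmm_selection`: `models` (list of
#'   `dmm_model`), `criteria` (data.frame K x criterion), and `best`
#'   (named list with the chosen K per criterion).
#' @export
select_k <- function(counts, k_max = 15, n_restarts = 10, seed = NULL,
                     ...) {
  models <- lapply(seq_len(k_max), function(k)
    fit_dmm(counts, k, n_restarts = n_restarts,
            seed = child_seed(seed, k), ...))
  criteria <- data.frame(
    K = seq_len(k_max),
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    laplace = vapply(models, `[[`, numeric(1), "laplace"),
    aic = vapply(models, `[[`, numeric(1), "aic"),
    bic = vapply(models, `[[`, numeric(1), "bic"),
    converged = vapply(models, `[[`, logical(1), "converged")
  )
  best <- list(laplace = criteria$K[which.min(criteria$laplace)],
               aic = criteria$K[which.min(criteria$aic)],
               bic = criteria$K[which.min(criteria$bic)])
  structure(list(models = models, criteria = criteria, best = best),
            class = "dmm_selection")
}

#' @export
print.dmm_selection <- function(x, ...) {
  cat(sprintf("<dmm_selection> K by Laplace=%d, AIC=%d, BIC=%d\n",
              x$best$laplace, x$best$aic, x$best$bic))
  print(x$criteria, row.names = FALSE)
  invisible(x)
}

#' Maximum-posterior community-type assignment
#'
#' @param model a [fit_dmm()] result.
#' @return integer labels (1..K) named by sample when the count matrix
#'   had rownames.
#' @export
fct_assign <- function(model) {
  lab <- max.col(model$resp, ties.method = "first")
  names(lab) <- rownames(model$resp)
  lab
}

#' Relabel community types by chronological prevalence
#'
#' Components are relabeled `1..K` by ascending mean visit index of
#' their member samples (so type 1 is the earliest community); ties are
#' broken by descending overall prevalence. Components with no members
#' are placed last with a warning.
#'
#' @param labels integer component labels named by `sample_id`.
#' @param meta data.frame with `sample_id` and `visit_index` (or a
#'   `visit` column with ordered labels `V1 < V2 < ...`).
#' @param K total number of components (defaults to `max(labels)`).
#' @return list with `labels` (relabeled, same names), `order` (old
#'   labels in new order) and `mean_visit` per old label.
#' @export
order_chronologically <- function(labels, meta, K = max(labels)) {
  if (is.null(meta$visit_index)) {
    meta$visit_index <- as.integer(factor(meta$visit,
                                          levels = sort(unique(meta$visit))))
  }
  vi <- meta$visit_index[match(names(labels), meta$sample_id)]
  if (anyNA(vi)) {
    sf_stop("every sample needs a visit index",
            class = "strainflow_invalid_argument")
  }
  mean_visit <- vapply(seq_len(K), function(k) {
    m <- vi[labels == k]
    if (length(m)) mean(m) else Inf
  }, numeric(1))
  if (any(is.infinite(mean_visit))) {
    warning("component(s) with zero members placed last")
  }
  prevalence <- tabulate(labels, K)
  ord <- order(mean_visit, -prevalence)
  new_of_old <- integer(K)
  new_of_old[ord] <- seq_len(K)
  relabeled <- new_of_old[labels]
  names(relabeled) <- names(labels)
  list(labels = relabeled, order = ord, mean_visit = mean_visit)
}

#' Community-type transition counts between consecutive visits
#'
#' @param labels integer FCT labels named by `sample_id`.
#' @param meta data.frame with `sample_id`, `infant_id`, `visit_index`
#'   (or ordered `visit`).
#' @param K number of community types.
#' @return named list, one element per consecutive visit pair, each with
#'   `counts` (K x K, rows = source type) and `fractions`
#'   (row-normalized; rows with no transitions are `NA`).
#' @export
transition_summary <- function(labels, meta, K = max(labels)) {
  if (is.null(meta$visit_index)) {
    meta$visit_index <- as.integer(factor(meta$visit,
                                          levels = sort(unique(meta$visit))))
  }
  m <- meta[match(names(labels), meta$sample_id), ]
  m$label <- labels
  out <- list()
  for (v in seq_len(max(m$visit_index) - 1L)) {
    a <- m[m$visit_index == v, c("infant_id", "label")]
    b <- m[m$visit_index == v + 1L, c("infant_id", "label")]
    j <- merge(a, b, by = "infant_id", suffixes = c("_from", "_to"))
    counts <- matrix(0L, K, K,
                     dimnames = list(paste0("FCT", seq_len(K)),
                                     paste0("FCT", seq_len(K))))
    if (nrow(j)) {
      t_ <- table(factor(j$label_from, levels = seq_len(K)),
                  factor(j$label_to, levels = seq_len(K)))
      counts[] <- as.integer(t_)
    }
    rs <- rowSums(counts)
    fractions <- counts / ifelse(rs > 0, rs, NA_real_)
    out[[sprintf("V%d_V%d", v, v + 1L)]] <-
      list(counts = counts, fractions = fractions)
  }
  out
}

#' Compare community-type trajectories between colonization groups
#'
#' Per-visit chi-square tests of the FCT x colonization-group
#' contingency (Monte-Carlo p-values for sparse tables), with
#' Benjamini-Hochberg adjustment across visits.
#'
#' @param labels FCT labels named by `sample_id`.
#' @param groups named per-infant colonization group (e.g.
#'   `"NoInfantis"`, `"LMG11588"`, `"OtherInfantis"`).
#' @param meta data.frame with `sample_id`, `infant_id`, `visit`.
#' @param monte_carlo,n_mc,seed forwarded to [category_group_test()].
#' @return data.frame with `visit`, `statistic`, `p`, `p_adj`.
#' @export
compare_trajectories <- function(labels, groups, meta, monte_carlo = TRUE,
                                 n_mc = 2000, seed = NULL) {
  m <- meta[match(names(labels), meta$sample_id), ]
  m$label <- labels
  m$group <- groups[m$infant_id]
  m <- m[!is.na(m$group), ]
  visits <- sort(unique(m$visit))
  res <- lapply(seq_along(visits), function(i) {
    mv <- m[m$visit == visits[i], ]
    if (length(unique(mv$group)) < 2 || length(unique(mv$label)) < 2) {
      warning(sprintf("visit %s skipped (degenerate table)", visits[i]))
      return(data.frame(visit = visits[i], statistic = NA_real_,
                        p = NA_real_))
    }
    tt <- category_group_test(table(mv$label, mv$group),
                              monte_carlo = monte_carlo, n_mc = n_mc,
                              seed = child_seed(seed, i))
    data.frame(visit = visits[i], statistic = tt$statistic, p = tt$p)
  })
  res <- do.call(rbind, res)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}
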