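#' Paired differential expression between two time points
#'
#' For one group, computes per-gene within-individual differences
#' `d_i = x(tp_b, i) - x(tp_a, i)` and tests them against zero.
#' `log2fc` is the mean difference; the signed linear fold change is
#' `2^log2fc` for up- and `-2^(-log2fc)` for downregulation, so the
#' `|FC| >= threshold` gate reads identically in both directions.
#' `test = "paired_t"` is the standard one-sample t on the differences;
#' `"moderated_paired_t"` shrinks the per-gene variance towards a common
#' prior fitted by method of moments on the log sample variances
#' (empirical-Bayes posterior variance
#' `(d0*s0^2 + df*s_g^2) / (d0 + df)`, p-values on `df + d0` degrees of
#' freedom). Multiple testing is summarised by Storey q-values; the
#' significance flag itself is `|fc| >= fc_threshold AND p < p_threshold`.
#'
#' @param expr An `expression_study` (typically background-filtered).
#' @param group Group label to analyse.
#' @param tp_a,tp_b Time point indices; the contrast is `tp_b - tp_a`.
#' @param params A [de_params()].
#' @param pi0_method,lambda Passed to [storey_qvalue()].
#' @return A `contrast_result`: `table` (gene, log2fc, fc, t_stat, p_value,
#'   q_value, zero_var, significant) plus the fitted `pi0`, `prior_df`,
#'   `prior_var` and the contrast metadata.
#' @export
paired_contrast <- function(expr, group, tp_a, tp_b, params = de_params(),
                            pi0_method = "smoother",
                            lambda = seq(0.05, 0.95, 0.05)) {
  stopifnot(inherits(expr, "expression_study"),
            inherits(params, "de_params"))
  ann <- expr$samples[expr$samples$group == group, , drop = FALSE]
  if (!nrow(ann)) stop("unknown or empty group: ", group)
  inds <- unique(ann$individual_id)
  col_of <- function(tp) {
    cols <- vapply(inds, function(i) {
      s <- ann$sample_id[ann$individual_id == i & ann$timepoint == tp]
      if (length(s) != 1)
        stop("individual ", i, " lacks time point ", tp)
      s
    }, character(1))
    cols
  }
  d <- expr$values[, col_of(tp_b), drop = FALSE] -
       expr$values[, col_of(tp_a), drop = FALSE]
  n <- length(inds)
  if (n < 3) stop("need at least 3 individuals with both time points")
  df <- n - 1
  log2fc <- rowMeans(d)
  s2 <- apply(d, 1, stats::var)
  zero_var <- s2 == 0

  if (params$test == "paired_t") {
    t_stat <- log2fc / sqrt(s2 / n)
    p <- 2 * stats::pt(-abs(t_stat), df = df)
    p[zero_var] <- NaN
    t_stat[zero_var] <- NaN
    d0 <- 0; s02 <- NA_real_
  } else {
    fit <- fit_variance_prior(s2[!zero_var], df, prior_df = params$prior_df)
    d0 <- fit$prior_df; s02 <- fit$prior_var
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
      else if (d0 == 0) s2
      else (d0 * s02 + df * s2) / (d0 + df)
    t_stat <- log2fc / sqrt(s2_post / n)
    p <- 2 * stats::pt(-abs(t_stat), df = df + d0)
    if (d0 == 0) { p[zero_var] <- NaN; t_stat[zero_var] <- NaN }
  }

  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pi0 <- NA_real_
  if (any(ok)) {
    st <- storey_qvalue(p[ok], pi0_method = pi0_method, lambda = lambda)
    q[ok] <- st$q_values
    pi0 <- st$pi0
  }
  fc <- ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
  significant <- !is.na(p) & abs(fc) >= params$fc_threshold &
    p < params$p_threshold
  tab <- data.frame(gene = rownames(d), log2fc = log2fc, fc = fc,
                    t_stat = t_stat, p_value = p, q_value = q,
                    zero_var = zero_var, significant = significant,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, group = group, tp_a = tp_a, tp_b = tp_b,
                 params = params, n_individuals = n, pi0 = pi0,
                 prior_df = d0, prior_var = s02),
            class = "contrast_result")
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior on
# log sample variances: matches mean and variance of log(s^2) through
# digamma/trigamma identities for log chi-square moments.
fit_variance_prior <- function(s2, df, prior_df = NULL) {
  if (!is.null(prior_df)) {
    d0 <- prior_df
    if (d0 == 0) return(list(prior_df = 0, prior_var = NA_real_))
  }
  z <- log(s2[s2 > 0])
  if (!length(z)) return(list(prior_df = 0, prior_var = NA_real_))
  e <- z - digamma(df / 2) + log(df / 2)
  if (is.null(prior_df)) {
    excess <- stats::var(e) - trigamma(df / 2)
    d0 <- if (is.na(excess) || excess <= 0) Inf
          else 2 * trigamma_inverse(excess)
  }
  s02 <- if (is.infinite(d0)) exp(mean(e))
         else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(prior_df = d0, prior_var = s02)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (approximately
# linear in y), as is standard for this moment equation.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast_result: group ", x$group, ", time points ", x$tp_b, "-",
      x$tp_a, " (", x$n_individuals, " individuals, ",
      x$params$test, ")\n", sep = "")
  cat("  genes:", nrow(x$table),
      " significant:", sum(x$table$significant),
      " pi0:", signif(x$pi0, 3), "\n")
  invisible(x)
}

#' Storey q-values
#'
#' Converts p-values to q-values: `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`
#' over the sorted p-values, capped at 1; tied p-values share a q. The null
#' proportion `pi0` is estimated by the smoother method (natural cubic
#' spline through `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`,
#' evaluated at the largest lambda) unless fixed. With `pi0 = 1` the
#' procedure is exactly Benjamini-Hochberg.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param pi0_method `"smoother"`, `"fixed"` (use `pi0`), or `"one"`
#'   (`pi0 = 1`, i.e. Benjamini-Hochberg).
#' @param lambda Tuning grid for the smoother.
#' @param pi0 Fixed value when `pi0_method = "fixed"`.
#' @return List with `q_values` (input order) and `pi0`.
#' @export
storey_qvalue <- function(p, pi0_method = c("smoother", "fixed", "one"),
                          lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  pi0_method <- match.arg(pi0_method)
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and lie in [0, 1]")
  m <- length(p)
  pi0_hat <- switch(pi0_method,
    one = 1,
    fixed = {
      if (is.null(pi0)) stop("pi0_method = 'fixed' requires `pi0`")
      pi0
    },
    smoother = estimate_pi0_smoother(p, lambda))
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0_hat * (m / seq_len(m)) * p[o])))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q_values = q, pi0 = pi0_hat)
}

estimate_pi0_smoother <- function(p, lambda) {
  m <- length(p)
  if (m < 20 || length(lambda) < 4)
    return(1)  # too few tests for a stable smoother; conservative null
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Significant genes of a contrast
#'
#' Applies the gate `|fc| >= fc_threshold AND p < p_threshold`; the
#' fold-change boundary is inclusive, the p boundary exclusive. Genes with
#' undefined p (zero variance under the plain paired t) never qualify.
#'
#' @param result A `contrast_result`.
#' @param params A [de_params()]; defaults to the contrast's own.
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(result, params = NULL) {
  stopifnot(inherits(result, "contrast_result"))
  if (is.null(params)) params <- result$params
  tab <- result$table
  keep <- !is.na(tab$p_value) & abs(tab$fc) >= params$fc_threshold &
    tab$p_value < params$p_threshold
  tab$gene[keep]
}

#' Union of significant genes over several contrasts
#'
#' @param contrasts Non-empty list of `contrast_result`s from one group.
#' @param params Optional [de_params()] applied to all contrasts.
#' @return Character vector (sorted union of per-contrast significant
#'   sets).
#' @export
de_gene_union <- function(contrasts, params = NULL) {
  if (!length(contrasts)) stop("empty contrast list")
  sort(unique(unlist(lapply(contrasts, significant_genes,
                            params = params))))
}
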