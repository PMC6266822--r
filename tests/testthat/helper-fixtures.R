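# Fixture builders and independent reference implementations used across
# the suite. References are deliberately naive (loops, direct formulas) so
# they stay independent of the package's vectorised code paths.

# A tiny annotated study: `series` is a list
#   group -> individual -> gene -> numeric vector over timepoints.
make_study <- function(series, sexes = NULL) {
  samples <- NULL
  vals <- list()
  for (g in names(series)) {
    for (ind in names(series[[g]])) {
      tps <- length(series[[g]][[ind]][[1]])
      sid <- sprintf("%s_T%d", ind, seq_len(tps))
      sex <- if (!is.null(sexes) && ind %in% names(sexes))
        sexes[[ind]] else "male"
      samples <- rbind(samples, data.frame(
        sample_id = sid, individual_id = ind, group = g,
        timepoint = seq_len(tps), sex = sex,
        stringsAsFactors = FALSE))
      for (gene in names(series[[g]][[ind]]))
        vals[[gene]] <- c(vals[[gene]],
                          stats::setNames(series[[g]][[ind]][[gene]], sid))
    }
  }
  m <- do.call(rbind, vals)
  rownames(m) <- names(vals)
  m <- m[, samples$sample_id, drop = FALSE]
  expression_study(m, samples)
}

# Assemble a correlation_stack directly from per-individual matrices.
make_stack <- function(gene_ids, matrices, group = "G") {
  for (i in seq_along(matrices))
    dimnames(matrices[[i]]) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, group = group, matrices = matrices),
            class = "correlation_stack")
}

# Stack in which one gene pair has the prescribed per-individual
# correlations and all other entries are 0.
pair_stack <- function(r_values, n_genes = 2) {
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  mats <- lapply(r_values, function(r) {
    m <- diag(n_genes)
    m[1, 2] <- m[2, 1] <- r
    m
  })
  make_stack(gene_ids, mats)
}

# Random correlation stack generated through real expression data so the
# matrices are genuine Pearson correlations.
random_stack <- function(n_genes, n_ind, T = 3, constant_gene = FALSE) {
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  mats <- lapply(seq_len(n_ind), function(i) {
    x <- matrix(stats::rnorm(n_genes * T), n_genes)
    if (constant_gene) x[1, ] <- 1  # zero variance -> NA correlations
    suppressWarnings(stats::cor(t(x)))
  })
  make_stack(gene_ids, mats)
}

# Reference edge rule: plain triple loop over pairs and individuals.
reference_network_edges <- function(stack, corr_cutoff, support_fraction) {
  g <- stack$gene_ids
  n_ind <- length(stack$matrices)
  rows <- list()
  for (a in seq_along(g)) for (b in seq_along(g)) {
    if (a >= b) next
    rs <- numeric(0)
    for (i in seq_len(n_ind)) {
      r <- stack$matrices[[i]][a, b]
      if (!is.na(r) && abs(r) >= corr_cutoff) rs <- c(rs, r)
    }
    if (length(rs) / n_ind >= support_fraction && length(rs) > 0 &&
        (all(rs > 0) || all(rs < 0))) {
      rows[[length(rows) + 1]] <-
        data.frame(gene_a = min(g[a], g[b]), gene_b = max(g[a], g[b]),
                   weight = mean(rs), support = length(rs) / n_ind,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), support = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# Reference Frobenius distance: explicit double loop over the full matrix.
reference_frobenius <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    d <- A[i, j] - B[i, j]
    if (!is.na(d)) s <- s + d^2
  }
  sqrt(s)
}

# Reference hypergeometric upper tail via direct combinatorial summation.
reference_hyper_tail <- function(k, K, N, n) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

random_symmetric <- function(p) {
  m <- matrix(stats::runif(p * p, -1, 1), p)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# One-group study whose per-gene tp2 - tp1 differences across individuals
# equal d[[gene]]; time point 3 repeats time point 2.
diff_study <- function(d) {
  n <- length(d[[1]])
  series <- list(G = lapply(stats::setNames(seq_len(n),
                                            sprintf("I%02d", seq_len(n))),
    function(i) lapply(d, function(dg) c(5, 5 + dg[i], 5 + dg[i]))))
  make_study(series)
}

# A bare contrast_result for testing the significance gate in isolation.
fake_contrast <- function(log2fc, p, params = de_params()) {
  fc <- ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
  tab <- data.frame(gene = sprintf("g%d", seq_along(log2fc)),
                    log2fc = log2fc, fc = fc, t_stat = NA_real_,
                    p_value = p, q_value = NA_real_,
                    zero_var = FALSE,
                    significant = NA, stringsAsFactors = FALSE)
  structure(list(table = tab, group = "G", tp_a = 1, tp_b = 2,
                 params = params, n_individuals = NA, pi0 = NA,
                 prior_df = NA, prior_var = NA),
            class = "contrast_result")
}
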