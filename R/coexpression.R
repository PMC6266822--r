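#' Per-individual correlation matrices over a time series
#'
#' The within-individual stage: for every individual of a group, the
#' Pearson correlation of each gene pair across that individual's
#' time-ordered expression values. Correlations are undefined (NA) when
#' either gene has zero variance across the individual's time points.
#'
#' @param expr An `expression_study`; every individual of the group must
#'   have a complete time series of at least 3 points.
#' @param genes Genes to correlate (>= 2), a subset of the study's genes.
#' @param group Group label.
#' @return A `correlation_stack`: list with `gene_ids`, `group`, and
#'   `matrices` (one symmetric unit-diagonal correlation matrix per
#'   individual).
#' @export
individual_correlations <- function(expr, genes, group) {
  stopifnot(inherits(expr, "expression_study"))
  genes <- as.character(genes)
  if (length(genes) < 2) stop("need at least 2 genes")
  bad <- setdiff(genes, rownames(expr$values))
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  ann <- expr$samples[expr$samples$group == group, , drop = FALSE]
  if (!nrow(ann)) stop("unknown or empty group: ", group)
  tps <- sort(unique(expr$samples$timepoint))
  if (length(tps) < 3) stop("need at least 3 time points")
  inds <- unique(ann$individual_id)
  mats <- lapply(inds, function(ind) {
    rows <- ann[ann$individual_id == ind, , drop = FALSE]
    rows <- rows[order(rows$timepoint), , drop = FALSE]
    if (!identical(rows$timepoint, as.integer(tps)))
      stop("individual ", ind, " has an incomplete time series")
    m <- suppressWarnings(
      stats::cor(t(expr$values[genes, rows$sample_id, drop = FALSE])))
    diag(m)[is.na(diag(m))] <- NA_real_
    m
  })
  names(mats) <- inds
  structure(list(gene_ids = genes, group = group, matrices = mats),
            class = "correlation_stack")
}

#' @export
print.correlation_stack <- function(x, ...) {
  cat("correlation_stack [", x$group, "]: ", length(x$gene_ids),
      " genes x ", length(x$matrices), " individuals\n", sep = "")
  invisible(x)
}

#' Build a group co-expression network from a correlation stack
#'
#' The edge rule: an individual supports a gene pair when its correlation
#' is defined and `|r| >= corr_cutoff`. The pair becomes an edge when the
#' supporting individuals are at least `support_fraction` of the group AND
#' all supporting correlations share one sign. Edge weight is the mean
#' correlation over supporting individuals (so `|weight| >= corr_cutoff`);
#' with `weight_over = "all"` it is the mean over all individuals with a
#' defined correlation instead. Undefined correlations never count as
#' support but the denominator stays the full group size.
#'
#' @param stack A `correlation_stack`.
#' @param params A [network_params()].
#' @param provenance Label for the network; defaults to the stack's group.
#' @param weight_over `"qualifying"` (default) or `"all"`.
#' @param keep_isolated Also keep input genes without edges as nodes.
#' @return A `coexpression_network`.
#' @export
build_network <- function(stack, params = network_params(),
                          provenance = stack$group,
                          weight_over = c("qualifying", "all"),
                          keep_isolated = FALSE) {
  stopifnot(inherits(stack, "correlation_stack"),
            inherits(params, "network_params"))
  weight_over <- match.arg(weight_over)
  g <- stack$gene_ids
  n_ind <- length(stack$matrices)
  if (!n_ind) stop("empty correlation stack")
  arr <- simplify2array(stack$matrices)      # genes x genes x individuals
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  qual <- !is.na(arr) & abs(arr) >= params$corr_cutoff
  n_qual <- apply(qual, c(1, 2), sum)
  pos_ok <- apply(qual & !is.na(arr) & arr > 0, c(1, 2), sum)
  neg_ok <- apply(qual & !is.na(arr) & arr < 0, c(1, 2), sum)
  support <- n_qual / n_ind
  consistent <- (pos_ok == n_qual) | (neg_ok == n_qual)
  is_edge <- support >= params$support_fraction & n_qual > 0 & consistent
  is_edge[lower.tri(is_edge, diag = TRUE)] <- FALSE
  idx <- which(is_edge, arr.ind = TRUE)
  if (nrow(idx)) {
    w <- vapply(seq_len(nrow(idx)), function(k) {
      r <- arr[idx[k, 1], idx[k, 2], ]
      if (weight_over == "qualifying")
        mean(r[!is.na(r) & abs(r) >= params$corr_cutoff])
      else mean(r, na.rm = TRUE)
    }, numeric(1))
    edges <- data.frame(gene_a = g[idx[, 1]], gene_b = g[idx[, 2]],
                        weight = pmax(pmin(w, 1), -1),
                        support = support[idx],
                        stringsAsFactors = FALSE)
    edges <- edges[edges$weight != 0, , drop = FALSE]
  } else edges <- NULL
  coexpression_network(edges, nodes = if (keep_isolated) g else NULL,
                       provenance = provenance)
}

#' Group-mean correlation matrix
#'
#' Entry-wise mean over the stack's individuals, ignoring undefined
#' entries (NA when no individual defines an entry); unit diagonal.
#'
#' @param stack A `correlation_stack`.
#' @return A symmetric correlation matrix over the stack's genes.
#' @export
group_mean_correlation <- function(stack) {
  stopifnot(inherits(stack, "correlation_stack"))
  arr <- simplify2array(stack$matrices)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  m <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  diag(m) <- 1
  dimnames(m) <- list(stack$gene_ids, stack$gene_ids)
  m
}

#' Frobenius distance between two correlation matrices
#'
#' `||A - B||_F = sqrt(sum_ij |a_ij - b_ij|^2)` over the full matrix (both
#' triangles and the diagonal). Entries undefined in either matrix are
#' excluded pairwise by default, or raise an error.
#'
#' @param A,B Correlation matrices over the same genes (same dimnames).
#' @param na_action `"pairwise"` (default) or `"error"`.
#' @return Non-negative distance.
#' @export
frobenius_distance <- function(A, B, na_action = c("pairwise", "error")) {
  na_action <- match.arg(na_action)
  if (!all(dim(A) == dim(B)))
    stop("correlation matrices have mismatched dimensions")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("correlation matrices cover different gene sets")
  d2 <- (A - B)^2
  if (anyNA(d2)) {
    if (na_action == "error")
      stop("undefined entries in correlation matrices")
    d2 <- d2[!is.na(d2)]
  }
  sqrt(sum(d2))
}

#' Per-individual distance from the group correlation structure
#'
#' For each individual, the Frobenius distance between its correlation
#' matrix and the group mean matrix — a variability diagnostic showing how
#' far each individual's co-expression structure lies from the group's.
#'
#' @param stack A `correlation_stack` with at least 2 individuals.
#' @param na_action Passed to [frobenius_distance()].
#' @return Named numeric vector sorted in decreasing distance.
#' @export
individual_distance_profile <- function(stack,
                                        na_action = "pairwise") {
  stopifnot(inherits(stack, "correlation_stack"))
  if (length(stack$matrices) < 2)
    stop("distance profile needs at least 2 individuals")
  mu <- group_mean_correlation(stack)
  d <- vapply(stack$matrices, frobenius_distance, numeric(1),
              B = mu, na_action = na_action)
  sort(d, decreasing = TRUE)
}
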