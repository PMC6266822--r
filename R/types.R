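#' Construct an annotated expression study
#'
#' Binds a genes-by-samples matrix of log2 expression values to its sample
#' annotation sheet. The annotation must cover exactly the matrix's samples;
#' every sample maps to one individual, group, time point and sex, and no
#' individual is measured twice at the same time point.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names and no missing entries.
#' @param samples Data frame with columns `sample_id`, `individual_id`,
#'   `group`, `timepoint` (positive integer), `sex` (`"female"`/`"male"`).
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in expression matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-numeric values")
  samples <- validate_samples(samples)
  missing_ann <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_ann))
    stop("unannotated sample: ", paste(missing_ann, collapse = ", "))
  extra_ann <- setdiff(samples$sample_id, colnames(values))
  if (length(extra_ann))
    stop("annotated sample absent from matrix: ",
         paste(extra_ann, collapse = ", "))
  # annotation rows follow the matrix's column order
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "expression_study")
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "group", "timepoint", "sex")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$individual_id <- as.character(samples$individual_id)
  samples$group <- as.character(samples$group)
  samples$sex <- as.character(samples$sex)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  tp <- suppressWarnings(as.numeric(samples$timepoint))
  if (anyNA(tp) || any(tp < 1) || any(tp != round(tp)))
    stop("timepoint must be a positive integer")
  samples$timepoint <- as.integer(tp)
  if (!all(samples$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  key <- paste(samples$individual_id, samples$timepoint)
  if (anyDuplicated(key))
    stop("duplicate time point: individual measured twice at one timepoint")
  grp_per_ind <- tapply(samples$group, samples$individual_id,
                        function(g) length(unique(g)))
  if (any(grp_per_ind > 1))
    stop("individual assigned to more than one group")
  samples
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  cat("  individuals:", length(unique(x$samples$individual_id)),
      " groups:", paste(sort(unique(x$samples$group)), collapse = ", "), "\n")
  cat("  timepoints:", paste(sort(unique(x$samples$timepoint)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Genes of an expression study
#' @param expr An `expression_study`.
#' @return Character vector of gene identifiers.
#' @export
genes <- function(expr) rownames(expr$values)

#' Subset an expression study by gene and/or sample
#'
#' @param expr An `expression_study`.
#' @param genes Optional character vector of genes to keep (order preserved).
#' @param samples Optional character vector of sample ids to keep.
#' @return A new `expression_study`.
#' @export
subset_study <- function(expr, genes = NULL, samples = NULL) {
  v <- expr$values
  if (!is.null(genes)) {
    bad <- setdiff(genes, rownames(v))
    if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(v))
    if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  ann <- expr$samples[expr$samples$sample_id %in% colnames(v), , drop = FALSE]
  expression_study(v, ann)
}

#' Construct a co-expression network
#'
#' Undirected signed weighted gene graph. Edges are stored once in canonical
#' order (`gene_a < gene_b` lexicographically) with a correlation-scale
#' weight, the fraction of individuals supporting the edge, and a sign.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`
#'   (in \[-1, 1\], non-zero), `support` (in (0, 1\]); a `sign` column
#'   (`"+"`/`"-"`) is derived from `weight` if absent.
#' @param nodes Character vector of node gene ids; defaults to the genes
#'   incident to at least one edge.
#' @param provenance Free-text label (group name or `"overlap(A,B)"`).
#' @return An object of class `coexpression_network`.
#' @export
coexpression_network <- function(edges, nodes = NULL, provenance = "") {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), support = numeric(),
                        sign = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("gene_a", "gene_b", "weight", "support")
    miss <- setdiff(need, names(edges))
    if (length(miss))
      stop("edge table lacks column(s): ", paste(miss, collapse = ", "))
    a <- pmin(as.character(edges$gene_a), as.character(edges$gene_b))
    b <- pmax(as.character(edges$gene_a), as.character(edges$gene_b))
    if (any(a == b)) stop("self-edges are not allowed")
    edges$gene_a <- a
    edges$gene_b <- b
    if (anyDuplicated(paste(a, b))) stop("duplicate edges")
    if (any(edges$weight == 0) || any(abs(edges$weight) > 1))
      stop("edge weights must lie in [-1, 1] and be non-zero")
    if (any(edges$support <= 0) || any(edges$support > 1))
      stop("edge support must lie in (0, 1]")
    edges$sign <- ifelse(edges$weight > 0, "+", "-")
    edges <- edges[order(edges$gene_a, edges$gene_b),
                   c("gene_a", "gene_b", "weight", "support", "sign")]
    rownames(edges) <- NULL
  }
  incident <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- if (is.null(nodes)) incident else sort(unique(c(nodes, incident)))
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  neg <- sum(x$edges$sign == "-")
  cat("coexpression_network [", x$provenance, "]: ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      neg, " negative)\n", sep = "")
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, ...) {
  deg <- degree_report(object)
  out <- list(provenance = object$provenance,
              n_nodes = length(object$nodes),
              n_edges = nrow(object$edges),
              n_negative = sum(object$edges$sign == "-"),
              max_degree = if (length(deg)) deg[1] else integer())
  class(out) <- "summary.coexpression_network"
  out
}

#' @export
print.summary.coexpression_network <- function(x, ...) {
  cat("Network [", x$provenance, "]\n", sep = "")
  cat("  nodes:", x$n_nodes, " edges:", x$n_edges,
      " negative edges:", x$n_negative, "\n")
  if (length(x$max_degree))
    cat("  top degree:", names(x$max_degree), "=", x$max_degree, "\n")
  invisible(x)
}

edge_keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b)

#' Convert a co-expression network to an igraph object
#'
#' @param net A `coexpression_network`.
#' @param all_nodes Include isolated nodes as vertices.
#' @return An undirected `igraph` graph with `weight`, `support` and `sign`
#'   edge attributes.
#' @export
as_igraph <- function(net, all_nodes = TRUE) {
  stopifnot(inherits(net, "coexpression_network"))
  verts <- if (all_nodes) net$nodes else
    sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
}

#' Network construction parameters
#'
#' @param corr_cutoff Absolute per-individual Pearson correlation an
#'   individual must reach to support an edge (default 0.6).
#' @param support_fraction Minimum fraction of a group's individuals that
#'   must support an edge (default 0.25).
#' @return A `network_params` list.
#' @export
network_params <- function(corr_cutoff = 0.6, support_fraction = 0.25) {
  if (!(corr_cutoff > 0 && corr_cutoff <= 1))
    stop("corr_cutoff must lie in (0, 1]")
  if (!(support_fraction > 0 && support_fraction <= 1))
    stop("support_fraction must lie in (0, 1]")
  structure(list(corr_cutoff = corr_cutoff,
                 support_fraction = support_fraction),
            class = "network_params")
}

#' Differential-expression parameters
#'
#' @param fc_threshold Linear fold-change gate, `|FC| >= fc_threshold`
#'   (default 1.2; must exceed 1).
#' @param p_threshold Raw p-value gate, `p < p_threshold` (default 0.05).
#' @param test `"moderated_paired_t"` (empirical-Bayes variance moderation)
#'   or `"paired_t"`.
#' @param prior_df Optional fixed prior degrees of freedom for the moderated
#'   test; `NULL` (default) estimates it from the data; `0` reduces the
#'   moderated test to the plain paired t.
#' @return A `de_params` list.
#' @export
de_params <- function(fc_threshold = 1.2, p_threshold = 0.05,
                      test = c("moderated_paired_t", "paired_t"),
                      prior_df = NULL) {
  test <- match.arg(test)
  if (!(fc_threshold > 1)) stop("fc_threshold must be > 1")
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must lie in (0, 1)")
  if (!is.null(prior_df) && (!is.numeric(prior_df) || prior_df < 0))
    stop("prior_df must be NULL or a non-negative number")
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 test = test, prior_df = prior_df),
            class = "de_params")
}
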