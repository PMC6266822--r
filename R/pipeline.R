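#' Run the full co-expression workflow
#'
#' Executes the complete analysis on an annotated expression study:
#' background filtering against the female Y-chromosome noise floor,
#' paired differential expression per group for the requested time-point
#' contrasts, per-group within-individual correlation networks over each
#' group's differentially expressed genes, per-individual Frobenius
#' distance profiles, the sign-consistent overlap network between the two
#' groups, community clustering of the overlap network, and (when a gene
#' set collection is supplied) over-representation analysis of each cluster
#' against the background-filtered universe.
#'
#' @param expr An `expression_study`.
#' @param chrom Gene -> chromosome map for the background filter; `NULL`
#'   skips filtering.
#' @param groups Group labels to analyse (default: all groups, in sorted
#'   order; the overlap stage requires exactly two).
#' @param contrasts List of `c(tp_b, tp_a)` pairs (default
#'   `list(c(2, 1), c(3, 1))`).
#' @param de A [de_params()].
#' @param network A [network_params()].
#' @param min_cluster_size Minimum size of a numbered cluster.
#' @param collection Optional `gene_set_collection` for enrichment.
#' @param threshold_method Passed to [y_background_threshold()].
#' @param seed Seed forwarded to [community_cluster()].
#' @param verbose Log each stage's input/output sizes.
#' @return A `dcen_pipeline` list: `filtered`, `threshold`, `contrasts`
#'   (per group), `de_genes` (per group), `stacks`, `networks`,
#'   `distance_profiles`, `overlap`, `clusters`, `enrichment`.
#' @export
run_pipeline <- function(expr, chrom = NULL, groups = NULL,
                         contrasts = list(c(2, 1), c(3, 1)),
                         de = de_params(), network = network_params(),
                         min_cluster_size = 3, collection = NULL,
                         threshold_method = "pooled", seed = 1L,
                         verbose = FALSE) {
  stopifnot(inherits(expr, "expression_study"))
  say <- function(...) if (verbose) message(...)
  if (is.null(groups)) groups <- sort(unique(expr$samples$group))

  threshold <- -Inf
  filtered <- expr
  if (!is.null(chrom)) {
    threshold <- y_background_threshold(expr, chrom,
                                        method = threshold_method)
    filtered <- filter_background(expr, threshold)
    say("background filter: ", nrow(expr$values), " -> ",
        nrow(filtered$values), " genes (threshold ",
        signif(threshold, 4), ")")
  }

  contr <- list(); de_genes <- list()
  for (g in groups) {
    contr[[g]] <- lapply(contrasts, function(tp)
      paired_contrast(filtered, g, tp_a = tp[2], tp_b = tp[1],
                      params = de))
    de_genes[[g]] <- de_gene_union(contr[[g]])
    say("DE [", g, "]: ",
        paste(vapply(contr[[g]], function(x) sum(x$table$significant),
                     integer(1)), collapse = "/"),
        " significant per contrast; union ", length(de_genes[[g]]))
  }

  stacks <- list(); nets <- list(); dists <- list()
  for (g in groups) {
    if (length(de_genes[[g]]) < 2) {
      say("network [", g, "]: fewer than 2 DE genes; empty network")
      nets[[g]] <- coexpression_network(NULL, provenance = g)
      next
    }
    stacks[[g]] <- individual_correlations(filtered, de_genes[[g]], g)
    nets[[g]] <- build_network(stacks[[g]], network, provenance = g)
    dists[[g]] <- individual_distance_profile(stacks[[g]])
    say("network [", g, "]: ", length(nets[[g]]$nodes), " nodes, ",
        nrow(nets[[g]]$edges), " edges")
  }

  overlap <- NULL; clusters <- NULL; enrichment <- NULL
  if (length(groups) == 2) {
    overlap <- overlap_network(nets[[groups[1]]], nets[[groups[2]]])
    say("overlap: ", length(overlap$nodes), " nodes, ",
        nrow(overlap$edges), " edges")
    clusters <- community_cluster(overlap, min_cluster_size, seed = seed)
    say("clusters: ", length(attr(clusters, "sizes")), " (sizes ",
        paste(attr(clusters, "sizes"), collapse = ", "), "), ",
        sum(clusters$cluster == "unclustered"), " genes unclustered")
    if (!is.null(collection)) {
      universe <- rownames(filtered$values)
      ids <- setdiff(unique(clusters$cluster), "unclustered")
      enrichment <- if (!length(ids)) list() else
        lapply(stats::setNames(ids, paste0("cluster", ids)), function(cl)
          ora(clusters$gene[clusters$cluster == cl], universe, collection))
    }
  }

  structure(list(filtered = filtered, threshold = threshold,
                 contrasts = contr, de_genes = de_genes, stacks = stacks,
                 networks = nets, distance_profiles = dists,
                 overlap = overlap, clusters = clusters,
                 enrichment = enrichment,
                 params = list(de = de, network = network,
                               min_cluster_size = min_cluster_size)),
            class = "dcen_pipeline")
}

#' @export
print.dcen_pipeline <- function(x, ...) {
  cat("dcen_pipeline\n")
  cat("  filtered genes:", nrow(x$filtered$values),
      if (is.finite(x$threshold))
        paste0("(background threshold ", signif(x$threshold, 4), ")")
      else "(no background filter)", "\n")
  for (g in names(x$networks)) {
    cat("  [", g, "] DE union: ", length(x$de_genes[[g]]),
        "; network: ", length(x$networks[[g]]$nodes), " nodes / ",
        nrow(x$networks[[g]]$edges), " edges\n", sep = "")
  }
  if (!is.null(x$overlap))
    cat("  overlap: ", length(x$overlap$nodes), " nodes / ",
        nrow(x$overlap$edges), " edges (",
        sum(x$overlap$edges$sign == "-"), " negative)\n", sep = "")
  if (!is.null(x$clusters)) {
    sz <- attr(x$clusters, "sizes")
    cat("  clusters:", paste(sz, collapse = ", "), "| unclustered:",
        sum(x$clusters$cluster == "unclustered"), "\n")
  }
  invisible(x)
}
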