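#' Sign-consistent overlap of two co-expression networks
#'
#' Keeps the gene pairs present in both networks with the same correlation
#' sign — the co-expression behaviour shared across the two conditions.
#' Overlap weight is the mean of the parent weights, support the minimum of
#' the parent supports; nodes are the incident genes only.
#'
#' @param net_a,net_b `coexpression_network`s.
#' @return A `coexpression_network` with provenance
#'   `"overlap(<a>,<b>)"`.
#' @export
overlap_network <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "coexpression_network"),
            inherits(net_b, "coexpression_network"))
  ka <- edge_keys(net_a); kb <- edge_keys(net_b)
  ia <- match(intersect(ka, kb), ka)
  prov <- paste0("overlap(", net_a$provenance, ",", net_b$provenance, ")")
  if (!length(ia)) return(coexpression_network(NULL, provenance = prov))
  ib <- match(ka[ia], kb)
  ea <- net_a$edges[ia, , drop = FALSE]
  eb <- net_b$edges[ib, , drop = FALSE]
  same <- ea$sign == eb$sign
  if (!any(same)) return(coexpression_network(NULL, provenance = prov))
  edges <- data.frame(gene_a = ea$gene_a[same], gene_b = ea$gene_b[same],
                      weight = (ea$weight[same] + eb$weight[same]) / 2,
                      support = pmin(ea$support[same], eb$support[same]),
                      stringsAsFactors = FALSE)
  coexpression_network(edges, provenance = prov)
}

#' Community clustering of a co-expression network
#'
#' Connected components smaller than `min_cluster_size` are labelled
#' `"unclustered"` (isolated correlated pairs stay unclustered); the
#' remaining graph is partitioned by greedy modularity maximisation on the
#' unweighted undirected graph. Communities that come out smaller than
#' `min_cluster_size` are also labelled unclustered, so every numbered
#' cluster has at least `min_cluster_size` members. Cluster ids are dense
#' from 1 in decreasing cluster size (ties broken by first gene id), and
#' the result is deterministic given the canonical node order and seed.
#'
#' @param net A `coexpression_network`.
#' @param min_cluster_size Minimum members of a numbered cluster.
#' @param seed Integer seed (the greedy algorithm is deterministic, but the
#'   seed is fixed for reproducibility of any pluggable alternative).
#' @return A `cluster_assignment`: data frame (`gene`, `cluster`) where
#'   `cluster` is a positive integer as character or `"unclustered"`,
#'   plus a `sizes` attribute.
#' @export
community_cluster <- function(net, min_cluster_size = 3, seed = 1L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!length(net$nodes)) {
    out <- data.frame(gene = character(), cluster = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cluster_assignment", "data.frame")
    attr(out, "sizes") <- integer()
    return(out)
  }
  set.seed(seed)
  g <- as_igraph(net, all_nodes = TRUE)
  comp <- igraph::components(g)
  label <- stats::setNames(rep("unclustered", length(net$nodes)),
                           igraph::V(g)$name)
  big <- which(comp$csize >= min_cluster_size)
  if (length(big)) {
    keep <- igraph::V(g)[comp$membership %in% big]
    sub <- igraph::induced_subgraph(g, keep)
    cm <- igraph::cluster_fast_greedy(
      sub, weights = NA, merges = TRUE, modularity = TRUE)
    # cut the merge dendrogram at maximal modularity ourselves: round away
    # floating-point noise so a whole-graph community (Q = 0 up to epsilon,
    # e.g. a clique) beats strictly negative cuts
    steps <- which.max(round(cm$modularity, 10)) - 1L
    mem <- stats::setNames(igraph::cut_at(cm, steps = steps),
                           igraph::V(sub)$name)
    sizes <- table(mem)
    ok <- names(sizes)[sizes >= min_cluster_size]
    mem <- mem[as.character(mem) %in% ok]
    if (length(mem)) {
      # dense ids 1.. by decreasing size, ties by first member gene id
      first_gene <- tapply(names(mem), mem, min)
      sz <- table(mem)[names(first_gene)]
      ord <- order(-as.integer(sz), first_gene)
      relabel <- stats::setNames(seq_along(ord), names(first_gene)[ord])
      label[names(mem)] <- as.character(relabel[as.character(mem)])
    }
  }
  out <- data.frame(gene = names(label), cluster = unname(label),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_assignment", "data.frame")
  numbered <- out$cluster[out$cluster != "unclustered"]
  attr(out, "sizes") <- if (length(numbered)) {
    tt <- table(as.integer(numbered))
    stats::setNames(as.integer(tt), names(tt))
  } else integer()
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat("cluster_assignment:", length(sz), "clusters",
      sprintf("(sizes %s)", paste(sz, collapse = ", ")),
      "+", sum(x$cluster == "unclustered"), "unclustered genes\n")
  invisible(x)
}

#' Node degrees, sorted
#'
#' @param net A `coexpression_network`.
#' @return Named integer vector of edge counts per node with at least one
#'   edge, sorted by decreasing degree (ties by gene id).
#' @export
degree_report <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!nrow(net$edges)) return(stats::setNames(integer(), character()))
  tab <- table(c(net$edges$gene_a, net$edges$gene_b))
  deg <- stats::setNames(as.integer(tab), names(tab))
  deg[order(-deg, names(deg))]
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set S: with `N = |universe|`, `K = |S inter universe|`,
#' `n = |query|`, `k = |S inter query|`, the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution. Reported rows satisfy
#' `k >= min_overlap`, the number-or-percentage gate
#' (`k >= min_genes OR k/K >= min_fraction`), and `p <= p_threshold`.
#' Adjusted p-values are Benjamini-Hochberg over all sets tested (K > 0),
#' computed before filtering.
#'
#' @param query Gene set of interest (must be contained in `universe`).
#' @param universe Background gene set.
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param min_overlap Minimum overlap count (default 2).
#' @param p_threshold Raw p-value gate (default 0.01).
#' @param min_genes,min_fraction The number-or-percentage gate
#'   (defaults 0 disable it).
#' @return Data frame (`set_name`, `overlap_count`, `set_size_in_universe`,
#'   `p_value`, `adjusted_p`, `overlap_genes`) sorted by p-value;
#'   `overlap_genes` is a comma-separated gene list.
#' @export
ora <- function(query, universe, collection, min_overlap = 2,
                p_threshold = 0.01, min_genes = 0, min_fraction = 0) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) absent from universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    S <- intersect(collection[[nm]]$genes, universe)
    K <- length(S)
    if (!K) return(NULL)
    ov <- intersect(S, query)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k,
               set_size_in_universe = K, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(data.frame(set_name = character(), overlap_count = integer(),
                      set_size_in_universe = integer(),
                      p_value = numeric(), adjusted_p = numeric(),
                      overlap_genes = character()))
  tab$adjusted_p <- stats::p.adjust(tab$p_value, method = "BH")
  keep <- tab$overlap_count >= min_overlap &
    (tab$overlap_count >= min_genes |
       tab$overlap_count / tab$set_size_in_universe >= min_fraction) &
    tab$p_value <= p_threshold
  tab <- tab[keep, c("set_name", "overlap_count", "set_size_in_universe",
                     "p_value", "adjusted_p", "overlap_genes")]
  tab <- tab[order(tab$p_value, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items
#' (1 = identical partitions, ~0 = chance agreement).
#'
#' @param x,y Vectors of cluster labels of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("label vectors differ in length")
  if (length(x) < 2) return(1)
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  d <- choose(sum(tab), 2)
  expected <- b * c_ / d
  denom <- (b + c_) / 2 - expected
  if (denom == 0) return(1)
  (a - expected) / denom
}
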