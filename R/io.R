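# Native tabular dialect is TSV, UTF-8, no quoting; reals are written with
# "%.17g" so that write -> read round-trips are bit-exact.

fmt_real <- function(x) sprintf("%.17g", x)

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is TSV with gene ids in the first column and sample ids
#' in the header; the sample sheet is TSV with columns `sample_id`,
#' `individual_id`, `group`, `timepoint`, `sex`. Every matrix sample must be
#' annotated and vice versa; missing or non-numeric expression cells are an
#' error.
#'
#' @param matrix_path Path to the expression TSV.
#' @param samplesheet_path Path to the sample sheet TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  tab <- read_tsv_raw(matrix_path)
  if (ncol(tab) < 2) stop("expression matrix has no sample columns")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers in expression matrix")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals))
    stop("non-numeric or missing expression cells in ", matrix_path)
  rownames(vals) <- gene_ids
  sheet <- read_tsv_raw(samplesheet_path)
  expression_study(vals, sheet)
}

#' Write an expression study to TSV
#'
#' @param expr An `expression_study`.
#' @param matrix_path Output path for the expression TSV.
#' @param samplesheet_path Optional output path for the sample sheet TSV.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, matrix_path, samplesheet_path = NULL) {
  stopifnot(inherits(expr, "expression_study"))
  chr <- apply(expr$values, 2, fmt_real)
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(expr$values))
  out <- data.frame(gene_id = rownames(expr$values), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(expr$values))
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samplesheet_path))
    utils::write.table(expr$samples, samplesheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(expr)
}

#' Read a gene-to-chromosome map
#'
#' TSV with columns `gene_id` and `chromosome`; chromosome label `"Y"`
#' identifies Y-chromosome genes for the background filter.
#'
#' @param path Path to the TSV.
#' @return Named character vector, gene id -> chromosome label.
#' @export
read_chromosome_map <- function(path) {
  tab <- read_tsv_raw(path)
  miss <- setdiff(c("gene_id", "chromosome"), names(tab))
  if (length(miss))
    stop("chromosome map lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in chromosome map")
  stats::setNames(as.character(tab$chromosome), as.character(tab$gene_id))
}

#' Write a gene-to-chromosome map
#' @param chrom Named character vector, gene id -> chromosome.
#' @param path Output path.
#' @export
write_chromosome_map <- function(chrom, path) {
  utils::write.table(
    data.frame(gene_id = names(chrom), chromosome = unname(chrom)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(chrom)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB ...`.
#' Duplicate genes within a line are de-duplicated; fewer than three fields
#' or a repeated set name is an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of `list(description =, genes =)`, class
#'   `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line with fewer than 3 fields: ",
           substr(ln, 1, 40))
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    g <- unique(fields[-(1:2)])
    g <- g[nzchar(g)]
    if (!length(g)) stop("empty gene set: ", nm)
    sets[[nm]] <- list(description = fields[2], genes = g)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param collection A `gene_set_collection` (or compatible named list).
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets\n")
  invisible(x)
}

#' Write a co-expression network
#'
#' `edge_tsv` has columns `source`, `target`, `weight`, `support`, `sign`
#' (reals at full precision, so read-back is exact); `sif` uses relations
#' `"pos"`/`"neg"`; `graphml` carries weight/support/sign as edge
#' attributes.
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @param format `"edge_tsv"`, `"sif"` or `"graphml"`.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, path,
                          format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "coexpression_network"))
  format <- match.arg(format)
  e <- net$edges
  if (format == "edge_tsv") {
    out <- data.frame(source = e$gene_a, target = e$gene_b,
                      weight = fmt_real(e$weight),
                      support = fmt_real(e$support),
                      sign = e$sign, stringsAsFactors = FALSE)
    if (!nrow(e))
      out <- data.frame(source = character(), target = character(),
                        weight = character(), support = character(),
                        sign = character())
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    rel <- ifelse(e$sign == "+", "pos", "neg")
    writeLines(paste(e$gene_a, rel, e$gene_b), path)
  } else {
    writeLines(graphml_lines(net), path)
  }
  invisible(net)
}

# GraphML serialised in-package: edge reals are written with "%.17g" so a
# write -> read round-trip is bit-exact (igraph's own writer rounds to 15
# significant digits). Reading uses igraph's GraphML parser.
graphml_lines <- function(net) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  e <- net$edges
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="v_name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="e_weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="e_support" for="edge" attr.name="support" attr.type="double"/>',
    '  <key id="e_sign" for="edge" attr.name="sign" attr.type="string"/>',
    '  <graph edgedefault="undirected">',
    vapply(seq_along(net$nodes), function(i) sprintf(
      '    <node id="n%d"><data key="v_name">%s</data></node>',
      i - 1L, esc(net$nodes[i])), character(1)),
    if (nrow(e)) vapply(seq_len(nrow(e)), function(k) sprintf(
      paste0('    <edge source="n%d" target="n%d">',
             '<data key="e_weight">%s</data>',
             '<data key="e_support">%s</data>',
             '<data key="e_sign">%s</data></edge>'),
      match(e$gene_a[k], net$nodes) - 1L,
      match(e$gene_b[k], net$nodes) - 1L,
      fmt_real(e$weight[k]), fmt_real(e$support[k]), e$sign[k]),
      character(1)),
    '  </graph>',
    '</graphml>')
}

#' Read a co-expression network
#'
#' Inverse of [write_network()]. `edge_tsv` and `graphml` restore weights
#' and supports exactly; `sif` carries topology and sign only, so weights
#' are restored as +/-1 and supports as 1.
#'
#' @param path Input path.
#' @param format `"edge_tsv"`, `"sif"` or `"graphml"`.
#' @param provenance Provenance label for the restored network.
#' @return A `coexpression_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "sif", "graphml"),
                         provenance = "") {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    tab <- read_tsv_raw(path)
    if (!nrow(tab)) return(coexpression_network(NULL, provenance = provenance))
    edges <- data.frame(gene_a = tab$source, gene_b = tab$target,
                        weight = as.numeric(tab$weight),
                        support = as.numeric(tab$support),
                        stringsAsFactors = FALSE)
    coexpression_network(edges, provenance = provenance)
  } else if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(coexpression_network(NULL, provenance = provenance))
    parts <- strsplit(lines, "[ \t]+")
    edges <- data.frame(
      gene_a = vapply(parts, `[`, "", 1L),
      gene_b = vapply(parts, `[`, "", 3L),
      weight = ifelse(vapply(parts, `[`, "", 2L) == "pos", 1, -1),
      support = 1, stringsAsFactors = FALSE)
    coexpression_network(edges, provenance = provenance)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- igraph::V(g)$name
    if (!nrow(ed))
      return(coexpression_network(NULL, nodes = nodes,
                                  provenance = provenance))
    edges <- data.frame(gene_a = ed$from, gene_b = ed$to,
                        weight = ed$weight, support = ed$support,
                        stringsAsFactors = FALSE)
    coexpression_network(edges, nodes = nodes, provenance = provenance)
  }
}

#' Write a differential-expression contrast result to TSV
#' @param result A `contrast_result`.
#' @param path Output path.
#' @export
write_contrast <- function(result, path) {
  stopifnot(inherits(result, "contrast_result"))
  out <- result$table
  for (cl in c("log2fc", "fc", "t_stat", "p_value", "q_value"))
    out[[cl]] <- fmt_real(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(result)
}
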