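#' Y-chromosome noise-floor threshold
#'
#' Y-chromosome genes are not expressed in females, so their measured
#' signal in female samples is a biological negative control for the
#' platform's noise floor. The default pools every (Y gene, female sample)
#' value into one vector and takes its median; `method = "per_gene"`
#' instead takes the median of per-gene medians over female samples.
#'
#' @param expr An `expression_study`.
#' @param chrom Named chromosome map (gene -> chromosome, `"Y"` marks
#'   Y-chromosome genes).
#' @param method `"pooled"` (default) or `"per_gene"`.
#' @return The threshold, in log2 units.
#' @export
y_background_threshold <- function(expr, chrom,
                                   method = c("pooled", "per_gene")) {
  stopifnot(inherits(expr, "expression_study"))
  method <- match.arg(method)
  female <- expr$samples$sample_id[expr$samples$sex == "female"]
  if (!length(female)) stop("no female samples in the study")
  y_genes <- intersect(rownames(expr$values),
                       names(chrom)[chrom == "Y"])
  if (!length(y_genes))
    stop("no Y-chromosome genes present in the expression matrix")
  block <- expr$values[y_genes, female, drop = FALSE]
  if (method == "pooled") stats::median(as.vector(block))
  else stats::median(apply(block, 1, stats::median))
}

#' Remove background-level genes
#'
#' Keeps exactly the genes whose median expression across all samples is
#' strictly greater than the threshold; genes whose median is equal to or
#' lower than the threshold are removed. The sample set is unchanged.
#'
#' @param expr An `expression_study`.
#' @param threshold Log2 threshold, typically from
#'   [y_background_threshold()].
#' @return The filtered `expression_study`; the number of genes removed is
#'   available as `attr(, "n_removed")` and the removed ids as
#'   `attr(, "removed")`.
#' @export
filter_background <- function(expr, threshold) {
  stopifnot(inherits(expr, "expression_study"))
  if (!is.finite(threshold) && !identical(threshold, -Inf))
    stop("threshold must be finite (or -Inf for no filtering)")
  med <- apply(expr$values, 1, stats::median)
  keep <- med > threshold
  if (!any(keep))
    stop("background filter removed every gene; degenerate threshold ",
         format(threshold))
  out <- expression_study(expr$values[keep, , drop = FALSE], expr$samples)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed") <- rownames(expr$values)[!keep]
  out
}
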