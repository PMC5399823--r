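#' Ward clustering of samples on their MSAP characteristics
#'
#' Agglomerative hierarchical clustering of the per-sample
#' characteristic vectors using squared Euclidean distance and Ward's
#' criterion (Lance-Williams update, \code{stats::hclust} method
#' \code{"ward.D"} on squared distances). An automatic truncation cuts
#' the tree where the gap between successive merge heights is largest,
#' mirroring the usual "automatic truncation" of clustering software.
#'
#' @param x A fitted [msap()] object or an unrounded characteristics
#'   matrix (characteristics x samples).
#' @param k Number of clusters; \code{NULL} (default) picks it by the
#'   largest merge-height gap.
#' @return Object of class \code{msap_cluster}: list with the
#'   \code{hclust} tree, \code{k}, the \code{clusters} assignment and
#'   the merge \code{heights}. Methods: \code{print}, \code{plot}.
#' @examples
#' counts <- read_code_counts(msap_example("triticale_code_counts.tsv"))
#' cl <- msap_cluster(msap(counts))
#' cl$clusters
#' @export
msap_cluster <- function(x, k = NULL) {
  pct <- if (inherits(x, "msap")) x$characteristics else as.matrix(x)
  if (ncol(pct) < 2) stop("clustering needs at least 2 samples", call. = FALSE)
  d2 <- stats::dist(t(pct))^2
  hc <- stats::hclust(stats::as.dist(d2), method = "ward.D")
  n <- ncol(pct)
  if (is.null(k)) {
    k <- if (n == 2) 2L else n - which.max(diff(hc$height))
  }
  structure(list(hclust = hc, k = k,
                 clusters = stats::cutree(hc, k = k),
                 heights = hc$height),
            class = "msap_cluster")
}

#' @export
print.msap_cluster <- function(x, ...) {
  cat("Ward / squared-Euclidean clustering of", length(x$clusters),
      "samples; automatic truncation at k =", x$k, "\n")
  print(split(names(x$clusters), x$clusters))
  invisible(x)
}

#' @export
plot.msap_cluster <- function(x, main = "MSAP characteristics (Ward)", ...) {
  plot(x$hclust, main = main,
       xlab = "", sub = "", ylab = "Ward criterion", ...)
  if (x$k > 1 && length(x$clusters) > 2) {
    h <- x$heights
    cut_at <- mean(h[(length(h) - x$k + 1):(length(h) - x$k + 2)])
    if (is.finite(cut_at)) graphics::abline(h = cut_at, lty = 3)
  }
  invisible(x)
}

#' Export a clustering as a Newick tree
#'
#' Converts the merge tree to a phylogeny (branch lengths derive from
#' merge heights) and writes Newick text.
#'
#' @param x An \code{msap_cluster} object.
#' @param path Output file.
#' @return Invisibly, the \code{ape::phylo} tree.
#' @export
write_cluster_newick <- function(x, path) {
  tree <- ape::as.phylo(x$hclust)
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Write the truncated cluster assignment
#'
#' @param x An \code{msap_cluster} object.
#' @param path Output file (two-column TSV: sample, cluster).
#' @param header Optional \code{#}-prefixed comment lines.
#' @return Invisibly, \code{x}.
#' @export
write_cluster_assignments <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(sample = names(x$clusters),
                                cluster = unname(x$clusters)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
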