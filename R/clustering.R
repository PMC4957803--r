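#' Hierarchically cluster samples on a gene panel
#'
#' Clusters the samples of an expression matrix restricted to a gene panel,
#' using correlation distance (`1 - Pearson R` between sample profiles) and
#' average linkage by default - the usual choices for expression heatmaps.
#' Genes are standardized (per-gene z-score across samples) first, the
#' heatmap convention; zero-variance genes are dropped with a warning
#' before standardization.
#'
#' @param em an ExpressionMatrix (sample sheet optional).
#' @param panel optional [gene_set()]; NULL clusters on all probes.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage any method accepted by [stats::hclust()], default
#'   `"average"`.
#' @param standardize z-score genes before clustering (default TRUE).
#' @return an [stats::hclust()] object with extra class
#'   `"sample_dendrogram"` and attributes `metric`, `linkage`, `panel_size`.
#' @export
cluster_samples <- function(em, panel = NULL,
                            metric = c("correlation", "euclidean"),
                            linkage = "average", standardize = TRUE) {
  metric <- match.arg(metric)
  E <- em$E
  if (!is.null(panel)) {
    tab <- data.frame(probe_id = em$genes$probe_id,
                      gene_symbol = em$genes$gene_symbol)
    idx <- match_gene_set(tab, panel, allow_missing = TRUE)
    if (length(idx) < 2L)
      stop2("panel must match at least 2 genes in the matrix")
    E <- E[idx, , drop = FALSE]
  }
  if (nrow(E) < 2L) stop2("need at least 2 genes to cluster samples")
  if (ncol(E) < 3L) stop2("need at least 3 samples to cluster")
  gene_sd <- apply(E, 1L, stats::sd)
  if (standardize) {
    flat <- gene_sd == 0
    if (any(flat)) {
      warning(sum(flat), " zero-variance gene(s) dropped before standardization",
              call. = FALSE)
      E <- E[!flat, , drop = FALSE]
      if (nrow(E) < 2L) stop2("fewer than 2 variable genes in the panel")
    }
    E <- (E - rowMeans(E)) / apply(E, 1L, stats::sd)
  }
  if (metric == "correlation") {
    prof_sd <- apply(E, 2L, stats::sd)
    if (any(prof_sd == 0))
      stop2("zero-variance sample profile(s): ",
            paste(colnames(E)[prof_sd == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(E))
  } else {
    d <- stats::dist(t(E))
  }
  hc <- stats::hclust(d, method = linkage)
  class(hc) <- c("sample_dendrogram", "hclust")
  attr(hc, "metric") <- metric
  attr(hc, "linkage") <- linkage
  attr(hc, "panel_size") <- nrow(E)
  hc
}

#' Cluster membership of query samples at a k-cluster cut
#'
#' Cuts the dendrogram into `k` clusters and reports, for each query
#' sample, its cluster and the co-members of that cluster -
#' operationalizing "sample X clusters with group Y" statements.
#'
#' @param dend a [cluster_samples()] result.
#' @param query character vector of sample ids (must be dendrogram leaves).
#' @param k number of clusters, `2 <= k <=` number of leaves.
#' @return data.frame `sample`, `cluster`, `co_members`
#'   (comma-separated); full assignment in attribute `assignment`.
#' @export
nearest_major_cluster <- function(dend, query, k = 2) {
  if (k < 2) stop2("k must be at least 2")
  n <- length(dend$labels)
  if (k > n) stop2("k cannot exceed the number of leaves (", n, ")")
  miss <- setdiff(query, dend$labels)
  if (length(miss))
    stop2("query sample(s) not in dendrogram: ", paste(miss, collapse = ", "))
  cl <- stats::cutree(dend, k = k)
  out <- data.frame(sample = query, cluster = unname(cl[query]))
  out$co_members <- vapply(query, function(s) {
    members <- names(cl)[cl == cl[[s]]]
    paste(setdiff(members, s), collapse = ",")
  }, "")
  rownames(out) <- NULL
  attr(out, "assignment") <- cl
  out
}

#' Write a dendrogram's merge history as a linkage TSV
#' @param dend an hclust-like object.
#' @param path output path.
#' @export
write_linkage <- function(dend, path) {
  tab <- data.frame(node1 = dend$merge[, 1L], node2 = dend$merge[, 2L],
                    height = dend$height)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sample dendrogram as Newick text
#' @param dend an hclust-like object.
#' @param path output path.
#' @export
write_newick <- function(dend, path) {
  build <- function(i) {
    # negative entries are leaves, positive are earlier merges
    node <- function(j, h) {
      if (j < 0) sprintf("%s:%g", dend$labels[-j], h)
      else sprintf("%s:%g", build(j), h - dend$height[j])
    }
    h <- dend$height[i]
    sprintf("(%s,%s)", node(dend$merge[i, 1L], h), node(dend$merge[i, 2L], h))
  }
  writeLines(paste0(build(nrow(dend$merge)), ";"), path)
  invisible(path)
}
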