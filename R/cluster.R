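#' Filter to consistently expressed, variable genes
#'
#' Keeps genes that are significantly expressed in every sample and whose
#' coefficient of variation (SD/mean of the untransformed per-sample
#' values) exceeds `cv_threshold`. The CV is computed on the linear RPKM
#' scale because it is scale-dependent and defined as SD over mean of the
#' measurement itself.
#'
#' @param matrix Numeric gene x sample matrix of untransformed (linear
#'   scale) expression values.
#' @param flags Logical matrix of the same shape: per-cell significance of
#'   expression.
#' @param cv_threshold CV cutoff (default 0.33, strict inequality).
#' @return Character vector of retained gene ids (possibly empty).
#' @export
filter_genes <- function(matrix, flags, cv_threshold = 0.33) {
  m <- as.matrix(matrix)
  stopifnot(identical(dim(m), dim(flags)))
  all_sig <- rowSums(!flags) == 0
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  rownames(m)[all_sig & cv > cv_threshold]
}

#' Per-condition log2 fold-change profiles
#'
#' Replicate samples are averaged per condition on the linear scale; each
#' condition's log2 mean expression is then centred on the gene's mean
#' log2 expression over all conditions, so every profile averages to zero
#' across equally weighted conditions.
#'
#' @param matrix Numeric gene x sample matrix on the linear scale.
#' @param replicate_map Named character vector: sample id -> condition
#'   label. Condition order follows first appearance.
#' @param floor Positive floor applied before log2.
#' @return Numeric gene x condition matrix of log2 fold changes.
#' @export
condition_profiles <- function(matrix, replicate_map, floor = 0.01) {
  m <- as.matrix(matrix)
  unmapped <- setdiff(colnames(m), names(replicate_map))
  if (length(unmapped))
    stop("samples without a condition: ", paste(unmapped, collapse = ", "))
  cond <- replicate_map[colnames(m)]
  levels <- unique(unname(cond))
  cond_log2 <- vapply(levels, function(cc) {
    log2(pmax(rowMeans(m[, cond == cc, drop = FALSE]), floor))
  }, numeric(nrow(m)))
  cond_log2 <- matrix(cond_log2, nrow = nrow(m),
                      dimnames = list(rownames(m), levels))
  cond_log2 - rowMeans(cond_log2)
}

#' K-means clustering of expression profiles
#'
#' Euclidean K-means on log2 fold-change profiles, best of `n_restarts`
#' random initialisations by within-cluster sum of squares. Restarts that
#' fail (for instance an empty cluster under a poor initialisation) are
#' replaced by additional draws so a total partition is always returned.
#'
#' @param profiles Numeric gene x condition matrix (see
#'   [condition_profiles]).
#' @param k Number of clusters, 1 <= k <= number of genes.
#' @param seed Integer seed; results are deterministic for a fixed seed.
#' @param n_restarts Number of random initialisations (default 50).
#' @return A `gene_clusters` object: list with `membership` (named integer
#'   vector), `clusters` (per-cluster list with id, members, mean_profile),
#'   `wcss` and `conditions`.
#' @export
kmeans_cluster <- function(profiles, k, seed = 1L, n_restarts = 50) {
  profiles <- as.matrix(profiles)
  if (k < 1 || k > nrow(profiles))
    stop("k must be between 1 and the number of profiles")
  set.seed(seed)
  # initial centers are drawn from the distinct profiles so that exactly
  # repeated profiles (e.g. noise-free replicates) cannot abort a restart
  uniqp <- unique(profiles)
  if (nrow(uniqp) < k)
    stop("fewer distinct profiles (", nrow(uniqp), ") than clusters")
  best <- NULL
  tries <- 0
  done <- 0
  while (done < n_restarts && tries < 10 * n_restarts) {
    tries <- tries + 1
    centers <- uniqp[sample.int(nrow(uniqp), k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(profiles, centers = centers,
                                     iter.max = 100)),
      error = function(e) tryCatch(
        suppressWarnings(stats::kmeans(profiles, centers = centers,
                                       iter.max = 100,
                                       algorithm = "Lloyd")),
        error = function(e2) NULL))
    if (is.null(fit) || any(fit$size == 0)) next
    done <- done + 1
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce a total partition")
  membership <- stats::setNames(best$cluster, rownames(profiles))
  clusters <- lapply(seq_len(k), function(i) {
    members <- names(membership)[membership == i]
    list(id = i, members = members,
         mean_profile = colMeans(profiles[members, , drop = FALSE]))
  })
  structure(list(membership = membership, clusters = clusters,
                 wcss = best$tot.withinss, conditions = colnames(profiles)),
            class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("gene_clusters: %d clusters over %d genes (sizes %s)\n",
              length(x$clusters), length(x$membership),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Annotation-term enrichment of a gene set
#'
#' Upper-tail cumulative binomial enrichment of each annotation term in a
#' cluster against its frequency in a background gene set (see
#' [cbd_enrichment_p]). Terms never seen in the background are skipped.
#'
#' @param members Character vector of cluster gene ids (subset of
#'   `background`).
#' @param annotations Named list: gene id -> character vector of terms, or
#'   a two-column data.frame (gene, term).
#' @param background Character vector of background gene ids.
#' @param alpha Significance cutoff (default 0.05); only terms with
#'   p < alpha are returned.
#' @return data.frame with columns term, p, n_members (carriers in the
#'   cluster), sorted by p.
#' @export
enrich_terms <- function(members, annotations, background, alpha = 0.05) {
  if (is.data.frame(annotations))
    annotations <- split(as.character(annotations[[2]]),
                         as.character(annotations[[1]]))
  if (!all(members %in% background))
    stop("cluster members must be a subset of the background")
  bg_terms <- annotations[intersect(background, names(annotations))]
  term_bg <- table(unlist(lapply(bg_terms, unique), use.names = FALSE))
  cl_terms <- annotations[intersect(members, names(annotations))]
  term_cl <- table(unlist(lapply(cl_terms, unique), use.names = FALSE))
  n <- length(members)
  nb <- length(background)
  terms <- names(term_cl)[names(term_cl) %in% names(term_bg)]
  if (!length(terms))
    return(data.frame(term = character(), p = numeric(),
                      n_members = integer()))
  x <- as.integer(term_cl[terms])
  f <- as.numeric(term_bg[terms]) / nb
  p <- cbd_enrichment_p(x, n, f)
  out <- data.frame(term = terms, p = p, n_members = x,
                    stringsAsFactors = FALSE)
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
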