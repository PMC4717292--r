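#' Correlate metabolite turnover with cluster expression profiles
#'
#' Pearson correlation, over the shared condition axis, between each
#' metabolite's turnover-score profile and each gene cluster's mean log2
#' fold-change profile. Profiles with zero variance give an undefined
#' coefficient, recorded as NA.
#'
#' @param scores A `turnover_scores` object (see [prmt_scores]).
#' @param clusters A `gene_clusters` object (see [kmeans_cluster]).
#' @param condition_map Optional named character vector renaming turnover
#'   conditions to cluster conditions; by default shared names are used.
#' @return A `correlation_matrix`: list with `r` (metabolite x cluster
#'   matrix) and `conditions` (the shared axis).
#' @export
correlate_turnover <- function(scores, clusters, condition_map = NULL) {
  sm <- scores$scores
  if (!is.null(condition_map))
    colnames(sm) <- ifelse(colnames(sm) %in% names(condition_map),
                           condition_map[colnames(sm)], colnames(sm))
  shared <- intersect(colnames(sm), clusters$conditions)
  if (length(shared) < 3) stop("need >= 3 shared conditions")
  prof <- vapply(clusters$clusters, function(cl) cl$mean_profile[shared],
                 numeric(length(shared)))
  colnames(prof) <- vapply(clusters$clusters, function(cl)
    as.character(cl$id), "")
  sm <- sm[, shared, drop = FALSE]
  r <- matrix(NA_real_, nrow(sm), ncol(prof),
              dimnames = list(rownames(sm), colnames(prof)))
  sd_m <- apply(sm, 1, stats::sd)
  sd_c <- apply(prof, 2, stats::sd)
  ok_m <- sd_m > 0
  ok_c <- sd_c > 0
  if (any(ok_m) && any(ok_c))
    r[ok_m, ok_c] <- stats::cor(t(sm[ok_m, , drop = FALSE]),
                                prof[, ok_c, drop = FALSE])
  structure(list(r = r, conditions = shared), class = "correlation_matrix")
}

#' Select the strongest metabolite-cluster correlations
#'
#' Keeps the pairs in the top and bottom `percentile` fraction of the
#' pooled empirical distribution of all metabolite x cluster coefficients
#' (strictly beyond the two quantile cutoffs). Negative-r links are
#' flagged as synthesis-coupled: increased predicted synthesis of the
#' metabolite (negative turnover score) tracking increased cluster
#' expression.
#'
#' @param corr A `correlation_matrix` (see [correlate_turnover]).
#' @param percentile Tail fraction (default 0.001).
#' @return data.frame with columns metabolite, cluster, r, coupling
#'   ("consumption_coupled" or "synthesis_coupled").
#' @export
select_strong_links <- function(corr, percentile = 0.001) {
  r <- corr$r
  if (!length(r)) stop("empty correlation matrix")
  pool <- r[!is.na(r)]
  idx <- which(!is.na(r), arr.ind = TRUE)
  vals <- r[!is.na(r)]
  if (length(pool) < 1 / percentile) {
    warning("fewer pairs than 1/percentile; keeping only the extreme pair")
    sel <- c(which.min(vals), which.max(vals))
  } else {
    cuts <- stats::quantile(pool, c(percentile, 1 - percentile),
                            names = FALSE)
    sel <- which(vals < cuts[1] | vals > cuts[2])
    if (!length(sel))
      warning("no coefficient strictly beyond the percentile cutoffs")
  }
  out <- data.frame(
    metabolite = rownames(r)[idx[sel, 1]],
    cluster = colnames(r)[idx[sel, 2]],
    r = vals[sel],
    coupling = ifelse(vals[sel] < 0, "synthesis_coupled",
                      "consumption_coupled"),
    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Link sensor complexes to gene clusters by shared genes
#'
#' A complex is presumed to regulate a cluster when the two share at least
#' one gene; the intersection is kept as evidence.
#'
#' @param complexes List of `sensor_complex` objects.
#' @param clusters A `gene_clusters` object.
#' @return data.frame with columns complex, cluster, n_shared and a list
#'   column shared_genes.
#' @export
link_complexes_to_clusters <- function(complexes, clusters) {
  rows <- list()
  for (cx in complexes) {
    for (cl in clusters$clusters) {
      shared <- intersect(cx$nodes$gene, cl$members)
      if (!length(shared)) next
      rows[[length(rows) + 1L]] <- data.frame(
        complex = cx$id, cluster = as.character(cl$id),
        n_shared = length(shared), stringsAsFactors = FALSE)
      rows[[length(rows)]]$shared_genes <- list(shared)
    }
  }
  if (!length(rows))
    return(data.frame(complex = character(), cluster = character(),
                      n_shared = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Assemble the integrated signal-to-phenotype model
#'
#' Applies the four assembly rules: (1) complexes regulate the clusters
#' they share genes with; (2) strongly correlated metabolites signal
#' through the complex associated with their cluster (a metabolite whose
#' cluster has no linked complex is emitted as a dangling signal edge with
#' a warning); (3) binding motifs connect to clusters from two evidence
#' channels -- motifs of complex transcription factors and motifs enriched
#' in the cluster -- labelled by source; (4) each linked cluster's
#' significantly enriched annotation terms become its predicted phenotype.
#' Complex member proteins are included as role-typed nodes with member-of
#' edges.
#'
#' @param strong_links Output of [select_strong_links].
#' @param complex_links Output of [link_complexes_to_clusters].
#' @param complexes List of `sensor_complex` objects.
#' @param motif_enrichments data.frame of per-cluster motif enrichment
#'   with a `cluster` column (rows with passes = TRUE are used).
#' @param complex_tf_motifs Output of [motifs_for_complex_tfs]; rows with
#'   n_carriers > 0 contribute motif edges for linked complex/cluster
#'   pairs.
#' @param phenotypes Named list: cluster id -> [enrich_terms] data.frame.
#' @return An `integrated_model`: list with `nodes` (id, type, label) and
#'   `edges` (from, to, type, rule, evidence) data.frames, canonically
#'   ordered so assembly is order-independent in its inputs.
#' @export
assemble_model <- function(strong_links, complex_links, complexes,
                           motif_enrichments = NULL,
                           complex_tf_motifs = NULL, phenotypes = NULL) {
  nodes <- list()
  edges <- list()
  add_node <- function(id, type, label = id) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, type = type, label = label, stringsAsFactors = FALSE)
  }
  add_edge <- function(from, to, type, rule, evidence) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, rule = rule,
      evidence = evidence, stringsAsFactors = FALSE)
  }
  cluster_node <- function(cl) paste0("cluster:", cl)

  linked_clusters <- character()

  # rule 1: complex -> cluster, with member proteins attached
  by_id <- stats::setNames(complexes,
                           vapply(complexes, `[[`, "", "id"))
  if (nrow(complex_links)) {
    for (i in seq_len(nrow(complex_links))) {
      cx <- complex_links$complex[i]
      cl <- complex_links$cluster[i]
      add_node(cx, "complex")
      add_node(cluster_node(cl), "cluster", paste("cluster", cl))
      add_edge(cx, cluster_node(cl), "regulates", 1L,
               paste0("shared_genes=", complex_links$n_shared[i]))
      linked_clusters <- c(linked_clusters, cl)
      for (j in seq_len(nrow(by_id[[cx]]$nodes))) {
        gene <- by_id[[cx]]$nodes$gene[j]
        add_node(gene, by_id[[cx]]$nodes$role[j])
        add_edge(gene, cx, "member-of", 1L, "complex membership")
      }
    }
  }

  # rule 2: metabolite signals, routed through the cluster's complex
  if (nrow(strong_links)) {
    for (i in seq_len(nrow(strong_links))) {
      met <- strong_links$metabolite[i]
      cl <- strong_links$cluster[i]
      ev <- sprintf("r=%.4f;%s", strong_links$r[i],
                    strong_links$coupling[i])
      add_node(paste0("metabolite:", met), "metabolite", met)
      cxs <- complex_links$complex[complex_links$cluster == cl]
      if (length(cxs)) {
        for (cx in cxs)
          add_edge(paste0("metabolite:", met), cx, "signals", 2L, ev)
      } else {
        warning("metabolite ", met, " correlates with cluster ", cl,
                " which has no linked sensor complex; dangling signal edge")
        add_node(cluster_node(cl), "cluster", paste("cluster", cl))
        add_edge(paste0("metabolite:", met), cluster_node(cl), "signals",
                 2L, ev)
      }
      # the metabolite-cluster correlation itself stays traceable
      add_node(cluster_node(cl), "cluster", paste("cluster", cl))
      add_edge(paste0("metabolite:", met), cluster_node(cl),
               "correlates", 2L, ev)
    }
  }

  # rule 3: motif edges from both evidence channels
  if (!is.null(motif_enrichments) && nrow(motif_enrichments)) {
    hits <- motif_enrichments[motif_enrichments$passes, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      cl <- as.character(hits$cluster[i])
      add_node(paste0("motif:", hits$motif[i]), "motif", hits$motif[i])
      add_node(cluster_node(cl), "cluster", paste("cluster", cl))
      add_edge(paste0("motif:", hits$motif[i]), cluster_node(cl),
               "binds-motif", 3L,
               sprintf("source=enriched;p=%.3g;x=%d", hits$p[i],
                       hits$x[i]))
    }
  }
  if (!is.null(complex_tf_motifs) && nrow(complex_tf_motifs)) {
    ct <- complex_tf_motifs[complex_tf_motifs$n_carriers > 0, ,
                            drop = FALSE]
    if (nrow(complex_links)) {
      linked <- paste(complex_links$complex, complex_links$cluster)
      ct <- ct[paste(ct$complex, ct$cluster) %in% linked, , drop = FALSE]
    } else {
      ct <- ct[0, , drop = FALSE]
    }
    for (i in seq_len(nrow(ct))) {
      cl <- as.character(ct$cluster[i])
      add_node(paste0("motif:", ct$motif[i]), "motif", ct$motif[i])
      add_node(cluster_node(cl), "cluster", paste("cluster", cl))
      add_edge(paste0("motif:", ct$motif[i]), cluster_node(cl),
               "binds-motif", 3L,
               sprintf("source=complex_tf;tf=%s;carriers=%d",
                       ct$tf_gene[i], ct$n_carriers[i]))
    }
  }

  # rule 4: enriched annotations of linked clusters become phenotypes
  if (!is.null(phenotypes)) {
    for (cl in intersect(unique(linked_clusters), names(phenotypes))) {
      ph <- phenotypes[[cl]]
      for (i in seq_len(nrow(ph))) {
        add_node(paste0("phenotype:", ph$term[i]), "phenotype",
                 ph$term[i])
        add_edge(cluster_node(cl), paste0("phenotype:", ph$term[i]),
                 "enriched-phenotype", 4L,
                 sprintf("p=%.3g;n=%d", ph$p[i], ph$n_members[i]))
      }
    }
  }

  nodes <- if (length(nodes)) {
    nd <- do.call(rbind, c(nodes, list(make.row.names = FALSE)))
    nd <- nd[!duplicated(nd$id), , drop = FALSE]
    nd[order(nd$type, nd$id), , drop = FALSE]
  } else {
    data.frame(id = character(), type = character(), label = character())
  }
  edges <- if (length(edges)) {
    ed <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
    ed <- ed[!duplicated(ed[c("from", "to", "type", "evidence")]), ,
             drop = FALSE]
    ed[order(ed$rule, ed$from, ed$to), , drop = FALSE]
  } else {
    data.frame(from = character(), to = character(), type = character(),
               rule = integer(), evidence = character())
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "integrated_model")
}

#' @export
print.integrated_model <- function(x, ...) {
  cat(sprintf("integrated_model: %d nodes, %d edges\n", nrow(x$nodes),
              nrow(x$edges)))
  if (nrow(x$nodes))
    print(table(x$nodes$type))
  invisible(x)
}

#' Export an integrated model as GraphML
#'
#' Node and edge attributes (type, rule, evidence) are preserved as typed
#' GraphML attributes for downstream network tools.
#'
#' @param model An `integrated_model`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_model_graphml <- function(model, path) {
  if (!nrow(model$nodes)) stop("cannot serialise an empty model")
  g <- igraph::graph_from_data_frame(model$edges, directed = TRUE,
                                     vertices = model$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export an integrated model as flat JSON
#'
#' @param model An `integrated_model`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(nodes = model$nodes, edges = model$edges),
                       path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
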