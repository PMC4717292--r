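#' Run the full multi-omics inference pipeline on a synthetic world
#'
#' Chains every stage: gene filtering and condition profiling of the host
#' expression matrix, K-means co-expression clustering with annotation
#' (phenotype) enrichment, upstream motif association and per-cluster
#' enrichment, sensor-complex prediction (rank-based co-expression
#' network, likelihood-of-interaction refinement, connected components),
#' symbiont turnover scoring (quantile normalisation, enzyme-function
#' abundance, pathway-restricted reaction network), metabolite-cluster
#' correlation, and the four-rule assembly of the integrated model.
#'
#' @param world A `synthetic_world` (see [generate_world] /
#'   [import_world]).
#' @param k Number of K-means clusters (default the world's planted
#'   count).
#' @param cv_threshold Coefficient-of-variation filter (default 0.33).
#' @param enrich_alpha Annotation-enrichment threshold (default 0.05).
#' @param motif_alpha,motif_min_genes Motif-enrichment thresholds
#'   (defaults 0.01 and 10).
#' @param neighborhood,pcc_alpha Co-expression network parameters
#'   (defaults 5 and 0.01).
#' @param loi_iterations,loi_threshold Likelihood-of-interaction
#'   parameters (defaults 10000 and 1).
#' @param percentile Tail fraction for strong metabolite-cluster links
#'   (default 0.001).
#' @param n_restarts K-means restarts (default 50).
#' @param seed Integer seed covering clustering and resampling.
#' @return A `pipeline_result` list with every intermediate product and
#'   the assembled `model`.
#' @export
run_pipeline <- function(world, k = world$config$k_means_k,
                         cv_threshold = 0.33, enrich_alpha = 0.05,
                         motif_alpha = 0.01, motif_min_genes = 10,
                         neighborhood = 5, pcc_alpha = 0.01,
                         loi_iterations = 10000, loi_threshold = 1,
                         percentile = 0.001, n_restarts = 50, seed = 1L) {
  host <- world$host

  # host side: filter, profile, cluster, annotate
  filtered <- filter_genes(host$rpkm, host$flags, cv_threshold)
  profiles <- condition_profiles(host$rpkm[filtered, , drop = FALSE],
                                 host$replicate_map)
  clusters <- kmeans_cluster(profiles, k = k, seed = seed,
                             n_restarts = n_restarts)
  phenotypes <- stats::setNames(lapply(clusters$clusters, function(cl)
    enrich_terms(cl$members, world$annotations$functional, filtered,
                 alpha = enrich_alpha)),
    vapply(clusters$clusters, function(cl) as.character(cl$id), ""))

  # motifs: associations over the differentially regulated background
  associations <- build_associations(world$upstreams,
                                     world$config$motif_library, filtered)
  motif_enrichments <- do.call(rbind, lapply(clusters$clusters,
    function(cl) {
      d <- enrich_motifs(cl$members, associations, alpha = motif_alpha,
                         min_genes = motif_min_genes)
      cbind(cluster = cl$id, d)
    }))
  rownames(motif_enrichments) <- NULL

  # sensor complexes
  localizations <- assign_localizations(world$localization_scores)
  loi <- compute_loi_table(world$reference_ppi, localizations,
                           iterations = loi_iterations, seed = seed)
  expressed_all <- rowSums(!host$flags) == 0
  sensing <- names(world$annotations$functional)[vapply(
    world$annotations$functional,
    function(t) length(intersect(t, world$config$allow_list)) > 0,
    NA)]
  allowed <- intersect(names(expressed_all)[expressed_all], sensing)
  network <- grvn_network(world$compendium, allowed,
                          neighborhood = neighborhood, alpha = pcc_alpha)
  filtered_net <- filter_candidate_edges(
    network, loi, localizations, expressed_all,
    world$annotations$functional, world$config$allow_list,
    loi_threshold = loi_threshold)
  complexes <- extract_complexes(filtered_net,
                                 world$annotations$functional,
                                 world$config$role_map)

  # symbiont side: turnover scores
  sym_qn <- quantile_normalize(world$symbiont$rpkm)
  uef <- uef_abundance(sym_qn, world$annotations$ec)
  reaction_net <- build_reaction_network(world$reactions,
                                         world$allowed_pathways)
  turnover <- prmt_scores(uef, reaction_net)

  # integration
  corr <- correlate_turnover(turnover, clusters)
  strong_links <- select_strong_links(corr, percentile = percentile)
  complex_links <- link_complexes_to_clusters(complexes, clusters)
  complex_tf_motifs <- motifs_for_complex_tfs(
    complexes, world$annotations$functional, world$tf_motif_map,
    clusters, associations)
  model <- assemble_model(strong_links, complex_links, complexes,
                          motif_enrichments, complex_tf_motifs,
                          phenotypes)

  structure(list(
    filtered = filtered, profiles = profiles, clusters = clusters,
    phenotypes = phenotypes, associations = associations,
    motif_enrichments = motif_enrichments, localizations = localizations,
    loi = loi, network = network, filtered_network = filtered_net,
    complexes = complexes, uef = uef, reaction_network = reaction_net,
    turnover = turnover, correlations = corr,
    strong_links = strong_links, complex_links = complex_links,
    complex_tf_motifs = complex_tf_motifs, model = model),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "pipeline_result: %d filtered genes in %d clusters; %d passing motif",
    " enrichments; %d sensor complexes; %d metabolites scored; %d strong",
    " links; model %d nodes / %d edges\n"),
    length(x$filtered), length(x$clusters$clusters),
    sum(x$motif_enrichments$passes), length(x$complexes),
    nrow(x$turnover$scores), nrow(x$strong_links), nrow(x$model$nodes),
    nrow(x$model$edges)))
  invisible(x)
}

#' Map planted clusters onto recovered clusters by majority overlap
#'
#' Utility for truth comparison: returns, for each planted cluster id,
#' the recovered cluster id sharing the most genes.
#'
#' @param truth_membership Named vector: gene -> planted cluster id.
#' @param clusters A `gene_clusters` object.
#' @return Named character vector: planted id -> recovered id.
#' @export
match_clusters <- function(truth_membership, clusters) {
  planted <- sort(unique(truth_membership))
  out <- vapply(planted, function(pc) {
    genes <- names(truth_membership)[truth_membership == pc]
    ov <- vapply(clusters$clusters, function(cl)
      length(intersect(cl$members, genes)), 0L)
    as.character(clusters$clusters[[which.max(ov)]]$id)
  }, "")
  stats::setNames(out, as.character(planted))
}
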