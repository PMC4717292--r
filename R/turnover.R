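#' Parse a reaction table's metabolite list columns
#'
#' Reaction tables store reactant and product lists as semicolon-separated
#' strings; this helper normalises either representation to list columns.
#' @keywords internal
.metabolite_list <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  strsplit(as.character(x), ";", fixed = TRUE)
}

#' Build a pathway-restricted signed enzyme-metabolite incidence
#'
#' Keeps the reactions whose pathway is in the allowed set and accumulates,
#' per (enzyme EC, metabolite), the number of kept reactions consuming the
#' metabolite (reactant, +1) minus the number producing it (product, -1).
#' A metabolite appearing on both sides of one reaction nets to zero. The
#' sign convention makes a positive downstream turnover score mean
#' predicted consumption.
#'
#' @param reactions data.frame with columns ec, reaction_id, reactants,
#'   products (semicolon lists or list columns), pathway.
#' @param allowed_pathways Non-empty character vector of pathway ids.
#' @return A `reaction_network`: list with `incidence` (EC x metabolite
#'   signed weight matrix), `stats` (metabolite/reaction/EC counts and the
#'   largest connected component of the bipartite metabolite-reaction
#'   graph).
#' @export
build_reaction_network <- function(reactions, allowed_pathways) {
  if (!length(allowed_pathways)) stop("allowed_pathways must be non-empty")
  keep <- reactions$pathway %in% allowed_pathways
  dropped_ecs <- setdiff(reactions$ec, reactions$ec[keep])
  if (length(dropped_ecs))
    warning("EC(s) with no reaction in an allowed pathway dropped: ",
            paste(utils::head(dropped_ecs, 5), collapse = ", "))
  rx <- reactions[keep, , drop = FALSE]
  if (!nrow(rx)) stop("no reactions left after pathway restriction")
  reac <- .metabolite_list(rx$reactants)
  prod <- .metabolite_list(rx$products)
  ecs <- sort(unique(as.character(rx$ec)))
  mets <- sort(unique(c(unlist(reac), unlist(prod))))
  W <- matrix(0, length(ecs), length(mets), dimnames = list(ecs, mets))
  for (i in seq_len(nrow(rx))) {
    e <- as.character(rx$ec[i])
    for (m in reac[[i]]) W[e, m] <- W[e, m] + 1
    for (m in prod[[i]]) W[e, m] <- W[e, m] - 1
  }
  # bipartite metabolite-reaction connectivity
  edges <- do.call(rbind, lapply(seq_len(nrow(rx)), function(i) {
    cbind(paste0("rxn:", rx$reaction_id[i]),
          paste0("met:", unique(c(reac[[i]], prod[[i]]))))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  largest <- which.max(comp$csize)
  largest_mets <- sum(startsWith(
    names(comp$membership)[comp$membership == largest], "met:"))
  structure(list(
    incidence = W,
    stats = list(n_metabolites = length(mets),
                 n_reactions = length(unique(rx$reaction_id)),
                 n_uefs = length(ecs),
                 largest_component_metabolites = largest_mets)),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(paste0("reaction_network: %d UEFs, %d reactions, ",
                     "%d metabolites (largest component %d metabolites)\n"),
              x$stats$n_uefs, x$stats$n_reactions, x$stats$n_metabolites,
              x$stats$largest_component_metabolites))
  invisible(x)
}

#' Unique-enzyme-function abundance from an expression matrix
#'
#' Sums (quantile-normalized) expression over all gene models annotated
#' with each EC number. A gene with k EC labels contributes its full value
#' to each of the k enzyme functions. ECs with no expressed gene are
#' absent from the result.
#'
#' @param expr Numeric gene x condition matrix (quantile-normalized RPKM).
#' @param ec_annotations Named list: gene id -> character vector of ECs.
#' @return Numeric EC x condition matrix.
#' @export
uef_abundance <- function(expr, ec_annotations) {
  expr <- as.matrix(expr)
  genes <- intersect(rownames(expr), names(ec_annotations))
  pairs <- data.frame(
    gene = rep(genes, lengths(ec_annotations[genes])),
    ec = unlist(ec_annotations[genes], use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(pairs))
    return(matrix(0, 0, ncol(expr),
                  dimnames = list(character(), colnames(expr))))
  agg <- rowsum(expr[pairs$gene, , drop = FALSE], group = pairs$ec)
  agg[sort(rownames(agg)), , drop = FALSE]
}

#' Predicted relative metabolic turnover scores
#'
#' Per enzyme function, the log2 deviation of its abundance in each
#' condition from its cross-condition mean (a floor is applied before the
#' logarithm) is propagated onto metabolites through the signed incidence:
#' score(m, c) = sum_e w(e, m) * delta_e(c), divided by the number of
#' expressed enzyme functions touching m (the default normalisation, which
#' keeps scores comparable across metabolites of different connectivity).
#' A positive score predicts net consumption of the metabolite, a negative
#' score net synthesis. Metabolites touched by no expressed enzyme are
#' absent.
#'
#' @param uef Numeric EC x condition abundance matrix (>= 2 conditions).
#' @param network A `reaction_network` (see [build_reaction_network]).
#' @param floor Positive log floor; default half the smallest positive
#'   abundance, so unexpressed conditions stay finite.
#' @param normalize Divide each metabolite's score by its expressed-enzyme
#'   count (default TRUE); FALSE gives the raw signed sum.
#' @param baseline Either "mean" (delta relative to the cross-condition
#'   mean, the default) or the name of a reference condition.
#' @return A `turnover_scores`: list with `scores` (metabolite x condition
#'   matrix), `delta` (EC x condition log2 deviations) and `stats` carried
#'   over from the network.
#' @export
prmt_scores <- function(uef, network, floor = NULL, normalize = TRUE,
                        baseline = "mean") {
  uef <- as.matrix(uef)
  if (ncol(uef) < 2) stop("turnover needs >= 2 conditions")
  W <- network$incidence
  ecs <- intersect(rownames(W), rownames(uef))
  if (!length(ecs)) stop("no expressed enzyme function is in the network")
  if (is.null(floor)) {
    pos <- uef[uef > 0]
    floor <- if (length(pos)) min(pos) * 0.5 else 1e-6
  }
  lg <- log2(pmax(uef[ecs, , drop = FALSE], floor))
  ref <- if (identical(baseline, "mean")) {
    rowMeans(lg)
  } else {
    if (!baseline %in% colnames(lg)) stop("unknown baseline condition")
    lg[, baseline]
  }
  delta <- lg - ref
  Wk <- W[ecs, , drop = FALSE]
  n_m <- colSums(Wk != 0)
  keep <- n_m > 0
  scores <- t(Wk[, keep, drop = FALSE]) %*% delta
  if (normalize) scores <- scores / n_m[keep]
  structure(list(scores = scores, delta = delta, stats = network$stats),
            class = "turnover_scores")
}

#' @export
print.turnover_scores <- function(x, ...) {
  cat(sprintf("turnover_scores: %d metabolites x %d conditions\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
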