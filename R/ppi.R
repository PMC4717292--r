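#' Rank-based co-expression network (fixed-size value neighborhoods)
#'
#' For each allowed gene, all other allowed genes are ranked by Pearson
#' correlation over the compendium samples and the gene proposes edges to
#' its top-`neighborhood` partners; a proposed edge is kept when the
#' correlation's two-sided significance (t test with n - 2 df) is below
#' `alpha`. The edge set is the union of per-gene proposals, which yields
#' the scale-free-like topology expected of biological networks without a
#' global correlation cutoff.
#'
#' @param compendium Numeric gene x sample matrix (>= 4 samples).
#' @param allowed Character vector of gene ids to build the network over.
#' @param neighborhood Proposals per gene (default 5).
#' @param alpha Correlation significance threshold (default 0.01).
#' @return A `coexpression_network`: list with `nodes` and an `edges`
#'   data.frame (gene_a < gene_b, r, p, proposed_by in {"a","b","both"}).
#' @export
grvn_network <- function(compendium, allowed, neighborhood = 5,
                         alpha = 0.01) {
  m <- as.matrix(compendium)
  if (ncol(m) < 4) stop("compendium needs >= 4 samples")
  missing <- setdiff(allowed, rownames(m))
  if (length(missing))
    stop("allowed genes absent from compendium: ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- m[allowed, , drop = FALSE]
  vars <- apply(m, 1, stats::var)
  if (any(vars == 0)) {
    warning("excluding constant-expression gene(s): ",
            paste(rownames(m)[vars == 0], collapse = ", "))
    m <- m[vars > 0, , drop = FALSE]
  }
  genes <- sort(rownames(m))
  m <- m[genes, , drop = FALSE]
  ng <- length(genes)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(),
                      proposed_by = character(), stringsAsFactors = FALSE)
  if (ng < 2)
    return(structure(list(nodes = genes, edges = empty),
                     class = "coexpression_network"))
  cmat <- stats::cor(t(m))
  nsmp <- ncol(m)
  proposals <- new.env(parent = emptyenv())
  for (i in seq_len(ng)) {
    r <- cmat[i, -i]
    # rank by correlation, boundary ties broken lexicographically by id
    ord <- order(-r, names(r))
    top <- names(r)[ord][seq_len(min(neighborhood, ng - 1))]
    for (j in top) {
      if (pcc_pvalue(cmat[genes[i], j], nsmp) >= alpha) next
      a <- min(genes[i], j); b <- max(genes[i], j)
      key <- paste(a, b, sep = "\r")
      side <- if (genes[i] == a) "a" else "b"
      prev <- proposals[[key]]
      proposals[[key]] <- if (is.null(prev)) side else "both"
    }
  }
  keys <- ls(proposals)
  if (!length(keys))
    return(structure(list(nodes = genes, edges = empty),
                     class = "coexpression_network"))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- data.frame(
    gene_a = ab[, 1], gene_b = ab[, 2],
    r = cmat[cbind(ab[, 1], ab[, 2])],
    p = pcc_pvalue(cmat[cbind(ab[, 1], ab[, 2])], nsmp),
    proposed_by = vapply(keys, function(k) proposals[[k]], ""),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Assign subcellular localizations from predictor scores
#'
#' Takes each protein's highest-scoring localization label; score ties
#' assign all tied labels. Compound labels are split on ":" into their
#' component compartments (a "nuclear:cytoplasm" prediction assigns both
#' "nuclear" and "cytoplasm").
#'
#' @param scores Named list: protein -> named numeric vector of label
#'   scores, or a data.frame with columns protein, label, score.
#' @return Named list: protein -> character vector of localization labels.
#' @export
assign_localizations <- function(scores) {
  if (is.data.frame(scores)) {
    scores <- lapply(split(scores, as.character(scores$protein)),
                     function(d) stats::setNames(d$score,
                                                 as.character(d$label)))
  }
  lapply(scores, function(s) {
    if (!length(s)) stop("protein with an empty localization score map")
    top <- names(s)[s == max(s)]
    unique(unlist(strsplit(top, ":", fixed = TRUE), use.names = FALSE))
  })
}

#' Likelihood-of-interaction Z-scores for localization-label pairs
#'
#' For every unordered pair of localization labels, counts how often
#' proteins carrying those labels interact in a reference PPI set (a
#' multi-label protein contributes each of its labels) and compares the
#' count with a null built from `iterations` degree-preserving
#' re-pairings of the reference edge endpoints: the 2m endpoint stubs are
#' pooled and randomly re-matched into m edges, so every protein keeps
#' its degree in every iteration. Z = (observed - null mean) / null SD;
#' pairs with a degenerate null (SD 0) get Z = 0 by convention.
#'
#' @param reference data.frame with columns protein_a, protein_b
#'   (undirected, no self or duplicate edges).
#' @param localizations Named list: protein -> localization label set
#'   (already split, see [assign_localizations]).
#' @param iterations Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A `loi_table`: list with symmetric matrices `z`, `observed`,
#'   `null_mean`, `null_sd` over the label universe, plus `labels` and
#'   `iterations`.
#' @export
compute_loi_table <- function(reference, localizations, iterations = 10000,
                              seed = 1L) {
  pa <- as.character(reference[[1]])
  pb <- as.character(reference[[2]])
  prots <- unique(c(pa, pb))
  un <- prots[!prots %in% names(localizations) |
                lengths(localizations[prots]) == 0]
  if (length(un))
    stop("reference proteins without localization annotation: ",
         paste(utils::head(un, 5), collapse = ", "))
  labels <- sort(unique(unlist(localizations[prots], use.names = FALSE)))
  nl <- length(labels)
  # indicator matrix rows = edge endpoints, cols = labels
  ind <- function(p) {
    out <- matrix(0, length(p), nl, dimnames = list(NULL, labels))
    for (i in seq_along(p)) out[i, localizations[[p[i]]]] <- 1
    out
  }
  m <- length(pa)
  S <- ind(c(pa, pb))                # one indicator row per endpoint stub
  pair_counts <- function(Am, Bm) {
    cc <- crossprod(Am, Bm)          # ordered label-pair counts
    sym <- cc + t(cc)
    diag(sym) <- diag(cc)            # unordered: off-diagonal summed once
    sym
  }
  observed <- pair_counts(S[seq_len(m), , drop = FALSE],
                          S[m + seq_len(m), , drop = FALSE])
  set.seed(seed)
  s1 <- matrix(0, nl, nl)
  s2 <- matrix(0, nl, nl)
  for (i in seq_len(iterations)) {
    perm <- sample.int(2 * m)
    cnt <- pair_counts(S[perm[seq_len(m)], , drop = FALSE],
                       S[perm[m + seq_len(m)], , drop = FALSE])
    s1 <- s1 + cnt
    s2 <- s2 + cnt^2
  }
  null_mean <- s1 / iterations
  null_sd <- sqrt(pmax(s2 / iterations - null_mean^2, 0))
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, 0)
  dimnames(z) <- dimnames(observed)
  structure(list(z = z, observed = observed, null_mean = null_mean,
                 null_sd = null_sd, labels = labels,
                 iterations = iterations),
            class = "loi_table")
}

#' Edge likelihood-of-interaction score under multi-label localization
#'
#' The interaction is possible if any compatible pairing of the two
#' proteins' compartments supports it, so the edge score is the maximum Z
#' over all label pairs.
#' @keywords internal
.edge_loi <- function(loi, labels_a, labels_b) {
  la <- intersect(labels_a, loi$labels)
  lb <- intersect(labels_b, loi$labels)
  if (!length(la) || !length(lb)) return(-Inf)
  max(loi$z[la, lb, drop = FALSE])
}

#' Refine a co-expression network into candidate physical interactions
#'
#' Retains an edge only when (i) both proteins are significantly expressed
#' in every in-house sample, (ii) both carry at least one functional
#' annotation from the environmental-sensing allow-list, and (iii) the
#' edge's localization-pair likelihood-of-interaction score exceeds
#' `loi_threshold` (edge score = maximum Z over the two proteins' label
#' pairs). Interactions are intra-organism by construction: the network is
#' built within one organism's gene set.
#'
#' @param network A `coexpression_network`.
#' @param loi A `loi_table`.
#' @param localizations Named list: protein -> localization labels.
#' @param expressed_all Named logical vector: protein -> significantly
#'   expressed in every sample.
#' @param annotations Named list: protein -> functional terms.
#' @param allow_list Character vector of sensing/signalling terms.
#' @param loi_threshold Minimum edge Z (default 1, strict).
#' @return Filtered `coexpression_network` whose edges carry a `loi`
#'   column.
#' @export
filter_candidate_edges <- function(network, loi, localizations,
                                   expressed_all, annotations, allow_list,
                                   loi_threshold = 1) {
  e <- network$edges
  if (!nrow(e)) return(network)
  ok_gene <- function(g) {
    isTRUE(expressed_all[g]) && length(intersect(annotations[[g]],
                                                 allow_list)) > 0
  }
  keep <- logical(nrow(e))
  loi_score <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    a <- e$gene_a[i]; b <- e$gene_b[i]
    loi_score[i] <- .edge_loi(loi, localizations[[a]], localizations[[b]])
    keep[i] <- ok_gene(a) && ok_gene(b) && loi_score[i] > loi_threshold
  }
  e$loi <- loi_score
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(unique(c(e$gene_a, e$gene_b))), edges = e),
            class = "coexpression_network")
}

#' Extract role-typed sensor complexes from a filtered network
#'
#' Connected components of the filtered co-expression network are
#' hypothesised sensor complexes. Each node is role-typed from its
#' functional annotations: transmembrane/receptor terms make a receptor,
#' transcription-factor terms a transcription_factor, defense terms
#' defense, anything else a signal-cascade protein (precedence in that
#' order).
#'
#' @param network A filtered `coexpression_network`.
#' @param annotations Named list: protein -> functional terms.
#' @param role_map Named list: role -> character vector of annotation
#'   terms, with entries `receptor`, `transcription_factor`, `defense`.
#' @return List of `sensor_complex` objects: id, nodes (data.frame gene,
#'   role), edges, size.
#' @export
extract_complexes <- function(network, annotations, role_map) {
  e <- network$edges
  if (!nrow(e)) return(list())
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  assign_role <- function(gene) {
    terms <- annotations[[gene]]
    for (role in c("receptor", "transcription_factor", "defense")) {
      if (length(intersect(terms, role_map[[role]]))) return(role)
    }
    "cascade"
  }
  lapply(seq_len(comp$no), function(i) {
    members <- sort(names(comp$membership)[comp$membership == i])
    nodes <- data.frame(gene = members,
                        role = vapply(members, assign_role, ""),
                        stringsAsFactors = FALSE, row.names = NULL)
    sub <- e[e$gene_a %in% members & e$gene_b %in% members, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(id = paste0("complex_", i), nodes = nodes, edges = sub,
                   size = length(members)),
              class = "sensor_complex")
  })
}

#' @export
print.sensor_complex <- function(x, ...) {
  cat(sprintf("sensor_complex %s: %d proteins (%s), %d interactions\n",
              x$id, x$size,
              paste(sprintf("%d %s", table(x$nodes$role),
                            names(table(x$nodes$role))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
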