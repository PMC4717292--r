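#' Default planted cluster profiles
#'
#' Phase-shifted cosines over the condition axis: amplitude-2 log2
#' fold-change profiles that are mutually distinct, span the full time
#' course, and average exactly to zero over the conditions.
#' @keywords internal
.default_profiles <- function(conditions, k, amplitude = 2) {
  nc <- length(conditions)
  prof <- t(vapply(seq_len(k), function(i) {
    amplitude * cos(2 * pi * (seq_len(nc) - 1) / nc - 2 * pi * (i - 1) / k)
  }, numeric(nc)))
  prof <- prof - rowMeans(prof)
  dimnames(prof) <- list(paste0("planted_", seq_len(k)), conditions)
  prof
}

.default_motif_library <- function(k) {
  # 8-symbol patterns (some degenerate) keep the chance-hit rate per kb
  # low enough that planted carrier fractions stay recoverable
  pats <- c("TWAACCAG", "CACGTGTC", "TTGACYAA", "GRTAAAGT", "CCWACCAA",
            "AGATCCGC", "TGTCGGYA", "CATGCATG", "ACGTRTCC", "GGCGGTAT",
            "TCCAWTGG", "AATCGRCT")
  n <- min(length(pats), k + 3)
  data.frame(name = sprintf("motif_%02d", seq_len(n)),
             pattern = pats[seq_len(n)], stringsAsFactors = FALSE)
}

#' Configuration of a synthetic multi-omics world
#'
#' Defines the study design the generator emulates: a free-living
#' condition, six root-fungus interaction time points and a mycorrhizal
#' condition (replicated 2,1,1,1,1,1,1,2 for ten host samples), nine
#' planted co-regulation clusters with distinct log2 fold-change profiles,
#' upstream motifs planted at a target carrier fraction per cluster,
#' sensor complexes drawn from the first clusters, an
#' annotation-structured reference PPI set, and metabolite-cluster
#' couplings planted through enzyme expression.
#'
#' @param seed Integer seed; the whole world is deterministic given the
#'   config.
#' @param conditions Ordered condition labels.
#' @param replicates Named integer vector of per-condition replicate
#'   counts.
#' @param n_host_genes,n_symbiont_genes Gene counts for the two organisms.
#' @param n_clusters_planted Number of planted co-regulation clusters.
#' @param genes_per_cluster Members per planted cluster.
#' @param cluster_profiles Numeric cluster x condition matrix of log2
#'   fold changes (default phase-shifted cosines of amplitude 2).
#' @param noise_sd Log2-expression noise SD per host sample.
#' @param base_log2_expr Baseline log2 expression level.
#' @param motif_library data.frame (name, pattern) of IUPAC motifs.
#' @param planted_motif_enrichment data.frame (cluster, motif, fraction):
#'   target carrier fraction of each planted motif in its cluster.
#' @param background_motif_frequency Probability that a non-carrier gene
#'   receives a motif instance.
#' @param upstream_length Upstream sequence length in bases.
#' @param n_complexes,complex_size Planted sensor complexes (members come
#'   from the first clusters; default size 6, one receptor, four cascade
#'   proteins, one transcription factor).
#' @param ppi_pair_preferences Symmetric matrix of relative interaction
#'   propensity per localization-label pair.
#' @param n_reference_proteins,n_reference_ppis Size of the reference PPI
#'   set used for likelihood-of-interaction scores.
#' @param n_background_ecs Background enzyme functions (each with one
#'   chained reaction).
#' @param hub_fanin Number of background reactions that additionally feed
#'   the shared hub metabolite, diluting its turnover signal.
#' @param n_excluded_reactions Reactions placed in a disallowed pathway to
#'   exercise pathway restriction.
#' @param planted_metabolite_links data.frame (metabolite, cluster, sign):
#'   couplings between symbiont metabolites and host clusters; sign +1
#'   plants a consumption-coupled link, -1 a synthesis-coupled one.
#' @param reads_per_sample Aligned reads per simulated sample.
#' @param multimap_fraction Fraction of reads carrying two candidate
#'   genes.
#' @param n_compendium_samples Samples in the external expression
#'   compendium used for co-expression network construction.
#' @return A validated `world_config` list.
#' @export
world_config <- function(
    seed = 1L,
    conditions = c("FL", "6h", "12h", "24h", "48h", "72h", "96h", "Myc"),
    replicates = stats::setNames(c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 2L),
                                 conditions),
    n_host_genes = 300L,
    n_symbiont_genes = 200L,
    n_clusters_planted = 9L,
    genes_per_cluster = 24L,
    cluster_profiles = NULL,
    noise_sd = 0.25,
    base_log2_expr = 6,
    motif_library = NULL,
    planted_motif_enrichment = NULL,
    background_motif_frequency = 0.08,
    upstream_length = 1000L,
    n_complexes = 3L,
    complex_size = 6L,
    ppi_pair_preferences = NULL,
    n_reference_proteins = 120L,
    n_reference_ppis = 400L,
    n_background_ecs = 163L,
    hub_fanin = 14L,
    n_excluded_reactions = 8L,
    planted_metabolite_links = NULL,
    reads_per_sample = 5000L,
    multimap_fraction = 0.1,
    n_compendium_samples = 40L) {

  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  if (!all(names(replicates) == conditions))
    stop("replicates must be named by the conditions, in order")
  if (is.null(cluster_profiles))
    cluster_profiles <- .default_profiles(conditions, n_clusters_planted)
  if (nrow(cluster_profiles) != n_clusters_planted ||
      ncol(cluster_profiles) != length(conditions))
    stop("cluster_profiles must be n_clusters_planted x length(conditions)")
  if (is.null(motif_library))
    motif_library <- .default_motif_library(n_clusters_planted)
  if (is.null(planted_motif_enrichment))
    planted_motif_enrichment <- data.frame(
      cluster = seq_len(n_clusters_planted),
      motif = motif_library$name[seq_len(n_clusters_planted)],
      fraction = 0.8, stringsAsFactors = FALSE)
  fr <- c(background_motif_frequency, multimap_fraction,
          planted_motif_enrichment$fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(planted_motif_enrichment$fraction < background_motif_frequency))
    stop("planted motif enrichment below the background frequency is ",
         "inconsistent: the planted signal would be undetectable")
  localizations <- c("plasma_membrane", "cytoplasm", "nuclear",
                     "extracellular", "chloroplast")
  if (is.null(ppi_pair_preferences)) {
    L <- length(localizations)
    pref <- matrix(1, L, L, dimnames = list(localizations, localizations))
    high <- rbind(c("plasma_membrane", "cytoplasm"),
                  c("plasma_membrane", "plasma_membrane"),
                  c("cytoplasm", "cytoplasm"),
                  c("cytoplasm", "nuclear"),
                  c("nuclear", "nuclear"))
    for (i in seq_len(nrow(high))) {
      pref[high[i, 1], high[i, 2]] <- 8
      pref[high[i, 2], high[i, 1]] <- 8
    }
    ppi_pair_preferences <- pref
  }
  if (is.null(planted_metabolite_links)) {
    nl <- min(6L, n_clusters_planted)
    planted_metabolite_links <- data.frame(
      metabolite = sprintf("met_link_%d", seq_len(nl)),
      cluster = seq_len(nl),
      sign = rep_len(c(1L, -1L), nl), stringsAsFactors = FALSE)
  }
  if (!all(planted_metabolite_links$sign %in% c(1L, -1L)))
    stop("planted link signs must be +1 or -1")
  if (n_clusters_planted * genes_per_cluster > n_host_genes)
    stop("planted clusters need more genes than n_host_genes provides")
  if (n_complexes > n_clusters_planted ||
      complex_size > genes_per_cluster)
    stop("planted complexes must fit inside the planted clusters")

  structure(list(
    seed = as.integer(seed), conditions = conditions,
    replicates = replicates, n_host_genes = as.integer(n_host_genes),
    n_symbiont_genes = as.integer(n_symbiont_genes),
    n_clusters_planted = as.integer(n_clusters_planted),
    genes_per_cluster = as.integer(genes_per_cluster),
    cluster_profiles = cluster_profiles, noise_sd = noise_sd,
    base_log2_expr = base_log2_expr, motif_library = motif_library,
    planted_motif_enrichment = planted_motif_enrichment,
    background_motif_frequency = background_motif_frequency,
    upstream_length = as.integer(upstream_length),
    n_complexes = as.integer(n_complexes),
    complex_size = as.integer(complex_size),
    localization_labels = localizations,
    ppi_pair_preferences = ppi_pair_preferences,
    n_reference_proteins = as.integer(n_reference_proteins),
    n_reference_ppis = as.integer(n_reference_ppis),
    n_background_ecs = as.integer(n_background_ecs),
    hub_fanin = as.integer(hub_fanin),
    n_excluded_reactions = as.integer(n_excluded_reactions),
    planted_metabolite_links = planted_metabolite_links,
    reads_per_sample = as.integer(reads_per_sample),
    multimap_fraction = multimap_fraction,
    n_compendium_samples = as.integer(n_compendium_samples),
    allow_list = c("transmembrane_receptor", "kinase_cascade",
                   "signal_transduction", "transcription_factor_activity",
                   "defense_response"),
    role_map = list(receptor = "transmembrane_receptor",
                    transcription_factor = "transcription_factor_activity",
                    defense = "defense_response"),
    tf_families = c("myb_family", "bzip_family", "wrky_family"),
    k_means_k = as.integer(n_clusters_planted)),
    class = "world_config")
}

.insert_motif <- function(seq, pattern) {
  # concrete instance of the IUPAC pattern at a uniform forward-strand
  # offset
  syms <- strsplit(pattern, "")[[1]]
  inst <- vapply(syms, function(s) {
    bases <- strsplit(sub("N$", "", .IUPAC_MATCH[[s]]), "")[[1]]
    if (!length(bases)) bases <- c("A", "C", "G", "T")
    sample(bases, 1)
  }, "")
  pos <- sample.int(nchar(seq) - length(syms) + 1L, 1)
  paste0(substr(seq, 1, pos - 1), paste(inst, collapse = ""),
         substr(seq, pos + length(syms), nchar(seq)))
}

#' Generate a synthetic multi-omics world with planted ground truth
#'
#' Produces every pipeline input -- host upstream sequences, host and
#' symbiont expression with significance flags, an external co-expression
#' compendium, functional/localization/EC annotation tables, a reference
#' PPI edge list structured by localization-pair preferences, and a
#' pathway-annotated reaction table -- together with the planted truth
#' each downstream stage should recover.
#'
#' @param config A [world_config].
#' @return A `synthetic_world` list; see the package vignette for the
#'   component-by-component description.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  cfg <- config
  conditions <- cfg$conditions
  k <- cfg$n_clusters_planted

  host_genes <- sprintf("aspen_g%04d", seq_len(cfg$n_host_genes))
  n_clustered <- k * cfg$genes_per_cluster
  cluster_of <- c(rep(seq_len(k), each = cfg$genes_per_cluster),
                  rep(NA_integer_, cfg$n_host_genes - n_clustered))
  names(cluster_of) <- host_genes
  gene_lengths <- stats::setNames(
    sample(seq(500L, 3000L, by = 10L), cfg$n_host_genes, replace = TRUE),
    host_genes)

  # ten in-house samples: replicates per condition
  samples <- unlist(lapply(conditions, function(cc)
    paste0(cc, "_", seq_len(cfg$replicates[[cc]]))), use.names = FALSE)
  replicate_map <- stats::setNames(
    rep(conditions, times = cfg$replicates), samples)

  # latent log2 expression: cluster profile (or flat) + per-sample noise
  profile_of <- function(g) {
    cl <- cluster_of[[g]]
    if (is.na(cl)) rep(0, length(conditions)) else
      cfg$cluster_profiles[cl, ]
  }
  latent <- t(vapply(host_genes, function(g) {
    cfg$base_log2_expr + profile_of(g)[match(replicate_map, conditions)] +
      stats::rnorm(length(samples), 0, cfg$noise_sd)
  }, numeric(length(samples))))
  colnames(latent) <- samples
  # a few weak background genes exercise the all-samples significance gate
  weak <- utils::tail(host_genes, 12L)
  latent[weak, ] <- latent[weak, ] - 5
  flags <- matrix(TRUE, cfg$n_host_genes, length(samples),
                  dimnames = dimnames(latent))
  for (g in weak)
    flags[g, sample.int(length(samples), 3L)] <- FALSE
  host_rpkm <- 2^latent

  # upstream sequences with planted motif instances
  upstreams <- stats::setNames(vapply(seq_len(cfg$n_host_genes),
    function(i) paste(sample(c("A", "C", "G", "T"), cfg$upstream_length,
                             replace = TRUE), collapse = ""), ""),
    host_genes)
  carriers <- stats::setNames(
    vector("list", nrow(cfg$motif_library)), cfg$motif_library$name)
  for (i in seq_len(nrow(cfg$motif_library))) {
    motif <- cfg$motif_library$name[i]
    pattern <- cfg$motif_library$pattern[i]
    planted <- cfg$planted_motif_enrichment[
      cfg$planted_motif_enrichment$motif == motif, , drop = FALSE]
    target <- rep(cfg$background_motif_frequency, cfg$n_host_genes)
    for (j in seq_len(nrow(planted))) {
      in_cl <- !is.na(cluster_of) & cluster_of == planted$cluster[j]
      target[in_cl] <- planted$fraction[j]
    }
    hit <- stats::runif(cfg$n_host_genes) < target
    for (g in host_genes[hit])
      upstreams[[g]] <- .insert_motif(upstreams[[g]], pattern)
    carriers[[motif]] <- host_genes[hit]
  }

  # planted sensor complexes: first complex_size genes of the first
  # clusters; one receptor, cascade core, one transcription factor
  complexes <- lapply(seq_len(cfg$n_complexes), function(i) {
    members <- host_genes[cluster_of %in% i][seq_len(cfg$complex_size)]
    roles <- c("receptor", rep("cascade", cfg$complex_size - 2),
               "transcription_factor")
    list(id = i, members = members,
         roles = stats::setNames(roles, members),
         tf_family = cfg$tf_families[((i - 1) %% length(cfg$tf_families))
                                     + 1L])
  })
  complex_members <- unlist(lapply(complexes, `[[`, "members"),
                            use.names = FALSE)
  decoys <- host_genes[is.na(cluster_of)][seq_len(6L)]

  # functional annotations
  filler <- c("metabolism", "transport", "structural", "photosynthesis")
  functional <- stats::setNames(vector("list", cfg$n_host_genes),
                                host_genes)
  for (g in host_genes) {
    terms <- sample(filler, 1L)
    cl <- cluster_of[[g]]
    if (!is.na(cl) && stats::runif(1) < 0.8)
      terms <- c(terms, sprintf("phen_response_%d", cl))
    if (is.na(cl) && stats::runif(1) < 0.05)
      terms <- c(terms, sprintf("phen_response_%d",
                                sample.int(k, 1L)))
    functional[[g]] <- terms
  }
  for (cx in complexes) {
    for (g in cx$members) {
      role_term <- switch(cx$roles[[g]],
                          receptor = "transmembrane_receptor",
                          cascade = "kinase_cascade",
                          transcription_factor =
                            "transcription_factor_activity")
      functional[[g]] <- unique(c(functional[[g]], role_term,
                                  "signal_transduction"))
      if (cx$roles[[g]] == "transcription_factor")
        functional[[g]] <- c(functional[[g]], cx$tf_family)
    }
  }
  for (g in decoys)
    functional[[g]] <- unique(c(functional[[g]], "signal_transduction"))

  # transcription-factor family -> known binding motif (the motif planted
  # in the complex's own cluster)
  tf_motif_map <- stats::setNames(
    cfg$motif_library$name[seq_along(cfg$tf_families)], cfg$tf_families)

  # localization scores (predictor-style): strong single labels for
  # complex members, a tie and a compound label to exercise both rules
  loc_rows <- list()
  add_loc <- function(protein, label, score)
    loc_rows[[length(loc_rows) + 1L]] <<- data.frame(
      protein = protein, label = label, score = score,
      stringsAsFactors = FALSE)
  for (cx in complexes) {
    for (j in seq_along(cx$members)) {
      g <- cx$members[j]
      role <- cx$roles[[g]]
      if (role == "receptor") {
        add_loc(g, "plasma_membrane", 9)
      } else if (role == "transcription_factor") {
        if (cx$id == 2L) add_loc(g, "nuclear:cytoplasm", 9)
        else add_loc(g, "nuclear", 9)
      } else if (j == 3L) {
        add_loc(g, "plasma_membrane", 7)  # tie: dual assignment
        add_loc(g, "cytoplasm", 7)
      } else {
        add_loc(g, "cytoplasm", 9)
        add_loc(g, "nuclear", 2)
      }
    }
  }
  for (g in decoys) add_loc(g, "extracellular", 9)
  rest <- setdiff(host_genes, c(complex_members, decoys))
  rest_label <- sample(cfg$localization_labels, length(rest),
                       replace = TRUE)
  for (i in seq_along(rest)) add_loc(rest[i], rest_label[i], 9)

  # reference PPI set over its own protein namespace, edges drawn with
  # probability proportional to the localization-pair preference
  ref_prots <- sprintf("ref_%04d", seq_len(cfg$n_reference_proteins))
  ref_label <- sample(cfg$localization_labels, cfg$n_reference_proteins,
                      replace = TRUE)
  names(ref_label) <- ref_prots
  for (p in ref_prots) add_loc(p, ref_label[[p]], 9)
  pairs <- t(utils::combn(cfg$n_reference_proteins, 2L))
  w <- cfg$ppi_pair_preferences[cbind(ref_label[pairs[, 1]],
                                      ref_label[pairs[, 2]])]
  take <- sample.int(nrow(pairs), cfg$n_reference_ppis, prob = w)
  reference_ppi <- data.frame(protein_a = ref_prots[pairs[take, 1]],
                              protein_b = ref_prots[pairs[take, 2]],
                              stringsAsFactors = FALSE)
  localization_scores <- do.call(rbind,
                                 c(loc_rows, list(make.row.names = FALSE)))

  # external compendium: complex members share a latent factor
  comp_samples <- sprintf("geo_s%03d", seq_len(cfg$n_compendium_samples))
  compendium <- matrix(stats::rnorm(cfg$n_host_genes *
                                      cfg$n_compendium_samples),
                       cfg$n_host_genes,
                       dimnames = list(host_genes, comp_samples))
  for (cx in complexes) {
    f <- stats::rnorm(cfg$n_compendium_samples)
    for (g in cx$members)
      compendium[g, ] <- f + stats::rnorm(cfg$n_compendium_samples, 0,
                                          0.6 * cfg$noise_sd)
  }
  compendium <- compendium + 8  # arbitrary positive log2 scale

  # symbiont: one gene per enzyme function plus unannotated genes
  n_ec <- cfg$n_background_ecs + nrow(cfg$planted_metabolite_links)
  if (cfg$n_symbiont_genes < n_ec)
    stop("n_symbiont_genes must cover all enzyme functions")
  sym_genes <- sprintf("lacc_g%04d", seq_len(cfg$n_symbiont_genes))
  ecs <- sprintf("ec_%03d", seq_len(n_ec))
  ec_annotations <- stats::setNames(as.list(ecs), sym_genes[seq_len(n_ec)])
  n_links <- nrow(cfg$planted_metabolite_links)
  planted_ec <- ecs[seq_len(n_links)]
  delta_ec <- matrix(0, n_ec, length(conditions),
                     dimnames = list(ecs, conditions))
  for (i in seq_len(n_links)) {
    cl <- cfg$planted_metabolite_links$cluster[i]
    s <- cfg$planted_metabolite_links$sign[i]
    delta_ec[planted_ec[i], ] <- s * cfg$cluster_profiles[cl, ]
  }
  bg_ec <- ecs[(n_links + 1):n_ec]
  delta_ec[bg_ec, ] <- stats::rnorm(length(bg_ec) * length(conditions),
                                    0, 0.5)
  sym_latent <- matrix(cfg$base_log2_expr, cfg$n_symbiont_genes,
                       length(conditions),
                       dimnames = list(sym_genes, conditions))
  sym_latent[seq_len(n_ec), ] <- sym_latent[seq_len(n_ec), ] + delta_ec
  sym_latent <- sym_latent +
    stats::rnorm(length(sym_latent), 0, 0.4 * cfg$noise_sd)
  symbiont_rpkm <- 2^sym_latent

  # reaction table: planted enzymes consume their linked metabolite and
  # feed a shared hub; background enzymes form chained pairs
  rx <- list()
  add_rx <- function(ec, rid, reac, prod, pathway)
    rx[[length(rx) + 1L]] <<- data.frame(
      ec = ec, reaction_id = rid, reactants = paste(reac, collapse = ";"),
      products = paste(prod, collapse = ";"), pathway = pathway,
      stringsAsFactors = FALSE)
  for (i in seq_len(n_links))
    add_rx(planted_ec[i], sprintf("rx_link_%d", i),
           cfg$planted_metabolite_links$metabolite[i], "met_hub",
           "map_core_syn")
  for (j in seq_along(bg_ec)) {
    prods <- sprintf("met_bg_%03d", 2 * j)
    if (j <= cfg$hub_fanin) prods <- c(prods, "met_hub")
    add_rx(bg_ec[j], sprintf("rx_bg_%03d", j),
           sprintf("met_bg_%03d", 2 * j - 1), prods, "map_core_syn")
  }
  for (j in seq_len(cfg$n_excluded_reactions))
    add_rx(bg_ec[j], sprintf("rx_ex_%02d", j),
           sprintf("met_x_%02d", 2 * j - 1), sprintf("met_x_%02d", 2 * j),
           "map_excluded_syn")
  reactions <- do.call(rbind, c(rx, list(make.row.names = FALSE)))

  # per-sample alignment tables, drawn last so their per-sample seeds do
  # not perturb the main generation stream
  alignments <- stats::setNames(lapply(seq_along(samples), function(i) {
    .draw_alignments(host_rpkm[, samples[i]], gene_lengths,
                     cfg$reads_per_sample, cfg$multimap_fraction,
                     seed = cfg$seed + i)
  }), samples)

  truth <- list(
    clusters = cluster_of[!is.na(cluster_of)],
    cluster_profiles = cfg$cluster_profiles,
    motif_carriers = carriers,
    complexes = complexes,
    metabolite_links = cfg$planted_metabolite_links,
    weak_genes = weak,
    decoy_genes = decoys)

  world <- structure(list(
    config = cfg,
    gene_lengths = gene_lengths,
    host = list(rpkm = host_rpkm, flags = flags, latent = latent,
                replicate_map = replicate_map, samples = samples),
    upstreams = upstreams,
    annotations = list(functional = functional, ec = ec_annotations),
    localization_scores = localization_scores,
    reference_ppi = reference_ppi,
    compendium = compendium,
    symbiont = list(rpkm = symbiont_rpkm, conditions = conditions),
    alignments = alignments,
    reactions = reactions,
    allowed_pathways = "map_core_syn",
    tf_motif_map = tf_motif_map,
    truth = truth), class = "synthetic_world")
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world: %d host genes (%d clustered), ",
                     "%d symbiont genes, %d conditions, seed %d\n"),
              x$config$n_host_genes, length(x$truth$clusters),
              x$config$n_symbiont_genes, length(x$config$conditions),
              x$config$seed))
  invisible(x)
}

.draw_alignments <- function(expr_linear, gene_lengths, n_reads,
                             multimap_fraction, seed) {
  if (n_reads == 0) return(alignment_table(list()))
  set.seed(seed)
  genes <- names(gene_lengths)
  wts <- expr_linear[genes] * gene_lengths
  counts <- as.vector(stats::rmultinom(1, n_reads, prob = wts))
  gene_of <- rep(genes, counts)
  cand <- as.list(gene_of)
  multi <- which(stats::runif(n_reads) < multimap_fraction)
  for (i in multi) {
    other <- sample(setdiff(genes, gene_of[i]), 1L)
    cand[[i]] <- c(gene_of[i], other)
  }
  names(cand) <- sprintf("read_%06d", seq_len(n_reads))
  alignment_table(cand)
}

#' Simulate a read-to-gene alignment table for one sample
#'
#' Reads are drawn multinomially across genes with probability
#' proportional to linear expression times gene length; a configured
#' fraction of reads additionally lists a second candidate gene, emulating
#' multi-mapped alignments.
#'
#' @param world A `synthetic_world`.
#' @param sample A sample id of the in-house design (a column of the host
#'   expression matrix).
#' @param seed Integer seed for the read draw.
#' @return An [alignment_table].
#' @export
generate_alignments <- function(world, sample, seed = 1L) {
  if (!sample %in% world$host$samples)
    stop("unknown sample label: ", sample)
  .draw_alignments(world$host$rpkm[, sample], world$gene_lengths,
                   world$config$reads_per_sample,
                   world$config$multimap_fraction, seed = seed)
}
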