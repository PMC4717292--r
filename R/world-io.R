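# Typed (de)serialisation of nested R structures to JSON, preserving
# matrices, data.frames, named vectors and atomic types exactly, so that
# configs and truth records survive an export/import round trip.
.ser <- function(x) {
  if (is.matrix(x)) {
    list(`_kind` = "matrix", type = typeof(x), dim = dim(x),
         rn = rownames(x), cn = colnames(x), data = as.vector(unname(x)))
  } else if (is.data.frame(x)) {
    list(`_kind` = "df", names = names(x),
         columns = lapply(x, .ser))
  } else if (is.list(x)) {
    list(`_kind` = "list", names = names(x), items = lapply(unname(x), .ser))
  } else if (is.null(x)) {
    list(`_kind` = "null")
  } else {
    list(`_kind` = "atomic", type = typeof(x), names = names(x),
         values = unname(x))
  }
}

.deser <- function(x) {
  kind <- x$`_kind`
  retype <- function(v, type) {
    if (!length(v)) v <- logical(0)
    switch(type, integer = as.integer(v), double = as.numeric(v),
           character = as.character(v), logical = as.logical(v), v)
  }
  if (kind == "matrix") {
    m <- matrix(retype(x$data, x$type), nrow = x$dim[1], ncol = x$dim[2])
    rn <- if (length(x$rn)) as.character(x$rn) else NULL
    cn <- if (length(x$cn)) as.character(x$cn) else NULL
    dimnames(m) <- if (is.null(rn) && is.null(cn)) NULL else list(rn, cn)
    m
  } else if (kind == "df") {
    cols <- lapply(x$columns, .deser)
    names(cols) <- as.character(x$names)
    as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  } else if (kind == "list") {
    out <- lapply(x$items, .deser)
    if (length(x$names)) names(out) <- as.character(x$names)
    out
  } else if (kind == "null") {
    NULL
  } else {
    v <- retype(x$values, x$type)
    if (length(x$names)) names(v) <- as.character(x$names)
    v
  }
}

.write_typed_json <- function(x, path) {
  jsonlite::write_json(.ser(x), path, auto_unbox = FALSE, digits = NA,
                       null = "null", pretty = FALSE)
}

.read_typed_json <- function(path) {
  .deser(jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE))
}

.write_num_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- sprintf("%.6f",
                                                              m[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.read_num_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

.write_pairs <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.read_pairs <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = colClasses)
}

#' Export a synthetic world to pipeline input files
#'
#' Writes every generated input in its standard on-disk format: upstream
#' FASTA, expression/significance/compendium TSV matrices, motif,
#' annotation, localization, reference-PPI and reaction tables,
#' per-sample alignment TSVs, and JSON records of the configuration and
#' the planted truth. The file set round-trips losslessly through
#' [import_world].
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
export_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(world$upstreams), p("upstream.fasta"))
  .write_pairs(data.frame(gene = names(world$gene_lengths),
                          length = unname(world$gene_lengths)),
               p("gene_lengths.tsv"))
  .write_num_matrix(world$host$rpkm, p("expr_host.tsv"))
  .write_num_matrix(world$host$latent, p("latent_host.tsv"))
  sig <- world$host$flags
  sig_df <- data.frame(id = rownames(sig), check.names = FALSE)
  for (j in seq_len(ncol(sig))) sig_df[[colnames(sig)[j]]] <- sig[, j]
  utils::write.table(sig_df, p("sig_host.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_pairs(data.frame(sample = names(world$host$replicate_map),
                          condition = unname(world$host$replicate_map)),
               p("samples.tsv"))
  .write_num_matrix(world$symbiont$rpkm, p("expr_symbiont.tsv"))
  .write_num_matrix(world$compendium, p("compendium.tsv"))
  .write_pairs(world$config$motif_library, p("motifs.tsv"))
  fn <- world$annotations$functional
  .write_pairs(data.frame(gene = rep(names(fn), lengths(fn)),
                          term = unlist(fn, use.names = FALSE)),
               p("annotations.tsv"))
  ec <- world$annotations$ec
  .write_pairs(data.frame(gene = rep(names(ec), lengths(ec)),
                          ec = unlist(ec, use.names = FALSE)),
               p("ec_annotations.tsv"))
  .write_pairs(world$localization_scores, p("localization.tsv"))
  .write_pairs(world$reference_ppi, p("reference_ppi.tsv"))
  .write_pairs(world$reactions, p("reactions.tsv"))
  .write_pairs(data.frame(pathway = world$allowed_pathways),
               p("pathways.tsv"))
  .write_pairs(data.frame(term = names(world$tf_motif_map),
                          motif = unname(world$tf_motif_map)),
               p("tf_motifs.tsv"))
  for (s in names(world$alignments)) {
    at <- world$alignments[[s]]
    k <- lengths(at$candidates)
    .write_pairs(data.frame(
      read_id = rep(names(at$candidates), k),
      gene_id = unlist(at$candidates, use.names = FALSE)),
      p("alignments", paste0(s, ".tsv")))
  }
  .write_typed_json(world$config, p("config.json"))
  .write_typed_json(world$truth, p("truth.json"))
  invisible(dir)
}

#' Import a synthetic world from an exported directory
#'
#' Inverse of [export_world].
#'
#' @param dir Directory written by [export_world].
#' @return A `synthetic_world`.
#' @export
import_world <- function(dir) {
  p <- function(...) file.path(dir, ...)
  cfg <- .read_typed_json(p("config.json"))
  class(cfg) <- "world_config"
  seqs <- Biostrings::readDNAStringSet(p("upstream.fasta"))
  upstreams <- stats::setNames(as.character(seqs), names(seqs))
  gl <- .read_pairs(p("gene_lengths.tsv"))
  gene_lengths <- stats::setNames(as.integer(gl$length), gl$gene)
  rpkm <- .read_num_matrix(p("expr_host.tsv"))
  latent <- .read_num_matrix(p("latent_host.tsv"))
  sig_df <- utils::read.table(p("sig_host.tsv"), sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
  flags <- as.matrix(sig_df[, -1, drop = FALSE])
  rownames(flags) <- sig_df$id
  smp <- .read_pairs(p("samples.tsv"))
  replicate_map <- stats::setNames(smp$condition, smp$sample)
  ann <- .read_pairs(p("annotations.tsv"))
  functional <- lapply(split(ann$term, ann$gene), as.character)
  functional <- functional[unique(ann$gene)]
  ecann <- .read_pairs(p("ec_annotations.tsv"))
  ec <- lapply(split(ecann$ec, ecann$gene), as.character)
  ec <- ec[unique(ecann$gene)]
  align_files <- sort(list.files(p("alignments"), full.names = TRUE))
  alignments <- stats::setNames(
    lapply(align_files, read_alignment_tsv),
    sub("\\.tsv$", "", basename(align_files)))
  alignments <- alignments[smp$sample]
  structure(list(
    config = cfg,
    gene_lengths = gene_lengths,
    host = list(rpkm = rpkm, flags = flags, latent = latent,
                replicate_map = replicate_map, samples = smp$sample),
    upstreams = upstreams,
    annotations = list(functional = functional, ec = ec),
    localization_scores = .read_pairs(p("localization.tsv"),
                                      colClasses = c("character",
                                                     "character",
                                                     "numeric")),
    reference_ppi = .read_pairs(p("reference_ppi.tsv")),
    compendium = .read_num_matrix(p("compendium.tsv")),
    symbiont = list(rpkm = .read_num_matrix(p("expr_symbiont.tsv")),
                    conditions = cfg$conditions),
    alignments = alignments,
    reactions = .read_pairs(p("reactions.tsv"),
                            colClasses = "character"),
    allowed_pathways = .read_pairs(p("pathways.tsv"))$pathway,
    tf_motif_map = with(.read_pairs(p("tf_motifs.tsv")),
                        stats::setNames(motif, term)),
    truth = .read_typed_json(p("truth.json"))),
    class = "synthetic_world")
}
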