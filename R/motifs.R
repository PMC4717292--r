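# IUPAC nucleotide codes and the sequence bases each motif symbol accepts.
# A sequence N (unknown base) is matched by nothing except the motif
# wildcard N itself, so unresolved bases can never create a specific match.
.IUPAC_MATCH <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN"
)

.iupac_regex <- function(pattern) {
  syms <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(syms, names(.IUPAC_MATCH))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in motif: ", paste(bad, collapse = ", "))
  paste0(vapply(syms, function(s) {
    bases <- .IUPAC_MATCH[[s]]
    if (nchar(bases) == 1) bases else paste0("[", bases, "]")
  }, ""), collapse = "")
}

#' Reverse-complement an IUPAC pattern
#' @param pattern IUPAC motif string.
#' @return Reverse complement with degeneracy preserved.
#' @keywords internal
.iupac_revcomp <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(pattern), "")[[1]]]), collapse = "")
}

#' Scan an upstream sequence for an IUPAC motif
#'
#' Presence/absence scan: returns TRUE if the motif matches at one or more
#' positions (every motif symbol's IUPAC base set contains the sequence
#' base at that offset). Match multiplicity is deliberately not counted.
#' Scanning is forward strand by default; `both_strands = TRUE` also tests
#' the motif's reverse complement.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param motif IUPAC pattern string, e.g. "WAACCA".
#' @param both_strands Also scan the reverse complement of the motif.
#' @return Logical scalar; FALSE when the motif is longer than the
#'   sequence.
#' @export
scan_upstream <- function(sequence, motif, both_strands = FALSE) {
  hit <- grepl(.iupac_regex(motif), toupper(sequence))
  if (!hit && both_strands)
    hit <- grepl(.iupac_regex(.iupac_revcomp(motif)), toupper(sequence))
  hit
}

#' Build motif-gene associations over a background gene set
#'
#' A gene is associated with ("carries") a motif when at least one upstream
#' instance is found. The background frequency f of each motif is computed
#' over the supplied background set -- the differentially regulated gene
#' set, not the whole genome -- because that is the reference population
#' the enrichment test draws clusters from.
#'
#' @param upstreams Named character vector: gene id -> upstream sequence.
#' @param library data.frame with columns `name` and `pattern` (IUPAC).
#' @param background Character vector of gene ids (subset of scanned
#'   genes); must be non-empty.
#' @param both_strands Scan reverse complements too (default FALSE).
#' @return A `motif_associations` object: named list, per motif, of
#'   `carriers` (genes with >= 1 match, across all scanned genes) and `f`
#'   (carrier fraction within `background`).
#' @export
build_associations <- function(upstreams, library, background,
                               both_strands = FALSE) {
  if (!length(background)) stop("background gene set must be non-empty")
  if (!all(background %in% names(upstreams)))
    stop("background contains genes without upstream sequences")
  seqs <- toupper(upstreams)
  assoc <- lapply(seq_len(nrow(library)), function(i) {
    rx <- .iupac_regex(library$pattern[i])
    hit <- grepl(rx, seqs)
    if (both_strands) {
      rc <- .iupac_regex(.iupac_revcomp(library$pattern[i]))
      hit <- hit | grepl(rc, seqs)
    }
    carriers <- names(upstreams)[hit]
    list(motif = library$name[i], pattern = library$pattern[i],
         carriers = carriers,
         f = mean(background %in% carriers))
  })
  structure(stats::setNames(assoc, library$name),
            class = "motif_associations")
}

#' Motif enrichment in a gene cluster
#'
#' Upper-tail cumulative binomial test of each motif's carrier count in the
#' cluster against its background frequency (see [cbd_enrichment_p]). A
#' motif passes when p < `alpha` AND at least `min_genes` cluster genes
#' carry it; the carrier floor keeps motifs that merely co-occur in a few
#' functionally related genes from being called regulatory.
#'
#' @param members Character vector of cluster gene ids.
#' @param associations A `motif_associations` object (see
#'   [build_associations]).
#' @param alpha Significance threshold (default 0.01).
#' @param min_genes Minimum carrier count in the cluster (default 10).
#' @return data.frame with columns motif, n, x, f, p, passes.
#' @export
enrich_motifs <- function(members, associations, alpha = 0.01,
                          min_genes = 10) {
  n <- length(members)
  rows <- lapply(associations, function(a) {
    x <- sum(members %in% a$carriers)
    stopifnot(x == 0 || a$f > 0)  # a carrier in the cluster implies f > 0
    p <- if (x == 0) 1 else cbd_enrichment_p(x, n, a$f)
    data.frame(motif = a$motif, n = n, x = x, f = a$f, p = p,
               passes = p < alpha && x >= min_genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$p), , drop = FALSE]
}

#' Known binding motifs of sensor-complex transcription factors
#'
#' For every transcription-factor node of each predicted sensor complex,
#' looks up its known binding motif (via the functional-annotation ->
#' motif map) and counts, per gene cluster, the cluster genes that carry
#' that motif upstream. Transcription factors whose family has no known
#' motif yield no rows, as do complexes without transcription factors.
#'
#' @param complexes List of `sensor_complex` objects (see
#'   [extract_complexes]).
#' @param annotations Named list: gene id -> functional terms.
#' @param tf_motif_map Named character vector: functional term -> motif
#'   name.
#' @param clusters A `gene_clusters` object.
#' @param associations A `motif_associations` object covering the mapped
#'   motifs.
#' @return data.frame with columns complex, tf_gene, motif, cluster,
#'   n_carriers.
#' @export
motifs_for_complex_tfs <- function(complexes, annotations, tf_motif_map,
                                   clusters, associations) {
  rows <- list()
  for (cx in complexes) {
    tfs <- cx$nodes$gene[cx$nodes$role == "transcription_factor"]
    for (tf in tfs) {
      terms <- intersect(annotations[[tf]], names(tf_motif_map))
      for (motif in unique(unname(tf_motif_map[terms]))) {
        a <- associations[[motif]]
        if (is.null(a)) next
        for (cl in clusters$clusters) {
          rows[[length(rows) + 1L]] <- data.frame(
            complex = cx$id, tf_gene = tf, motif = motif, cluster = cl$id,
            n_carriers = sum(cl$members %in% a$carriers),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(complex = character(), tf_gene = character(),
                      motif = character(), cluster = integer(),
                      n_carriers = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
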