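#' Alignment tables
#'
#' An alignment table records, for every aligned read, the set of candidate
#' gene models it maps to. Multi-mapped reads keep all their candidates:
#' the aligner is run so that it returns all possible placements, and the
#' bootstrap quantifier (not the aligner) resolves the ambiguity.
#'
#' @param candidates Named list: read id -> character vector of candidate
#'   gene ids (duplicate-free, length >= 1).
#' @return An `alignment_table` object.
#' @export
alignment_table <- function(candidates) {
  stopifnot(is.list(candidates))
  if (length(candidates)) {
    lens <- lengths(candidates)
    if (any(lens < 1)) stop("every read needs at least one candidate gene")
    if (any(vapply(candidates, anyDuplicated, 0L) > 0))
      stop("candidate lists must be duplicate-free")
  }
  structure(list(candidates = candidates, n_reads = length(candidates)),
            class = "alignment_table")
}

#' @export
print.alignment_table <- function(x, ...) {
  multi <- if (x$n_reads) mean(lengths(x$candidates) > 1) else 0
  cat(sprintf("alignment_table: %d reads, %.1f%% multi-mapped\n",
              x$n_reads, 100 * multi))
  invisible(x)
}

#' Read an alignment table from a two-column TSV (read id, gene id)
#'
#' A read aligned to several genes appears on several rows.
#'
#' @param path File path.
#' @return An [alignment_table].
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected columns: read_id, gene_id")
  alignment_table(lapply(split(df[[2]], df[[1]]), unique))
}

#' Read an alignment table from a SAM file
#'
#' Only the QNAME and RNAME columns are used: with an aligner configured to
#' report all placements, the candidate set -- not any single placement --
#' is the unit of information, so flags, positions, CIGAR and qualities are
#' ignored. Unmapped records (RNAME `*`) are dropped.
#'
#' @param path SAM file path.
#' @return An [alignment_table].
#' @export
read_alignment_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(alignment_table(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(parts, `[[`, "", 1L)
  rname <- vapply(parts, `[[`, "", 3L)
  keep <- rname != "*"
  alignment_table(lapply(split(rname[keep], qname[keep]), unique))
}

#' Bootstrap quantification of gene expression (RPKM with confidence)
#'
#' Resamples the aligned reads with replacement `iterations` times. Within
#' each iteration every sampled multi-mapped read is assigned to exactly one
#' of its candidate genes, uniformly at random (or fractionally, 1/k to each
#' of its k candidates, when `fractional = TRUE`), and per-gene RPKM is
#' computed as 1e9 * count / (n_reads * length). The mean and standard
#' deviation over iterations summarise each gene, and expression is called
#' significant when the lower normal tail at zero,
#' P(Normal(mean, sd) <= 0), falls below `alpha`.
#'
#' The uniform single-assignment default propagates mapping ambiguity into
#' the standard deviation, which is the point of bootstrapping alignments
#' rather than counts.
#'
#' @param alignments An [alignment_table].
#' @param gene_lengths Named numeric vector, gene id -> length in bases
#'   (> 0). Genes listed here but receiving no reads are reported with mean
#'   0 and p 1.
#' @param iterations Bootstrap iterations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @param alpha Significance threshold on the expression p-value
#'   (default 1e-4, uncorrected).
#' @param fractional Use fractional 1/k multi-map weighting instead of
#'   random single assignment.
#' @return data.frame with columns gene, mean_rpkm, sd_rpkm, p_expressed,
#'   significant.
#' @export
bowstrap_quantify <- function(alignments, gene_lengths, iterations = 10000,
                              seed = 1L, alpha = 1e-4, fractional = FALSE) {
  stopifnot(inherits(alignments, "alignment_table"))
  if (iterations < 1) stop("iterations must be >= 1")
  if (is.null(names(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene_lengths must be a named vector of positive lengths")
  genes <- names(gene_lengths)
  ng <- length(genes)
  nr <- alignments$n_reads

  out <- data.frame(gene = genes, mean_rpkm = 0, sd_rpkm = 0,
                    p_expressed = 1, significant = FALSE,
                    stringsAsFactors = FALSE)
  if (nr == 0) return(out)

  cand <- alignments$candidates
  unknown <- setdiff(unique(unlist(cand, use.names = FALSE)), genes)
  if (length(unknown))
    stop("candidate genes missing from gene_lengths: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  # flattened candidate arrays for O(n_reads) sampling per iteration
  k <- lengths(cand)
  flat_gene <- match(unlist(cand, use.names = FALSE), genes)
  flat_start <- cumsum(c(0L, k[-length(k)]))  # 0-based start per read
  inv_k <- 1 / k

  set.seed(seed)
  sum_c <- numeric(ng)
  sumsq_c <- numeric(ng)
  for (i in seq_len(iterations)) {
    samp <- sample.int(nr, nr, replace = TRUE)
    if (fractional) {
      tab <- tabulate(samp, nbins = nr)
      contrib <- tab[rep.int(seq_len(nr), k)] * inv_k[rep.int(seq_len(nr), k)]
      counts <- numeric(ng)
      agg <- rowsum(contrib, group = flat_gene)
      counts[as.integer(rownames(agg))] <- agg[, 1L]
    } else {
      pick <- flat_start[samp] + floor(stats::runif(nr) * k[samp]) + 1L
      counts <- tabulate(flat_gene[pick], nbins = ng)
    }
    sum_c <- sum_c + counts
    sumsq_c <- sumsq_c + counts^2
  }

  scale <- 1e9 / (nr * unname(gene_lengths))
  mean_c <- sum_c / iterations
  var_c <- if (iterations > 1) {
    pmax(0, (sumsq_c - iterations * mean_c^2) / (iterations - 1))
  } else {
    numeric(ng)
  }
  out$mean_rpkm <- mean_c * scale
  out$sd_rpkm <- sqrt(var_c) * scale
  # guard against representation noise: constant counts give exactly sd 0
  out$sd_rpkm[var_c < 1e-9 * pmax(1, mean_c^2)] <- 0

  zero_sd <- out$sd_rpkm == 0
  out$p_expressed[!zero_sd] <-
    stats::pnorm(0, out$mean_rpkm[!zero_sd], out$sd_rpkm[!zero_sd])
  out$p_expressed[zero_sd] <- ifelse(out$mean_rpkm[zero_sd] > 0, 0, 1)
  out$significant <- out$p_expressed < alpha
  out
}

#' Quantile-normalize an expression matrix
#'
#' Makes every sample's value distribution identical (the cross-sample mean
#' of order statistics) while preserving within-sample ranks.
#'
#' @param matrix Numeric gene x sample matrix.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Floor-and-log2 transform an expression matrix
#'
#' @param matrix Numeric matrix with values >= 0.
#' @param floor Positive floor applied before the logarithm, so that zeros
#'   map to log2(floor) rather than -Inf.
#' @return log2-transformed matrix.
#' @export
log2_transform <- function(matrix, floor = 0.01) {
  stopifnot(floor > 0, all(matrix >= 0))
  log2(pmax(as.matrix(matrix), floor))
}
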