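test_that("world generation is deterministic for a fixed seed", {
  w1 <- generate_world(world_config(seed = 7, n_host_genes = 120,
                                    genes_per_cluster = 10,
                                    reads_per_sample = 500))
  w2 <- generate_world(world_config(seed = 7, n_host_genes = 120,
                                    genes_per_cluster = 10,
                                    reads_per_sample = 500))
  expect_identical(w1, w2)
  w3 <- generate_world(world_config(seed = 8, n_host_genes = 120,
                                    genes_per_cluster = 10,
                                    reads_per_sample = 500))
  expect_false(identical(w1$upstreams, w3$upstreams))
})

test_that("config validation rejects inconsistent worlds", {
  expect_error(world_config(conditions = c("a", "a", "b")), "unique")
  expect_error(world_config(background_motif_frequency = 1.2), "fraction")
  expect_error(world_config(background_motif_frequency = 0.9),
               "inconsistent")
  expect_error(world_config(n_host_genes = 50), "planted clusters")
  bad_links <- data.frame(metabolite = "m", cluster = 1, sign = 2)
  expect_error(world_config(planted_metabolite_links = bad_links),
               "sign")
})

test_that("forced planting makes every cluster gene a carrier", {
  cfg <- world_config(seed = 3, n_host_genes = 120, genes_per_cluster = 10,
                      n_clusters_planted = 3, n_complexes = 1,
                      reads_per_sample = 200,
                      planted_motif_enrichment = data.frame(
                        cluster = 1, motif = "motif_01", fraction = 1.0))
  w <- generate_world(cfg)
  cl1 <- names(w$truth$clusters)[w$truth$clusters == 1]
  pat <- cfg$motif_library$pattern[1]
  expect_true(all(vapply(w$upstreams[cl1], scan_upstream, NA,
                         motif = pat)))
})

test_that("planted carrier fractions converge binomially with gene count", {
  cfg <- world_config(seed = 11, n_host_genes = 1200,
                      genes_per_cluster = 120, n_clusters_planted = 9,
                      reads_per_sample = 100)
  w <- generate_world(cfg)
  for (i in c(1, 5)) {
    motif <- cfg$planted_motif_enrichment$motif[i]
    frac <- cfg$planted_motif_enrichment$fraction[i]
    genes <- names(w$truth$clusters)[w$truth$clusters == i]
    pat <- cfg$motif_library$pattern[cfg$motif_library$name == motif]
    observed <- mean(vapply(w$upstreams[genes], scan_upstream, NA,
                            motif = pat))
    tol <- 3 * sqrt(frac * (1 - frac) / length(genes)) + 0.04
    expect_lt(abs(observed - frac), tol)
  }
})

test_that("upstream sequences and truth satisfy the world invariants", {
  w <- tiny_world()
  cfg <- w$config
  expect_equal(length(w$upstreams), cfg$n_host_genes)
  expect_true(all(nchar(w$upstreams) == cfg$upstream_length))
  # cluster memberships are disjoint and reference PPI is simple
  expect_equal(anyDuplicated(names(w$truth$clusters)), 0L)
  key <- paste(pmin(w$reference_ppi$protein_a, w$reference_ppi$protein_b),
               pmax(w$reference_ppi$protein_a, w$reference_ppi$protein_b))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(w$reference_ppi$protein_a != w$reference_ppi$protein_b))
  expect_equal(nrow(w$reference_ppi), cfg$n_reference_ppis)
})

test_that("simulated alignments follow expression-length read shares", {
  w <- generate_world(world_config(seed = 5, n_host_genes = 120,
                                   genes_per_cluster = 10,
                                   reads_per_sample = 400))
  # multimap 0 gives single candidates; zero reads give an empty table
  w0 <- generate_world(world_config(seed = 5, n_host_genes = 120,
                                    genes_per_cluster = 10,
                                    reads_per_sample = 400,
                                    multimap_fraction = 0))
  a0 <- generate_alignments(w0, "FL_1", seed = 2)
  expect_true(all(lengths(a0$candidates) == 1))
  wz <- generate_world(world_config(seed = 5, n_host_genes = 120,
                                    genes_per_cluster = 10,
                                    reads_per_sample = 0))
  expect_equal(generate_alignments(wz, "FL_1", seed = 2)$n_reads, 0)
  expect_error(generate_alignments(w, "nope", 1), "unknown sample")

  # expected read share of a gene matches its expression x length share
  wts <- w$host$rpkm[, "FL_1"] * w$gene_lengths
  share <- wts / sum(wts)
  top <- names(sort(share, decreasing = TRUE))[1]
  counts <- vapply(1:50, function(s) {
    at <- generate_alignments(w, "FL_1", seed = 100 + s)
    sum(vapply(at$candidates, `[`, "", 1) == top)
  }, 0)
  n <- w$config$reads_per_sample
  se <- sqrt(n * share[top] * (1 - share[top]) / 50)
  expect_lt(abs(mean(counts) - n * share[top]), 4 * se)
})

test_that("export and import round-trip the world losslessly", {
  w <- generate_world(world_config(seed = 13, n_host_genes = 120,
                                   genes_per_cluster = 10,
                                   n_reference_proteins = 40,
                                   n_reference_ppis = 80,
                                   n_background_ecs = 30, hub_fanin = 5,
                                   n_symbiont_genes = 40,
                                   reads_per_sample = 300))
  d1 <- file.path(tempdir(), "world_rt1")
  export_world(w, d1)
  expect_equal(length(Biostrings::readDNAStringSet(
    file.path(d1, "upstream.fasta"))), w$config$n_host_genes)
  w2 <- import_world(d1)
  expect_equal(w2, w, tolerance = 1e-5)
  # a second export of the imported world is byte-identical
  d2 <- file.path(tempdir(), "world_rt2")
  export_world(w2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
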