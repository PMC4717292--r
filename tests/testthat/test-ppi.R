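test_that("rank-based network equals the exhaustive all-pairs oracle", {
  set.seed(17)
  # two planted co-expression blocks of five genes over 20 samples
  f1 <- rnorm(20); f2 <- rnorm(20)
  mat <- rbind(
    t(replicate(5, f1 + rnorm(20, 0, 0.2))),
    t(replicate(5, f2 + rnorm(20, 0, 0.2))))
  rownames(mat) <- sprintf("g%02d", 1:10)
  colnames(mat) <- sprintf("s%02d", 1:20)
  net <- grvn_network(mat, rownames(mat), neighborhood = 5, alpha = 0.01)
  got <- sort(paste(net$edges$gene_a, net$edges$gene_b))
  expect_equal(got, grvn_oracle(mat, 5, 0.01))
  # edge count bound and subset-of-significant property
  expect_lte(nrow(net$edges), 5 * 10)
  allp <- which(upper.tri(diag(10)), arr.ind = TRUE)
  sig <- apply(allp, 1, function(ij) {
    ct <- cor.test(mat[ij[1], ], mat[ij[2], ])
    ct$p.value < 0.01
  })
  sig_pairs <- paste(rownames(mat)[pmin(allp[sig, 1], allp[sig, 2])],
                     rownames(mat)[pmax(allp[sig, 1], allp[sig, 2])])
  expect_true(all(got %in% sort(sig_pairs)))
})

test_that("degenerate networks: perfect duplicates and singleton sets", {
  set.seed(8)
  base <- rnorm(10)
  mat <- rbind(a = base, b = base, c = rnorm(10))
  colnames(mat) <- paste0("s", 1:10)
  net <- grvn_network(mat, c("a", "b", "c"), neighborhood = 1,
                      alpha = 0.01)
  expect_true(any(net$edges$gene_a == "a" & net$edges$gene_b == "b"))
  expect_equal(net$edges$p[net$edges$gene_a == "a" &
                             net$edges$gene_b == "b"], 0)
  expect_equal(nrow(grvn_network(mat, "a", 5, 0.01)$edges), 0)
  mat2 <- rbind(mat, flat = rep(1, 10))
  expect_warning(grvn_network(mat2, rownames(mat2), 2, 0.01), "constant")
})

test_that("localization assignment takes the top score, ties and splits", {
  out <- assign_localizations(list(
    p1 = c(nuclear = 9, cytoplasm = 3),
    p2 = c(nuclear = 5, plasma_membrane = 5),
    p3 = c("nuclear:cytoplasm" = 9, extracellular = 1)))
  expect_equal(out$p1, "nuclear")
  expect_setequal(out$p2, c("nuclear", "plasma_membrane"))
  expect_setequal(out$p3, c("nuclear", "cytoplasm"))
  df <- data.frame(protein = c("q", "q"), label = c("a", "b"),
                   score = c(1, 2))
  expect_equal(assign_localizations(df)$q, "b")
  expect_error(assign_localizations(list(p = numeric())), "empty")
})

test_that("LOI Z-scores match exhaustive permutation enumeration", {
  # 6 proteins, 2 labels, 4 edges: all 4! endpoint permutations
  labels <- c(p1 = "a", p2 = "a", p3 = "a", p4 = "b", p5 = "b", p6 = "b")
  pa <- c("p1", "p2", "p3", "p1")
  pb <- c("p4", "p5", "p6", "p2")
  oracle <- loi_enumeration_oracle(pa, pb, labels)
  loi <- compute_loi_table(data.frame(protein_a = pa, protein_b = pb),
                           lapply(labels, identity),
                           iterations = 10000, seed = 4)
  for (key in names(oracle$mean)) {
    ab <- strsplit(key, " ")[[1]]
    z_oracle <- if (oracle$sd[key] > 0)
      (oracle$observed[key] - oracle$mean[key]) / oracle$sd[key] else 0
    expect_equal(unname(loi$z[ab[1], ab[2]]), unname(z_oracle),
                 tolerance = 0.1)
  }
  expect_equal(loi$z, t(loi$z))  # symmetry
})

test_that("forced label pairing dominates the LOI table", {
  labels <- list(x1 = "a", x2 = "a", x3 = "a", y1 = "b", y2 = "b",
                 y3 = "b")
  ref <- data.frame(protein_a = c("x1", "x2", "x3"),
                    protein_b = c("y1", "y2", "y3"))
  loi <- compute_loi_table(ref, labels, iterations = 2000, seed = 1)
  expect_gt(loi$z["a", "b"], 0)
  expect_equal(max(loi$z), loi$z["a", "b"])
  expect_error(compute_loi_table(ref, labels[-1], 10, 1), "without")
})

test_that("edge filtering enforces expression, function and LOI gates", {
  edges <- data.frame(gene_a = c("a", "a", "c"),
                      gene_b = c("b", "c", "d"),
                      r = c(0.9, 0.8, 0.7), p = c(1e-5, 1e-4, 1e-3),
                      proposed_by = "both", stringsAsFactors = FALSE)
  net <- structure(list(nodes = c("a", "b", "c", "d"), edges = edges),
                   class = "coexpression_network")
  z <- matrix(c(2, 0.5, 0.5, 2), 2, 2,
              dimnames = list(c("cy", "nu"), c("cy", "nu")))
  loi <- structure(list(z = z, labels = c("cy", "nu")),
                   class = "loi_table")
  locs <- list(a = "cy", b = "cy", c = "nu", d = "cy")
  ann <- list(a = "signal_transduction", b = "signal_transduction",
              c = "signal_transduction", d = "metabolism")
  expr <- c(a = TRUE, b = TRUE, c = TRUE, d = TRUE)
  out <- filter_candidate_edges(net, loi, locs, expr, ann,
                                "signal_transduction")
  # a-b passes (cy-cy Z=2); a-c fails LOI (cy-nu 0.5); c-d fails function
  expect_equal(nrow(out$edges), 1)
  expect_equal(out$edges$gene_a, "a")
  expect_equal(out$edges$gene_b, "b")
  # losing significance in one sample removes all of a protein's edges
  expr2 <- c(a = FALSE, b = TRUE, c = TRUE, d = TRUE)
  expect_equal(nrow(filter_candidate_edges(net, loi, locs, expr2, ann,
                                           "signal_transduction")$edges),
               0)
  # raising the threshold is monotone
  n1 <- nrow(filter_candidate_edges(net, loi, locs, expr, ann,
                                    "signal_transduction", 0.4)$edges)
  n2 <- nrow(filter_candidate_edges(net, loi, locs, expr, ann,
                                    "signal_transduction", 1.9)$edges)
  expect_gte(n1, n2)
})

test_that("complex extraction matches a union-find oracle and role types", {
  edges <- data.frame(
    gene_a = c("r1", "k1", "k2", "t2"), gene_b = c("k1", "t1", "t2", "d2"),
    r = 0.9, p = 1e-6, proposed_by = "both", loi = 2,
    stringsAsFactors = FALSE)
  net <- structure(list(nodes = unique(c(edges$gene_a, edges$gene_b)),
                        edges = edges), class = "coexpression_network")
  ann <- list(r1 = "transmembrane_receptor", k1 = "kinase_cascade",
              t1 = "transcription_factor_activity", k2 = "other",
              t2 = "transcription_factor_activity",
              d2 = "defense_response")
  rm <- list(receptor = "transmembrane_receptor",
             transcription_factor = "transcription_factor_activity",
             defense = "defense_response")
  cx <- extract_complexes(net, ann, rm)
  oracle <- components_oracle(edges$gene_a, edges$gene_b)
  expect_equal(length(cx), length(oracle))
  got_sets <- lapply(cx, function(c) sort(c$nodes$gene))
  expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                  vapply(oracle, function(s) paste(sort(s), collapse = ","),
                         ""))
  roles <- do.call(rbind, lapply(cx, `[[`, "nodes"))
  expect_equal(roles$role[roles$gene == "r1"], "receptor")
  expect_equal(roles$role[roles$gene == "k2"], "cascade")
  expect_equal(roles$role[roles$gene == "t2"], "transcription_factor")
  expect_equal(roles$role[roles$gene == "d2"], "defense")
  expect_equal(extract_complexes(structure(list(
    nodes = character(), edges = edges[0, ]),
    class = "coexpression_network"), ann, rm), list())
})
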