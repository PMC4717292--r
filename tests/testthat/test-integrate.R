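fake_clusters <- function(profiles) {
  ids <- rownames(profiles)
  structure(list(
    membership = setNames(seq_along(ids), paste0("gene_", ids)),
    clusters = lapply(seq_along(ids), function(i)
      list(id = i, members = paste0("gene_", ids[i]),
           mean_profile = profiles[i, ])),
    conditions = colnames(profiles)), class = "gene_clusters")
}

test_that("turnover-cluster correlation matches the textbook formula", {
  conds <- paste0("c", 1:8)
  set.seed(51)
  sc <- matrix(rnorm(24), 3, 8, dimnames = list(c("m1", "m2", "m3"),
                                                conds))
  prof <- matrix(rnorm(16), 2, 8, dimnames = list(c("k1", "k2"), conds))
  prof <- prof - rowMeans(prof)
  tv <- structure(list(scores = sc), class = "turnover_scores")
  corr <- correlate_turnover(tv, fake_clusters(prof))
  cov_r <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (m in rownames(sc)) for (k in 1:2)
    expect_equal(corr$r[m, as.character(k)], cov_r(sc[m, ], prof[k, ]),
                 tolerance = 1e-12)
  # exact negation gives r = -1; a constant profile is missing
  tv2 <- structure(list(scores = rbind(m = -prof["k1", ])),
                   class = "turnover_scores")
  corr2 <- correlate_turnover(tv2, fake_clusters(prof))
  expect_equal(corr2$r["m", "1"], -1)
  flat <- matrix(0, 1, 8, dimnames = list("kf", conds))
  corr3 <- correlate_turnover(tv, fake_clusters(flat))
  expect_true(all(is.na(corr3$r)))
})

test_that("strong-link selection equals a full-sort oracle on the pool", {
  set.seed(53)
  r <- matrix(runif(10000, -0.9, 0.9), 1000, 10,
              dimnames = list(paste0("m", 1:1000), paste0("k", 1:10)))
  corr <- structure(list(r = r), class = "correlation_matrix")
  links <- select_strong_links(corr, percentile = 0.001)
  cuts <- quantile(as.vector(r), c(0.001, 0.999), names = FALSE)
  pool <- sort(as.vector(r))
  oracle_vals <- sort(c(pool[pool < cuts[1]], pool[pool > cuts[2]]))
  expect_equal(sort(links$r), oracle_vals)
  expect_true(all(links$coupling[links$r < 0] == "synthesis_coupled"))
  # degenerate inputs
  small <- structure(list(r = matrix(c(0.1, 0.9, -0.5, 0.2), 2, 2,
                                     dimnames = list(c("a", "b"),
                                                     c("1", "2")))),
                     class = "correlation_matrix")
  expect_warning(out <- select_strong_links(small, 0.001), "extreme")
  expect_setequal(out$r, c(-0.5, 0.9))
  allsame <- structure(list(r = matrix(0.5, 40, 40,
                                       dimnames = list(paste0("m", 1:40),
                                                       paste0("k", 1:40)))),
                       class = "correlation_matrix")
  expect_warning(none <- select_strong_links(allsame, 0.001), "cutoff")
  expect_equal(nrow(none), 0)
})

test_that("complex-cluster links require a shared gene and keep evidence", {
  cx <- list(
    structure(list(id = "cxA",
                   nodes = data.frame(gene = c("g1", "g2"),
                                      role = c("receptor", "cascade")),
                   edges = data.frame(), size = 2),
              class = "sensor_complex"),
    structure(list(id = "cxB",
                   nodes = data.frame(gene = "g9", role = "cascade"),
                   edges = data.frame(), size = 1),
              class = "sensor_complex"))
  cl <- structure(list(
    membership = setNames(c(1L, 1L, 2L), c("g1", "g3", "g2")),
    clusters = list(list(id = 1, members = c("g1", "g3"),
                         mean_profile = 0),
                    list(id = 2, members = "g2", mean_profile = 0)),
    conditions = "c1"), class = "gene_clusters")
  links <- link_complexes_to_clusters(cx, cl)
  expect_equal(nrow(links), 2)       # cxA shares with both clusters
  expect_setequal(links$cluster, c("1", "2"))
  expect_false("cxB" %in% links$complex)  # disjoint complex: no edge
  expect_equal(links$shared_genes[[which(links$cluster == "1")]], "g1")
})

test_that("assembly wires a planted chain with all four rule provenances", {
  strong <- data.frame(metabolite = "metX", cluster = "1", r = -0.99,
                       coupling = "synthesis_coupled")
  cx <- list(structure(list(
    id = "cxA",
    nodes = data.frame(gene = c("g1", "g2"),
                       role = c("receptor", "transcription_factor")),
    edges = data.frame(), size = 2), class = "sensor_complex"))
  clinks <- data.frame(complex = "cxA", cluster = "1", n_shared = 1)
  clinks$shared_genes <- list("g1")
  motifs <- data.frame(cluster = "1", motif = "motif_01", n = 20, x = 15,
                       f = 0.1, p = 1e-9, passes = TRUE)
  ctf <- data.frame(complex = "cxA", tf_gene = "g2", motif = "motif_02",
                    cluster = "1", n_carriers = 12)
  phen <- list(`1` = data.frame(term = "phen_defense", p = 0.001,
                                n_members = 9))
  model <- assemble_model(strong, clinks, cx, motifs, ctf, phen)
  expect_setequal(model$edges$rule, 1:4)
  expect_true(any(model$edges$from == "metabolite:metX" &
                    model$edges$to == "cxA" & model$edges$type == "signals"))
  expect_true(any(model$edges$from == "cxA" &
                    model$edges$to == "cluster:1"))
  expect_true(any(model$edges$from == "motif:motif_01" &
                    grepl("enriched", model$edges$evidence)))
  expect_true(any(model$edges$from == "motif:motif_02" &
                    grepl("complex_tf", model$edges$evidence)))
  expect_true(any(model$edges$to == "phenotype:phen_defense"))
  expect_setequal(
    model$nodes$type[model$nodes$id %in% c("g1", "g2")],
    c("receptor", "transcription_factor"))

  # idempotence / order independence
  model2 <- assemble_model(strong[1, ], clinks, cx,
                           motifs, ctf, phen)
  expect_identical(model, model2)

  # a correlated cluster without a complex dangles with a warning
  strong_d <- data.frame(metabolite = "metY", cluster = "7", r = 0.98,
                         coupling = "consumption_coupled")
  expect_warning(md <- assemble_model(strong_d, clinks[0, ], list(),
                                      NULL, NULL, NULL), "dangling")
  expect_true(any(md$edges$from == "metabolite:metY" &
                    md$edges$to == "cluster:7" &
                    md$edges$type == "signals"))

  # empty inputs give an empty model
  empty <- assemble_model(strong[0, ], clinks[0, ], list(), NULL, NULL,
                          NULL)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("model exports round-trip through GraphML and JSON", {
  strong <- data.frame(metabolite = "metX", cluster = "1", r = 0.95,
                       coupling = "consumption_coupled")
  cx <- list(structure(list(
    id = "cxA", nodes = data.frame(gene = "g1", role = "receptor"),
    edges = data.frame(), size = 1), class = "sensor_complex"))
  clinks <- data.frame(complex = "cxA", cluster = "1", n_shared = 1)
  model <- assemble_model(strong, clinks, cx)
  gml <- tempfile(fileext = ".graphml")
  write_model_graphml(model, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(model$nodes))
  expect_equal(igraph::ecount(g), nrow(model$edges))
  expect_setequal(igraph::vertex_attr(g, "type"), model$nodes$type)
  js <- tempfile(fileext = ".json")
  write_model_json(model, js)
  back <- jsonlite::fromJSON(js)
  expect_equal(nrow(back$edges), nrow(model$edges))
})
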