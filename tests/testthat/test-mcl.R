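test_that("graph construction thresholds, transforms and merges edges", {
  e <- make_edges(c("a", "b", "c", "a", "d"),
                  c("b", "a", "d", "a", "c"),
                  c(1e-40, 1e-42, 1e-30, 1e-99, 0))
  g <- build_graph(e, nodes = c("a", "b", "c", "d", "lonely"))
  # self-hit dropped, 1e-30 dropped at the 1e-35 default
  expect_equal(nrow(g$edges), 2)
  ab <- g$edges[g$edges$from == "a" & g$edges$to == "b", ]
  expect_equal(ab$weight, 42)  # reciprocal merge keeps the larger weight
  cd <- g$edges[g$edges$from == "c" & g$edges$to == "d", ]
  expect_equal(cd$weight, 200)  # e-value 0 capped
  expect_true("lonely" %in% g$nodes)

  expect_error(build_graph(e, nodes = c("a", "b")), "outside the node")
  g30 <- build_graph(e, evalue_threshold = 1e-25)
  expect_true(any(g30$edges$from == "c" & g30$edges$to == "d" |
                    g30$edges$weight == 30))
})

test_that("disconnected cliques and isolated nodes cluster trivially", {
  e <- make_edges(c("a", "a", "b", "x", "x", "y"),
                  c("b", "c", "c", "y", "z", "z"), 1e-50)
  g <- build_graph(e, nodes = c(letters[1:3], "x", "y", "z", "solo"))
  cl <- mcl_cluster(g)
  parts <- partition_of(cl)
  expect_equal(parts, list(c("a", "b", "c"), "solo", c("x", "y", "z")))
  expect_true(attr(cl, "converged"))
})

test_that("MCL output always partitions the node set", {
  for (seed in 1:5) {
    set.seed(seed)
    nodes <- paste0("n", 1:8)
    pick <- t(combn(nodes, 2))
    take <- runif(nrow(pick)) < 0.4
    e <- make_edges(pick[take, 1], pick[take, 2],
                    10^-runif(sum(take), 36, 120))
    cl <- mcl_cluster(build_graph(e, nodes = nodes))
    expect_setequal(cl$member, nodes)
    expect_equal(anyDuplicated(cl$member), 0L)
    # repeated runs are identical (deterministic interpretation)
    expect_identical(cl, mcl_cluster(build_graph(e, nodes = nodes)))
  }
})

test_that("small-instance partitions match the reference MCL", {
  fixtures <- list(
    barbell = make_edges(
      c("a", "a", "b", "x", "x", "y", "m", "m"),
      c("b", "c", "c", "y", "z", "z", "c", "x"),
      c(1e-50, 1e-50, 1e-50, 1e-50, 1e-50, 1e-50, 1e-40, 1e-40)),
    chain = make_edges(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                       c(1e-60, 1e-45, 1e-45, 1e-60)),
    star = make_edges(rep("hub", 4), paste0("s", 1:4), 1e-50),
    uneven = make_edges(c("a", "a", "b", "c", "d"),
                        c("b", "c", "c", "d", "e"),
                        c(1e-120, 1e-110, 1e-100, 1e-38, 1e-36)))
  for (nm in names(fixtures)) {
    e <- fixtures[[nm]]
    nodes <- sort(unique(c(e$query, e$subject)))
    cl <- mcl_cluster(build_graph(e, nodes = nodes))
    ref <- oracle_mcl(adj_from_edges(e, nodes))
    expect_equal(partition_of(cl), ref, info = nm)
  }
})

test_that("raising inflation never merges clusters on the toy suite", {
  e <- make_edges(c("a", "a", "b", "c", "d", "d", "e"),
                  c("b", "c", "c", "d", "e", "f", "f"),
                  c(1e-90, 1e-80, 1e-85, 1e-40, 1e-90, 1e-80, 1e-85))
  nodes <- sort(unique(c(e$query, e$subject)))
  n2 <- max(mcl_cluster(build_graph(e, nodes = nodes),
                        mcl_params(inflation = 2))$cluster)
  n6 <- max(mcl_cluster(build_graph(e, nodes = nodes),
                        mcl_params(inflation = 6))$cluster)
  expect_gte(n6, n2)
})

test_that("core labelling needs an effector and 5 of 8 focal datasets", {
  clusters <- data.frame(
    cluster = c(rep(1L, 5), rep(2L, 4), rep(3L, 8)),
    member = paste0("m", 1:17), stringsAsFactors = FALSE)
  ds <- stats::setNames(paste0("d", c(1:5, 1:4, 1:8)), clusters$member)
  lab <- label_and_find_core(clusters, effector_ids = c("m1", "m6"),
                             dataset_of = ds,
                             aphid_datasets = paste0("d", 1:8))
  expect_equal(lab$contains_effector, c(TRUE, TRUE, FALSE))
  expect_equal(lab$core, c(TRUE, FALSE, FALSE))
  expect_error(label_and_find_core(clusters, "m1", ds[-1]), "without a dataset")
})

test_that("outgroup datasets never count towards core membership", {
  clusters <- data.frame(cluster = rep(1L, 5), member = paste0("m", 1:5))
  ds <- stats::setNames(c("d1", "d2", "d3", "d4", "fly"), clusters$member)
  lab <- label_and_find_core(clusters, "m1", ds,
                             aphid_datasets = paste0("d", 1:8),
                             min_datasets = 5L)
  expect_equal(lab$n_datasets, 4L)
  expect_false(lab$core)
})

test_that("pioneer clusters are unannotated, effector-bearing, confined", {
  clusters <- data.frame(cluster = c(1L, 1L, 2L, 2L, 3L, 3L),
                         member = paste0("m", 1:6))
  ds <- stats::setNames(c("d1", "d1", "d2", "d2", "d1", "d5"),
                        clusters$member)
  species <- stats::setNames(paste0("sp", c(1, 1, 1, 4, 5)), paste0("d", 1:5))
  genus <- stats::setNames(paste0("g", c(1, 1, 1, 4, 5)), paste0("d", 1:5))
  ann <- annotation_table(paste0("m", 1:6),
                          TRUE, FALSE, FALSE,
                          best_db_hit_evalue = c(NA, NA, NA, NA, NA, NA),
                          has_pfamA = c(FALSE, FALSE, TRUE, FALSE,
                                        FALSE, FALSE))
  pio <- find_pioneers(clusters, ann, effector_ids = c("m1", "m3", "m5"),
                       ds, species, genus)
  expect_equal(pio$pioneer, c(TRUE, FALSE, FALSE))  # 2: Pfam; 3: two genera

  # a hit below the 1e-5 threshold also disqualifies
  ann2 <- ann
  ann2$best_db_hit_evalue[1] <- 1e-8
  pio2 <- find_pioneers(clusters, ann2, c("m1", "m3", "m5"),
                        ds, species, genus)
  expect_false(pio2$pioneer[1])

  expect_error(find_pioneers(clusters, ann, "m1", ds,
                             species_of = unname(species),
                             genus_of = genus), "named")
})
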