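# Generator determinism and manifest verifiability: every manifest claim
# must be recoverable by re-reading the generated files with the package's
# own parsers.

test_that("synth_config validates its invariants", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(admet_pass_fraction = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(ppi_core_size = 100, ppi_nodes = 100), "smaller")
  expect_error(synth_config(core_density = 0.01, periphery_density = 0.5),
               "core_density")
  expect_error(synth_config(planted_term_overlap = 30, query_size = 20),
               "overlap")
})

test_that("gen_compounds plants an exact ADMET pass count", {
  cfg <- synth_config(seed = 1, n_compounds = 20, admet_pass_fraction = 0.5)
  fx <- gen_compounds(cfg, tempfile("cmp"))
  tab <- parse_compound_table(fx$path)
  expect_equal(nrow(tab), 20L)
  kept <- admet_filter(tab)
  expect_equal(nrow(kept), 10L)
  expect_setequal(kept$name, fx$manifest$pass_names)

  all_pass <- gen_compounds(synth_config(seed = 2, n_compounds = 10,
                                         admet_pass_fraction = 1),
                            tempfile("cmp"))
  expect_equal(nrow(admet_filter(parse_compound_table(all_pass$path))), 10L)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 99)
  d1 <- tempfile("a"); d2 <- tempfile("b")
  f1 <- gen_all(cfg, d1)
  f2 <- gen_all(cfg, d2)
  for (rel in c("compounds.tsv", "target_map.tsv", "ppi_edges.tsv",
                "sets_pathway.gmt", "plate.tsv", "query.txt",
                "manifest.json", "source_01.txt"))
    expect_identical(readLines(file.path(d1, rel)),
                     readLines(file.path(d2, rel)),
                     label = rel)
  # a different seed perturbs the draws
  f3 <- gen_compounds(synth_config(seed = 100), tempfile("c"))
  expect_false(identical(readLines(f3$path),
                         readLines(file.path(d1, "compounds.tsv"))))
})

test_that("gen_target_universe manifest matches re-parsed lists", {
  cfg <- synth_config(seed = 8, overlap_gene_count = 25,
                      source_sizes = c(240L, 60L, 40L, 50L, 80L))
  fx <- gen_target_universe(cfg, tempfile("tgt"))
  sets <- lapply(fx$paths, load_gene_list, kind = "disease")
  expect_equal(vapply(sets, function(s) length(s$genes), integer(1)),
               unname(fx$manifest$source_sizes))
  u <- union_disease_targets(sets)
  expect_equal(length(u$genes), fx$manifest$union_size)
  expect_equal(u$genes, fx$manifest$union)
  # the designated core sits in every source
  inter_all <- Reduce(intersect, lapply(sets, `[[`, "genes"))
  expect_true(all(fx$manifest$core_genes %in% inter_all))
  expect_gte(length(inter_all), 25L)
  # pairwise intersections as recorded
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(length(intersect(sets[[i]]$genes, sets[[j]]$genes)),
                 fx$manifest$pairwise[i, j])

  single <- gen_target_universe(synth_config(seed = 8, n_sources = 1L,
                                             source_sizes = 50L),
                                tempfile("tgt1"))
  expect_equal(single$manifest$union_size, 50L)

  disj <- gen_target_universe(cfg, tempfile("tgtd"), disjoint = TRUE)
  expect_equal(disj$manifest$union_size, sum(cfg$source_sizes))
})

test_that("gen_ppi emits the recorded planted-core edge list", {
  cfg <- synth_config(seed = 15)
  fx <- gen_ppi(cfg, tempfile("ppi"))
  edges <- read_ppi_edges(fx$path)
  expect_equal(nrow(edges), fx$manifest$n_edges)
  expect_true(all(edges$score >= cfg$edge_score_range[1] &
                    edges$score <= cfg$edge_score_range[2]))
  g <- ppi_graph(edges, min_score = 0)
  expect_true(all(fx$manifest$core_nodes %in% g$nodes))
  expect_equal(length(fx$manifest$core_nodes), cfg$ppi_core_size)
  # the planted core is denser than the rest
  core_sub <- induced_subgraph(g, fx$manifest$core_nodes)
  core_possible <- choose(cfg$ppi_core_size, 2)
  expect_gt(graph_size(core_sub) / core_possible, 0.6)
})

test_that("gen_gene_sets plants a recoverable enriched term", {
  cfg <- synth_config(seed = 30)
  fx <- gen_gene_sets(cfg, tempfile("sets"))
  coll <- read_gmt(fx$gmt_paths[["pathway"]], category = "pathway")
  ids <- vapply(coll, `[[`, character(1), "term_id")
  expect_true("T_PLANTED" %in% ids)
  planted <- coll[[which(ids == "T_PLANTED")]]
  query <- load_gene_list(fx$query_path)
  expect_equal(length(intersect(planted$members, query$genes)),
               cfg$planted_term_overlap)
  res <- suppressMessages(run_ora(query, coll))
  expect_equal(res$term_id[1], "T_PLANTED")
  # zero planted overlap: the term cannot appear in the results
  none <- gen_gene_sets(synth_config(seed = 31, planted_term_overlap = 0L),
                        tempfile("sets0"))
  coll0 <- read_gmt(none$gmt_paths[["pathway"]], category = "pathway")
  res0 <- suppressMessages(run_ora(load_gene_list(none$query_path), coll0))
  expect_false("T_PLANTED" %in% res0$term_id)
})

test_that("gen_plate manifest parameters are recoverable from the file", {
  fx <- gen_plate(synth_config(seed = 44, od_noise_sd = 0),
                  tempfile("plate"))
  vb <- plate_viability(read_plate(fx$path))
  truth <- fourpl_curve(vb$dose, 0, 100, fx$manifest$hill_true,
                        fx$manifest$ic50_true)
  expect_equal(vb$viability_pct, truth, tolerance = 1e-6)
})
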