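# Gene-list loading, union/intersection set algebra, bipartite network.

test_that("load_gene_list normalizes, de-duplicates and round-trips", {
  f <- tempfile()
  writeLines(c("akt1", "AKT1", "EGFR", ""), f)
  ts <- load_gene_list(f, name = "demo", kind = "drug")
  expect_equal(ts$genes, c("AKT1", "EGFR"))
  expect_equal(attr(ts, "raw_n"), 3L)       # blank line ignored
  expect_equal(attr(ts, "unique_n"), 2L)

  writeLines(character(0), f)
  expect_equal(length(load_gene_list(f)$genes), 0L)

  f2 <- tempfile()
  five <- target_set(c("A", "B", "C", "D", "E"), "five")
  write_gene_list(five, f2)
  expect_equal(load_gene_list(f2)$genes, five$genes)
})

test_that("union_disease_targets merges with set semantics and guards kinds", {
  s1 <- target_set(c("A", "B"), "s1", "disease")
  s2 <- target_set(c("B", "C"), "s2", "disease")
  u <- union_disease_targets(list(s1, s2))
  expect_equal(u$genes, c("A", "B", "C"))
  expect_equal(as.vector(attr(u, "source_counts")), c(2L, 2L))
  expect_equal(union_disease_targets(list(s1))$genes, s1$genes)
  drug <- target_set("X", "d", "drug")
  expect_error(union_disease_targets(list(s1, drug)), "mixed kinds")
})

test_that("union of generated sets equals the brute-force union oracle", {
  set.seed(11)
  pool <- sprintf("G%03d", 1:60)
  sizes <- c(20, 5, 3, 4, 6)
  lists <- lapply(sizes, function(k) sample(pool, k))
  sets <- lapply(seq_along(lists), function(i)
    target_set(lists[[i]], sprintf("s%d", i), "disease"))
  u <- union_disease_targets(sets)
  expect_equal(u$genes, sort(Reduce(union, lists)))
  expect_lte(length(u$genes), sum(sizes))
})

test_that("intersect_drug_disease is the symmetric Venn intersection", {
  a <- target_set(c("A", "B", "C"), "a", "drug")
  b <- target_set(c("B", "C", "D"), "b", "disease")
  expect_equal(intersect_drug_disease(a, b)$genes, c("B", "C"))
  expect_equal(intersect_drug_disease(b, a)$genes,
               intersect_drug_disease(a, b)$genes)
  expect_equal(length(intersect_drug_disease(
    target_set("X", "x", "drug"), target_set("Y", "y", "disease"))$genes), 0L)
  # planted overlap of exactly k genes
  set.seed(5)
  core <- sprintf("C%02d", 1:7)
  drug <- target_set(c(core, sprintf("D%02d", 1:10)), "drug", "drug")
  dis <- target_set(c(core, sprintf("E%02d", 1:20)), "dis", "disease")
  expect_equal(intersect_drug_disease(drug, dis)$genes, core)
})

test_that("set algebra properties hold against naive oracles", {
  set.seed(21)
  pool <- sprintf("G%02d", 1:30)
  for (rep in 1:20) {
    x <- sample(pool, sample(0:15, 1))
    y <- sample(pool, sample(0:15, 1))
    z <- sample(pool, sample(0:15, 1))
    tx <- target_set(x, "x", "disease")
    ty <- target_set(y, "y", "disease")
    tz <- target_set(z, "z", "disease")
    # commutative + associative + idempotent union
    expect_equal(union_disease_targets(list(tx, ty))$genes,
                 union_disease_targets(list(ty, tx))$genes)
    expect_equal(
      union_disease_targets(list(
        union_disease_targets(list(tx, ty)), tz))$genes,
      union_disease_targets(list(tx,
        union_disease_targets(list(ty, tz))))$genes)
    expect_equal(union_disease_targets(list(tx, tx))$genes, tx$genes)
    # intersection distributes over union
    lhs <- intersect_drug_disease(tx, union_disease_targets(list(ty, tz)))
    rhs <- sort(union(intersect(tx$genes, ty$genes),
                      intersect(tx$genes, tz$genes)))
    expect_equal(lhs$genes, rhs)
  }
})

test_that("venn_counts partitions the union", {
  s1 <- target_set(c("A", "B", "C"), "s1", "disease")
  s2 <- target_set(c("B", "C", "D"), "s2", "disease")
  vc <- venn_counts(list(s1, s2))
  expect_equal(vc$count[vc$combination == "s1&s2"], 2L)
  expect_equal(vc$count[vc$combination == "total_union"], 4L)
  parts <- vc$count[vc$combination != "total_union"]
  expect_equal(sum(parts), 4L)
})

test_that("build_bipartite keeps exactly the common-target edges", {
  map <- list(cmp1 = c("T1", "X1"), cmp2 = c("T1", "X2"))
  keep <- target_set("T1", "common", "common")
  net <- build_bipartite(map, keep)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$targets, "T1")
  expect_equal(sort(net$compounds), c("cmp1", "cmp2"))

  empty <- build_bipartite(map, target_set("ZZ", "none", "common"))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(length(empty$compounds), 0L)
})

test_that("bipartite edges match the per-pair membership oracle", {
  set.seed(31)
  genes <- sprintf("G%02d", 1:30)
  map <- lapply(stats::setNames(1:5, sprintf("cmp%d", 1:5)),
                function(i) sample(genes, sample(3:12, 1)))
  keep <- sample(genes, 10)
  net <- build_bipartite(map, keep)
  # brute force: every (compound, gene) pair
  expected <- do.call(rbind, lapply(names(map), function(cn) {
    hits <- sort(intersect(map[[cn]], keep))
    if (length(hits)) data.frame(compound = cn, gene = hits,
                                 stringsAsFactors = FALSE)
  }))
  expect_equal(net$edges, expected, ignore_attr = TRUE)
  expect_true(all(net$edges$gene %in% keep))
  expect_true(all(net$edges$compound %in% names(map)))
})

test_that("read_target_map applies the score floor inclusively", {
  f <- tempfile()
  writeLines(c("cmp1\takt1\t0.95", "cmp1\tegfr\t0.80", "cmp1\tsrc\t0.79",
               "cmp2\tjun\t0.10"), f)
  map <- read_target_map(f, score_floor = 0.8)
  expect_equal(map$cmp1, c("AKT1", "EGFR"))  # 0.80 kept, 0.79 dropped
  expect_null(map$cmp2)
  # two-column maps pass through untouched
  f2 <- tempfile()
  writeLines(c("cmp1\ta", "cmp1\tb"), f2)
  expect_equal(read_target_map(f2)$cmp1, c("A", "B"))
})
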