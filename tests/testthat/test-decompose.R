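test_that("global regulators are the genes with kout strictly above kappa", {
  t1 <- toy_t1()
  expect_equal(identify_global_regulators(t1, 5), "R0")
  expect_equal(identify_global_regulators(t1, 6), character())
  expect_setequal(identify_global_regulators(t1, 0),
                  c("R0", "A1", "A2", "B1"))
})

test_that("the T1 fixture decomposes into the hand-traced partition", {
  dec <- nda_decompose(toy_t1(), "R0", kappa_used = 5)
  expect_equal(dec$global_regulators, t1_expected$globals)
  expect_setequal(
    vapply(dec$modules$genes, paste, "", collapse = ","),
    c(paste(t1_expected$module_a, collapse = ","),
      paste(t1_expected$module_b, collapse = ","))
  )
  cl <- setNames(dec$classes$class, dec$classes$gene)
  expect_true(all(cl[t1_expected$basal] == "basal"))
  expect_equal(unname(cl["X"]), "intermodular")
  expect_setequal(dec$intermodular$modules[[1]], c(1L, 2L))
})

test_that("empty and total global sets give the degenerate partitions", {
  t1 <- toy_t1()
  none <- nda_decompose(t1, character())
  expect_equal(nrow(none$modules), 1)
  expect_setequal(none$modules$genes[[1]], grn_genes(t1))
  expect_equal(sum(none$classes$class == "basal"), 0)

  all_regs <- nda_decompose(t1, c("R0", "A1", "A2", "B1"))
  expect_equal(nrow(all_regs$modules), 0)
  expect_true(all(all_regs$classes$class[!all_regs$classes$gene %in%
                                           c("R0", "A1", "A2", "B1")] ==
                    "basal"))
  expect_error(nda_decompose(t1, "NOPE"), "subset")
})

test_that("run_nda with an override matches the manual pipeline", {
  dec <- run_nda(toy_t1(), kappa_override = 5)
  expect_equal(dec$kappa_used, 5)
  expect_equal(dec$provenance$kappa_source, "override")
  expect_equal(dec$global_regulators, "R0")
  expect_equal(nrow(dec$modules), 2)
})

test_that("networks without structural genes have no intermodular genes", {
  cyc <- normalize_network(grn(tibble::tibble(
    regulator = c("A", "B", "C"), target = c("B", "C", "A"),
    effect = "activation"
  )))
  dec <- nda_decompose(cyc, character())
  expect_equal(nrow(dec$intermodular), 0)
  expect_equal(nrow(dec$modules), 1)
})

test_that("a regulator left disconnected by global removal is basal", {
  # P regulates only the hub; after hub removal it is a disconnected node
  g <- normalize_network(grn(tibble::tibble(
    regulator = c("G", "G", "G", "P"),
    target = c("a", "b", "c", "G"),
    effect = "activation"
  )))
  dec <- nda_decompose(g, "G")
  cl <- setNames(dec$classes$class, dec$classes$gene)
  expect_equal(unname(cl["P"]), "basal")
  expect_true(all(cl[c("a", "b", "c")] == "basal"))
})

test_that("a regulator of structural genes forms its own module", {
  g <- normalize_network(grn(tibble::tibble(
    regulator = c("G", "G", "P"), target = c("a", "P", "s"),
    effect = "activation"
  )))
  dec <- nda_decompose(g, "G")
  expect_equal(nrow(dec$modules), 1)
  expect_setequal(dec$modules$genes[[1]], c("P", "s"))
})

test_that("the four classes always partition the gene set", {
  for (s in 1:10) {
    g <- random_grn(s, n_genes = sample(8:30, 1), n_edges = sample(10:60, 1),
                    isolated = sample(0:2, 1))
    ko <- out_connectivity(g)
    kappa <- sample(0:max(ko$kout), 1)
    dec <- nda_decompose(g, identify_global_regulators(g, kappa))
    expect_equal(sort(dec$classes$gene), grn_genes(g))
    expect_equal(
      length(dec$global_regulators) +
        sum(lengths(dec$modules$genes)) +
        sum(dec$classes$class == "basal") +
        nrow(dec$intermodular),
      n_genes(g)
    )
    # intermodular genes are sinks regulated from >= 2 modules
    if (nrow(dec$intermodular)) {
      kvec <- setNames(ko$kout, ko$gene)
      expect_true(all(kvec[dec$intermodular$gene] == 0))
      expect_true(all(lengths(dec$intermodular$modules) >= 2))
    }
  }
})

test_that("module membership equals the exhaustive-reachability oracle", {
  for (s in 1:40) {
    g <- random_grn(100 + s, n_genes = sample(5:30, 1),
                    n_edges = sample(5:50, 1))
    ko <- out_connectivity(g)
    kappa <- withr::with_seed(s, sample(0:max(ko$kout), 1))
    globals <- identify_global_regulators(g, kappa)
    dec <- nda_decompose(g, globals)
    expect_same_partition(dec, oracle_decompose(g, globals))
  }
})

test_that("default planted networks are recovered exactly", {
  sim <- generate_grn(synth_spec(seed = 42))
  dec <- run_nda(sim$grn)
  tr <- sim$truth
  cl <- setNames(dec$classes$class,
                 dec$classes$gene)[tr$gene]
  want <- ifelse(tr$class == "global", "global", tr$class)
  expect_identical(unname(cl), want)
  # planted hubs dominate: kout of globals at least twice the local max
  ko <- out_connectivity(sim$grn)
  glob_k <- ko$kout[ko$gene %in% tr$gene[tr$class == "global"]]
  loc_k <- ko$kout[ko$gene %in% tr$gene[tr$class == "modular"]]
  expect_gte(min(glob_k), 2 * max(loc_k))
})

test_that("decomposition summaries are tidy", {
  dec <- run_nda(toy_t1(), kappa_override = 5)
  expect_equal(nrow(tidy(dec)), 11)
  gl <- glance(dec)
  expect_equal(gl$n_global, 1L)
  expect_equal(gl$n_modules, 2L)
  f <- withr::local_tempfile(fileext = ".json")
  write_decomposition_json(dec, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$kappa_used, 5)
  expect_length(j$modules, 2)
})

test_that("robustness scans are seeded, bounded, and ordered at zero", {
  sim <- generate_grn(synth_spec(seed = 7))
  r0 <- robustness_scan(sim$grn, "interactions", fractions = 0,
                        n_reps = 2, seed = 3)
  expect_true(all(r0$mean_jaccard == 1))
  r1 <- robustness_scan(sim$grn, "interactions", fractions = 0.2,
                        n_reps = 3, seed = 5)
  r2 <- robustness_scan(sim$grn, "interactions", fractions = 0.2,
                        n_reps = 3, seed = 5)
  expect_equal(r1$mean_jaccard, r2$mean_jaccard)
  expect_true(all(r1$mean_jaccard >= 0 & r1$mean_jaccard <= 1))
  expect_error(robustness_scan(sim$grn, fractions = 1), "fractions")
})

test_that("wiping one module's interactions spares the others", {
  sim <- generate_grn(synth_spec(seed = 9))
  g <- sim$grn
  tr <- sim$truth
  m1 <- tr$gene[!is.na(tr$module_id) & tr$module_id == 1]
  ia <- grn_interactions(g)
  g2 <- g
  g2$interactions <- ia[!(ia$regulator %in% m1 | ia$target %in% m1), ]
  ref <- run_nda(g, kappa_override = 9)
  dec <- run_nda(g2, kappa_override = 9)
  cl_ref <- setNames(ref$classes$class, ref$classes$gene)
  cl <- setNames(dec$classes$class, dec$classes$gene)
  # module-1 genes lose their modular status...
  expect_true(all(cl[intersect(m1, names(cl))] != "modular"))
  # ...while genes of the other modules keep their class, except
  # intermodular genes that lost one of their two module inputs
  others <- setdiff(names(cl_ref)[cl_ref == "modular"], m1)
  expect_identical(cl[others], cl_ref[others])
})
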