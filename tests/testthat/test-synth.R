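test_that("generation is byte-identical for identical specs", {
  a <- generate_grn(synth_spec(seed = 5))
  b <- generate_grn(synth_spec(seed = 5))
  fa <- withr::local_tempfile()
  fb <- withr::local_tempfile()
  write_network(a$grn, fa, "tsv3")
  write_network(b$grn, fb, "tsv3")
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$truth, b$truth)
  c_ <- generate_grn(synth_spec(seed = 6))
  expect_false(identical(grn_interactions(a$grn), grn_interactions(c_$grn)))
})

test_that("spec validation enforces the recipe invariants", {
  expect_error(synth_spec(module_recipes = list(
    list(type = "concilion", n_regulators = 1, n_structural = 3,
         inter_regulator_edges = 1))), ">= 2 regulators")
  expect_error(synth_spec(module_recipes = list(
    list(type = "simple_regulon", n_regulators = 2, n_structural = 3))),
    "exactly 1")
  expect_error(synth_spec(module_recipes = list(
    list(type = "simple_regulon", n_regulators = 1, n_structural = 3)),
    n_intermodular = 2), ">= 2 modules")
  expect_error(synth_spec(module_recipes = list(
    list(type = "frobulon", n_regulators = 1, n_structural = 3)),
    n_intermodular = 0), "unknown module type")
})

test_that("no intermodular recipe means no gene is wired from two modules", {
  sim <- generate_grn(synth_spec(seed = 3, n_intermodular = 0))
  tr <- sim$truth
  ia <- grn_interactions(sim$grn)
  mod_of <- setNames(tr$module_id, tr$gene)
  regs <- tr$gene[tr$class == "modular"]
  sinks <- out_connectivity(sim$grn)
  sinks <- sinks$gene[sinks$kout == 0]
  for (s in sinks) {
    mods <- unique(mod_of[intersect(ia$regulator[ia$target == s], regs)])
    expect_lte(length(mods[!is.na(mods)]), 1)
  }
})

test_that("planted structure is sink-dominated with hub-topped degrees", {
  sim <- generate_grn(synth_spec(seed = 7))
  ko <- out_connectivity(sim$grn)
  expect_gt(mean(ko$kout == 0), 0.5)
  hub <- ko$gene[which.max(ko$kout)]
  expect_true(hub %in% sim$truth$gene[sim$truth$class == "global"])
})

test_that("density decreases as module recipes are scaled up", {
  density_of <- function(sim) {
    n_interactions(sim$grn) / (n_genes(sim$grn) * (n_genes(sim$grn) - 1))
  }
  small <- generate_grn(synth_spec(seed = 2))
  rec <- rep(default_module_recipes(), 3)
  big <- generate_grn(synth_spec(seed = 2, module_recipes = rec,
                                 n_intermodular = 8,
                                 global_out_range = c(15, 200)))
  expect_lt(density_of(big), density_of(small))
})

test_that("complex-regulon recipes are wired faithfully but warn", {
  spec <- synth_spec(module_recipes = list(
    list(type = "complex_regulon", n_regulators = 2, n_structural = 3),
    list(type = "simple_regulon", n_regulators = 1, n_structural = 3)
  ), n_intermodular = 0, seed = 4)
  expect_warning(sim <- generate_grn(spec), "split this module")
  ia <- grn_interactions(sim$grn)
  rr <- ia[ia$regulator %in% c("M1R1", "M1R2") &
             ia$target %in% c("M1R1", "M1R2"), ]
  expect_equal(nrow(rr), 0)
  shared <- ia$target[ia$regulator == "M1R2"]
  expect_true(any(shared %in% ia$target[ia$regulator == "M1R1"]))
})

test_that("unsatisfiable degree separation is refused and can be waived", {
  weak <- synth_spec(n_basal = 0, global_coverage = 0.01, seed = 8,
                     global_out_range = c(0, 80))
  expect_error(generate_grn(weak), "separation violated")
  weak$separation <- "warn"
  expect_warning(generate_grn(weak), "separation violated")
})

test_that("degradation removes the exact fraction and is seed-stable", {
  ia <- tibble::tibble(
    regulator = rep(paste0("r", 1:10), each = 10),
    target = paste0("t", 1:100), effect = "activation"
  )
  g <- normalize_network(grn(ia))
  expect_equal(n_interactions(degrade_grn(g, "interactions", 0, seed = 1)),
               100)
  half <- degrade_grn(g, "interactions", 0.5, seed = 1)
  expect_equal(n_interactions(half), 50)
  again <- degrade_grn(g, "interactions", 0.5, seed = 1)
  expect_identical(grn_interactions(half), grn_interactions(again))
  other <- degrade_grn(g, "interactions", 0.5, seed = 2)
  expect_false(identical(grn_interactions(half), grn_interactions(other)))
  expect_error(degrade_grn(g, "interactions", 1, seed = 1), "fraction")
})

test_that("gene-mode degradation drops genes with their interactions", {
  sim <- generate_grn(synth_spec(seed = 11))
  d <- degrade_grn(sim$grn, "genes", 0.2, seed = 3, truth = sim$truth)
  gone <- setdiff(grn_genes(sim$grn), grn_genes(d))
  expect_gt(length(gone), 0)
  ia <- grn_interactions(d)
  expect_false(any(ia$regulator %in% gone | ia$target %in% gone))
  # with truth provided, planted globals are never removed
  expect_false(any(sim$truth$gene[sim$truth$class == "global"] %in% gone))
})

test_that("specs round-trip through YAML and JSON files", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_globals = 2, n_basal = 4, n_intermodular = 0,
                        seed = 12, global_coverage = 0.7,
                        module_recipes = list(
                          list(type = "simple_regulon", n_regulators = 1,
                               n_structural = 3))), fy)
  sp <- read_synth_spec(fy)
  expect_equal(sp$n_basal, 4)
  expect_equal(sp$seed, 12L)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 13, n_intermodular = 0,
                            module_recipes = list(
                              list(type = "simple_regulon", n_regulators = 1,
                                   n_structural = 3))),
                       fj, auto_unbox = TRUE)
  expect_equal(read_synth_spec(fj)$seed, 13L)
})

test_that("the T1 preset matches its documented wiring", {
  t1 <- toy_t1()
  expect_equal(n_genes(t1), 11)
  expect_equal(n_interactions(t1), 13)
  ia <- grn_interactions(t1)
  expect_setequal(ia$target[ia$regulator == "R0"],
                  c("A1", "A2", "B1", "B2", "H1", "H2"))
  expect_setequal(ia$target[ia$regulator == "A1"], c("A2", "A4", "X"))
  expect_setequal(ia$target[ia$regulator == "B1"], c("B2", "B3", "X"))
  expect_equal(ia$target[ia$regulator == "A2"], "A3")
})
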