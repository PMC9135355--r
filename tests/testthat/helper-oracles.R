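# Independent brute-force oracles used to cross-check the implementation.
# They deliberately avoid igraph and the package's own graph code.

# Local clustering coefficient by exhaustive triangle enumeration on the
# undirected simple projection (self-loops dropped).
oracle_clustering <- function(grn) {
  ia <- grn_interactions(grn)
  ia <- ia[ia$regulator != ia$target, , drop = FALSE]
  und <- unique(rbind(
    data.frame(a = ia$regulator, b = ia$target),
    data.frame(a = ia$target, b = ia$regulator)
  ))
  nb <- split(und$b, und$a)
  vapply(grn_genes(grn), function(g) {
    n <- unique(nb[[g]])
    d <- length(n)
    if (d < 2) return(0)
    tri <- 0
    for (i in 1:(d - 1)) {
      for (j in (i + 1):d) {
        if (n[j] %in% nb[[n[i]]]) tri <- tri + 1
      }
    }
    tri / (d * (d - 1) / 2)
  }, numeric(1))
}

# Connected components by exhaustive label propagation over an undirected
# edge list; returns an integer membership named by node.
oracle_components <- function(nodes, from, to) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_along(from)) {
      ca <- comp[[from[i]]]
      cb <- comp[[to[i]]]
      if (ca != cb) {
        comp[comp == cb] <- ca
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Full decomposition oracle: re-derives the four classes and module
# membership from first principles (no igraph, no shared code paths).
oracle_decompose <- function(grn, globals) {
  ia <- grn_interactions(grn)
  genes <- grn_genes(grn)
  kout <- table(factor(unique(ia[, c("regulator", "target")])$regulator,
                       levels = genes))
  remaining <- setdiff(genes, globals)
  red <- ia[!(ia$regulator %in% globals) & !(ia$target %in% globals), ]
  red_ns <- red[red$regulator != red$target, ]
  touched <- unique(c(red_ns$regulator, red_ns$target))
  basal <- setdiff(remaining, touched)
  structural <- remaining[kout[remaining] == 0]
  reg_active <- setdiff(setdiff(remaining, structural), basal)
  rr <- red[red$regulator %in% reg_active & red$target %in% reg_active, ]
  comp <- if (length(reg_active)) {
    oracle_components(reg_active, rr$regulator, rr$target)
  } else stats::setNames(integer(), character())
  class_of <- stats::setNames(rep("basal", length(genes)), genes)
  class_of[globals] <- "global"
  class_of[names(comp)] <- "modular"
  module_of <- comp
  for (s in setdiff(structural, basal)) {
    regs <- unique(red$regulator[red$target == s &
                                   red$regulator %in% reg_active])
    mods <- unique(comp[regs])
    if (length(mods) == 1) {
      class_of[s] <- "modular"
      module_of[s] <- mods
    } else if (length(mods) >= 2) {
      class_of[s] <- "intermodular"
    }
  }
  # module membership as a set of gene sets (ids are arbitrary)
  module_sets <- unname(split(names(module_of), module_of))
  list(class_of = class_of, module_sets = module_sets)
}

# Random normalized GRN over at most `n_genes` genes.
random_grn <- function(seed, n_genes = 20, n_edges = 30,
                       isolated = 0) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    ia <- tibble::tibble(
      regulator = sample(genes, n_edges, replace = TRUE),
      target = sample(genes, n_edges, replace = TRUE),
      effect = sample(c("activation", "repression", "dual", "unknown"),
                      n_edges, replace = TRUE)
    )
    iso <- if (isolated > 0) paste0("iso", seq_len(isolated)) else character()
    normalize_network(grn(ia, genes = iso,
                          name = paste0("random", seed)),
                      self_loops = "keep")
  })
}

# Compare two decompositions of the same network: identical class vectors
# and identical module partitions up to module relabeling.
expect_same_partition <- function(dec, oracle) {
  got <- stats::setNames(dec$classes$class, dec$classes$gene)
  expect_identical(got[names(oracle$class_of)], oracle$class_of)
  got_sets <- lapply(dec$modules$genes, sort)
  want_sets <- lapply(oracle$module_sets, sort)
  expect_setequal(
    vapply(got_sets, paste, "", collapse = "|"),
    vapply(want_sets, paste, "", collapse = "|")
  )
}

t1_expected <- list(
  globals = "R0",
  module_a = c("A1", "A2", "A3", "A4"),
  module_b = c("B1", "B2", "B3"),
  basal = c("H1", "H2"),
  intermodular = "X"
)
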