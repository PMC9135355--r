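#' Specification for a planted-structure synthetic network
#'
#' Describes a synthetic regulatory network mirroring the architecture the
#' decomposition is designed to recover: a few high-out-degree global
#' regulators, locally independent modules (concilions and regulons) with
#' no cross-module regulation, basal genes controlled only by globals,
#' intermodular sink genes wired from two or more modules, and a
#' sink-dominated degree distribution.
#'
#' @param n_globals Number of global regulator hubs.
#' @param global_out_range Acceptable range for each global's realized
#'   out-degree; a warning is raised when wiring falls outside it.
#' @param module_recipes List of recipes, each a list with `type`
#'   (`"concilion"`, `"simple_regulon"`, `"complex_regulon"`),
#'   `n_regulators`, `n_structural`, and for concilions
#'   `inter_regulator_edges` (at least `n_regulators - 1` edges are wired
#'   to keep the regulator cascade connected).
#' @param n_basal Number of basal machinery genes; every global regulates
#'   every basal gene (basal genes are controlled only by globals).
#' @param n_intermodular Number of intermodular sink genes, each wired
#'   from regulators of two distinct modules; requires at least two
#'   modules.
#' @param global_coverage Probability that a global regulates any given
#'   non-global, non-basal gene (on top of the mandatory basal edges).
#' @param effect_mix Sampling probabilities for interaction effects.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param separation `"enforce"` (error when the planted local out-degrees
#'   reach the global ones), `"warn"`, or `"ignore"`; well-separated
#'   degrees are what lets the kappa fit recover the planted globals.
#' @return A validated list of class `grnda_synth_spec`.
#' @export
synth_spec <- function(n_globals = 2,
                       global_out_range = c(15, 80),
                       module_recipes = default_module_recipes(),
                       n_basal = 10,
                       n_intermodular = 4,
                       global_coverage = 0.8,
                       effect_mix = c(activation = 0.6, repression = 0.35,
                                      dual = 0.05),
                       seed = 7,
                       separation = c("enforce", "warn", "ignore")) {
  separation <- match.arg(separation)
  stopifnot(n_globals >= 0, n_basal >= 0, n_intermodular >= 0,
            global_coverage >= 0, global_coverage <= 1,
            length(effect_mix) >= 1, all(effect_mix >= 0))
  for (i in seq_along(module_recipes)) {
    r <- module_recipes[[i]]
    if (!r$type %in% c("concilion", "simple_regulon", "complex_regulon")) {
      abort(paste0("recipe ", i, ": unknown module type '", r$type, "'"))
    }
    if (r$type == "concilion" &&
        (r$n_regulators < 2 || (r$inter_regulator_edges %||% 0) < 1)) {
      abort(paste0("recipe ", i, ": a concilion needs >= 2 regulators and ",
                   ">= 1 inter-regulator edge"))
    }
    if (r$type == "simple_regulon" && r$n_regulators != 1) {
      abort(paste0("recipe ", i, ": a simple regulon has exactly 1 regulator"))
    }
    if (r$type == "complex_regulon" && r$n_regulators < 2) {
      abort(paste0("recipe ", i, ": a complex regulon needs >= 2 regulators"))
    }
    if (r$n_structural < 1) {
      abort(paste0("recipe ", i, ": modules need >= 1 structural gene"))
    }
  }
  if (n_intermodular > 0 && length(module_recipes) < 2) {
    abort("intermodular genes require >= 2 modules")
  }
  structure(
    list(n_globals = n_globals, global_out_range = global_out_range,
         module_recipes = module_recipes, n_basal = n_basal,
         n_intermodular = n_intermodular, global_coverage = global_coverage,
         effect_mix = effect_mix / sum(effect_mix), seed = as.integer(seed),
         separation = separation),
    class = "grnda_synth_spec"
  )
}

#' @rdname synth_spec
#' @export
default_module_recipes <- function() {
  list(
    list(type = "concilion", n_regulators = 4, n_structural = 8,
         inter_regulator_edges = 5),
    list(type = "concilion", n_regulators = 3, n_structural = 6,
         inter_regulator_edges = 3),
    list(type = "simple_regulon", n_regulators = 1, n_structural = 4),
    list(type = "simple_regulon", n_regulators = 1, n_structural = 4),
    list(type = "simple_regulon", n_regulators = 1, n_structural = 5),
    list(type = "simple_regulon", n_regulators = 1, n_structural = 5)
  )
}

#' Read a synthetic-network spec from a YAML or JSON file
#'
#' @param path File with fields matching the [synth_spec()] arguments.
#' @return A `grnda_synth_spec`.
#' @export
read_synth_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(synth_spec)))]
  if (!is.null(args$effect_mix)) args$effect_mix <- unlist(args$effect_mix)
  if (!is.null(args$global_out_range)) {
    args$global_out_range <- unlist(args$global_out_range)
  }
  do.call(synth_spec, args)
}

sample_effects <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic network with planted ground truth
#'
#' Wires the network described by a [synth_spec()] and returns it together
#' with the planted labels. Within a concilion the regulators form a
#' cascade (plus extra inter-regulator edges up to the recipe count), and
#' each inter-regulator edge is doubled into a feed-forward loop over the
#' downstream regulator's first targets so that local regulators carry
#' triangles — the clustering signal the power-law fit needs. Globals form
#' a cascade, regulate every basal gene, and pick up each remaining
#' non-global gene with probability `global_coverage`. Complex-regulon
#' recipes are wired faithfully (shared structural targets, no
#' inter-regulator edges) but a warning notes that the decomposition
#' procedure will split such a module into per-regulator regulons with the
#' shared targets classed intermodular.
#'
#' @param spec A `grnda_synth_spec`.
#' @return A list with `grn` (normalized [grn]), `truth` (tibble `gene`,
#'   `class`, `module_id`), and `module_types` (tibble `module_id`,
#'   `type`).
#' @export
generate_grn <- function(spec) {
  stopifnot(inherits(spec, "grnda_synth_spec"))
  withr::with_seed(spec$seed, generate_grn_impl(spec))
}

generate_grn_impl <- function(spec) {
  edges <- list()
  add <- function(from, to) {
    edges[[length(edges) + 1]] <<- tibble::tibble(regulator = from,
                                                  target = to)
  }
  globals <- if (spec$n_globals > 0) paste0("G", seq_len(spec$n_globals))
             else character()
  basal <- if (spec$n_basal > 0) paste0("B", seq_len(spec$n_basal))
           else character()
  truth <- list()
  module_types <- list()
  local_regs_by_module <- list()

  for (m in seq_along(spec$module_recipes)) {
    r <- spec$module_recipes[[m]]
    regs <- paste0("M", m, "R", seq_len(r$n_regulators))
    stru <- paste0("M", m, "S", seq_len(r$n_structural))
    local_regs_by_module[[m]] <- regs
    primary <- regs[((seq_along(stru) - 1) %% length(regs)) + 1]
    add(primary, stru)
    if (r$type == "concilion") {
      casc_from <- regs[-length(regs)]
      casc_to <- regs[-1]
      add(casc_from, casc_to)
      rr_pairs <- tibble::tibble(from = casc_from, to = casc_to)
      extra_needed <- max(0, (r$inter_regulator_edges %||% 1) -
                            nrow(rr_pairs))
      if (extra_needed > 0) {
        cand <- expand.grid(from = regs, to = regs,
                            stringsAsFactors = FALSE)
        cand <- cand[cand$from != cand$to, ]
        cand <- dplyr::anti_join(tibble::as_tibble(cand), rr_pairs,
                                 by = c("from", "to"))
        # deterministic order: skip-ahead pairs first (r1->r3, ...)
        if (nrow(cand)) {
          picked <- head(cand, extra_needed)
          add(picked$from, picked$to)
          rr_pairs <- dplyr::bind_rows(rr_pairs, picked)
        }
      }
      # double every inter-regulator edge into a feed-forward loop over
      # the downstream regulator's first structural target (plants the
      # triangles that give local regulators their clustering signal)
      for (i in seq_len(nrow(rr_pairs))) {
        downstream_targets <- stru[primary == rr_pairs$to[i]]
        ff <- head(downstream_targets, 1)
        if (length(ff)) add(rr_pairs$from[i], ff)
      }
    } else if (r$type == "complex_regulon") {
      shared <- stru[1]
      add(setdiff(regs, primary[1]), shared)
      warn(paste0(
        "recipe ", m, " (complex_regulon): regulators share targets but do ",
        "not interact, so the NDA decomposition will split this module ",
        "into per-regulator regulons and class the shared targets ",
        "intermodular"
      ))
    }
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene = c(regs, stru), class = "modular", module_id = m
    )
    module_types[[m]] <- tibble::tibble(module_id = m, type = r$type)
  }

  n_mod <- length(spec$module_recipes)
  inter <- if (spec$n_intermodular > 0) {
    paste0("X", seq_len(spec$n_intermodular))
  } else character()
  for (i in seq_along(inter)) {
    m1 <- ((i - 1) %% n_mod) + 1
    m2 <- (i %% n_mod) + 1
    # wire from the last (least-loaded) regulator of each module
    r1 <- local_regs_by_module[[m1]]
    r2 <- local_regs_by_module[[m2]]
    add(r1[length(r1)], inter[i])
    add(r2[length(r2)], inter[i])
  }
  if (length(inter)) {
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene = inter, class = "intermodular", module_id = NA_integer_
    )
  }

  if (length(basal)) {
    for (g in globals) add(g, basal)
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene = basal, class = "basal", module_id = NA_integer_
    )
  }
  if (length(globals) >= 2) {
    add(globals[-length(globals)], globals[-1])
  }
  coverage_pool <- c(unlist(local_regs_by_module),
                     unlist(lapply(seq_len(n_mod), function(m)
                       paste0("M", m, "S",
                              seq_len(spec$module_recipes[[m]]$n_structural)))),
                     inter)
  for (g in globals) {
    hit <- coverage_pool[runif(length(coverage_pool)) < spec$global_coverage]
    if (length(hit)) add(g, hit)
  }
  if (length(globals)) {
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene = globals, class = "global", module_id = NA_integer_
    )
  }

  ia <- dplyr::distinct(dplyr::bind_rows(edges))
  ia$effect <- sample_effects(nrow(ia), spec$effect_mix)
  ia$weight <- NA_real_
  g <- grn(ia, name = paste0("synthetic_seed", spec$seed),
           metadata = list(generator = "grnda::generate_grn",
                           seed = spec$seed))
  g <- normalize_network(g, self_loops = "keep")

  # separation guarantee: planted local out-degrees must stay below the
  # global ones or the kappa threshold cannot split the two groups
  kout <- out_connectivity(g)
  local_regs <- unlist(local_regs_by_module)
  if (length(globals) && length(local_regs)) {
    max_local <- max(kout$kout[kout$gene %in% local_regs])
    min_global <- min(kout$kout[kout$gene %in% globals])
    if (max_local >= min_global) {
      msg <- paste0("degree separation violated: max local out-degree ",
                    max_local, " >= min global out-degree ", min_global)
      if (spec$separation == "enforce") {
        abort(paste0(msg, "; reduce module sizes or raise global_coverage, ",
                     "or set separation = 'warn'"))
      }
      if (spec$separation == "warn") warn(msg)
    }
    rng <- spec$global_out_range
    g_kout <- kout$kout[kout$gene %in% globals]
    if (any(g_kout < rng[1] | g_kout > rng[2])) {
      warn(paste0("global out-degrees [", paste(range(g_kout),
                  collapse = ", "), "] fall outside global_out_range"))
    }
  }

  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$gene)
  list(grn = g, truth = truth,
       module_types = dplyr::bind_rows(module_types))
}

#' Degrade a network to emulate incompleteness
#'
#' Removes a fraction of interactions (rounded to the nearest count), or a
#' fraction of genes together with their incident interactions, uniformly
#' at random and deterministically for a fixed seed. When planted truth is
#' supplied, gene-mode removal spares the global regulators (emulating
#' that hubs are the best-known part of a reconstruction); any removed
#' gene is also dropped from the gene set.
#'
#' @param grn A [grn].
#' @param mode `"interactions"` or `"genes"`.
#' @param fraction Fraction to remove, in `[0, 1)`.
#' @param seed Integer seed.
#' @param truth Optional ground-truth tibble from [generate_grn()].
#' @return The degraded [grn]; the truth tibble is never modified.
#' @export
degrade_grn <- function(grn, mode = c("interactions", "genes"),
                        fraction, seed, truth = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    abort("fraction must be in [0, 1)")
  }
  withr::with_seed(as.integer(seed), {
    out <- grn
    if (mode == "interactions") {
      m <- nrow(grn$interactions)
      k <- round(fraction * m)
      if (k > 0) {
        drop <- sample.int(m, k)
        out$interactions <- grn$interactions[-drop, ]
      }
    } else {
      pool <- unique(c(grn$interactions$regulator, grn$interactions$target))
      if (!is.null(truth)) {
        pool <- setdiff(pool, truth$gene[truth$class == "global"])
      }
      k <- round(fraction * length(pool))
      if (k > 0) {
        gone <- sample(pool, k)
        ia <- grn$interactions
        out$interactions <- ia[!(ia$regulator %in% gone) &
                                 !(ia$target %in% gone), ]
        out$genes <- setdiff(grn$genes, gone)
      }
    }
    out$metadata$degraded <- list(mode = mode, fraction = fraction,
                                  seed = as.integer(seed))
    out
  })
}

#' The T1 toy network fixture
#'
#' An 11-gene worked example: hub `R0` regulates six genes; local
#' regulators `A1`, `A2` form a cascade over module A (`A1`->`A2`->`A3`,
#' `A1`->`A4`), `B1` drives module B (`B2`, `B3`); `H1`, `H2` are
#' regulated only by the hub; and the sink `X` is wired from both `A1`
#' and `B1`. Decomposing with `kappa = 5` yields globals `{R0}`, modules
#' `{A1, A2, A3, A4}` (a concilion: `A1`->`A2`) and `{B1, B2, B3}` (a
#' simple regulon), basal `{H1, H2}`, and intermodular `{X}`.
#'
#' @return A normalized [grn] named `"T1"`.
#' @export
toy_t1 <- function() {
  ia <- tibble::tribble(
    ~regulator, ~target,
    "R0", "A1", "R0", "A2", "R0", "B1", "R0", "B2", "R0", "H1", "R0", "H2",
    "A1", "A2", "A1", "A4", "A1", "X",
    "A2", "A3",
    "B1", "B2", "B1", "B3", "B1", "X"
  )
  ia$effect <- "activation"
  normalize_network(grn(ia, name = "T1"), self_loops = "keep")
}

#' Write planted ground truth as TSV
#'
#' @param truth Truth tibble from [generate_grn()].
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}
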