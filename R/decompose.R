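#' Identify global regulators by the kappa threshold
#'
#' Global regulators are the genes whose out-connectivity strictly exceeds
#' the kappa value; a gene sitting exactly at kappa is not global.
#'
#' @param grn A normalized [grn].
#' @param kappa Non-negative threshold, usually [kappa_value()] of the
#'   fitted clustering power law.
#' @return Sorted character vector of global regulator genes.
#' @export
identify_global_regulators <- function(grn, kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa >= 0)
  kout <- out_connectivity(grn)
  sort(kout$gene[kout$kout > kappa])
}

#' Decompose a network into its system-level elements
#'
#' Implements the controlled decomposition at the heart of the natural
#' decomposition approach. Given the set of global regulators:
#'
#' 1. Globals and all their incident interactions are removed.
#' 2. Among the survivors, the structural genes (out-connectivity 0 in the
#'    full network) are set aside, and the *proto-modules* are the weakly
#'    connected components of the subgraph induced on the remaining local
#'    regulators. A local regulator left with edges only to structural
#'    genes forms a singleton proto-module; a survivor left with no
#'    remaining edges at all (a disconnected node) belongs to the basal
#'    machinery.
#' 3. Each structural gene is assigned by its surviving regulators: all in
#'    one proto-module makes it modular (member of that module); in two or
#'    more proto-modules makes it intermodular; none makes it basal.
#'
#' Structural genes are removed before taking components so that
#' intermodular genes cannot spuriously glue modules together — modules
#' stay locally independent (no cross-module regulation), which
#' [check_local_independence()] verifies.
#'
#' @param grn A normalized [grn].
#' @param globals Character vector of global regulator genes (subset of
#'   the gene set), e.g. from [identify_global_regulators()].
#' @param kappa_used Optional kappa recorded in the result for provenance.
#' @param provenance Optional list (fit report or override note).
#' @return An object of class `grnda_decomposition`: a list with
#'   `classes` (tibble `gene`, `class`, `module_id`), `modules` (tibble
#'   `module_id`, `genes`, `regulators`, `structural` list-columns),
#'   `intermodular` (tibble `gene`, `modules` list-column of regulating
#'   module ids), `global_regulators`, `kappa_used`, `provenance`, and the
#'   input `grn`.
#' @export
nda_decompose <- function(grn, globals, kappa_used = NA_real_,
                          provenance = list()) {
  if (!all(globals %in% grn$genes)) {
    abort(paste0("globals not a subset of network genes: ",
                 paste(setdiff(globals, grn$genes), collapse = ", ")))
  }
  globals <- sort(unique(globals))
  kout <- out_connectivity(grn)
  kout_of <- setNames(kout$kout, kout$gene)
  remaining <- setdiff(grn$genes, globals)
  structural <- remaining[kout_of[remaining] == 0]
  regulators <- setdiff(remaining, structural)

  ia <- grn$interactions
  reduced <- ia[!(ia$regulator %in% globals) & !(ia$target %in% globals), ]

  # survivors with no remaining edge at all (self-loops aside) are the
  # disconnected nodes left by global removal: basal machinery
  touched <- unique(c(
    reduced$regulator[reduced$regulator != reduced$target],
    reduced$target[reduced$regulator != reduced$target]
  ))
  basal <- setdiff(remaining, touched)
  reg_active <- setdiff(regulators, basal)

  # proto-modules: weak components of the local-regulator subgraph
  module_of <- integer(0)
  if (length(reg_active)) {
    rr <- reduced[reduced$regulator %in% reg_active &
                    reduced$target %in% reg_active, ]
    sub <- igraph::graph_from_data_frame(
      rr[, c("regulator", "target")], directed = TRUE,
      vertices = data.frame(name = reg_active)
    )
    comp <- igraph::components(sub, mode = "weak")
    module_of <- setNames(as.integer(comp$membership),
                          igraph::V(sub)$name)
  }

  # assign structural genes by the proto-modules of their surviving
  # regulators
  struct_active <- setdiff(structural, basal)
  inter <- list()
  assigned <- setNames(rep(NA_integer_, length(struct_active)), struct_active)
  if (length(struct_active)) {
    in_edges <- reduced[reduced$target %in% struct_active &
                          reduced$regulator %in% reg_active, ]
    regs_by_gene <- split(in_edges$regulator, in_edges$target)
    for (g in names(regs_by_gene)) {
      mods <- sort(unique(module_of[regs_by_gene[[g]]]))
      if (length(mods) == 1) {
        assigned[g] <- mods
      } else if (length(mods) >= 2) {
        inter[[g]] <- mods
      }
    }
  }
  basal <- c(basal, names(assigned)[is.na(assigned)])
  assigned <- assigned[!is.na(assigned)]

  mod_ids <- sort(unique(c(unname(module_of), unname(assigned))))
  if (length(mod_ids) == 0) {
    modules <- tibble::tibble(module_id = integer(), genes = list(),
                              regulators = list(), structural = list())
  } else modules <- purrr::map_dfr(mod_ids, function(id) {
    regs <- sort(names(module_of)[module_of == id])
    stru <- sort(names(assigned)[assigned == id])
    tibble::tibble(
      module_id = id,
      genes = list(c(regs, stru)),
      regulators = list(regs),
      structural = list(stru)
    )
  })
  # renumber modules 1..n in order of appearance for stable output
  if (nrow(modules)) {
    remap <- setNames(seq_len(nrow(modules)), modules$module_id)
    modules$module_id <- unname(remap[as.character(modules$module_id)])
    module_of[] <- remap[as.character(module_of)]
    assigned[] <- remap[as.character(assigned)]
    inter <- lapply(inter, function(m) unname(remap[as.character(m)]))
  }

  mod_lookup <- c(module_of, assigned)
  classes <- tibble::tibble(gene = grn$genes) |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$gene %in% globals ~ "global",
        .data$gene %in% names(inter) ~ "intermodular",
        .data$gene %in% names(mod_lookup) ~ "modular",
        TRUE ~ "basal"
      ),
      module_id = unname(mod_lookup[match(.data$gene, names(mod_lookup))])
    )
  classes$module_id[classes$class != "modular"] <- NA_integer_

  intermodular <- tibble::tibble(
    gene = names(inter),
    modules = unname(inter)
  )

  structure(
    list(
      classes = classes,
      modules = modules,
      intermodular = intermodular,
      global_regulators = globals,
      kappa_used = kappa_used,
      provenance = provenance,
      grn = grn
    ),
    class = "grnda_decomposition"
  )
}

#' Run the full natural decomposition pipeline
#'
#' Composes [out_connectivity()], [clustering_curve()], [fit_power_law()],
#' [kappa_value()], [identify_global_regulators()] and [nda_decompose()].
#' For tiny or toy networks whose clustering curve cannot support a fit,
#' `kappa_override` bypasses the fitting step.
#'
#' @param grn A [grn]; normalized automatically if it is not yet.
#' @param kappa_override Optional kappa to use instead of fitting.
#' @param method Robust fit method, see [fit_power_law()].
#' @param self_loops Normalization policy, see [normalize_network()].
#' @return A `grnda_decomposition` (see [nda_decompose()]) whose
#'   `provenance` holds the fit report or the override.
#' @export
run_nda <- function(grn, kappa_override = NULL,
                    method = c("irls_bisquare", "theil_sen"),
                    self_loops = c("keep", "drop")) {
  method <- match.arg(method)
  self_loops <- match.arg(self_loops)
  if (!isTRUE(grn$metadata$normalized)) {
    grn <- normalize_network(grn, self_loops = self_loops)
  }
  if (is.null(kappa_override)) {
    curve <- clustering_curve(grn)
    fit <- tryCatch(
      fit_power_law(curve, method = method),
      error = function(e) {
        abort(paste0(conditionMessage(e),
                     "; consider kappa_override for small networks"))
      }
    )
    if (!is.finite(fit$kappa)) {
      abort(paste0("fit does not decay (alpha <= 0); kappa undefined; ",
                   "consider kappa_override"))
    }
    kappa <- fit$kappa
    prov <- list(kappa_source = "fit", fit = glance(fit))
  } else {
    stopifnot(is.numeric(kappa_override), kappa_override >= 0)
    kappa <- kappa_override
    prov <- list(kappa_source = "override", kappa_override = kappa_override)
  }
  globals <- identify_global_regulators(grn, kappa)
  nda_decompose(grn, globals, kappa_used = kappa, provenance = prov)
}

#' @export
print.grnda_decomposition <- function(x, ...) {
  tab <- table(x$classes$class)
  cat("<grnda_decomposition> of ", x$grn$name, "\n", sep = "")
  cat(sprintf("  kappa used: %.4g\n", x$kappa_used))
  cat("  global regulators: ", length(x$global_regulators),
      "  modules: ", nrow(x$modules), "\n", sep = "")
  cat("  classes: ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.grnda_decomposition <- function(x, ...) x$classes

#' @export
glance.grnda_decomposition <- function(x, ...) {
  tab <- table(factor(x$classes$class,
                      levels = c("global", "modular", "basal",
                                 "intermodular")))
  tibble::tibble(
    n_genes = nrow(x$classes),
    n_interactions = nrow(x$grn$interactions),
    n_global = unname(tab["global"]),
    n_modular = unname(tab["modular"]),
    n_basal = unname(tab["basal"]),
    n_intermodular = unname(tab["intermodular"]),
    n_modules = nrow(x$modules),
    kappa_used = x$kappa_used
  )
}

#' @export
autoplot.grnda_decomposition <- function(object, ...) {
  df <- dplyr::count(object$classes, .data$class)
  df$class <- factor(df$class,
                     levels = c("global", "modular", "basal", "intermodular"))
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$n, fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "NDA gene classes") +
    ggplot2::theme_minimal()
}

#' Export a decomposition
#'
#' Writes the per-gene class table as TSV (`gene`, `class`, `module_id`)
#' or the full object (classes, modules, intermodular wiring, kappa,
#' provenance) as JSON.
#'
#' @param decomposition A `grnda_decomposition`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_decomposition_tsv <- function(decomposition, path) {
  readr::write_tsv(decomposition$classes, path)
  invisible(path)
}

#' @rdname write_decomposition_tsv
#' @export
write_decomposition_json <- function(decomposition, path) {
  x <- decomposition
  jsonlite::write_json(
    list(
      network = x$grn$name,
      kappa_used = x$kappa_used,
      provenance = x$provenance,
      global_regulators = x$global_regulators,
      classes = x$classes,
      modules = lapply(seq_len(nrow(x$modules)), function(i) list(
        module_id = x$modules$module_id[i],
        regulators = x$modules$regulators[[i]],
        structural = x$modules$structural[[i]]
      )),
      intermodular = lapply(seq_len(nrow(x$intermodular)), function(i) list(
        gene = x$intermodular$gene[i],
        modules = x$intermodular$modules[[i]]
      ))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
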