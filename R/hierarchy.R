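#' Assemble the three-tier diamond functional architecture
#'
#' Maps each NDA gene class onto its hierarchy layer: global regulators
#' form the *coordination* layer, modular plus basal machinery genes the
#' *processing* layer, and intermodular genes the *integration* layer.
#' Layer fractions are percentages of all genes in the network and sum to
#' 100. Feedback interactions (a processing-layer regulator targeting a
#' coordination-layer gene) are enumerated but never removed — occasional
#' feedback between layers is part of the architecture. Cross-module
#' interactions (violations of local independence, expected empty for any
#' [nda_decompose()] output) are also reported.
#'
#' @param decomposition A `grnda_decomposition`.
#' @return An object of class `grnda_hierarchy`: list with `layers`
#'   (tibble `gene`, `class`, `layer`), `fractions` (tibble `layer`,
#'   `n_genes`, `pct`), `feedback_edges`, `cross_module_edges`.
#' @export
layer_assignment <- function(decomposition) {
  layer_map <- c(global = "coordination", modular = "processing",
                 basal = "processing", intermodular = "integration")
  layers <- decomposition$classes |>
    dplyr::mutate(layer = unname(layer_map[.data$class]))
  fractions <- tibble::tibble(
    layer = c("coordination", "processing", "integration")
  ) |>
    dplyr::left_join(dplyr::count(layers, .data$layer, name = "n_genes"),
                     by = "layer") |>
    dplyr::mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      pct = 100 * .data$n_genes / nrow(layers)
    )
  ia <- decomposition$grn$interactions
  globals <- decomposition$global_regulators
  processing <- layers$gene[layers$layer == "processing"]
  feedback <- ia[ia$regulator %in% processing & ia$target %in% globals, ]
  structure(
    list(
      layers = layers,
      fractions = fractions,
      feedback_edges = feedback,
      cross_module_edges = check_local_independence(decomposition)
    ),
    class = "grnda_hierarchy"
  )
}

#' @export
print.grnda_hierarchy <- function(x, ...) {
  cat("<grnda_hierarchy> diamond architecture\n")
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("  %-13s %4d genes  %6.2f%%\n", x$fractions$layer[i],
                x$fractions$n_genes[i], x$fractions$pct[i]))
  }
  cat("  feedback edges: ", nrow(x$feedback_edges),
      "   cross-module violations: ", nrow(x$cross_module_edges), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.grnda_hierarchy <- function(x, ...) x$layers

#' @export
glance.grnda_hierarchy <- function(x, ...) {
  f <- setNames(x$fractions$pct, x$fractions$layer)
  tibble::tibble(
    coordination_pct = f[["coordination"]],
    processing_pct = f[["processing"]],
    integration_pct = f[["integration"]],
    n_feedback_edges = nrow(x$feedback_edges),
    n_cross_module_edges = nrow(x$cross_module_edges)
  )
}

#' Check local independence of modules
#'
#' Returns every interaction whose regulator is a modular gene of one
#' module and whose target is a modular gene of a different module. By
#' construction of [nda_decompose()] this list is empty; a non-empty
#' result flags a corrupted or hand-edited decomposition.
#'
#' @param decomposition A `grnda_decomposition`.
#' @param grn Optional network to scan; defaults to the one stored in the
#'   decomposition.
#' @return Tibble of violating interactions with `module_regulator` and
#'   `module_target` columns.
#' @export
check_local_independence <- function(decomposition, grn = NULL) {
  grn <- grn %||% decomposition$grn
  cl <- decomposition$classes
  mod_of <- setNames(cl$module_id, cl$gene)
  ia <- grn$interactions
  m_reg <- unname(mod_of[ia$regulator])
  m_tgt <- unname(mod_of[ia$target])
  bad <- !is.na(m_reg) & !is.na(m_tgt) & m_reg != m_tgt
  out <- ia[bad, ]
  out$module_regulator <- m_reg[bad]
  out$module_target <- m_tgt[bad]
  tibble::as_tibble(out)
}

#' Summarize decompositions across networks
#'
#' Builds the per-network summary table (genes, interactions, global
#' regulators, modules, concilions, layer fractions, concilion fraction)
#' and its unweighted means, the convention used for multi-organism
#' statistics. Because networks differ in module counts, the mean of
#' per-network concilion fractions and the pooled fraction (all concilions
#' over all modules) can differ; both are reported.
#'
#' @param results A named list of `grnda_decomposition` objects, or a list
#'   of lists with fields `name` and `decomposition`.
#' @return A tibble of class `grnda_atlas`, one row per network, with a
#'   `means` attribute (one-row tibble of unweighted means plus the pooled
#'   concilion fraction).
#' @export
summarize_atlas <- function(results) {
  if (length(results) == 0) abort("no results to summarize")
  rows <- purrr::imap_dfr(results, function(res, nm) {
    dec <- if (inherits(res, "grnda_decomposition")) res else res$decomposition
    name <- if (inherits(res, "grnda_decomposition")) {
      if (is.character(nm) && nzchar(nm)) nm else dec$grn$name
    } else {
      res$name %||% nm
    }
    cf <- concilion_fraction(dec)
    hier <- glance(layer_assignment(dec))
    dplyr::bind_cols(
      tibble::tibble(network = as.character(name)),
      glance(dec)[, c("n_genes", "n_interactions", "n_global", "n_modules")],
      cf[, c("n_concilion", "concilion_fraction")],
      hier[, c("coordination_pct", "processing_pct", "integration_pct")]
    )
  })
  num <- names(rows)[vapply(rows, is.numeric, logical(1))]
  means <- dplyr::summarise(
    rows, dplyr::across(dplyr::all_of(num), mean)
  )
  means$pooled_concilion_fraction <-
    sum(rows$n_concilion) / sum(rows$n_modules)
  out <- rows
  class(out) <- c("grnda_atlas", class(out))
  attr(out, "means") <- means
  out
}

#' @rdname summarize_atlas
#' @param atlas A `grnda_atlas` table.
#' @export
atlas_means <- function(atlas) attr(atlas, "means")

#' Diamond architecture diagram
#'
#' Draws the three-tier diamond with per-layer percentages: a narrow
#' coordination apex, a wide processing waist, and a narrow integration
#' base.
#'
#' @param hierarchy A `grnda_hierarchy`.
#' @return A ggplot object.
#' @export
plot_diamond <- function(hierarchy) {
  f <- hierarchy$fractions
  f$y <- c(2, 1, 0)[match(f$layer, c("coordination", "processing",
                                     "integration"))]
  f$width <- pmax(sqrt(f$pct / 100), 0.04)
  f$label <- sprintf("%s\n%.1f%%", f$layer, f$pct)
  ggplot2::ggplot(f) +
    ggplot2::geom_tile(
      ggplot2::aes(x = 0, y = .data$y, width = .data$width, height = 0.8,
                   fill = .data$layer),
      show.legend = FALSE
    ) +
    ggplot2::geom_text(ggplot2::aes(x = 0, y = .data$y, label = .data$label),
                       size = 3.2) +
    ggplot2::xlim(-0.6, 0.6) +
    ggplot2::theme_void()
}

#' @export
autoplot.grnda_hierarchy <- function(object, ...) plot_diamond(object)

#' @rdname summarize_atlas
#' @param path Output file for [write_atlas_tsv()] /
#'   [write_atlas_json()].
#' @export
write_atlas_tsv <- function(atlas, path) {
  readr::write_tsv(tibble::as_tibble(atlas), path)
  invisible(path)
}

#' @rdname summarize_atlas
#' @export
write_atlas_json <- function(atlas, path) {
  jsonlite::write_json(
    list(networks = tibble::as_tibble(atlas), means = atlas_means(atlas)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
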