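#' Construct a gene regulatory network object
#'
#' A `grn` bundles a tibble of signed directed interactions with the full
#' gene set (which may include isolated genes declared without any
#' interaction), a free-text name, and a metadata list recording
#' provenance and normalization history.
#'
#' @param interactions A data frame with columns `regulator`, `target`,
#'   `effect` (one of `"activation"`, `"repression"`, `"dual"`,
#'   `"unknown"`) and optionally `weight` (non-negative numeric,
#'   `NA` when absent).
#' @param genes Character vector of gene identifiers. Endpoints of
#'   `interactions` are always added; extra entries declare isolated genes.
#' @param name Free-text label for the network.
#' @param metadata Named list of provenance entries.
#'
#' @return An object of class `grn`.
#' @examples
#' g <- grn(tibble::tibble(
#'   regulator = c("R0", "A1"), target = c("A1", "A2"),
#'   effect = c("activation", "repression")
#' ))
#' g
#' @export
grn <- function(interactions = NULL, genes = character(), name = "GRN",
                metadata = list()) {
  if (is.null(interactions)) {
    interactions <- tibble::tibble(
      regulator = character(), target = character(),
      effect = character(), weight = numeric()
    )
  }
  interactions <- tibble::as_tibble(interactions)
  if (!all(c("regulator", "target") %in% names(interactions))) {
    abort("interactions must have 'regulator' and 'target' columns")
  }
  if (!"effect" %in% names(interactions)) {
    interactions$effect <- rep("unknown", nrow(interactions))
  }
  if (!"weight" %in% names(interactions)) {
    interactions$weight <- rep(NA_real_, nrow(interactions))
  }
  interactions <- interactions[, c("regulator", "target", "effect", "weight")]
  interactions$regulator <- trimws(as.character(interactions$regulator))
  interactions$target <- trimws(as.character(interactions$target))
  bad <- !interactions$effect %in% EFFECT_LEVELS
  if (any(bad)) {
    abort(paste0(
      "invalid effect value(s): ",
      paste(unique(interactions$effect[bad]), collapse = ", "),
      "; accepted: ", paste(EFFECT_LEVELS, collapse = ", ")
    ))
  }
  if (any(!nzchar(interactions$regulator)) || any(!nzchar(interactions$target))) {
    abort("regulator and target identifiers must be non-empty")
  }
  genes <- union(trimws(as.character(genes)),
                 union(interactions$regulator, interactions$target))
  genes <- genes[nzchar(genes)]
  structure(
    list(
      interactions = interactions,
      genes = sort(genes),
      name = name,
      metadata = metadata
    ),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  cat("<grn> ", x$name, "\n", sep = "")
  cat("  genes:        ", length(x$genes), "\n", sep = "")
  cat("  interactions: ", nrow(x$interactions), "\n", sep = "")
  if (isTRUE(x$metadata$normalized)) cat("  normalized\n")
  eff <- table(factor(x$interactions$effect, levels = EFFECT_LEVELS))
  cat("  effects:      ",
      paste(names(eff), eff, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @rdname grn
#' @param x A `grn`.
#' @export
is_grn <- function(x) inherits(x, "grn")

#' Accessors for `grn` objects
#'
#' @param grn A `grn` object.
#' @return `grn_interactions()` the interaction tibble; `grn_genes()` the
#'   gene identifier vector; `n_genes()`/`n_interactions()` counts.
#' @export
grn_interactions <- function(grn) grn$interactions

#' @rdname grn_interactions
#' @export
grn_genes <- function(grn) grn$genes

#' @rdname grn_interactions
#' @export
n_genes <- function(grn) length(grn$genes)

#' @rdname grn_interactions
#' @export
n_interactions <- function(grn) nrow(grn$interactions)

#' @export
as_tibble.grn <- function(x, ...) x$interactions

#' Isolated genes of a network
#'
#' Genes declared in the gene set but absent from every interaction.
#' @param grn A `grn`.
#' @return Character vector.
#' @export
isolated_genes <- function(grn) {
  setdiff(grn$genes,
          union(grn$interactions$regulator, grn$interactions$target))
}

# igraph view of the directed network over the full gene set
# (isolated genes included as vertices).
grn_igraph <- function(grn) {
  igraph::graph_from_data_frame(
    grn$interactions[, c("regulator", "target")],
    directed = TRUE,
    vertices = data.frame(name = grn$genes)
  )
}

# Undirected simple projection: self-loops dropped, multi-edges collapsed.
# This is the graph on which local clustering coefficients are defined.
grn_undirected <- function(grn) {
  igraph::simplify(
    igraph::as_undirected(grn_igraph(grn), mode = "collapse"),
    remove.loops = TRUE, remove.multiple = TRUE
  )
}

grn_equal <- function(a, b) {
  ia <- dplyr::arrange(a$interactions, .data$regulator, .data$target)
  ib <- dplyr::arrange(b$interactions, .data$regulator, .data$target)
  setequal(a$genes, b$genes) &&
    nrow(ia) == nrow(ib) &&
    all(ia$regulator == ib$regulator) &&
    all(ia$target == ib$target) &&
    all(ia$effect == ib$effect)
}
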