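#' Classify a module as concilion, simple regulon, or complex regulon
#'
#' A module is a *concilion* when at least one regulatory interaction runs
#' between two distinct local regulators of the module — the hierarchical
#' "council" of regulators that distinguishes it from a regulon. Failing
#' that, it is a *complex regulon* when some structural gene is controlled
#' by two or more distinct regulators within the module, and a *simple
#' regulon* otherwise (the single-regulator case included). Autoregulation
#' (a self-loop on a module regulator) never counts as concilion evidence.
#'
#' Note that modules produced by [nda_decompose()] with two or more
#' regulators always carry an inter-regulator interaction (their
#' regulators form one weakly connected component of the regulator
#' subgraph), so the complex-regulon branch is a guard that can only fire
#' for hand-assembled modules.
#'
#' @param module One row of the `modules` tibble of a
#'   `grnda_decomposition` (fields `module_id`, `regulators`,
#'   `structural`), or a list with those fields.
#' @param interactions The interaction tibble of the network the module
#'   came from (used to collect evidence edges).
#' @return A one-row tibble: `module_id`, `n_genes`, `n_regulators`,
#'   `n_structural`, `verdict`, and an `evidence` list-column holding the
#'   inter-regulator edges (concilion) or the multiply-regulated
#'   structural genes (complex regulon).
#' @export
classify_module <- function(module, interactions) {
  regs <- unlist(module$regulators)
  stru <- unlist(module$structural)
  if (length(regs) == 0) abort("malformed module: no regulators")
  members <- c(regs, stru)
  internal <- interactions[interactions$regulator %in% members &
                             interactions$target %in% members, ]
  rr <- internal[internal$regulator %in% regs &
                   internal$target %in% regs &
                   internal$regulator != internal$target, ]
  if (nrow(rr) > 0) {
    verdict <- "concilion"
    evidence <- rr[, c("regulator", "target", "effect")]
  } else {
    into_struct <- internal[internal$target %in% stru, ]
    multi <- into_struct |>
      dplyr::distinct(.data$regulator, .data$target) |>
      dplyr::count(.data$target) |>
      dplyr::filter(.data$n >= 2)
    if (nrow(multi) > 0) {
      verdict <- "complex_regulon"
      evidence <- multi
    } else {
      verdict <- "simple_regulon"
      evidence <- tibble::tibble()
    }
  }
  tibble::tibble(
    module_id = module$module_id,
    n_genes = length(members),
    n_regulators = length(regs),
    n_structural = length(stru),
    verdict = verdict,
    evidence = list(evidence)
  )
}

#' Classify every module of a decomposition
#'
#' @param decomposition A `grnda_decomposition`.
#' @return A tibble with one row per module, see [classify_module()].
#' @export
classify_modules <- function(decomposition) {
  mods <- decomposition$modules
  if (nrow(mods) == 0) abort("no modules to classify")
  ia <- decomposition$grn$interactions
  purrr::map_dfr(seq_len(nrow(mods)),
                 function(i) classify_module(mods[i, ], ia))
}

#' Concilion fraction of a decomposition
#'
#' The share of modules classified as concilions, with the full verdict
#' tally.
#'
#' @param decomposition A `grnda_decomposition`.
#' @return A one-row tibble: `n_modules`, `n_concilion`,
#'   `n_simple_regulon`, `n_complex_regulon`, `concilion_fraction`.
#' @export
concilion_fraction <- function(decomposition) {
  v <- classify_modules(decomposition)
  tab <- table(factor(v$verdict, levels = c("concilion", "simple_regulon",
                                            "complex_regulon")))
  tibble::tibble(
    n_modules = nrow(v),
    n_concilion = unname(tab["concilion"]),
    n_simple_regulon = unname(tab["simple_regulon"]),
    n_complex_regulon = unname(tab["complex_regulon"]),
    concilion_fraction = unname(tab["concilion"]) / nrow(v)
  )
}

#' Export per-module verdicts
#'
#' TSV with one row per module: id, sizes, verdict, and the evidence edge
#' list flattened to `"a->b; c->d"` form.
#'
#' @param verdicts Output of [classify_modules()].
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_module_verdicts <- function(verdicts, path) {
  flat <- verdicts |>
    dplyr::mutate(evidence = purrr::map_chr(.data$evidence, function(e) {
      if (!nrow(e)) return("")
      if ("regulator" %in% names(e)) {
        paste(e$regulator, e$target, sep = "->", collapse = "; ")
      } else {
        paste(e$target, collapse = "; ")
      }
    }))
  readr::write_tsv(flat, path)
  invisible(path)
}
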