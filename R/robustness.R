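jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

class_sets <- function(decomposition) {
  cl <- decomposition$classes
  lapply(setNames(nm = c("global", "modular", "basal", "intermodular")),
         function(k) cl$gene[cl$class == k])
}

#' Robustness of the decomposition to network incompleteness
#'
#' For each removal fraction and replicate, removes interactions (or genes
#' with their incident interactions) uniformly at random, re-runs the full
#' pipeline, and records the Jaccard similarity between the perturbed and
#' reference membership of each gene class. By default kappa is re-fitted
#' on every perturbed network, matching how incompleteness would bias a
#' real study; `refit_kappa = FALSE` freezes the reference kappa for
#' ablation. When a perturbed network cannot support a fit, the reference
#' kappa is used and the event counted in `n_fallback`. Replicate seeds
#' are derived as `seed + replicate`, so results are reproducible.
#'
#' @param grn A normalized [grn].
#' @param mode `"interactions"` or `"genes"`.
#' @param fractions Removal fractions, each in `[0, 1)`.
#' @param n_reps Replicates per fraction.
#' @param seed Root seed.
#' @param kappa_override Optional kappa for the reference decomposition
#'   (toy networks).
#' @param refit_kappa Re-fit kappa on each perturbed network?
#' @param method Robust fit method, see [fit_power_law()].
#' @return A tibble of class `grnda_robustness`: `fraction`, `class`,
#'   `mean_jaccard`, `sd_jaccard`, `n_reps`, `n_fallback`, with `mode` and
#'   `seed` attributes.
#' @export
robustness_scan <- function(grn, mode = c("interactions", "genes"),
                            fractions = c(0.1, 0.2, 0.3), n_reps = 10,
                            seed = 1, kappa_override = NULL,
                            refit_kappa = TRUE,
                            method = c("irls_bisquare", "theil_sen")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (any(fractions < 0 | fractions >= 1)) abort("fractions must be in [0, 1)")
  stopifnot(n_reps >= 1)
  reference <- run_nda(grn, kappa_override = kappa_override, method = method)
  ref_sets <- class_sets(reference)
  grn_norm <- reference$grn

  rows <- purrr::map_dfr(fractions, function(f) {
    res <- purrr::map_dfr(seq_len(n_reps), function(r) {
      deg <- degrade_grn(grn_norm, mode = mode, fraction = f,
                         seed = seed + r)
      fallback <- FALSE
      dec <- NULL
      if (is.null(kappa_override) && refit_kappa) {
        dec <- tryCatch(run_nda(deg, method = method),
                        error = function(e) NULL)
        if (is.null(dec)) fallback <- TRUE
      }
      if (is.null(dec)) {
        dec <- run_nda(deg, kappa_override = reference$kappa_used,
                       method = method)
      }
      sets <- class_sets(dec)
      tibble::tibble(
        class = names(ref_sets),
        jaccard = purrr::map2_dbl(ref_sets, sets, jaccard),
        fallback = fallback
      )
    })
    res |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        mean_jaccard = mean(.data$jaccard),
        sd_jaccard = if (n_reps > 1) sd(.data$jaccard) else 0,
        n_reps = n_reps,
        n_fallback = sum(.data$fallback),
        .groups = "drop"
      ) |>
      dplyr::mutate(fraction = f, .before = 1)
  })
  rows$class <- factor(rows$class,
                       levels = c("global", "modular", "basal",
                                  "intermodular"))
  rows <- dplyr::arrange(rows, .data$fraction, .data$class)
  class(rows) <- c("grnda_robustness", class(rows))
  attr(rows, "mode") <- mode
  attr(rows, "seed") <- seed
  rows
}

#' @export
autoplot.grnda_robustness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data$mean_jaccard,
                                       color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_jaccard - .data$sd_jaccard, 0),
                   ymax = pmin(.data$mean_jaccard + .data$sd_jaccard, 1)),
      width = 0.01, alpha = 0.5
    ) +
    ggplot2::labs(x = paste0("fraction of ", attr(object, "mode"),
                             " removed"),
                  y = "Jaccard agreement with reference",
                  color = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Export a robustness report as TSV
#'
#' @param report A `grnda_robustness` tibble.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_robustness_tsv <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path)
  invisible(path)
}
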