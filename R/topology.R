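#' Out-connectivity of every gene
#'
#' The out-connectivity \eqn{k_{out}} of a gene is its number of distinct
#' regulatory targets (a kept self-loop counts as one target). Genes with
#' no outgoing interaction — the structural genes — map to 0.
#'
#' @param grn A normalized [grn].
#' @return A tibble with columns `gene`, `kout`, one row per gene.
#' @export
out_connectivity <- function(grn) {
  ia <- dplyr::distinct(grn$interactions, .data$regulator, .data$target)
  counts <- dplyr::count(ia, gene = .data$regulator, name = "kout")
  tibble::tibble(gene = grn$genes) |>
    dplyr::left_join(counts, by = "gene") |>
    dplyr::mutate(kout = dplyr::coalesce(.data$kout, 0L))
}

#' Clustering coefficient versus out-connectivity curve
#'
#' Computes, for every distinct out-connectivity \eqn{k_{out} \ge 1}, the
#' mean local clustering coefficient of the genes with that
#' out-connectivity. Clustering is measured on the underlying undirected
#' simple graph (self-loops dropped, edge directions ignored): triangles
#' through a gene divided by the number of neighbor pairs; genes with
#' fewer than two neighbors get coefficient 0. Structural genes
#' (\eqn{k_{out} = 0}) contribute no curve point.
#'
#' @param grn A normalized [grn].
#' @return A tibble of class `grnda_curve` with columns `kout`,
#'   `kout_norm` (`kout / max(kout)`), `c_mean`, `n_genes`, ordered by
#'   `kout`.
#' @export
clustering_curve <- function(grn) {
  kout <- out_connectivity(grn)
  if (all(kout$kout == 0)) abort("no regulators; cannot fit")
  und <- grn_undirected(grn)
  cc <- igraph::transitivity(und, type = "localundirected",
                             vids = igraph::V(und), isolates = "zero")
  cc[is.nan(cc)] <- 0
  cc_tbl <- tibble::tibble(gene = igraph::V(und)$name, c_local = cc)
  curve <- kout |>
    dplyr::filter(.data$kout >= 1) |>
    dplyr::left_join(cc_tbl, by = "gene") |>
    dplyr::group_by(.data$kout) |>
    dplyr::summarise(c_mean = mean(.data$c_local), n_genes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(kout_norm = .data$kout / max(.data$kout)) |>
    dplyr::select("kout", "kout_norm", "c_mean", "n_genes") |>
    dplyr::arrange(.data$kout)
  class(curve) <- c("grnda_curve", class(curve))
  curve
}

# Iteratively reweighted least squares with Tukey's bisquare weights
# (tuning constant 4.685). Converges when the largest coefficient change
# drops below 1e-8, or after 50 iterations. The residual scale is
# MAD/0.6745, floored to avoid zero weights on exactly noise-free data.
irls_bisquare <- function(x, y, tuning = 4.685, tol = 1e-8, maxit = 50) {
  X <- cbind(1, x)
  beta <- qr.solve(X, y)
  scale <- 1
  for (i in seq_len(maxit)) {
    r <- y - X %*% beta
    scale <- max(median(abs(r)) / 0.6745, 1e-12)
    u <- as.vector(r) / (tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) w <- rep(1, length(y))
    fit <- lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) break
  }
  list(coefficients = unname(beta), scale = scale, iterations = i)
}

# Theil-Sen: median of pairwise slopes, median-based intercept.
theil_sen <- function(x, y) {
  ij <- utils::combn(length(x), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- dx != 0
  slope <- median(dy[ok] / dx[ok])
  intercept <- median(y - slope * x)
  r <- y - intercept - slope * x
  list(coefficients = c(intercept, slope),
       scale = max(median(abs(r)) / 0.6745, 1e-12), iterations = 1L)
}

#' Fit the clustering power law \eqn{C(k_{out}) = \gamma k_{out}^{-\alpha}}
#'
#' Fits `log(c_mean) = log(gamma) - alpha * log(kout_norm)` over curve
#' points with positive mean clustering, by robust least squares. Out-
#' connectivity is normalized by its maximum, so `gamma` is the fitted
#' clustering at `kout = kout_max`. Points with `c_mean == 0` are dropped
#' (their count is recorded). The fit is deterministic for a fixed curve
#' and method.
#'
#' @param curve Output of [clustering_curve()] (columns `kout`,
#'   `kout_norm`, `c_mean` required).
#' @param method `"irls_bisquare"` (iteratively reweighted least squares
#'   with Tukey bisquare weights, tuning constant 4.685) or `"theil_sen"`
#'   (median of pairwise slopes), both resistant to outlying curve points.
#' @return An object of class `grnda_fit` with fields `alpha`, `gamma`,
#'   `kout_max`, `kappa` (see [kappa_value()]; `NA` when the fitted curve
#'   does not decay), `residual_scale`, `n_points`, `n_zero_dropped`,
#'   `method`, and the fitted `curve`.
#' @export
fit_power_law <- function(curve, method = c("irls_bisquare", "theil_sen")) {
  method <- match.arg(method)
  usable <- curve[curve$c_mean > 0, ]
  if (nrow(usable) < 3) {
    abort(paste0("insufficient points: need >= 3 curve points with ",
                 "c_mean > 0, have ", nrow(usable)))
  }
  x <- log(usable$kout_norm)
  y <- log(usable$c_mean)
  fit <- switch(method,
    irls_bisquare = irls_bisquare(x, y),
    theil_sen = theil_sen(x, y)
  )
  alpha <- -fit$coefficients[2]
  gamma <- exp(fit$coefficients[1])
  out <- structure(
    list(
      alpha = alpha, gamma = gamma,
      kout_max = max(curve$kout),
      kappa = NA_real_,
      residual_scale = fit$scale,
      n_points = nrow(usable),
      n_zero_dropped = nrow(curve) - nrow(usable),
      method = method,
      iterations = fit$iterations,
      curve = curve
    ),
    class = "grnda_fit"
  )
  if (alpha > 0 && gamma > 0) {
    out$kappa <- kappa_value(out)
  } else {
    warn(paste0("fitted exponent alpha = ", signif(alpha, 4),
                " does not decay; kappa undefined"))
  }
  out
}

#' The kappa threshold of a fitted clustering power law
#'
#' kappa is the out-connectivity at which the fitted curve
#' \eqn{C(x) = \gamma x^{-\alpha}} (with \eqn{x = k_{out}/k_{out}^{max}}
#' normalized to (0, 1]) has slope -1, i.e. the solution of
#' \eqn{dC/dx = -1}, rescaled back to raw out-connectivity units:
#' \deqn{\kappa = (\alpha\gamma)^{1/(\alpha+1)} \cdot k_{out}^{max}.}
#' Genes whose out-connectivity strictly exceeds kappa are the global
#' regulators.
#'
#' @param fit A `grnda_fit` (or any list with `alpha`, `gamma`,
#'   `kout_max`).
#' @return The kappa value in raw out-connectivity units.
#' @seealso [kappa_closed_form()], [identify_global_regulators()]
#' @export
kappa_value <- function(fit) {
  if (!is.finite(fit$alpha) || !is.finite(fit$gamma) ||
      fit$alpha <= 0 || fit$gamma <= 0) {
    abort("kappa undefined for non-decaying fit (needs alpha > 0, gamma > 0)")
  }
  kappa_closed_form(fit$alpha, fit$gamma, fit$kout_max)
}

#' @rdname kappa_value
#' @param alpha,gamma Power-law exponent and prefactor (normalized units).
#' @param kout_max Maximum out-connectivity used for normalization.
#' @export
kappa_closed_form <- function(alpha, gamma, kout_max) {
  (alpha * gamma)^(1 / (alpha + 1)) * kout_max
}

#' @export
print.grnda_fit <- function(x, ...) {
  cat("<grnda_fit> C(kout) = gamma * kout_norm^-alpha  [", x$method, "]\n",
      sep = "")
  cat(sprintf("  alpha = %.6g  gamma = %.6g  kout_max = %d\n",
              x$alpha, x$gamma, x$kout_max))
  cat(sprintf("  kappa = %.6g  (points used: %d, zero-clustering dropped: %d)\n",
              x$kappa, x$n_points, x$n_zero_dropped))
  invisible(x)
}

#' @export
tidy.grnda_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "gamma", "kappa"),
    estimate = c(x$alpha, x$gamma, x$kappa)
  )
}

#' @export
glance.grnda_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, gamma = x$gamma, kappa = x$kappa,
    kout_max = x$kout_max, residual_scale = x$residual_scale,
    n_points = x$n_points, n_zero_dropped = x$n_zero_dropped,
    method = x$method
  )
}

#' @export
autoplot.grnda_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$kout, .data$c_mean)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_genes), alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "out-connectivity (kout)",
                  y = "mean clustering coefficient C(kout)",
                  size = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grnda_fit <- function(object, ...) {
  curve <- object$curve[object$curve$c_mean > 0, ]
  grid <- tibble::tibble(
    kout = exp(seq(log(min(curve$kout)), log(max(curve$kout)),
                   length.out = 100))
  )
  grid$c_fit <- object$gamma * (grid$kout / object$kout_max)^(-object$alpha)
  p <- autoplot.grnda_curve(object$curve) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(.data$kout, .data$c_fit),
                       inherit.aes = FALSE, color = "steelblue")
  if (is.finite(object$kappa)) {
    p <- p + ggplot2::geom_vline(xintercept = object$kappa,
                                 linetype = "dashed", color = "firebrick") +
      ggplot2::annotate("text", x = object$kappa, y = max(curve$c_mean),
                        label = sprintf("kappa = %.2f", object$kappa),
                        hjust = -0.1, size = 3)
  }
  p
}

#' Export a clustering curve or fit report
#'
#' @param curve A `grnda_curve`.
#' @param path Output TSV file.
#' @return `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path)
  invisible(path)
}

#' @rdname write_curve
#' @param fit A `grnda_fit`.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(
    list(alpha = fit$alpha, gamma = fit$gamma, kappa = fit$kappa,
         kout_max = fit$kout_max, method = fit$method,
         n_points = fit$n_points, n_zero_dropped = fit$n_zero_dropped,
         residual_scale = fit$residual_scale),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
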