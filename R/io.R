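#' Read a regulatory network from a file
#'
#' Supports three dialects. `tsv3`: tab-separated `regulator`, `target`,
#' `effect`, optional 4th `weight` column; lines starting with `#` are
#' comments, except a `#genes:` line which declares isolated genes.
#' `sif`: whitespace-separated `source relation target [target ...]`
#' records with SIF fan-out semantics; a single-token line declares an
#' isolated gene. `abasy`: an Abasy Atlas style TSV export with a header
#' line naming regulator/target/effect columns; extra columns are kept in
#' the network metadata.
#'
#' Effect symbols are mapped as `+` = activation, `-` = repression,
#' `+-`/`-+`/`±` = dual, `?` = unknown. The returned network is *not*
#' normalized (duplicate pairs may remain); see [normalize_network()].
#'
#' @param path File to read.
#' @param dialect One of `"tsv3"`, `"sif"`, `"abasy"`.
#' @param name Network label; defaults to the file name.
#' @return A [grn] object.
#' @seealso [write_network()], [normalize_network()]
#' @export
read_network <- function(path, dialect = c("tsv3", "sif", "abasy"),
                         name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  name <- name %||% basename(path)
  g <- switch(dialect,
    tsv3 = read_tsv3(path, name),
    sif = read_sif(path, name),
    abasy = read_abasy(path, name)
  )
  g$metadata$source <- path
  g$metadata$dialect <- dialect
  g
}

map_effect <- function(symbol, line_no) {
  eff <- unname(EFFECT_SYMBOLS[symbol])
  bad <- is.na(eff)
  if (any(bad)) {
    abort(paste0(
      "line ", line_no[bad][1], ": unknown effect symbol '",
      symbol[bad][1], "'; accepted symbols: ",
      paste(names(EFFECT_SYMBOLS), collapse = " ")
    ))
  }
  eff
}

content_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  tibble::tibble(line_no = seq_along(raw), text = trimws(raw))
}

read_tsv3 <- function(path, name) {
  ln <- content_lines(path)
  isolated <- character()
  gene_decl <- grepl("^#genes:", ln$text)
  if (any(gene_decl)) {
    decl <- sub("^#genes:", "", ln$text[gene_decl])
    isolated <- unlist(strsplit(trimws(decl), "[\t ,]+"))
  }
  body <- ln[!startsWith(ln$text, "#") & nzchar(ln$text), ]
  if (nrow(body) == 0 && length(isolated) == 0) {
    abort(paste0("empty network file: ", path))
  }
  parts <- strsplit(body$text, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3 | nf > 4)) {
    i <- which(nf < 3 | nf > 4)[1]
    abort(paste0(
      "line ", body$line_no[i], ": expected 3 or 4 tab-separated fields, got ",
      nf[i]
    ))
  }
  interactions <- tibble::tibble(
    regulator = trimws(vapply(parts, `[`, "", 1)),
    target = trimws(vapply(parts, `[`, "", 2)),
    effect = map_effect(trimws(vapply(parts, `[`, "", 3)), body$line_no),
    weight = vapply(parts, function(p) {
      if (length(p) >= 4 && nzchar(trimws(p[4]))) as.numeric(p[4]) else NA_real_
    }, numeric(1))
  )
  grn(interactions, genes = isolated, name = name,
      metadata = list(raw_records = nrow(interactions)))
}

read_sif <- function(path, name) {
  ln <- content_lines(path)
  body <- ln[!startsWith(ln$text, "#") & nzchar(ln$text), ]
  if (nrow(body) == 0) abort(paste0("empty network file: ", path))
  rows <- list()
  isolated <- character()
  for (i in seq_len(nrow(body))) {
    tok <- strsplit(body$text[i], "[\t ]+")[[1]]
    if (length(tok) == 1) {
      isolated <- c(isolated, tok)
      next
    }
    if (length(tok) == 2) {
      abort(paste0(
        "line ", body$line_no[i],
        ": SIF record needs 'source relation target [target ...]'"
      ))
    }
    eff <- map_effect(tok[2], body$line_no[i])
    rows[[length(rows) + 1]] <- tibble::tibble(
      regulator = tok[1], target = tok[-(1:2)], effect = eff,
      weight = NA_real_
    )
  }
  interactions <- dplyr::bind_rows(rows)
  grn(interactions, genes = isolated, name = name,
      metadata = list(raw_records = nrow(body)))
}

read_abasy <- function(path, name) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) abort(paste0("empty network file: ", path))
  low <- tolower(names(df))
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- which(grepl(p, low))
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  i_reg <- pick(c("^regulator", "regulator", "^source", "^tf\\b"))
  i_tgt <- pick(c("^target", "target", "regulated", "^gene"))
  i_eff <- pick(c("^effect", "effect", "^sign", "sign"))
  if (is.na(i_reg) || is.na(i_tgt) || is.na(i_eff)) {
    abort(paste0(
      "abasy dialect needs header columns naming regulator, target and ",
      "effect; found: ", paste(names(df), collapse = ", ")
    ))
  }
  eff_raw <- trimws(as.character(df[[i_eff]]))
  known_words <- tolower(eff_raw) %in% EFFECT_LEVELS
  eff <- ifelse(known_words, tolower(eff_raw), NA_character_)
  sym <- unname(EFFECT_SYMBOLS[eff_raw])
  eff[is.na(eff)] <- sym[is.na(eff)]
  if (anyNA(eff)) {
    abort(paste0(
      "unknown effect value '", eff_raw[is.na(eff)][1], "'; accepted: ",
      paste(c(names(EFFECT_SYMBOLS), EFFECT_LEVELS), collapse = " ")
    ))
  }
  interactions <- tibble::tibble(
    regulator = as.character(df[[i_reg]]),
    target = as.character(df[[i_tgt]]),
    effect = eff,
    weight = NA_real_
  )
  extra <- df[, -c(i_reg, i_tgt, i_eff), drop = FALSE]
  meta <- list(raw_records = nrow(df))
  if (ncol(extra)) meta$extra_columns <- tibble::as_tibble(extra)
  grn(interactions, name = name, metadata = meta)
}

# Merge effects seen on one (regulator, target) pair under the lattice
# unknown < {activation, repression} < dual.
merge_effects <- function(effects) {
  known <- unique(effects[effects != "unknown"])
  if (length(known) == 0) return("unknown")
  if ("dual" %in% known || length(known) > 1) return("dual")
  known
}

#' Normalize a regulatory network
#'
#' Collapses duplicate ordered (regulator, target) pairs into a single
#' interaction. Conflicting signs (activation + repression) merge to
#' `dual`; `unknown` merged with any known effect yields the known effect
#' (merge lattice: unknown < activation/repression < dual). Weights, where
#' present, are merged by their maximum. Self-loops are kept by default
#' (autoregulation is biologically meaningful) or dropped, with the policy
#' and the merge count logged in `metadata$normalization`. Idempotent.
#'
#' @param grn A [grn].
#' @param self_loops `"keep"` or `"drop"`.
#' @return A normalized [grn] (same gene set; dropping a self-loop never
#'   removes its gene).
#' @export
normalize_network <- function(grn, self_loops = c("keep", "drop")) {
  self_loops <- match.arg(self_loops)
  ia <- grn$interactions
  n_raw <- nrow(ia)
  if (self_loops == "drop") ia <- ia[ia$regulator != ia$target, ]
  ia <- ia |>
    dplyr::group_by(.data$regulator, .data$target) |>
    dplyr::summarise(
      effect = merge_effects(.data$effect),
      weight = if (all(is.na(.data$weight))) NA_real_ else
        max(.data$weight, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$regulator, .data$target)
  out <- grn
  out$interactions <- ia
  out$metadata$normalized <- TRUE
  out$metadata$normalization <- list(
    self_loops = self_loops,
    records_in = n_raw,
    records_out = nrow(ia)
  )
  out
}

#' Write a regulatory network to a file
#'
#' Serializes a normalized network in the `tsv3` or `sif` dialect.
#' Isolated genes are preserved: `tsv3` lists them in a `#genes:` header
#' comment, `sif` as single-token lines, so that
#' `read_network(write_network(g))` round-trips genes, interactions and
#' effects exactly.
#'
#' @param grn A normalized [grn].
#' @param path Output file.
#' @param dialect `"tsv3"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(grn, path, dialect = c("tsv3", "sif")) {
  dialect <- match.arg(dialect)
  ia <- dplyr::arrange(grn$interactions, .data$regulator, .data$target)
  iso <- isolated_genes(grn)
  lines <- character()
  if (dialect == "tsv3") {
    lines <- c(lines, "#regulator\ttarget\teffect\tweight")
    if (length(iso)) {
      lines <- c(lines, paste0("#genes: ", paste(iso, collapse = " ")))
    }
    if (nrow(ia)) {
      w <- ifelse(is.na(ia$weight), "", format(ia$weight, trim = TRUE))
      lines <- c(lines, paste(ia$regulator, ia$target,
                              effect_to_symbol[ia$effect], w, sep = "\t"))
    }
  } else {
    if (nrow(ia)) {
      lines <- c(lines, paste(ia$regulator, effect_to_symbol[ia$effect],
                              ia$target, sep = "\t"))
    }
    lines <- c(lines, iso)
  }
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort(paste0("cannot write '", path, "': ",
                                     conditionMessage(e)))
  )
  invisible(path)
}
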