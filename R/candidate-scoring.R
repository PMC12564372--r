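# Mutation scoring, ranking and candidate selection.

#' Activity-weighted mutation score
#'
#' Weighted sum of a variant's three relative free-energy changes,
#' `w_bind * ddG_binding + w_fold_complex * ddG_fold_complex +
#' w_fold_ligand * ddG_fold_ligand`. With the negative calibration weights, a
#' variant that lowers all three ddG terms (more favorable binding and
#' stability) gets a higher, more promising score.
#'
#' @param ddg numeric length-3 vector `(binding, fold_complex, fold_ligand)`
#'   in kcal/mol, or a data frame with those three `ddg_*` columns (one score
#'   per row).
#' @param weights numeric length-3 weight vector, e.g. from
#'   [derive_weights()] or [il18_published_calibration()].
#' @return numeric score(s), full precision (display rounding is the
#'   caller's choice; tables conventionally print 2 decimals).
#' @examples
#' w <- il18_published_calibration()$weights
#' mutation_score(c(-1.4, -1.7, -0.8), w)  # E6M from its published triple
#' @export
mutation_score <- function(ddg, weights) {
  stopifnot(is.numeric(weights), length(weights) == 3L,
            all(is.finite(weights)))
  if (is.data.frame(ddg)) {
    need <- c("ddg_binding", "ddg_fold_complex", "ddg_fold_ligand")
    stopifnot(all(need %in% names(ddg)))
    m <- as.matrix(ddg[, need])
  } else {
    stopifnot(is.numeric(ddg), length(ddg) == 3L)
    m <- matrix(ddg, nrow = 1L)
  }
  stopifnot(all(is.finite(m)))
  drop(m %*% as.numeric(weights))
}

#' Score a ddG table
#'
#' Adds a `score` column to a ddG table (see [read_ddg_table()]) using
#' [mutation_score()] row-wise.
#'
#' @param ddg_table data frame with columns `variant`, `ddg_binding`,
#'   `ddg_fold_complex`, `ddg_fold_ligand`.
#' @inheritParams mutation_score
#' @return the table with a numeric `score` column appended.
#' @export
score_variants <- function(ddg_table, weights) {
  ddg_table$score <- mutation_score(ddg_table, weights)
  ddg_table
}

#' Rank scored variants
#'
#' Deterministic ordering: descending score, ties broken by ascending
#' `ddg_binding` (binding affinity being the primary design objective), then
#' lexicographic variant label.
#'
#' @param scored data frame with `variant`, `ddg_binding` and `score`
#'   columns (e.g. from [score_variants()]).
#' @return the same data frame, reordered, with a `rank` column.
#' @export
rank_variants <- function(scored) {
  stopifnot(is.data.frame(scored),
            all(c("variant", "ddg_binding", "score") %in% names(scored)))
  if (nrow(scored) == 0L) {
    scored$rank <- integer(0)
    return(scored)
  }
  o <- order(-scored$score, scored$ddg_binding, scored$variant)
  out <- scored[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select candidate variants
#'
#' Two selection modes: `"strict_all_negative"` keeps variants whose three
#' ddG terms are all `< 0` (favorable binding, complex stability and ligand
#' stability simultaneously); `"top_n"` keeps the `n` best by
#' [rank_variants()] order.
#'
#' @param scored scored ddG table.
#' @param mode `"strict_all_negative"` or `"top_n"`.
#' @param n number of variants for `top_n` mode (>= 1).
#' @return subset of `scored`, in rank order.
#' @examples
#' w <- il18_published_calibration()$weights
#' tab <- data.frame(variant = c("E6M", "R131K"),
#'                   ddg_binding = c(-1.4, -3.0),
#'                   ddg_fold_complex = c(-1.7, 0.2),
#'                   ddg_fold_ligand = c(-0.8, 0.0))
#' select_candidates(score_variants(tab, w), "strict_all_negative")$variant
#' @export
select_candidates <- function(scored,
                              mode = c("strict_all_negative", "top_n"),
                              n = NULL) {
  mode <- match.arg(mode)
  ranked <- rank_variants(scored)
  if (mode == "strict_all_negative") {
    keep <- ranked$ddg_binding < 0 & ranked$ddg_fold_complex < 0 &
      ranked$ddg_fold_ligand < 0
    return(ranked[keep, , drop = FALSE])
  }
  if (is.null(n) || n < 1) stop("top_n mode requires n >= 1", call. = FALSE)
  utils::head(ranked, n)
}

#' Additive approximation of a combined variant's ddG triple
#'
#' Sums the single-mutant ddG triples of a multi-site variant. This is an
#' approximation: combined variants are in general non-additive (epistatic /
#' synergistic effects), so the result carries an `approximation` attribute
#' and downstream tables should flag it.
#'
#' @param variant a multi-site `variant`.
#' @param singles_table ddG table of single mutants (canonical labels).
#' @return length-3 named numeric triple with
#'   `attr(, "approximation") == "additive"`.
#' @export
additive_ddg <- function(variant, singles_table) {
  stopifnot(inherits(variant, "variant"))
  labels <- vapply(seq_len(nrow(variant)), function(i) {
    variant_label(new_variant(variant$wt_res[i], variant$position[i],
                              variant$mut_res[i]))
  }, "")
  i <- match(labels, singles_table$variant)
  if (anyNA(i)) {
    stop("single-mutant ddG missing for: ",
         paste(labels[is.na(i)], collapse = ", "), call. = FALSE)
  }
  out <- c(ddg_binding = sum(singles_table$ddg_binding[i]),
           ddg_fold_complex = sum(singles_table$ddg_fold_complex[i]),
           ddg_fold_ligand = sum(singles_table$ddg_fold_ligand[i]))
  attr(out, "approximation") <- "additive"
  out
}

#' Published ddG tables for the IL-18 design study
#'
#' The published single, double and multiple-mutation ddG tables (kcal/mol,
#' one decimal as printed) with their printed mutation scores, including the
#' experimentally characterized control rows (wild-type, E6K, T63A, M60Q,
#' M33Q). Variant labels are canonicalized on load.
#'
#' @param group optional filter: `"control"`, `"single"`, `"double"` or
#'   `"multiple"`.
#' @return data frame with columns `variant`, `group`, `ddg_binding`,
#'   `ddg_fold_complex`, `ddg_fold_ligand`, `score_published`.
#' @export
il18_published_ddg <- function(group = NULL) {
  path <- system.file("extdata", "il18_ddg_published.tsv",
                      package = "il18design", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$variant <- vapply(tab$variant,
                        function(s) variant_label(parse_variant(s)), "")
  if (!is.null(group)) {
    stopifnot(group %in% tab$group)
    tab <- tab[tab$group == group, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
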