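# Calibration of the mutation score against an in-vitro mutant activity
# panel: relative activity, ln(activity) ~ ddG regression per ddG type, and
# derivation of the scoring weights from the Pearson correlations.

#' Relative activity of a mutant
#'
#' Ratio of mutant to wild-type in-vitro activity, with the wild-type taken
#' as the 100% standard.
#'
#' @param mutant_pct,wildtype_pct activities in percent; both must be > 0
#'   (activity enters downstream regressions through its logarithm).
#' @return dimensionless ratio.
#' @export
relative_activity <- function(mutant_pct, wildtype_pct = 100) {
  stopifnot(is.numeric(mutant_pct), is.numeric(wildtype_pct))
  if (any(mutant_pct <= 0) || any(wildtype_pct <= 0)) {
    stop("activities must be positive (ln is taken downstream)",
         call. = FALSE)
  }
  mutant_pct / wildtype_pct
}

#' Regress a relative free-energy change on log activity
#'
#' Ordinary least squares of `y` (a ddG type, kcal/mol) on
#' `x = ln(% activity)`, with the Pearson correlation and its two-sided
#' p-value from the t distribution with `n - 2` degrees of freedom. This is
#' the calibration direction used for activity-weighted scoring: the fitted
#' line predicts ddG from activity, and [predict_activity()] inverts it.
#'
#' @param ln_activity numeric vector, natural log of % activity (wild-type
#'   = 100, i.e. `log(100)`).
#' @param ddg numeric vector, kcal/mol, same length.
#' @return object of class `ddg_fit`: list with `slope`, `intercept`,
#'   `pearson_r`, `p_value`, `n`.
#' @examples
#' f <- fit_ddg_activity(log(c(10, 50, 100, 200)), c(2, 0.9, 0.5, -0.1))
#' f$pearson_r
#' @export
fit_ddg_activity <- function(ln_activity, ddg) {
  x <- as.numeric(ln_activity)
  y <- as.numeric(ddg)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points to fit", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate predictor: ln(activity) has zero variance",
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("response has zero variance; correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = n),
            class = "ddg_fit")
}

#' @export
print.ddg_fit <- function(x, ...) {
  cat(sprintf("ddG ~ ln(activity): y = %.4f x + %.4f  (r = %.4f, p = %.4g, n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive scoring weights from the three calibration fits
#'
#' The mutation-score weight for each ddG type is its Pearson correlation
#' with ln(% activity), rounded to three decimals (half away from zero).
#' With the published panel correlations (-0.7019, -0.7443, -0.5770) this
#' yields the weight vector (-0.702, -0.744, -0.577).
#'
#' @param fits list of three `ddg_fit` objects, in the order binding,
#'   folding-of-complex, folding-of-free-ligand; alternatively a numeric
#'   vector of three correlations.
#' @return named numeric weight vector
#'   `c(w_bind =, w_fold_complex =, w_fold_ligand =)` with attribute
#'   `pearson_r` recording the unrounded correlations.
#' @export
derive_weights <- function(fits) {
  if (is.numeric(fits)) {
    r <- fits
  } else {
    stopifnot(is.list(fits),
              all(vapply(fits, inherits, TRUE, what = "ddg_fit")))
    r <- vapply(fits, function(f) f$pearson_r, 0)
  }
  if (length(r) != 3L) {
    stop("exactly three fits/correlations required (binding, fold-complex, ",
         "fold-ligand)", call. = FALSE)
  }
  w <- round_half_away(r, 3L)
  names(w) <- c("w_bind", "w_fold_complex", "w_fold_ligand")
  attr(w, "pearson_r") <- unname(r)
  w
}

#' Predict log activity from a ddG value
#'
#' Inverts a calibration line `ddg = slope * ln(activity) + intercept`,
#' returning the estimated `ln(% activity)`.
#'
#' @param ddg kcal/mol.
#' @param fit a `ddg_fit` (or any list with `slope` and `intercept`).
#' @return estimated natural log of % activity.
#' @export
predict_activity <- function(ddg, fit) {
  stopifnot(is.numeric(ddg), !is.null(fit$slope), !is.null(fit$intercept))
  if (fit$slope == 0) stop("cannot invert a zero-slope fit", call. = FALSE)
  (ddg - fit$intercept) / fit$slope
}

#' Published IL-18 calibration constants
#'
#' The published calibration of the three ddG types against ln(% in-vitro
#' activity) over a 17-mutant panel: Pearson correlations, regression lines
#' (`ddg = slope * ln(activity) + intercept`) and the resulting score
#' weights. Shipped as reference constants so screening can be run without
#' re-fitting when the panel data are not at hand.
#'
#' @return list with elements `pearson_r`, `p_value`, `lines` (data frame of
#'   slope/intercept per ddG type) and `weights` (via [derive_weights()]).
#' @examples
#' il18_published_calibration()$weights
#' @export
il18_published_calibration <- function() {
  r <- c(ddg_binding = -0.7019, ddg_fold_complex = -0.7443,
         ddg_fold_ligand = -0.5770)
  p <- c(ddg_binding = 0.0012, ddg_fold_complex = 0.0004,
         ddg_fold_ligand = 0.0122)
  lines <- data.frame(
    ddg_type = c("ddg_binding", "ddg_fold_complex", "ddg_fold_ligand"),
    slope = c(-0.6046, -0.4544, -0.2829),
    intercept = c(-0.5622, 0.5580, 0.5701)
  )
  list(pearson_r = r, p_value = p, lines = lines,
       weights = derive_weights(unname(r)))
}

#' Read a mutant activity panel or a ddG table
#'
#' `read_activity_panel` expects TSV columns `variant activity_pct`;
#' `read_ddg_table` expects
#' `variant ddg_binding ddg_fold_complex ddg_fold_ligand` (kcal/mol; extra
#' columns are preserved). Variant labels are canonicalized.
#'
#' @param path file path.
#' @return data frame; `variant` column holds canonical labels.
#' @export
read_activity_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "activity_pct") %in% names(tab))) {
    stop("activity panel must have columns: variant, activity_pct",
         call. = FALSE)
  }
  tab$variant <- vapply(tab$variant,
                        function(s) variant_label(parse_variant(s)), "")
  tab$activity_pct <- as.numeric(tab$activity_pct)
  if (any(!is.finite(tab$activity_pct)) || any(tab$activity_pct <= 0)) {
    stop("activity_pct must be finite and positive", call. = FALSE)
  }
  tab
}

#' @rdname read_activity_panel
#' @export
read_ddg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant", "ddg_binding", "ddg_fold_complex", "ddg_fold_ligand")
  if (!all(need %in% names(tab))) {
    stop("ddG table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$variant <- vapply(tab$variant,
                        function(s) variant_label(parse_variant(s)), "")
  for (col in need[-1L]) {
    tab[[col]] <- as.numeric(tab[[col]])
    if (anyNA(tab[[col]])) stop("non-numeric ", col, " in ", path,
                                call. = FALSE)
  }
  tab
}
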