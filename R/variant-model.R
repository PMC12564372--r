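#' @keywords internal
"_PACKAGE"

# Amino-acid alphabets. Ambiguity codes (B, Z, X) are deliberately absent:
# a substitution must name a concrete residue.
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Convert between one- and three-letter amino-acid codes
#'
#' Only the 20 standard residues are accepted; ambiguity codes (B, Z, X) and
#' anything else are rejected because a design variant must name a concrete
#' amino acid.
#'
#' @param x character vector of codes (case-insensitive).
#' @return character vector of codes in the other convention.
#' @examples
#' aa_three2one(c("GLU", "MET"))
#' aa_one2three("K")
#' @export
aa_three2one <- function(x) {
  i <- match(toupper(x), AA3)
  if (anyNA(i)) {
    stop("unknown three-letter amino-acid code(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  AA1[i]
}

#' @rdname aa_three2one
#' @export
aa_one2three <- function(x) {
  i <- match(toupper(x), AA1)
  if (anyNA(i)) {
    stop("unknown one-letter amino-acid code(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  AA3[i]
}

new_variant <- function(wt_res = character(), position = integer(),
                        mut_res = character()) {
  v <- data.frame(wt_res = wt_res, position = as.integer(position),
                  mut_res = mut_res, stringsAsFactors = FALSE)
  v <- v[order(v$position), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("variant", "data.frame")
  v
}

#' Parse a variant label into its mutation set
#'
#' A variant is a set of amino-acid substitutions on the mature IL-18 sequence
#' (1-based numbering, Tyr1 = 1). Labels are `"+"`-joined tokens of the form
#' `<wt><position><mut>`, e.g. `"E6M"` or `"E6M+K129M+R131G"`; the label
#' `"WT"` denotes the empty set (wild-type). Token order in the input is
#' irrelevant; the parsed variant is canonical (sorted by position).
#'
#' @param label character scalar, e.g. `"E6M+R131G"` or `"WT"`.
#' @return an object of class `variant`: a data frame with columns `wt_res`,
#'   `position`, `mut_res`, sorted by position. Wild-type is the zero-row
#'   variant.
#' @examples
#' parse_variant("E6M")
#' variant_label(parse_variant("R131G+E6M"))  # "E6M+R131G"
#' @seealso [variant_label()], [saturate()], [combine_variants()]
#' @export
parse_variant <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  label <- trimws(label)
  if (toupper(label) == "WT" || label == "") {
    return(new_variant())
  }
  tokens <- strsplit(label, "+", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("malformed mutation token(s): ",
         paste(shQuote(tokens[bad]), collapse = ", "),
         " (expected e.g. 'E6M')", call. = FALSE)
  }
  wt <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- toupper(vapply(m, `[`, "", 4L))
  chk <- c(wt, mut)
  if (!all(chk %in% AA1)) {
    stop("invalid amino-acid code(s): ",
         paste(unique(chk[!chk %in% AA1]), collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  silent <- wt == mut
  if (any(silent)) {
    stop("silent substitution(s) not allowed: ",
         paste(tokens[silent], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pos)) {
    stop("duplicate position(s) in variant: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "), call. = FALSE)
  }
  new_variant(wt, pos, mut)
}

#' Canonical label of a variant
#'
#' Mutations are printed sorted by ascending position and joined with `"+"`;
#' the empty (wild-type) variant prints as `"WT"`. `parse_variant()` and
#' `variant_label()` round-trip.
#'
#' @param v a `variant` object.
#' @return character scalar.
#' @export
variant_label <- function(v) {
  stopifnot(inherits(v, "variant"))
  if (nrow(v) == 0L) return("WT")
  v <- v[order(v$position), , drop = FALSE]
  paste0(v$wt_res, v$position, v$mut_res, collapse = "+")
}

#' @export
format.variant <- function(x, ...) variant_label(x)

#' @export
print.variant <- function(x, ...) {
  cat("<variant>", variant_label(x), "\n")
  invisible(x)
}

n_mutations <- function(v) nrow(v)

#' In silico saturation mutagenesis over a set of positions
#'
#' For each site, generates the 19 single-point variants substituting the
#' wild-type residue by every other standard amino acid (the wild-type
#' identity "variant" is excluded).
#'
#' @param sites data frame with columns `wt_res` (one-letter code) and
#'   `position`, or a list of `c(wt, pos)` pairs.
#' @return list of single-mutation `variant` objects, 19 per site, ordered by
#'   site then substituting residue (alphabet order).
#' @examples
#' length(saturate(data.frame(wt_res = "E", position = 6)))  # 19
#' @export
saturate <- function(sites) {
  if (is.list(sites) && !is.data.frame(sites)) {
    sites <- data.frame(
      wt_res = vapply(sites, function(s) as.character(s[[1]]), ""),
      position = vapply(sites, function(s) as.integer(s[[2]]), 1L)
    )
  }
  stopifnot(is.data.frame(sites), all(c("wt_res", "position") %in% names(sites)))
  if (nrow(sites) == 0L) return(list())
  wt <- toupper(sites$wt_res)
  if (!all(wt %in% AA1)) {
    stop("invalid wild-type code(s): ",
         paste(unique(wt[!wt %in% AA1]), collapse = ", "), call. = FALSE)
  }
  out <- vector("list", 0L)
  for (i in seq_len(nrow(sites))) {
    subs <- sort(setdiff(AA1, wt[i]))
    out <- c(out, lapply(subs, function(m) {
      new_variant(wt[i], sites$position[i], m)
    }))
  }
  out
}

#' Combine single-point variants into multi-site variants
#'
#' Enumerates all size-`k` subsets of the supplied single mutations whose
#' positions are pairwise distinct (two substitutions at the same position —
#' e.g. R131K and R131G — cannot coexist in one molecule). Output order is
#' deterministic: lexicographic by canonical label.
#'
#' @param singles list of single-mutation `variant` objects.
#' @param k integer >= 2, the combination size.
#' @return list of `variant` objects with `k` mutations each.
#' @examples
#' s <- lapply(c("E6M", "K129M", "R131K", "N111S", "R131G"), parse_variant)
#' length(combine_variants(s, 2))  # 9
#' length(combine_variants(s, 3))  # 7
#' @export
combine_variants <- function(singles, k) {
  stopifnot(is.list(singles))
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2", call. = FALSE)
  ok <- vapply(singles, function(v) inherits(v, "variant") && nrow(v) == 1L,
               TRUE)
  if (!all(ok)) {
    stop("all inputs to combine_variants() must be single-point variants",
         call. = FALSE)
  }
  n <- length(singles)
  if (k > n) return(list())
  idx <- utils::combn(n, k, simplify = FALSE)
  out <- list()
  for (ii in idx) {
    pos <- vapply(singles[ii], function(v) v$position, 1L)
    if (anyDuplicated(pos)) next
    merged <- do.call(rbind, lapply(singles[ii], as.data.frame))
    out[[length(out) + 1L]] <- new_variant(merged$wt_res, merged$position,
                                           merged$mut_res)
  }
  out[order(vapply(out, variant_label, ""))]
}

#' Read and write variant lists
#'
#' Plain-text interchange: one canonical label per line (`read_variants`
#' accepts any token order and canonicalizes). A TSV with a `variant` column
#' is also accepted.
#'
#' @param path file path.
#' @param variants list of `variant` objects (for `write_variants`).
#' @return `read_variants`: list of `variant` objects. `write_variants`:
#'   `path`, invisibly.
#' @export
read_variants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("\t", lines[[1]])) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"variant" %in% names(tab)) {
      stop("TSV variant file must have a 'variant' column", call. = FALSE)
    }
    lines <- tab$variant
  }
  lapply(lines, parse_variant)
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  writeLines(vapply(variants, variant_label, ""), path)
  invisible(path)
}
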