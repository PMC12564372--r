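# Per-residue interface energetics: loading decomposition tables and
# classifying residues as key / favorable / unfavorable.

ENERGY_COLS <- c("chain", "res_name", "res_index",
                 "e_total", "e_elec", "e_vdw", "e_desolv", "site")

#' Load a per-residue interface energy table
#'
#' Reads a TSV/CSV of per-residue binding-energy decompositions (kcal/mol):
#' the total contribution of each interface residue plus its electrostatic,
#' van der Waals and desolvation terms, and a receptor-epitope site annotation
#' (`I`, `II`, `III` or `none`). Site membership is an annotation supplied
#' with the data (it comes from the crystal-structure literature), never
#' derived here.
#'
#' @param path path to a tab- or comma-separated file with header columns
#'   `chain res_name res_index e_total e_elec e_vdw e_desolv site`.
#' @return data frame with those columns, row order preserved, energies
#'   numeric and finite.
#' @seealso [classify_interface()], [write_residue_energies()]
#' @export
load_residue_energies <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = TRUE)
  missing <- setdiff(ENERGY_COLS, names(tab))
  if (length(missing)) {
    stop("energy table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, ENERGY_COLS]
  for (col in c("e_total", "e_elec", "e_vdw", "e_desolv")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(val))
    if (length(bad)) {
      stop("non-numeric ", col, " in row(s) ", paste(bad, collapse = ", "),
           " of ", path, call. = FALSE)
    }
    tab[[col]] <- val
  }
  tab$res_index <- as.integer(tab$res_index)
  if (anyNA(tab$res_index)) {
    stop("non-integer res_index in row(s) ",
         paste(which(is.na(tab$res_index)), collapse = ", "), call. = FALSE)
  }
  bad_site <- !tab$site %in% c("I", "II", "III", "none")
  if (any(bad_site)) {
    stop("invalid site annotation in row(s) ",
         paste(which(bad_site), collapse = ", "),
         " (expected I, II, III or none)", call. = FALSE)
  }
  tab
}

#' @rdname load_residue_energies
#' @param records data frame as returned by `load_residue_energies`.
#' @export
write_residue_energies <- function(records, path) {
  stopifnot(all(ENERGY_COLS %in% names(records)))
  utils::write.table(records[, ENERGY_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify interface residues by their binding-energy contribution
#'
#' Partitions interface residues on the sign of their decomposed contribution
#' to complex binding: favorable (`e_total < 0`), unfavorable
#' (`e_total > 0`), and the key (hotspot) subset of favorable residues whose
#' contribution is at least as favorable as `key_threshold`. Residues with a
#' contribution of exactly zero are neither favorable nor unfavorable. The
#' threshold is inclusive: `e_total == key_threshold` is key.
#'
#' @param records data frame from [load_residue_energies()].
#' @param key_threshold kcal/mol; default `-1.0`. A residue is key when
#'   `e_total <= key_threshold`.
#' @return object of class `interface_classification`: a list with data-frame
#'   elements `key`, `favorable`, `unfavorable` (key is a subset of
#'   favorable), and `counts`, a site-by-class contingency table.
#' @examples
#' tab <- data.frame(chain = "A", res_name = c("LYS", "LYS", "ASP"),
#'                   res_index = c(79, 84, 98),
#'                   e_total = c(-0.08, -0.21, 0.32),
#'                   e_elec = 0, e_vdw = 0, e_desolv = 0, site = "III")
#' classify_interface(tab)$counts
#' @export
classify_interface <- function(records, key_threshold = -1.0) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(ENERGY_COLS %in% names(records)),
            is.numeric(key_threshold), length(key_threshold) == 1L,
            key_threshold < 0)
  fav <- records[records$e_total < 0, , drop = FALSE]
  unf <- records[records$e_total > 0, , drop = FALSE]
  key <- records[records$e_total <= key_threshold, , drop = FALSE]
  cls <- rep("neutral", nrow(records))
  cls[records$e_total < 0] <- "favorable"
  cls[records$e_total <= key_threshold] <- "key"
  cls[records$e_total > 0] <- "unfavorable"
  counts <- table(site = factor(records$site,
                                levels = c("I", "II", "III", "none")),
                  class = factor(cls, levels = c("key", "favorable",
                                                 "unfavorable", "neutral")))
  structure(list(key = key, favorable = fav, unfavorable = unf,
                 key_threshold = key_threshold, counts = counts),
            class = "interface_classification")
}

#' @export
print.interface_classification <- function(x, ...) {
  cat("Interface classification (key threshold ", x$key_threshold,
      " kcal/mol)\n", sep = "")
  cat("  key:", nrow(x$key), " favorable:", nrow(x$favorable),
      " unfavorable:", nrow(x$unfavorable), "\n")
  print(x$counts)
  invisible(x)
}
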