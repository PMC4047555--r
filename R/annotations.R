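# SoM annotation sidecar files.
#
# Experimental sites of metabolism are kept out of the mol2 files in a plain
# TSV sidecar: one line per molecule, `mol_id <TAB> i1,i2,...` with 1-based
# atom indices. Repeated lines for one molecule are merged by union.

#' Read SoM annotations
#'
#' @param path TSV with two columns and no header: mol_id, comma-separated
#'   1-based atom indices. Lines starting with `#` are ignored.
#' @return A tibble with columns `mol_id` (character) and `som_atoms` (list of
#'   sorted integer vectors), one row per distinct molecule.
#' @export
read_som_annotations <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parsed <- map(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L) {
      abort(sprintf("annotation line is not `mol_id<TAB>indices`: %s", ln),
            class = "somkit_format_error")
    }
    idx_str <- strsplit(trimws(f[2]), ",", fixed = TRUE)[[1]]
    idx <- suppressWarnings(as.integer(trimws(idx_str)))
    if (length(idx) == 0L || anyNA(idx) || any(idx < 1L)) {
      abort(sprintf("atom indices must be positive integers (1-based): %s", ln),
            class = "somkit_format_error")
    }
    tibble(mol_id = trimws(f[1]), som_atoms = list(idx))
  })
  bind_rows(parsed) |>
    group_by(.data$mol_id) |>
    summarise(som_atoms = list(sort(unique(unlist(.data$som_atoms)))),
              .groups = "drop")
}

#' Write SoM annotations
#'
#' Inverse of [read_som_annotations()]; rows are written sorted by mol_id so
#' the file is byte-stable across runs.
#'
#' @param annotations Tibble with columns `mol_id`, `som_atoms` (list column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_som_annotations <- function(annotations, path) {
  ann <- dplyr::arrange(annotations, .data$mol_id)
  lines <- sprintf("%s\t%s", ann$mol_id,
                   map_chr(ann$som_atoms, ~ paste(sort(unique(.x)), collapse = ",")))
  readr::write_lines(lines, path)
  invisible(path)
}

# check annotations against molecules; drop-in validation used by build step
validate_annotations <- function(molecules, annotations) {
  mol_ids <- map_chr(molecules, "mol_id")
  missing <- setdiff(annotations$mol_id, mol_ids)
  if (length(missing) > 0L) {
    abort(sprintf("annotations reference molecules absent from the corpus: %s",
                  paste(missing, collapse = ", ")),
          class = "somkit_consistency_error")
  }
  for (i in seq_len(nrow(annotations))) {
    m <- molecules[[match(annotations$mol_id[i], mol_ids)]]
    bad <- setdiff(annotations$som_atoms[[i]], m$atoms$index)
    if (length(bad) > 0L) {
      abort(sprintf("annotation for %s references atom(s) %s not in the molecule",
                    annotations$mol_id[i], paste(bad, collapse = ", ")),
            class = "somkit_consistency_error")
    }
  }
  invisible(annotations)
}
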