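# The per-site fingerprint dataset ("som_sites" tibble) and its TSV dialect.
#
# One row per candidate atomic site: mol_id, atom_index, label (SOM = class
# omega0, NONSOM = omega1) and L integer feature columns f_1..f_L laid out
# layer-major (all alphabet types at bond distance 0, then distance 1, ...).
# The bond depth and the ordered type alphabet are carried as attributes and
# persisted in the file header, because the feature indices are meaningless
# without them.

#' Coerce a data frame to a site dataset
#'
#' @param x Data frame with columns `mol_id`, `atom_index`, `label` (values
#'   `"SOM"`/`"NONSOM"`) and integer feature columns `f_1` ... `f_L`.
#' @param depth Bond depth d used to build the fingerprints (0-8).
#' @param alphabet Ordered character vector of SYBYL types; must satisfy
#'   `L == (depth + 1) * length(alphabet)`.
#' @return A tibble of class `som_sites` with `depth` and `alphabet` attributes.
#' @export
as_som_sites <- function(x, depth, alphabet) {
  x <- tibble::as_tibble(x)
  fcols <- grep("^f_\\d+$", names(x), value = TRUE)
  need <- c("mol_id", "atom_index", "label")
  if (!all(need %in% names(x))) {
    abort(sprintf("site dataset needs columns %s", paste(need, collapse = ", ")))
  }
  L <- length(fcols)
  if (!setequal(fcols, paste0("f_", seq_len(L)))) {
    abort("feature columns must be contiguous f_1..f_L")
  }
  depth <- as.integer(depth)
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet)) abort("alphabet must not contain duplicates")
  if (L != (depth + 1L) * length(alphabet)) {
    abort(sprintf("L = %d features but (depth+1) x |alphabet| = %d",
                  L, (depth + 1L) * length(alphabet)))
  }
  if (!all(x$label %in% .SOM_LABELS)) {
    abort("label must be 'SOM' or 'NONSOM'", class = "somkit_format_error")
  }
  x <- x[, c(need, paste0("f_", seq_len(L)))]
  for (fc in paste0("f_", seq_len(L))) {
    v <- x[[fc]]
    if (any(v < 0, na.rm = TRUE) || anyNA(v)) {
      abort(sprintf("feature column %s contains negative or missing counts", fc),
            class = "somkit_value_error")
    }
    x[[fc]] <- as.integer(v)
  }
  x$atom_index <- as.integer(x$atom_index)
  x$mol_id <- as.character(x$mol_id)
  structure(x, depth = depth, alphabet = alphabet,
            class = c("som_sites", class(tibble::tibble())))
}

#' Extract the integer feature matrix of a site dataset
#' @param sites A `som_sites` tibble.
#' @return Integer matrix, one row per site, L columns.
#' @export
feature_matrix <- function(sites) {
  L <- n_features(sites)
  m <- as.matrix(sites[, paste0("f_", seq_len(L))])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

n_features <- function(sites) sum(grepl("^f_\\d+$", names(sites)))

site_depth <- function(sites) attr(sites, "depth", exact = TRUE)
site_alphabet <- function(sites) attr(sites, "alphabet", exact = TRUE)

#' @export
print.som_sites <- function(x, ...) {
  cat(sprintf("<som_sites> %d sites (%d SoM / %d nonSoM), depth %d, |alphabet| %d, L = %d\n",
              nrow(x), sum(x$label == "SOM"), sum(x$label == "NONSOM"),
              site_depth(x), length(site_alphabet(x)), n_features(x)))
  NextMethod()
}

#' Read a per-site fingerprint dataset
#'
#' Reads the TSV dialect written by [write_site_dataset()]: `#`-prefixed
#' header lines recording depth and alphabet, then a header row
#' `mol_id atom_index label f_1..f_L` and one row per atomic site.
#'
#' @param path Input TSV path.
#' @return A `som_sites` tibble.
#' @export
read_site_dataset <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grep("^#", lines, value = TRUE)
  pick <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0L) {
      abort(sprintf("%s: missing '# %s:' header line", path, key),
            class = "somkit_format_error")
    }
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  depth <- as.integer(pick("depth"))
  alphabet <- strsplit(pick("alphabet"), ",", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    abort(sprintf("%s: no column header row", path), class = "somkit_format_error")
  }
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(cols)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ragged <- which(lengths(rows) != ncol_expect)
  if (length(ragged) > 0L) {
    abort(sprintf("%s: ragged row(s) %s (expected %d columns)",
                  path, paste(head(ragged, 5), collapse = ", "), ncol_expect),
          class = "somkit_format_error")
  }
  df <- if (length(rows) == 0L) {
    as_tibble(setNames(rep(list(character()), ncol_expect), cols))
  } else {
    m <- do.call(rbind, rows)
    as_tibble(setNames(as.data.frame(m, stringsAsFactors = FALSE), cols))
  }
  fcols <- grep("^f_\\d+$", cols, value = TRUE)
  for (fc in fcols) {
    v <- suppressWarnings(as.numeric(df[[fc]]))
    if (anyNA(v) && nrow(df) > 0L) {
      abort(sprintf("%s: non-numeric value in %s", path, fc),
            class = "somkit_value_error")
    }
    if (any(v < 0)) {
      abort(sprintf("%s: negative count in %s", path, fc),
            class = "somkit_value_error")
    }
    df[[fc]] <- as.integer(v)
  }
  if (nrow(df) > 0L) df$atom_index <- as.integer(df$atom_index)
  else df$atom_index <- integer()
  as_som_sites(df, depth = depth, alphabet = alphabet)
}

#' Write a per-site fingerprint dataset
#'
#' @param sites A `som_sites` tibble (see [as_som_sites()]).
#' @param path Output TSV path. UTF-8, Unix newlines; round-trips exactly
#'   through [read_site_dataset()].
#' @return `path`, invisibly.
#' @export
write_site_dataset <- function(sites, path) {
  if (!inherits(sites, "som_sites")) {
    abort("`sites` must be a som_sites tibble (see as_som_sites())")
  }
  L <- n_features(sites)
  header <- c(
    "# somkit site dataset v1",
    sprintf("# depth: %d", site_depth(sites)),
    sprintf("# alphabet: %s", paste(site_alphabet(sites), collapse = ",")),
    "# layout: layer-major (all types at distance 0, then distance 1, ...)"
  )
  cols <- c("mol_id", "atom_index", "label", paste0("f_", seq_len(L)))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(vapply(cols, function(cn) as.character(sites[[cn]][i]), ""),
          collapse = "\t")
  }, "")
  readr::write_lines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
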