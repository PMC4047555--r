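# TRIPOS mol2 input/output and the molecule container.
#
# Only the MOLECULE, ATOM and BOND record types are interpreted; other blocks
# (SUBSTRUCTURE, comments, ...) are ignored on read. SYBYL atom types are taken
# verbatim from column 6 of ATOM records -- they are the whole feature alphabet
# of the fingerprint method, so no normalisation is applied.

#' Construct a molecule
#'
#' A molecule is a typed, undirected atom/bond graph. Atom indices are 1-based
#' positions in the mol2 ATOM block; bonds are unordered index pairs.
#'
#' @param mol_id Molecule identifier (string).
#' @param atoms Tibble (or data frame) with at least columns `index` (integer),
#'   `sybyl_type` (character, e.g. `"C.3"`, `"N.ar"`, `"H"`). Optional columns
#'   `name`, `x`, `y`, `z`, `charge` are kept as-is.
#' @param bonds Tibble with integer columns `from`, `to` referencing `index`.
#' @return An object of class `som_mol` with elements `mol_id`, `atoms`
#'   (tibble; gains `element` and `is_heavy` columns) and `bonds` (tibble,
#'   stored with `from < to`).
#' @details The element symbol is derived from the SYBYL type (the part before
#'   the first `.`); `is_heavy` is `TRUE` for everything but hydrogen. Charges
#'   and coordinates are carried along but unused by the prediction method,
#'   which is purely topological.
#' @export
#' @examples
#' m <- som_molecule("water",
#'   atoms = tibble::tibble(index = 1:3, sybyl_type = c("O.3", "H", "H")),
#'   bonds = tibble::tibble(from = c(1, 1), to = c(2, 3)))
#' m
som_molecule <- function(mol_id, atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!all(c("index", "sybyl_type") %in% names(atoms))) {
    abort("`atoms` needs columns `index` and `sybyl_type`.")
  }
  if (nrow(atoms) == 0L) abort("a molecule must contain at least one atom")
  atoms$index <- as.integer(atoms$index)
  atoms$sybyl_type <- as.character(atoms$sybyl_type)
  if (anyDuplicated(atoms$index)) abort("atom indices must be unique within a molecule")
  if (any(!nzchar(atoms$sybyl_type)) || anyNA(atoms$sybyl_type)) {
    abort("every atom needs a non-empty SYBYL type")
  }
  atoms$element <- sub("\\..*$", "", atoms$sybyl_type)
  atoms$is_heavy <- toupper(atoms$element) != "H"
  if (nrow(bonds) > 0L) {
    from <- as.integer(bonds$from); to <- as.integer(bonds$to)
    bad <- !(from %in% atoms$index) | !(to %in% atoms$index)
    if (any(bad)) {
      abort(sprintf("bond references atom(s) absent from the molecule: %s",
                    paste(unique(c(from[bad], to[bad])), collapse = ", ")),
            class = "somkit_structural_error")
    }
    if (any(from == to)) abort("self-loop bonds are not allowed",
                               class = "somkit_structural_error")
    lo <- pmin(from, to); hi <- pmax(from, to)
    bonds <- dplyr::distinct(tibble(from = lo, to = hi))
  } else {
    bonds <- tibble(from = integer(), to = integer())
  }
  structure(list(mol_id = as.character(mol_id), atoms = atoms, bonds = bonds),
            class = "som_mol")
}

#' @export
print.som_mol <- function(x, ...) {
  cat(sprintf("<som_mol> %s: %d atoms (%d heavy), %d bonds\n",
              x$mol_id, nrow(x$atoms), sum(x$atoms$is_heavy), nrow(x$bonds)))
  invisible(x)
}

# igraph view of the bond graph; vertex names are atom indices as characters
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(mol$atoms$index))
  if (nrow(mol$bonds) > 0L) {
    ends <- rbind(match(mol$bonds$from, mol$atoms$index),
                  match(mol$bonds$to, mol$atoms$index))
    g <- igraph::add_edges(g, as.vector(ends))
  }
  g
}

#' Read molecules from a TRIPOS mol2 file
#'
#' Parses `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` blocks; everything else is
#' skipped. One [som_molecule()] is returned per MOLECULE block, in file order.
#'
#' @param path Path to a mol2 file (possibly multi-molecule).
#' @return A named list of `som_mol` objects (names are mol_ids; duplicated ids
#'   are made unique with a numeric suffix in the names only).
#' @export
read_mol2 <- function(path) {
  lines <- readr::read_lines(path)
  starts <- grep("^@<TRIPOS>MOLECULE\\s*$", lines)
  if (length(starts) == 0L) {
    abort(sprintf("%s: no @<TRIPOS>MOLECULE block found (line 1)", path),
          class = "somkit_parse_error")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  mols <- map2(starts, ends, function(s, e) {
    parse_mol2_block(lines[s:e], offset = s, path = path)
  })
  names(mols) <- make.unique(map_chr(mols, "mol_id"))
  mols
}

parse_mol2_block <- function(block, offset, path) {
  # block[1] is the @<TRIPOS>MOLECULE line; next non-blank line is the name
  body <- block[-1]
  nm_at <- which(!grepl("^\\s*$", body))[1]
  if (is.na(nm_at)) {
    abort(sprintf("%s: MOLECULE block at line %d has no name line", path, offset),
          class = "somkit_parse_error")
  }
  mol_id <- trimws(body[nm_at])
  section <- function(tag) {
    at <- grep(paste0("^@<TRIPOS>", tag, "\\s*$"), block)
    if (length(at) == 0L) return(NULL)
    at <- at[1]
    stop_at <- grep("^@<TRIPOS>", block)
    stop_at <- stop_at[stop_at > at]
    end <- if (length(stop_at)) stop_at[1] - 1L else length(block)
    rows <- block[seq(at + 1L, length.out = max(0L, end - at))]
    rows <- rows[!grepl("^\\s*$", rows) & !grepl("^\\s*#", rows)]
    list(rows = rows, line0 = offset + at - 1L)
  }
  at_sec <- section("ATOM")
  if (is.null(at_sec)) {
    abort(sprintf("%s: molecule '%s' has no @<TRIPOS>ATOM block (line %d)",
                  path, mol_id, offset), class = "somkit_parse_error")
  }
  atoms <- map2(at_sec$rows, seq_along(at_sec$rows), function(row, i) {
    f <- strsplit(trimws(row), "\\s+")[[1]]
    if (length(f) < 6L) {
      abort(sprintf("%s: malformed ATOM record at line %d (need >= 6 fields)",
                    path, at_sec$line0 + i), class = "somkit_parse_error")
    }
    idx <- suppressWarnings(as.integer(f[1]))
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (is.na(idx) || anyNA(xyz)) {
      abort(sprintf("%s: malformed ATOM record at line %d", path, at_sec$line0 + i),
            class = "somkit_parse_error")
    }
    chg <- if (length(f) >= 9L) suppressWarnings(as.numeric(f[9])) else NA_real_
    tibble(index = idx, name = f[2], x = xyz[1], y = xyz[2], z = xyz[3],
           sybyl_type = f[6], charge = chg)
  })
  atoms <- bind_rows(atoms)
  bd_sec <- section("BOND")
  bonds <- if (is.null(bd_sec) || length(bd_sec$rows) == 0L) {
    tibble(from = integer(), to = integer())
  } else {
    parsed <- map2(bd_sec$rows, seq_along(bd_sec$rows), function(row, i) {
      f <- strsplit(trimws(row), "\\s+")[[1]]
      ft <- suppressWarnings(as.integer(f[2:3]))
      if (length(f) < 4L || anyNA(ft)) {
        abort(sprintf("%s: malformed BOND record at line %d", path, bd_sec$line0 + i),
              class = "somkit_parse_error")
      }
      tibble(from = ft[1], to = ft[2])
    })
    bind_rows(parsed)
  }
  som_molecule(mol_id, atoms, bonds)
}

#' Write molecules to a TRIPOS mol2 file
#'
#' Emits minimal MOLECULE/ATOM/BOND blocks. The atom/bond graph (mol_id, atom
#' order, SYBYL types, bonds) round-trips losslessly through [read_mol2()];
#' coordinates and charges are written as parsed (0 where absent) and bond
#' types are written as single bonds (bond order is not used by the method).
#'
#' @param mols A `som_mol` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(mols, path) {
  if (inherits(mols, "som_mol")) mols <- list(mols)
  out <- unlist(map(mols, function(m) {
    a <- m$atoms
    x <- a[["x"]] %||% rep(0, nrow(a)); y <- a[["y"]] %||% rep(0, nrow(a))
    z <- a[["z"]] %||% rep(0, nrow(a))
    nmv <- a[["name"]] %||% paste0(a$element, a$index)
    chg <- a[["charge"]] %||% rep(NA_real_, nrow(a))
    chg[is.na(chg)] <- 0
    c(
      "@<TRIPOS>MOLECULE",
      m$mol_id,
      sprintf("%d %d 0 0 0", nrow(a), nrow(m$bonds)),
      "SMALL",
      "USER_CHARGES",
      "@<TRIPOS>ATOM",
      sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.4f",
              a$index, nmv, x, y, z, a$sybyl_type, 1L, "LIG", chg),
      "@<TRIPOS>BOND",
      if (nrow(m$bonds) > 0L)
        sprintf("%6d %5d %5d %s", seq_len(nrow(m$bonds)),
                m$bonds$from, m$bonds$to, "1")
    )
  }))
  readr::write_lines(out, path)
  invisible(path)
}
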