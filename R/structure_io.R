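#' Read a PDB file
#'
#' Minimal fixed-column parser for ATOM/HETATM records (PDB format v3.3).
#' Alternate locations are resolved at read time: for each atom the highest
#' occupancy altloc is kept, ties broken in favour of altloc "A" (then
#' alphabetically). Insertion codes are retained as part of the residue
#' identity. Multi-model files: `model = NULL` reads the first model; use
#' [read_pdb_trajectory()] to read all models as a trajectory.
#'
#' @param path Path to a PDB file.
#' @param model Integer model number to read, or `NULL` for the first.
#' @return An object of class `gpcr_structure`: a list with an `atoms`
#'   data frame (`record`, `serial`, `name`, `altloc`, `resname`, `chain`,
#'   `resnum`, `icode`, `x`, `y`, `z`, `occupancy`, `element`) and `source`.
#' @export
read_pdb <- function(path, model = NULL) {
  if (!file.exists(path))
    gpcr_abort(sprintf("PDB file not found: %s", path), "gpcrstates_io_error")
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  idx <- if (is.null(model)) 1L else match(model, as.integer(names(models)))
  if (is.na(idx) || idx > length(models))
    gpcr_abort(sprintf("model %s not present in %s", model, path),
               "gpcrstates_io_error")
  atoms <- parse_atom_lines(models[[idx]])
  new_structure(atoms, source = path)
}

# returns a named list of character vectors, one per MODEL (or one unnamed
# block for single-model files)
split_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL "))
  if (length(model_starts) == 0L) {
    out <- list(lines[is_atom])
    names(out) <- "1"
    return(out)
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  out <- vector("list", length(model_starts))
  nm <- character(length(model_starts))
  for (k in seq_along(model_starts)) {
    span <- model_starts[k]:model_ends[k]
    out[[k]] <- lines[span][is_atom[span]]
    nm[k] <- trimws(substr(lines[model_starts[k]], 7, 80))
  }
  names(out) <- ifelse(nzchar(nm), nm, as.character(seq_along(out)))
  out
}

parse_atom_lines <- function(lines) {
  if (length(lines) == 0L)
    gpcr_abort("no ATOM/HETATM records found", "gpcrstates_io_error")
  sub_ <- function(a, b) trimws(substr(lines, a, b))
  atoms <- data.frame(
    record = sub_(1, 6),
    serial = suppressWarnings(as.integer(sub_(7, 11))),
    name = sub_(13, 16),
    altloc = substr(lines, 17, 17),
    resname = sub_(18, 20),
    chain = substr(lines, 22, 22),
    resnum = suppressWarnings(as.integer(sub_(23, 26))),
    icode = substr(lines, 27, 27),
    x = suppressWarnings(as.numeric(sub_(31, 38))),
    y = suppressWarnings(as.numeric(sub_(39, 46))),
    z = suppressWarnings(as.numeric(sub_(47, 54))),
    occupancy = suppressWarnings(as.numeric(sub_(55, 60))),
    element = sub_(77, 78),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    gpcr_abort("unparseable coordinates in ATOM/HETATM record",
               "gpcrstates_parse_error")
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  # infer element from the atom name when column 77-78 is blank
  blank <- !nzchar(atoms$element)
  if (any(blank))
    atoms$element[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                atoms$name[blank])
  atoms$element <- toupper(atoms$element)
  resolve_altlocs(atoms)
}

# one location per atom: highest occupancy, ties -> altloc "A"/alphabetical
resolve_altlocs <- function(atoms) {
  has_alt <- atoms$altloc != " "
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$record, atoms$chain, atoms$resnum, atoms$icode,
               atoms$resname, atoms$name)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(paste(atoms$record, atoms$chain, atoms$resnum,
                            atoms$icode, atoms$resname, atoms$name))
  atoms <- atoms[keep, , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

new_structure <- function(atoms, source = "memory") {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "gpcr_structure")
}

#' @export
print.gpcr_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure> %d atoms, %d residues, chains: %s (source: %s)\n",
              nrow(a),
              length(unique(paste(a$chain, a$resnum, a$icode))),
              paste(unique(a$chain), collapse = ""), x$source))
  invisible(x)
}

#' Write a structure (or trajectory) to a PDB file
#'
#' @param x A `gpcr_structure`, or a `gpcr_trajectory` (written as a
#'   multi-MODEL file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "gpcr_trajectory")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(format_atom_lines(frame_structure(x, i)$atoms), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  stopifnot(inherits(x, "gpcr_structure"))
  writeLines(c(format_atom_lines(x$atoms), "END"), path)
  invisible(path)
}

format_atom_lines <- function(a) {
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, a$serial %% 100000L, name4,
          ifelse(a$altloc == "", " ", a$altloc),
          a$resname, a$chain, a$resnum %% 10000L,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occupancy, 0, a$element)
}

#' Select the atoms of one residue
#'
#' @param structure A `gpcr_structure`.
#' @param ref A `gpcr_residue_ref` (or a list with `chain` and `resnum`).
#' @return The rows of `structure$atoms` belonging to the residue.
#' @export
residue_atoms <- function(structure, ref) {
  a <- structure$atoms
  sel <- a$chain == ref$chain & a$resnum == ref$resnum & a$record == "ATOM"
  if (!is.null(ref$icode) && !is.na(ref$icode) && nzchar(trimws(ref$icode)))
    sel <- sel & a$icode == ref$icode
  a[sel, , drop = FALSE]
}
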