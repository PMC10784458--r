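BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Load a residue-pair list
#'
#' One pair of generic labels per line (`"5x62 6x37"`); `#` starts a
#' comment. The line order defines descriptor component order.
#'
#' @param path Path to the pair file.
#' @param name Free-text name of the list.
#' @return A `gpcr_pairlist`: data frame with columns `a`, `b` and a
#'   `name` attribute. Pair labels print as `"a:b"`.
#' @export
load_pairs <- function(path, name = basename(path)) {
  if (!file.exists(path))
    gpcr_abort(sprintf("pair file not found: %s", path), "gpcrstates_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(fields) != 2L
  if (any(bad))
    gpcr_abort(sprintf("pair line must have two labels: '%s'",
                       lines[which(bad)[1]]), "gpcrstates_parse_error")
  a <- vapply(fields, function(f) as_label_string(f[1]), character(1))
  b <- vapply(fields, function(f) as_label_string(f[2]), character(1))
  as_pairlist(data.frame(a = a, b = b, stringsAsFactors = FALSE), name)
}

#' Construct a pair list from a data frame
#' @param pairs Data frame with character columns `a` and `b`.
#' @param name Free-text name.
#' @return A `gpcr_pairlist`.
#' @export
as_pairlist <- function(pairs, name = "user") {
  stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)))
  a <- vapply(as.character(pairs$a), as_label_string, character(1), USE.NAMES = FALSE)
  b <- vapply(as.character(pairs$b), as_label_string, character(1), USE.NAMES = FALSE)
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  if (anyDuplicated(key))
    gpcr_abort(sprintf("duplicate unordered pair(s): %s",
                       paste(unique(key[duplicated(key)]), collapse = ", ")),
               "gpcrstates_validation_error")
  structure(data.frame(a = a, b = b, stringsAsFactors = FALSE),
            name = name, class = c("gpcr_pairlist", "data.frame"))
}

#' The default activation-pathway pair list
#'
#' Thirty-eight residue pairs spanning the class A activation pathway:
#' TM5/TM6 packing and the G-protein coupling region, the hydrophobic
#' lock, the PIF and CWxP motifs, the sodium pocket, NPxxY and DRY. The
#' list ships as a plain-text file under `extdata` and is user-replaceable;
#' no code assumes its length.
#'
#' @return A `gpcr_pairlist` of 38 pairs.
#' @export
default_pairs <- function() {
  load_pairs(system.file("extdata", "activation_pairs.txt",
                         package = "gpcrstates"),
             name = "activation-pathway-38")
}

pair_labels <- function(pairs) paste(pairs$a, pairs$b, sep = ":")

#' @export
print.gpcr_pairlist <- function(x, ...) {
  cat(sprintf("<pair list> %s: %d pairs\n", attr(x, "name"), nrow(x)))
  invisible(x)
}

#' Geometric center of a residue side chain
#'
#' Unweighted centroid of the side-chain heavy atoms (everything except
#' backbone N, CA, C, O, OXT and all hydrogens). Glycine, having no
#' side-chain heavy atom, falls back to its CA position.
#'
#' @param structure A `gpcr_structure`.
#' @param residue A `gpcr_residue_ref` from [resolve_residue()].
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
sidechain_center <- function(structure, residue) {
  atoms <- residue_atoms(structure, residue)
  idx <- sidechain_rows(atoms)
  if (is.null(idx))
    gpcr_abort(sprintf("degenerate residue %s%d: no side-chain heavy atoms and no CA",
                       residue$chain, residue$resnum),
               "gpcrstates_degenerate_residue")
  colMeans(as.matrix(atoms[idx, c("x", "y", "z"), drop = FALSE]))
}

# rows of `atoms` (one residue) entering the side-chain centroid; NULL if
# the residue is degenerate
sidechain_rows <- function(atoms) {
  heavy <- !(atoms$element %in% c("H", "D"))
  side <- heavy & !(atoms$name %in% BACKBONE_ATOMS)
  if (any(side)) return(which(side))
  ca <- which(atoms$name == "CA" & heavy)
  if (length(ca)) ca[1] else NULL
}

#' Side-chain center distance for one residue pair
#'
#' @param structure A `gpcr_structure`.
#' @param mapping A `gpcr_mapping`.
#' @param pair Length-2 character vector (or list of two labels).
#' @return Euclidean distance in Angstrom; symmetric in the pair order.
#' @export
pair_distance <- function(structure, mapping, pair) {
  labs <- vapply(as.list(pair), as_label_string, character(1))
  centers <- lapply(labs, function(l) {
    tryCatch(sidechain_center(structure, resolve_residue(mapping, l, structure)),
             gpcrstates_error = function(e)
               gpcr_abort(sprintf("pair %s: %s", paste(labs, collapse = ":"),
                                  conditionMessage(e)), class(e)[1]))
  })
  sqrt(sum((centers[[1]] - centers[[2]])^2))
}

# Precomputes, for each unique label of `pairs`, the topology atom rows that
# enter its side-chain centroid. Collects ALL failures before erroring so
# the message names every unresolvable pair.
descriptor_index <- function(structure, mapping, pairs) {
  labs <- unique(c(pairs$a, pairs$b))
  groups <- vector("list", length(labs))
  names(groups) <- labs
  errs <- character(0)
  for (l in labs) {
    res <- tryCatch({
      ref <- resolve_residue(mapping, l, structure)
      atoms <- residue_atoms(structure, ref)
      idx <- sidechain_rows(atoms)
      if (is.null(idx))
        gpcr_abort(sprintf("degenerate residue for label %s", l),
                   "gpcrstates_degenerate_residue")
      # convert to row numbers in the full atom table
      which(structure$atoms$chain == ref$chain &
              structure$atoms$resnum == ref$resnum &
              structure$atoms$record == "ATOM")[idx]
    }, gpcrstates_error = function(e) e)
    if (inherits(res, "condition")) {
      bad <- pair_labels(pairs)[pairs$a == l | pairs$b == l]
      errs <- c(errs, sprintf("%s (%s)", paste(bad, collapse = ", "),
                              conditionMessage(res)))
    } else groups[[l]] <- res
  }
  if (length(errs))
    gpcr_abort(paste0("unresolvable pair(s): ", paste(errs, collapse = "; ")),
               "gpcrstates_unresolvable_pairs")
  groups
}

# distances for one coordinate matrix given a descriptor_index
distances_from_groups <- function(xyz, groups, pairs) {
  centers <- t(vapply(groups, function(idx)
    colMeans(xyz[idx, , drop = FALSE]), numeric(3)))
  d <- sqrt(rowSums((centers[pairs$a, , drop = FALSE] -
                       centers[pairs$b, , drop = FALSE])^2))
  names(d) <- pair_labels(pairs)
  d
}

#' Extract the conformational descriptor of a structure
#'
#' The descriptor is the ordered vector of side-chain-center distances, one
#' per configured residue pair, in pair-list order.
#'
#' @param structure A `gpcr_structure` (or one trajectory frame via
#'   [frame_structure()]).
#' @param mapping A `gpcr_mapping` covering every label in `pairs`.
#' @param pairs A `gpcr_pairlist`.
#' @param frame Integer frame index recorded on the descriptor.
#' @return A `gpcr_descriptor`: named numeric vector (names are
#'   `"a:b"` pair labels) with `frame` and `source` attributes.
#' @export
extract_descriptor <- function(structure, mapping, pairs = default_pairs(),
                               frame = 0L) {
  groups <- descriptor_index(structure, mapping, pairs)
  d <- distances_from_groups(as.matrix(structure$atoms[, c("x", "y", "z")]),
                             groups, pairs)
  base::structure(d, frame = as.integer(frame), source = structure$source,
                  class = "gpcr_descriptor")
}

#' Descriptor matrix of a whole trajectory
#'
#' @param trajectory A `gpcr_trajectory`.
#' @param mapping A `gpcr_mapping`.
#' @param pairs A `gpcr_pairlist`.
#' @return Numeric matrix `frames x pairs`, columns named by pair label.
#' @export
descriptor_matrix <- function(trajectory, mapping, pairs = default_pairs()) {
  groups <- descriptor_index(trajectory$topology, mapping, pairs)
  nfr <- n_frames(trajectory)
  out <- matrix(NA_real_, nfr, nrow(pairs),
                dimnames = list(NULL, pair_labels(pairs)))
  for (i in seq_len(nfr)) {
    xyz <- trajectory$coords[i, , , drop = TRUE]
    dim(xyz) <- c(dim(trajectory$coords)[2], 3)
    out[i, ] <- distances_from_groups(xyz, groups, pairs)
  }
  out
}

#' Write descriptors to CSV
#'
#' Header row of pair labels preceded by a `frame` column, one row per
#' frame.
#'
#' @param mat Matrix from [descriptor_matrix()] (or a single descriptor).
#' @param path Output path.
#' @param frames Frame indices for the first column.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(mat, path, frames = seq_len(nrow(mat))) {
  if (is.null(dim(mat))) mat <- matrix(mat, 1, dimnames = list(NULL, names(mat)))
  df <- data.frame(frame = frames, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a descriptor CSV written by [write_descriptor_csv()]
#' @param path CSV path.
#' @return Matrix `frames x pairs` with a `frames` attribute.
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  attr(m, "frames") <- df$frame
  m
}
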