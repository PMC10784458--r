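#' Parse a GPCRdb generic residue label
#'
#' GPCRdb generic numbers have the form `"SxNN"` where `S` is the
#' transmembrane helix (1-7) or helix 8, and `NN` is the position index
#' relative to the helix's most conserved residue, which is assigned
#' position 50. Both the ASCII `"x"` and the typographic multiplication
#' sign are accepted as separators; the canonical printed form uses `"x"`.
#'
#' @param text A label string such as `"5x62"` or `"3x50"`.
#' @return An object of class `gpcr_generic_label` with fields `segment`
#'   (integer 1-8) and `position` (integer 1-99).
#' @examples
#' parse_generic_label("5x62")
#' format(parse_generic_label("7×53"))  # "7x53"
#' @export
parse_generic_label <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    gpcr_abort("generic label must be a single string", "gpcrstates_parse_error")
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^([0-9]+)[x×]([0-9]+)$", txt))[[1]]
  if (length(m) != 3L)
    gpcr_abort(sprintf("malformed generic label '%s' (expected 'SxNN')", txt),
               "gpcrstates_parse_error")
  seg <- as.integer(m[2]); pos <- as.integer(m[3])
  if (seg < 1L || seg > 8L)
    gpcr_abort(sprintf("segment '%s' outside 1-8 in label '%s'", m[2], txt),
               "gpcrstates_parse_error")
  if (pos < 1L || pos > 99L)
    gpcr_abort(sprintf("position '%s' outside 1-99 in label '%s'", m[3], txt),
               "gpcrstates_parse_error")
  structure(list(segment = seg, position = pos),
            class = "gpcr_generic_label")
}

#' @export
format.gpcr_generic_label <- function(x, ...) {
  sprintf("%dx%02d", x$segment, x$position)
}

#' @export
print.gpcr_generic_label <- function(x, ...) {
  cat("<generic label>", format(x), "\n")
  invisible(x)
}

# accepts either a label object or a string; returns the canonical string
as_label_string <- function(label) {
  if (inherits(label, "gpcr_generic_label")) return(format(label))
  format(parse_generic_label(label))
}

#' Load a generic-label to residue mapping table
#'
#' Reads a whitespace- or tab-separated text file with columns
#' `generic_label resnum [chain] [resname]`; lines starting with `#` are
#' comments. The mapping bridges GPCRdb generic numbers to author residue
#' numbers of one concrete structure.
#'
#' @param path Path to the mapping file.
#' @param receptor Free-text receptor identifier attached to the mapping.
#' @return An object of class `gpcr_mapping`: a data frame with columns
#'   `label`, `resnum`, `chain`, `resname` plus `receptor`/`source`
#'   attributes.
#' @export
load_mapping <- function(path, receptor = basename(path)) {
  if (!file.exists(path))
    gpcr_abort(sprintf("mapping file not found: %s", path), "gpcrstates_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(new_mapping(data.frame(label = character(), resnum = integer(),
                                  chain = character(), resname = character(),
                                  stringsAsFactors = FALSE),
                       receptor, path))
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    gpcr_abort(sprintf("mapping line with fewer than 2 columns: '%s'",
                       lines[which(nf < 2L)[1]]), "gpcrstates_parse_error")
  lab <- vapply(fields, function(f) as_label_string(f[1]), character(1))
  resnum <- vapply(fields, function(f) {
    v <- suppressWarnings(as.integer(f[2]))
    if (is.na(v)) gpcr_abort(sprintf("non-numeric residue number '%s'", f[2]),
                             "gpcrstates_parse_error")
    v
  }, integer(1))
  chain <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                  character(1))
  resname <- vapply(fields, function(f) if (length(f) >= 4) toupper(f[4]) else NA_character_,
                    character(1))
  if (anyDuplicated(lab))
    gpcr_abort(sprintf("duplicate generic label(s) in mapping: %s",
                       paste(unique(lab[duplicated(lab)]), collapse = ", ")),
               "gpcrstates_validation_error")
  new_mapping(data.frame(label = lab, resnum = resnum, chain = chain,
                         resname = resname, stringsAsFactors = FALSE),
              receptor, path)
}

#' Construct a mapping from a data frame
#'
#' Programmatic counterpart of [load_mapping()].
#'
#' @param entries Data frame with columns `label`, `resnum` and optionally
#'   `chain`, `resname`.
#' @param receptor,source Free-text provenance fields.
#' @return A `gpcr_mapping` object.
#' @export
as_mapping <- function(entries, receptor = "unknown", source = "user") {
  stopifnot(is.data.frame(entries), all(c("label", "resnum") %in% names(entries)))
  lab <- vapply(as.character(entries$label), as_label_string, character(1),
                USE.NAMES = FALSE)
  if (anyDuplicated(lab))
    gpcr_abort("duplicate generic label(s) in mapping entries",
               "gpcrstates_validation_error")
  new_mapping(data.frame(
    label = lab,
    resnum = as.integer(entries$resnum),
    chain = if ("chain" %in% names(entries)) as.character(entries$chain) else NA_character_,
    resname = if ("resname" %in% names(entries)) toupper(as.character(entries$resname)) else NA_character_,
    stringsAsFactors = FALSE), receptor, source)
}

new_mapping <- function(df, receptor, source) {
  structure(df, receptor = receptor, source = source,
            class = c("gpcr_mapping", "data.frame"))
}

#' @export
print.gpcr_mapping <- function(x, ...) {
  cat(sprintf("<residue mapping> receptor: %s, %d entries (source: %s)\n",
              attr(x, "receptor"), nrow(x), attr(x, "source")))
  invisible(x)
}

#' Resolve a generic label to a concrete residue of a structure
#'
#' Looks the label up in the mapping and verifies that the mapped residue
#' exists in the structure with at least one atom. When the mapping carries
#' no chain, the structure must have exactly one protein chain; ambiguous
#' multi-chain structures require an explicit chain column in the mapping.
#'
#' @param mapping A `gpcr_mapping`.
#' @param label A generic label (string or `gpcr_generic_label`).
#' @param structure A structure from [read_pdb()].
#' @return A `gpcr_residue_ref` list with `chain`, `resnum`, `resname`,
#'   `label` fields.
#' @export
resolve_residue <- function(mapping, label, structure) {
  lab <- as_label_string(label)
  i <- match(lab, mapping$label)
  if (is.na(i))
    gpcr_abort(sprintf("unmapped label '%s' (receptor %s)", lab,
                       attr(mapping, "receptor")), "gpcrstates_unmapped_label")
  chain <- mapping$chain[i]
  if (is.na(chain)) {
    chains <- unique(structure$atoms$chain[structure$atoms$record == "ATOM"])
    if (length(chains) != 1L)
      gpcr_abort(sprintf(
        "label '%s' has no chain in the mapping and the structure has %d protein chains (%s)",
        lab, length(chains), paste(chains, collapse = ", ")),
        "gpcrstates_validation_error")
    chain <- chains
  }
  resnum <- mapping$resnum[i]
  sel <- structure$atoms$chain == chain & structure$atoms$resnum == resnum &
    structure$atoms$record == "ATOM"
  if (!any(sel))
    gpcr_abort(sprintf("missing residue: chain %s residue %d (label %s) not in structure",
                       chain, resnum, lab), "gpcrstates_missing_residue")
  base::structure(list(chain = chain, resnum = resnum,
                       resname = structure$atoms$resname[which(sel)[1]],
                       label = lab),
                  class = "gpcr_residue_ref")
}
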