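#' Score every frame of a trajectory
#'
#' @param model A `gpcr_state_model`.
#' @param trajectory A `gpcr_trajectory`.
#' @param mapping A `gpcr_mapping` covering the model's pairs.
#' @param pairs Pair list; must reproduce the model's descriptor layout
#'   (defaults to the model's own stored pair list).
#' @return A `gpcr_score_series` data frame: `frame`, `time`, `score`,
#'   `smoothed` (equal to `score` until [smooth_scores()] is applied),
#'   with a `window` attribute.
#' @export
score_trajectory <- function(model, trajectory, mapping, pairs = NULL) {
  pairs <- pairs %||% model$pairlist
  mat <- descriptor_matrix(trajectory, mapping, pairs)
  sc <- score_state_model(model, mat)
  new_score_series(sc, trajectory$times)
}

new_score_series <- function(scores, times, smoothed = scores, window = 1L) {
  base::structure(data.frame(frame = seq_along(scores), time = times,
                             score = scores, smoothed = smoothed),
                  window = as.integer(window),
                  class = c("gpcr_score_series", "data.frame"))
}

#' Smooth a score series with a centered moving average
#'
#' The window must be odd; edges average over the truncated window (the
#' frames actually available). Smoothing is for reporting only - frame
#' classification always uses the raw scores.
#'
#' @param series A `gpcr_score_series`.
#' @param window Odd integer window length (default 5 consecutive frames).
#' @return The series with its `smoothed` column and `window` attribute
#'   updated.
#' @export
smooth_scores <- function(series, window = 5L) {
  if (window < 1L || window %% 2L == 0L)
    gpcr_abort(sprintf("smoothing window must be odd and >= 1, got %d", window),
               "gpcrstates_validation_error")
  n <- nrow(series)
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(series$score[lo:hi])
  }, numeric(1))
  new_score_series(series$score, series$time, sm, window)
}

#' Classify frames by score threshold
#'
#' A frame is active iff its raw score is strictly greater than `theta`.
#' The default threshold 0.375 is the operating point used for
#' trajectory-level annotation; boundary frames (score exactly `theta`)
#' are inactive.
#'
#' @param series A `gpcr_score_series` (or a bare numeric score vector).
#' @param theta Frame threshold in `[0, 1]`.
#' @return Character vector of `"active"` / `"inactive"` per frame.
#' @export
classify_frames <- function(series, theta = 0.375) {
  if (theta < 0 || theta > 1)
    gpcr_abort("theta must lie in [0, 1]", "gpcrstates_validation_error")
  sc <- if (is.data.frame(series)) series$score else as.numeric(series)
  ifelse(sc > theta, "active", "inactive")
}

#' Classify a whole trajectory from its frame labels
#'
#' The trajectory is active iff the ratio of active frames is strictly
#' greater than `delta`; a ratio exactly equal to `delta` is inactive.
#'
#' @param frame_labels Character vector from [classify_frames()].
#' @param delta Trajectory threshold in `[0, 1]` (default 0.5).
#' @param theta The frame threshold used upstream, recorded for the
#'   report.
#' @return A `gpcr_verdict` list: `ratio`, `theta`, `delta`, `verdict`,
#'   `n_frames`.
#' @export
classify_trajectory <- function(frame_labels, delta = 0.5, theta = 0.375) {
  if (length(frame_labels) == 0L)
    gpcr_abort("cannot classify an empty trajectory",
               "gpcrstates_validation_error")
  if (delta < 0 || delta > 1)
    gpcr_abort("delta must lie in [0, 1]", "gpcrstates_validation_error")
  ratio <- mean(frame_labels == "active")
  base::structure(list(ratio = ratio, theta = theta, delta = delta,
                       verdict = if (ratio > delta) "active" else "inactive",
                       n_frames = length(frame_labels)),
                  class = "gpcr_verdict")
}

#' @export
print.gpcr_verdict <- function(x, ...) {
  cat(sprintf("<trajectory verdict> %s (active ratio %.3f, theta %.3f, delta %.3f, %d frames)\n",
              x$verdict, x$ratio, x$theta, x$delta, x$n_frames))
  invisible(x)
}

# ---- binding-site analysis --------------------------------------------------

#' Define a binding site from reference structures
#'
#' Takes the union, over the reference structures, of receptor residues
#' having any heavy atom within `cutoff` of any heavy atom of the selected
#' reference entity (a ligand, or the G-alpha helix selection).
#'
#' @param references A list of `gpcr_structure` objects (or one).
#' @param selector Entity selector list: `kind` (`"ligand"` selects
#'   HETATM records, waters excluded; `"g-protein"` selects ATOM records
#'   of the given chain), plus optional `resname` (restrict by residue
#'   name), `chain`, `resnum_range` (length-2 for helix spans).
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @param mapping Optional `gpcr_mapping`; site residues are reported as
#'   generic labels where mapped, `chain:resnum` otherwise.
#' @param receptor_chain Restrict receptor residues to this chain.
#' @return A `gpcr_binding_site` list: `kind`, `cutoff`, `residues` (data
#'   frame with `chain`, `resnum`, `resname`, `label`), `n_references`.
#' @export
define_binding_site <- function(references, selector, cutoff = 8,
                                mapping = NULL, receptor_chain = NULL) {
  if (inherits(references, "gpcr_structure")) references <- list(references)
  kind <- selector$kind %||% "ligand"
  if (!kind %in% c("ligand", "g-protein"))
    gpcr_abort("selector kind must be 'ligand' or 'g-protein'",
               "gpcrstates_validation_error")
  found <- list()
  for (s in references) {
    a <- s$atoms
    heavy <- !(a$element %in% c("H", "D"))
    ent <- if (kind == "ligand") {
      a$record == "HETATM" & !(a$resname %in% c("HOH", "WAT")) & heavy
    } else {
      a$record == "ATOM" & heavy
    }
    if (!is.null(selector$chain)) ent <- ent & a$chain %in% selector$chain
    if (!is.null(selector$resname)) ent <- ent & a$resname %in% selector$resname
    if (!is.null(selector$resnum_range))
      ent <- ent & a$resnum >= selector$resnum_range[1] &
        a$resnum <= selector$resnum_range[2]
    if (!any(ent))
      gpcr_abort(sprintf("entity selector matches nothing in %s", s$source),
                 "gpcrstates_validation_error")
    rec <- a$record == "ATOM" & heavy & !ent
    if (!is.null(receptor_chain)) rec <- rec & a$chain %in% receptor_chain
    exy <- as.matrix(a[ent, c("x", "y", "z")])
    rxy <- as.matrix(a[rec, c("x", "y", "z")])
    # squared-distance test of every receptor heavy atom against the entity
    d2min <- apply(rxy, 1, function(r)
      min(colSums((t(exy) - r)^2)))
    hit <- d2min <= cutoff^2
    res <- unique(a[rec, c("chain", "resnum", "resname")][hit, , drop = FALSE])
    found[[length(found) + 1L]] <- res
  }
  residues <- unique(do.call(rbind, found))
  if (is.null(residues) || nrow(residues) == 0L)
    gpcr_abort(sprintf("empty site: no residue within %g A of the %s entity",
                       cutoff, kind), "gpcrstates_empty_site")
  residues <- residues[order(residues$chain, residues$resnum), , drop = FALSE]
  rownames(residues) <- NULL
  residues$label <- sprintf("%s:%d", residues$chain, residues$resnum)
  if (!is.null(mapping)) {
    m <- match(residues$resnum, mapping$resnum)
    hitm <- !is.na(m) & (is.na(mapping$chain[m]) |
                           mapping$chain[m] == residues$chain)
    residues$label[hitm] <- mapping$label[m[hitm]]
  }
  base::structure(list(kind = kind, cutoff = cutoff, residues = residues,
                       n_references = length(references)),
                  class = "gpcr_binding_site")
}

#' @export
print.gpcr_binding_site <- function(x, ...) {
  cat(sprintf("<binding site> kind: %s, cutoff %g A, %d residues (%d reference structures)\n",
              x$kind, x$cutoff, nrow(x$residues), x$n_references))
  invisible(x)
}

#' Write / read a binding-site definition as JSON
#' @param site A `gpcr_binding_site`.
#' @param path JSON path.
#' @return `path` (write) or the site (read).
#' @export
write_binding_site <- function(site, path) {
  writeLines(jsonlite::toJSON(list(kind = site$kind, cutoff = site$cutoff,
                                   residues = site$residues),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_binding_site
#' @export
read_binding_site <- function(path) {
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  base::structure(list(kind = x$kind, cutoff = x$cutoff,
                       residues = as.data.frame(x$residues),
                       n_references = NA_integer_),
                  class = "gpcr_binding_site")
}

# CA coordinates of the site residues in a structure, matched by
# chain/resnum (or via an optional mapping when labels are generic)
site_ca_coords <- function(structure, site, mapping = NULL) {
  a <- structure$atoms
  out <- matrix(NA_real_, nrow(site$residues), 3)
  missing <- character(0)
  for (i in seq_len(nrow(site$residues))) {
    ch <- site$residues$chain[i]; rn <- site$residues$resnum[i]
    if (!is.null(mapping) && grepl("^[0-9]+x[0-9]+$", site$residues$label[i])) {
      j <- match(site$residues$label[i], mapping$label)
      if (!is.na(j)) {
        rn <- mapping$resnum[j]
        if (!is.na(mapping$chain[j])) ch <- mapping$chain[j]
      }
    }
    sel <- a$chain == ch & a$resnum == rn & a$name == "CA" & a$record == "ATOM"
    if (!any(sel)) {
      missing <- c(missing, sprintf("%s:%d", ch, rn))
    } else {
      out[i, ] <- unlist(a[which(sel)[1], c("x", "y", "z")])
    }
  }
  if (length(missing))
    gpcr_abort(sprintf("site residue(s) unresolvable in %s: %s",
                       structure$source, paste(missing, collapse = ", ")),
               "gpcrstates_missing_residue")
  out
}

# Kabsch least-squares superposition: optimal rotation of P onto Q
kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  diffs <- Pc %*% R - Qc
  sqrt(sum(diffs^2) / nrow(P))
}

#' Binding-site RMSD between two structures
#'
#' Least-squares (Kabsch) superposition on the site residues' CA atoms,
#' then RMSD over the same CA set. Symmetric in its two structure
#' arguments.
#'
#' @param frame,reference `gpcr_structure` objects containing every site
#'   residue.
#' @param site A `gpcr_binding_site`.
#' @param mapping_frame,mapping_reference Optional mappings used to
#'   resolve generic-label site residues in either structure.
#' @return RMSD in Angstrom (>= 0; 0 for identical coordinates).
#' @export
binding_site_rmsd <- function(frame, reference, site,
                              mapping_frame = NULL, mapping_reference = NULL) {
  P <- site_ca_coords(frame, site, mapping_frame)
  Q <- site_ca_coords(reference, site, mapping_reference)
  kabsch_rmsd(P, Q)
}

#' Compare binding-site RMSD distributions of two frame groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the null hypothesis
#' that RMSD values of active-labelled and inactive-labelled frames come
#' from the same distribution, plus group medians.
#'
#' @param rmsd_active,rmsd_inactive Non-empty numeric vectors.
#' @return List: `p_value`, `median_active`, `median_inactive`,
#'   `statistic` (the U statistic).
#' @export
compare_rmsd_groups <- function(rmsd_active, rmsd_inactive) {
  if (length(rmsd_active) == 0L || length(rmsd_inactive) == 0L)
    gpcr_abort("both RMSD groups must be non-empty",
               "gpcrstates_validation_error")
  wt <- suppressWarnings(stats::wilcox.test(rmsd_active, rmsd_inactive,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(p_value = unname(wt$p.value),
       median_active = stats::median(rmsd_active),
       median_inactive = stats::median(rmsd_inactive),
       statistic = unname(wt$statistic))
}

#' Delta-sweep report of trajectory classification accuracy
#'
#' For a set of scored trajectories with known state annotations, sweeps
#' the trajectory threshold delta and reports classification accuracy at
#' each value - the desk-scale counterpart of large-scale database
#' sweeps.
#'
#' @param ratios Numeric vector of active-frame ratios, one per
#'   trajectory.
#' @param truth Character vector of true trajectory states.
#' @param deltas Thresholds to evaluate.
#' @return Data frame `delta`, `accuracy`.
#' @export
delta_sweep <- function(ratios, truth, deltas = seq(0, 1, by = 0.05)) {
  stopifnot(length(ratios) == length(truth))
  acc <- vapply(deltas, function(d)
    mean(ifelse(ratios > d, "active", "inactive") == truth), numeric(1))
  data.frame(delta = deltas, accuracy = acc)
}
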