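# Synthetic GPCR-like ensembles with known ground truth. Geometry is not
# physical: pseudo-residues are small clusters of dummy heavy atoms laid out
# so that the descriptor separates the two states by construction, imitating
# the outward TM6 swing (the geometric hallmark of activation).

RESIDUE_PATTERNS <- list(
  list(resname = "GLY", side = NULL),                       # CA fallback
  list(resname = "ALA", side = rbind(CB = c(0, 0, 0))),     # single atom
  list(resname = "SER", side = rbind(CB = c(0.7, 0, 0),
                                     OG = c(-0.7, 0, 0))),
  list(resname = "LEU", side = rbind(CB = c(0.8, 0, 0),
                                     CG = c(-0.4, 0.6928, 0),
                                     CD1 = c(-0.4, -0.6928, 0))),
  list(resname = "LYS", side = rbind(CB = c(0.7, 0, 0),
                                     CG = c(-0.7, 0, 0),
                                     CD = c(0, 0.7, 0),
                                     CE = c(0, -0.7, 0))))

#' Build active/inactive template structures for a pair list
#'
#' Constructs two coordinate sets over the same pseudo-residue roster
#' (every label of the pair list) such that every TM6-involving pair
#' distance differs by at least `separation` between the templates while
#' all other pair distances are identical. The inactive template displaces
#' the TM6 residues rigidly, imitating the outward TM6 movement; the
#' anchor pair (by default 5x62:6x37) sits at `anchor_distance` in the
#' active template and `anchor_distance + separation` in the inactive one,
#' reproducing the familiar ~6 vs ~15 Angstrom TM5/TM6 motif when
#' `separation = 9`.
#'
#' Pseudo-residues cycle through 1-5 heavy side-chain atoms (including a
#' glycine pattern exercising the CA fallback); side-chain atom offsets
#' sum to zero so each side-chain centroid equals the residue center
#' exactly.
#'
#' @param pairs A `gpcr_pairlist` containing at least one pair involving
#'   helix 6.
#' @param separation Minimum active/inactive distance difference
#'   (Angstrom) for TM6-involving pairs; must be > 0.
#' @param anchor_distance Active-template distance of the anchor pair;
#'   defaults to `2/3 * separation` (6 Angstrom when `separation = 9`).
#' @return List with `active` and `inactive` (`gpcr_structure`),
#'   `mapping` (`gpcr_mapping`), `pairs`, `anchor` (the anchor pair
#'   label), `tm6_shift` (the applied displacement in Angstrom).
#' @export
make_templates <- function(pairs, separation = 9,
                           anchor_distance = 2 * separation / 3) {
  stopifnot(separation > 0)
  labels <- unique(c(pairs$a, pairs$b))
  seg <- as.integer(sub("x.*$", "", labels))
  tm6 <- labels[seg == 6L]
  if (!length(tm6))
    gpcr_abort("pair list has no helix-6 label; cannot build a TM6-swing motif",
               "gpcrstates_validation_error")
  involves_tm6 <- (pairs$a %in% tm6) != (pairs$b %in% tm6) # exactly one side
  if (!any(involves_tm6))
    gpcr_abort("no pair couples helix 6 to another segment",
               "gpcrstates_validation_error")
  partners <- unique(c(pairs$a[involves_tm6 & !(pairs$a %in% tm6)],
                       pairs$b[involves_tm6 & !(pairs$b %in% tm6)]))
  anchor_pair <- if ("5x62:6x37" %in% pair_labels(pairs)) {
    c("5x62", "6x37")
  } else {
    i <- which(involves_tm6)[1]
    if (pairs$b[i] %in% tm6) c(pairs$a[i], pairs$b[i])
    else c(pairs$b[i], pairs$a[i])
  }
  others <- setdiff(labels, c(tm6, partners))

  centers <- matrix(NA_real_, length(labels), 3,
                    dimnames = list(labels, NULL))
  # TM6 cluster near the origin, anchor TM6 member exactly at it (z = 0)
  k <- 0L
  for (l in tm6) {
    if (l == anchor_pair[2]) {
      centers[l, ] <- c(0, 0, 0)
    } else {
      # jitter strictly towards the anchor partner (+x) so the anchor pair
      # remains the farthest TM6-involving pair and hits anchor_distance +
      # separation exactly in the inactive template
      k <- k + 1L
      centers[l, ] <- c(0.2, 0.25 * sin(2.1 * k) + 0.02 * k, 0)
    }
  }
  # partners at radius <= anchor_distance around the cluster (z = 0 so the
  # TM6 z-displacement is exactly orthogonal to every TM6-involving pair)
  k <- 0L
  for (l in partners) {
    if (l == anchor_pair[1]) centers[l, ] <- c(anchor_distance, 0, 0)
    else {
      k <- k + 1L
      ang <- 0.9 * k + 0.4
      r <- anchor_distance * (0.55 + 0.08 * (k %% 5))
      centers[l, ] <- c(r * cos(ang), r * sin(ang), 0)
    }
  }
  # remaining residues on a wide ring; their distances never change
  for (i in seq_along(others)) {
    ang <- 2 * pi * i / max(1, length(others))
    centers[others[i], ] <- c((14 + (i %% 4)) * cos(ang),
                              (14 + (i %% 4)) * sin(ang), 3 * (i %% 3))
  }

  active <- build_pseudo_structure(labels, centers, source = "synthetic-active")
  mapping <- template_mapping(labels)
  # displacement giving >= separation for every TM6-involving pair
  d_act <- vapply(which(involves_tm6), function(i)
    sqrt(sum((centers[pairs$a[i], ] - centers[pairs$b[i], ])^2)), numeric(1))
  d_max <- max(d_act)
  dz <- sqrt(separation^2 + 2 * separation * d_max)
  centers_in <- centers
  centers_in[tm6, 3] <- centers_in[tm6, 3] - dz
  inactive <- build_pseudo_structure(labels, centers_in,
                                     source = "synthetic-inactive")
  list(active = active, inactive = inactive, mapping = mapping,
       pairs = pairs, anchor = paste(anchor_pair, collapse = ":"),
       tm6_shift = dz)
}

# lays out one atom record block per pseudo-residue; side-chain centroid
# equals `centers[label, ]` exactly (zero-sum offsets; GLY -> CA at center)
build_pseudo_structure <- function(labels, centers, source) {
  rows <- list()
  serial <- 0L
  for (i in seq_along(labels)) {
    l <- labels[i]
    pat <- RESIDUE_PATTERNS[[(i - 1L) %% length(RESIDUE_PATTERNS) + 1L]]
    ctr <- centers[l, ]
    resnum <- template_resnum(l)
    atoms <- if (is.null(pat$side)) {
      rbind(N = ctr + c(1.3, 0.6, 0.4), CA = ctr,
            C = ctr + c(-1.2, 0.7, 0.3), O = ctr + c(-1.6, 1.4, -0.5))
    } else {
      rbind(N = ctr + c(1.3, 0.6, 1.6), CA = ctr + c(0.9, 0.2, 1.1),
            C = ctr + c(-0.7, 0.9, 1.5), O = ctr + c(-1.1, 1.8, 1.2),
            sweep(pat$side, 2, ctr, "+"))
    }
    for (j in seq_len(nrow(atoms))) {
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        record = "ATOM", serial = serial, name = rownames(atoms)[j],
        altloc = " ", resname = pat$resname, chain = "A", resnum = resnum,
        icode = " ", x = atoms[j, 1], y = atoms[j, 2], z = atoms[j, 3],
        occupancy = 1, element = substr(rownames(atoms)[j], 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows), source = source)
}

template_resnum <- function(label) {
  p <- parse_generic_label(label)
  p$segment * 100L + p$position
}

template_mapping <- function(labels) {
  resname <- vapply(seq_along(labels), function(i)
    RESIDUE_PATTERNS[[(i - 1L) %% length(RESIDUE_PATTERNS) + 1L]]$resname,
    character(1))
  as_mapping(data.frame(label = labels,
                        resnum = vapply(labels, template_resnum, integer(1)),
                        chain = "A", resname = resname,
                        stringsAsFactors = FALSE),
             receptor = "synthetic", source = "make_templates")
}

#' Specify a synthetic conformational ensemble
#'
#' @param n_frames Number of frames.
#' @param interval_ps Snapshot interval in ps (frame t sits at
#'   `t * interval_ps`).
#' @param sigma Per-atom isotropic Gaussian noise (Angstrom); 0.25 by
#'   default (small thermal jitter relative to the 9 Angstrom state
#'   separation).
#' @param lambda Interpolation schedule: scalar or per-frame vector in
#'   `[0, 1]` (0 = inactive template, 1 = active template).
#' @param seed Integer seed.
#' @return A `gpcr_ensemble_spec` list.
#' @export
ensemble_spec <- function(n_frames = 200L, interval_ps = 100,
                          sigma = 0.25, lambda = 1, seed = 1L) {
  stopifnot(n_frames >= 1L, sigma >= 0)
  lambda <- rep_len(lambda, n_frames)
  if (any(lambda < 0 | lambda > 1))
    gpcr_abort("lambda schedule must lie in [0, 1]",
               "gpcrstates_validation_error")
  base::structure(list(n_frames = as.integer(n_frames),
                       interval_ps = interval_ps, sigma = sigma,
                       lambda = lambda, seed = as.integer(seed)),
                  class = "gpcr_ensemble_spec")
}

#' Generate a synthetic conformational ensemble
#'
#' Frame coordinates are `lambda_t * active + (1 - lambda_t) * inactive`
#' plus per-atom Gaussian noise, seeded and reproducible bit-for-bit at
#' the descriptor level. Optionally writes the standard file set
#' (topology PDB, DCD trajectory, mapping table, ground-truth CSV).
#'
#' @param templates Output of [make_templates()].
#' @param spec A `gpcr_ensemble_spec`.
#' @param dir Output directory, or `NULL` to keep everything in memory.
#' @return List: `trajectory` (`gpcr_trajectory`), `mapping`,
#'   `ground_truth` (data frame `frame`, `time_ps`, `lambda`, `state`),
#'   and (when `dir` is given) `files` (named paths).
#' @export
generate_ensemble <- function(templates, spec = ensemble_spec(), dir = NULL) {
  act <- as.matrix(templates$active$atoms[, c("x", "y", "z")])
  ina <- as.matrix(templates$inactive$atoms[, c("x", "y", "z")])
  nat <- nrow(act)
  coords <- array(NA_real_, dim = c(spec$n_frames, nat, 3))
  with_private_seed(spec$seed, {
    for (t in seq_len(spec$n_frames)) {
      base <- spec$lambda[t] * act + (1 - spec$lambda[t]) * ina
      noise <- if (spec$sigma > 0)
        matrix(stats::rnorm(nat * 3, sd = spec$sigma), nat, 3) else 0
      coords[t, , ] <- base + noise
    }
  })
  traj <- new_trajectory(coords, spec$interval_ps * seq_len(spec$n_frames),
                         templates$active, source = "synthetic-ensemble")
  gt <- data.frame(frame = seq_len(spec$n_frames),
                   time_ps = traj$times, lambda = spec$lambda,
                   state = ifelse(spec$lambda >= 0.5, "active", "inactive"))
  out <- list(trajectory = traj, mapping = templates$mapping,
              ground_truth = gt)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(topology = file.path(dir, "topology.pdb"),
               trajectory = file.path(dir, "trajectory.dcd"),
               mapping = file.path(dir, "mapping.txt"),
               ground_truth = file.path(dir, "ground_truth.csv"))
    write_pdb(templates$active, files["topology"])
    write_dcd(traj, files["trajectory"])
    write_mapping(templates$mapping, files["mapping"])
    utils::write.csv(gt, files["ground_truth"], row.names = FALSE,
                     quote = FALSE)
    out$files <- files
  }
  out
}

#' Write a mapping table to its plain-text format
#' @param mapping A `gpcr_mapping`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  lines <- sprintf("%s %d %s %s", mapping$label, mapping$resnum,
                   ifelse(is.na(mapping$chain), "A", mapping$chain),
                   ifelse(is.na(mapping$resname), "UNK", mapping$resname))
  writeLines(c("# generic_label resnum chain resname", lines), path)
  invisible(path)
}

#' Generate a labelled collection of synthetic state ensembles
#'
#' Convenience wrapper producing `build_dataset()`-ready entries:
#' `n_active` trajectories at lambda = 1 and `n_inactive` at lambda = 0,
#' each with its own derived seed.
#'
#' @param n_active,n_inactive Trajectories per state.
#' @param pairs A `gpcr_pairlist`.
#' @param separation,sigma,n_frames,interval_ps Passed through to
#'   [make_templates()] / [ensemble_spec()].
#' @param seed Base seed; trajectory k uses `seed + k`.
#' @return List of entries (`trajectory`, `mapping`, `label`, `id`).
#' @export
generate_state_ensembles <- function(n_active, n_inactive,
                                     pairs = default_pairs(),
                                     separation = 9, sigma = 0.25,
                                     n_frames = 200L, interval_ps = 100,
                                     seed = 1L) {
  tpl <- make_templates(pairs, separation)
  states <- c(rep("active", n_active), rep("inactive", n_inactive))
  lapply(seq_along(states), function(k) {
    sp <- ensemble_spec(n_frames = n_frames, interval_ps = interval_ps,
                        sigma = sigma,
                        lambda = if (states[k] == "active") 1 else 0,
                        seed = seed + k)
    ens <- generate_ensemble(tpl, sp)
    list(trajectory = ens$trajectory, mapping = ens$mapping,
         label = states[k], id = sprintf("%s_%02d", states[k], k))
  })
}
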