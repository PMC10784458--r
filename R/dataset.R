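#' Build a labelled frame dataset from state-annotated trajectories
#'
#' Each trajectory is subsampled according to the plan, featurized with the
#' pair list, and every extracted frame inherits the trajectory's state
#' label (labels come from the starting structure; short production runs
#' are assumed not to cross states, so frames are never relabelled).
#'
#' @param entries List of entries, each a list with fields `trajectory`
#'   (`gpcr_trajectory`), `mapping` (`gpcr_mapping`), `label` (`"active"`
#'   or `"inactive"`) and `id` (unique identifier).
#' @param pairs A `gpcr_pairlist`.
#' @param plan A `gpcr_sampling_plan`; with the defaults (20 ns / 100 ps)
#'   38 trajectories yield a 7,600 x 38 matrix.
#' @return A `gpcr_dataset`: list with `matrix` (frames x pairs),
#'   `labels`, `traj_id`, `frame_index` (all per frame) and `pairs`.
#' @export
build_dataset <- function(entries, pairs = default_pairs(),
                          plan = sampling_plan()) {
  ids <- vapply(entries, function(e) as.character(e$id), character(1))
  if (anyDuplicated(ids))
    gpcr_abort(sprintf("duplicate trajectory id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "gpcrstates_validation_error")
  labs <- vapply(entries, function(e) e$label, character(1))
  if (!all(labs %in% c("active", "inactive")))
    gpcr_abort("every trajectory label must be 'active' or 'inactive'",
               "gpcrstates_validation_error")
  mats <- vector("list", length(entries))
  fidx <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    sub <- tryCatch(extract_frames(e$trajectory, plan),
                    gpcrstates_error = function(err)
                      gpcr_abort(sprintf("trajectory '%s': %s", ids[k],
                                         conditionMessage(err)), class(err)[1]))
    mats[[k]] <- tryCatch(descriptor_matrix(sub, e$mapping, pairs),
                          gpcrstates_error = function(err)
                            gpcr_abort(sprintf("trajectory '%s': %s", ids[k],
                                               conditionMessage(err)), class(err)[1]))
    fidx[[k]] <- seq_len(nrow(mats[[k]]))
  }
  nfr <- vapply(mats, nrow, integer(1))
  base::structure(list(
    matrix = do.call(rbind, mats),
    labels = rep(labs, nfr),
    traj_id = rep(ids, nfr),
    frame_index = unlist(fidx, use.names = FALSE),
    pairs = pairs), class = "gpcr_dataset")
}

#' @export
print.gpcr_dataset <- function(x, ...) {
  cat(sprintf("<frame dataset> %d frames x %d pairs, %d trajectories (%s)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$traj_id)),
              paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Assign trajectory folds to train/test partitions
#'
#' Every trajectory is its own fold (all frames of one simulation travel
#' together), so no frame of a trajectory can leak across partitions. The
#' fold-to-partition assignment is seeded-random with label
#' stratification: both partitions receive at least one trajectory of each
#' state.
#'
#' @param dataset A `gpcr_dataset`.
#' @param n_train,n_test Number of folds per partition; must sum to the
#'   number of distinct trajectories (28/10 for the default 38).
#' @param seed Integer seed; fixed seed gives identical assignments.
#' @return A `gpcr_folds` data frame: one row per trajectory with
#'   `traj_id`, `label`, `fold`, `partition`.
#' @export
assign_folds <- function(dataset, n_train, n_test, seed = 1L) {
  per_traj <- !duplicated(dataset$traj_id)
  ids <- dataset$traj_id[per_traj]
  labs <- dataset$labels[per_traj]
  n <- length(ids)
  if (n_train + n_test != n)
    gpcr_abort(sprintf("n_train + n_test = %d but there are %d trajectories",
                       n_train + n_test, n), "gpcrstates_validation_error")
  if (n_train < 1L || n_test < 1L)
    gpcr_abort("both partitions need at least one fold",
               "gpcrstates_validation_error")
  cnt <- table(labs)
  if (length(cnt) < 2L || any(cnt < 2L))
    gpcr_abort(paste0("infeasible stratification: each state needs at least ",
                      "2 trajectories so both partitions contain each state"),
               "gpcrstates_validation_error")
  # per-label test counts: proportional, clamped to keep >=1 per partition
  n_test_l <- pmin(pmax(round(as.numeric(cnt) * n_test / n), 1L),
                   as.numeric(cnt) - 1L)
  names(n_test_l) <- names(cnt)
  drift <- n_test - sum(n_test_l)
  while (drift != 0L) {
    adj <- if (drift > 0L) which(n_test_l < as.numeric(cnt) - 1L)
           else which(n_test_l > 1L)
    if (!length(adj))
      gpcr_abort("infeasible stratification for the requested split sizes",
                 "gpcrstates_validation_error")
    k <- adj[which.max(as.numeric(cnt)[adj])]
    n_test_l[k] <- n_test_l[k] + sign(drift)
    drift <- drift - sign(drift)
  }
  test_ids <- with_private_seed(seed, {
    unlist(lapply(names(n_test_l), function(l) {
      pool <- ids[labs == l]
      pool[sample.int(length(pool), n_test_l[[l]])]
    }), use.names = FALSE)
  })
  base::structure(data.frame(
    traj_id = ids, label = labs, fold = seq_len(n),
    partition = ifelse(ids %in% test_ids, "test", "train"),
    stringsAsFactors = FALSE),
    seed = seed, class = c("gpcr_folds", "data.frame"))
}

#' Assert that a fold assignment has no trajectory leakage
#'
#' @param folds A `gpcr_folds`.
#' @return `TRUE` invisibly; aborts if any trajectory id appears in both
#'   partitions or any fold spans partitions.
#' @export
check_no_leakage <- function(folds) {
  tr <- folds$traj_id[folds$partition == "train"]
  te <- folds$traj_id[folds$partition == "test"]
  if (length(intersect(tr, te)))
    gpcr_abort(sprintf("trajectory leakage across partitions: %s",
                       paste(intersect(tr, te), collapse = ", ")),
               "gpcrstates_leakage_error")
  if (anyDuplicated(folds$fold))
    gpcr_abort("a fold spans more than one trajectory/partition",
               "gpcrstates_leakage_error")
  invisible(TRUE)
}

# Groups the TRAIN folds into k cross-validation groups, stratified by
# label; every CV iteration holds out whole trajectories.
assign_cv_groups <- function(folds, k = 5L, seed = 1L) {
  train <- folds[folds$partition == "train", , drop = FALSE]
  if (nrow(train) < k)
    gpcr_abort(sprintf("cannot form %d CV groups from %d train folds", k,
                       nrow(train)), "gpcrstates_validation_error")
  with_private_seed(seed + 1L, {
    grp <- integer(nrow(train))
    for (l in unique(train$label)) {
      i <- which(train$label == l)
      grp[i[sample.int(length(i))]] <- (seq_along(i) - 1L) %% k + 1L
    }
    data.frame(traj_id = train$traj_id, cv_group = grp,
               stringsAsFactors = FALSE)
  })
}

#' Read a dataset manifest and build the dataset
#'
#' The manifest is a CSV with columns `trajectory`, `topology`, `mapping`,
#' `label`, `id`; paths are resolved relative to the manifest's directory.
#' Trajectories may be DCD (with the PDB topology) or multi-MODEL PDB
#' (topology column then ignored, may be empty).
#'
#' @param path Manifest CSV path.
#' @param pairs,plan Passed to [build_dataset()].
#' @return A `gpcr_dataset`.
#' @export
build_dataset_from_manifest <- function(path, pairs = default_pairs(),
                                        plan = sampling_plan()) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory", "mapping", "label", "id")
  if (!all(need %in% names(man)))
    gpcr_abort(sprintf("manifest must have columns: %s",
                       paste(need, collapse = ", ")), "gpcrstates_parse_error")
  root <- dirname(normalizePath(path))
  rel <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  entries <- lapply(seq_len(nrow(man)), function(i) {
    tp <- rel(man$trajectory[i])
    traj <- if (grepl("\\.dcd$", tp, ignore.case = TRUE)) {
      read_dcd(tp, read_pdb(rel(man$topology[i])),
               interval_ps = NULL)
    } else {
      read_pdb_trajectory(tp, interval_ps = plan$interval_ps)
    }
    list(trajectory = traj, mapping = load_mapping(rel(man$mapping[i])),
         label = man$label[i], id = man$id[i])
  })
  build_dataset(entries, pairs, plan)
}
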