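make_flat_traj <- function(total_ps, dt_ps, natoms_struct = tiny_structure()) {
  nfr <- as.integer(total_ps / dt_ps)
  nat <- nrow(natoms_struct$atoms)
  coords <- array(rep(as.matrix(natoms_struct$atoms[, c("x", "y", "z")]),
                      each = nfr),
                  dim = c(nfr, nat, 3))
  new_trajectory(coords, dt_ps * seq_len(nfr), natoms_struct)
}

test_that("sampling plans do the frame arithmetic", {
  expect_equal(sampling_plan()$n_frames, 200L)
  expect_equal(sampling_plan(1, 100)$n_frames, 10L)
  # oracle: enumerate snapshot times k*30 <= 20000
  expect_equal(sampling_plan(20, 30)$n_frames,
               length(seq(30, 20000, by = 30)))
  expect_equal(sampling_plan(20, 30)$n_frames, 666L)
})

test_that("extract_frames yields evenly spaced snapshots at the interval", {
  tr <- make_flat_traj(20000, 10)
  sub <- extract_frames(tr, sampling_plan(20, 100))
  expect_equal(n_frames(sub), 200L)
  expect_equal(unique(diff(sub$times)), 100)
  expect_equal(sub$times[1], 100)

  sub30 <- extract_frames(tr, sampling_plan(20, 30))
  expect_equal(n_frames(sub30), 666L)
  # spacing within half a trajectory timestep of the interval
  expect_true(all(abs(diff(sub30$times) - 30) <= 5))

  short <- make_flat_traj(1000, 10)
  expect_equal(n_frames(extract_frames(short, sampling_plan(1, 100))), 10L)
  expect_error(extract_frames(short, sampling_plan(20, 100)),
               class = "gpcrstates_validation_error")
})

test_that("build_dataset assembles matrices and rejects duplicate ids", {
  pairs <- tiny_pairs()
  tpl <- make_templates(pairs, separation = 6)
  ens <- generate_ensemble(tpl, ensemble_spec(n_frames = 10, sigma = 0.1,
                                              seed = 4))
  entry <- list(trajectory = ens$trajectory, mapping = tpl$mapping,
                label = "active", id = "t1")
  ds <- build_dataset(list(entry), pairs, sampling_plan(1, 100))
  expect_equal(dim(ds$matrix), c(10L, 2L))
  expect_equal(unique(ds$labels), "active")
  expect_equal(ds$frame_index, 1:10)

  e2 <- entry; e2$label <- "inactive"
  expect_error(build_dataset(list(entry, e2), pairs, sampling_plan(1, 100)),
               "duplicate", class = "gpcrstates_validation_error")
  e3 <- entry; e3$label <- "limbo"; e3$id <- "t2"
  expect_error(build_dataset(list(entry, e3), pairs, sampling_plan(1, 100)),
               class = "gpcrstates_validation_error")
})

test_that("fold assignment is stratified, leakage-free and deterministic", {
  ds <- stub_dataset(10, 28)
  folds <- assign_folds(ds, 28, 10, seed = 3)
  expect_equal(nrow(folds), 38L)
  expect_equal(length(unique(folds$fold)), 38L)
  expect_equal(sum(folds$partition == "train"), 28L)
  expect_equal(sum(folds$partition == "test"), 10L)
  # stratification: both labels present in both partitions
  tab <- table(folds$partition, folds$label)
  expect_true(all(tab >= 1))
  expect_true(check_no_leakage(folds))

  # determinism + seed sensitivity
  expect_identical(folds, assign_folds(ds, 28, 10, seed = 3))
  expect_false(identical(folds$partition,
                         assign_folds(ds, 28, 10, seed = 4)$partition))

  # property: no leakage for any seed
  for (s in 1:20)
    expect_true(check_no_leakage(assign_folds(ds, 28, 10, seed = s)))
})

test_that("infeasible stratification and bad sizes error out", {
  expect_error(assign_folds(stub_dataset(1, 1), 1, 1, seed = 1),
               class = "gpcrstates_validation_error")
  expect_error(assign_folds(stub_dataset(10, 28), 30, 10, seed = 1),
               class = "gpcrstates_validation_error")
  expect_error(assign_folds(stub_dataset(2, 36), 38, 0, seed = 1),
               class = "gpcrstates_validation_error")
})

test_that("grouped CV holds out whole trajectories, never frames", {
  ds <- stub_dataset(10, 28, frames_per = 3L)
  folds <- assign_folds(ds, 28, 10, seed = 5)
  groups <- gpcrstates:::assign_cv_groups(folds, k = 5, seed = 5)
  expect_setequal(groups$traj_id, folds$traj_id[folds$partition == "train"])
  expect_equal(anyDuplicated(groups$traj_id), 0L)
  for (g in 1:5) {
    held <- groups$traj_id[groups$cv_group == g]
    fit <- groups$traj_id[groups$cv_group != g]
    expect_length(intersect(held, fit), 0L)
  }
})

test_that("a manifest on disk reproduces the in-memory dataset", {
  pairs <- tiny_pairs()
  tpl <- make_templates(pairs, separation = 6)
  dir <- withr::local_tempdir()
  ens1 <- generate_ensemble(tpl, ensemble_spec(n_frames = 5, sigma = 0.2,
                                               seed = 21),
                            dir = file.path(dir, "t1"))
  ens2 <- generate_ensemble(tpl, ensemble_spec(n_frames = 5, sigma = 0.2,
                                               lambda = 0, seed = 22),
                            dir = file.path(dir, "t2"))
  man <- file.path(dir, "manifest.csv")
  write.csv(data.frame(
    trajectory = c(ens1$files["trajectory"], ens2$files["trajectory"]),
    topology = c(ens1$files["topology"], ens2$files["topology"]),
    mapping = c(ens1$files["mapping"], ens2$files["mapping"]),
    label = c("active", "inactive"), id = c("t1", "t2")),
    man, row.names = FALSE)
  ds_file <- build_dataset_from_manifest(man, pairs, sampling_plan(0.5, 100))
  ds_mem <- build_dataset(list(
    list(trajectory = ens1$trajectory, mapping = tpl$mapping,
         label = "active", id = "t1"),
    list(trajectory = ens2$trajectory, mapping = tpl$mapping,
         label = "inactive", id = "t2")), pairs, sampling_plan(0.5, 100))
  expect_equal(ds_file$labels, ds_mem$labels)
  # DCD stores float32: agreement to single precision
  expect_lt(max(abs(ds_file$matrix - ds_mem$matrix)), 1e-4)
})
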