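series_of <- function(scores) gpcrstates:::new_score_series(scores, 100 * seq_along(scores))

test_that("smoothing is a centered truncated moving average", {
  s <- smooth_scores(series_of(rep(0.4, 7)), 5)
  expect_equal(s$smoothed, rep(0.4, 7))
  s <- smooth_scores(series_of(c(0, 0, 1, 0, 0)), 5)
  expect_equal(s$smoothed[3], 0.2)
  expect_equal(s$smoothed[1], 1 / 3)  # truncated edge window
  expect_equal(s$smoothed[2], 0.25)
  s1 <- smooth_scores(series_of(c(.1, .9, .3)), 1)
  expect_equal(s1$smoothed, s1$score)
  expect_error(smooth_scores(series_of(1:4 / 4), 4),
               class = "gpcrstates_validation_error")
  # smoothed values never leave the raw range
  set.seed(8)
  r <- runif(50)
  sm <- smooth_scores(series_of(r), 5)$smoothed
  expect_true(all(sm >= min(r) & sm <= max(r)))
})

test_that("frame classification applies the strict theta rule to raw scores", {
  expect_equal(classify_frames(c(0.0, 0.65), theta = 0.375),
               c("inactive", "active"))
  expect_equal(classify_frames(0.375, theta = 0.375), "inactive")
  expect_equal(classify_frames(c(0, 1e-9, .5), theta = 0),
               c("inactive", "active", "active"))
  expect_error(classify_frames(0.5, theta = 1.5),
               class = "gpcrstates_validation_error")
  # raw not smoothed scores decide
  sm <- smooth_scores(series_of(c(0, 0, 1, 0, 0)), 5)
  expect_equal(sum(classify_frames(sm, 0.375) == "active"), 1L)
})

test_that("trajectory verdicts follow the strict delta rule, monotone in delta", {
  labs <- rep(c("active", "inactive"), c(4, 6))  # ratio 0.4
  expect_equal(classify_trajectory(labs, delta = 0.375)$verdict, "active")
  expect_equal(classify_trajectory(labs, delta = 0.4)$verdict, "inactive")
  expect_equal(classify_trajectory(rep("active", 10), delta = 0.999)$verdict,
               "active")
  expect_error(classify_trajectory(character(0)),
               class = "gpcrstates_validation_error")
  # monotone: raising delta never flips inactive -> active
  set.seed(12)
  for (rep_ in 1:10) {
    labs <- sample(c("active", "inactive"), 20, replace = TRUE)
    verdicts <- vapply(seq(0, 1, by = 0.05), function(d)
      classify_trajectory(labs, delta = d)$verdict, character(1))
    active_at <- which(verdicts == "active")
    if (length(active_at))
      expect_equal(active_at, seq_len(max(active_at)))
  }
})

test_that("trajectory scoring separates constructed states and streams per frame", {
  pairs <- default_pairs()
  m <- fixture_model()
  tpl <- make_templates(pairs)
  ens_in <- generate_ensemble(tpl, ensemble_spec(n_frames = 15, sigma = 0.25,
                                                 lambda = 0, seed = 41))
  s_in <- score_trajectory(m, ens_in$trajectory, tpl$mapping)
  expect_equal(nrow(s_in), 15L)
  expect_true(all(s_in$score < 0.375))

  one <- ens_in$trajectory
  one$coords <- one$coords[1, , , drop = FALSE]
  one$times <- one$times[1]
  expect_equal(nrow(score_trajectory(m, one, tpl$mapping)), 1L)

  # switch mid-way: scores cross theta near the known switch frame
  sw <- generate_ensemble(tpl, ensemble_spec(
    n_frames = 30, sigma = 0.25, lambda = rep(c(0, 1), each = 15), seed = 42))
  s_sw <- score_trajectory(m, sw$trajectory, tpl$mapping)
  labs <- classify_frames(s_sw, 0.375)
  expect_true(all(labs[1:15] == "inactive"))
  expect_true(all(labs[16:30] == "active"))

  # concatenation property
  both <- ens_in$trajectory
  both$coords <- abind_frames(ens_in$trajectory$coords, sw$trajectory$coords)
  both$times <- c(ens_in$trajectory$times,
                  max(ens_in$trajectory$times) + sw$trajectory$times)
  s_both <- score_trajectory(m, both, tpl$mapping)
  expect_equal(s_both$score, c(s_in$score, s_sw$score))
})

test_that("binding sites honor the cutoff, union and empty-site contract", {
  ref <- toy_structure(list(
    list(record = "HETATM", resname = "LIG", resnum = 900L,
         atoms = list(C1 = c(0, 0, 0))),
    list(resnum = 1L, atoms = list(CA = c(5, 0, 0), CB = c(5, 1, 0))),
    list(resnum = 2L, atoms = list(CA = c(7.9, 0, 0))),
    list(resnum = 3L, atoms = list(CA = c(8.1, 0, 0)))))
  site <- define_binding_site(ref, list(kind = "ligand"), cutoff = 8)
  expect_equal(site$residues$resnum, c(1L, 2L))

  ref2 <- toy_structure(list(
    list(record = "HETATM", resname = "LIG", resnum = 900L,
         atoms = list(C1 = c(100, 0, 0))),
    list(resnum = 7L, atoms = list(CA = c(103, 0, 0)))))
  both <- define_binding_site(list(ref, ref2), list(kind = "ligand"), 8)
  expect_setequal(both$residues$resnum, c(1L, 2L, 7L))

  expect_error(define_binding_site(ref, list(kind = "ligand"), cutoff = 0),
               class = "gpcrstates_empty_site")
  expect_error(define_binding_site(ref, list(kind = "ligand",
                                             resname = "XYZ"), 8),
               class = "gpcrstates_validation_error")
  # generic labels attached where a mapping covers the residues
  mp <- as_mapping(data.frame(label = "3x50", resnum = 1L, chain = "A"))
  lab <- define_binding_site(ref, list(kind = "ligand"), 8, mapping = mp)
  expect_equal(lab$residues$label, c("3x50", "A:2"))
})

test_that("binding-site RMSD matches a brute-force superposition oracle", {
  set.seed(77)
  n <- 9
  res <- lapply(seq_len(n), function(i)
    list(resnum = i, atoms = list(CA = rnorm(3, sd = 5))))
  s1 <- toy_structure(res)
  site <- structure(list(kind = "ligand", cutoff = 8,
                         residues = data.frame(chain = "A", resnum = seq_len(n),
                                               resname = "ALA",
                                               label = sprintf("A:%d", seq_len(n))),
                         n_references = 1L), class = "gpcr_binding_site")
  expect_equal(binding_site_rmsd(s1, s1, site), 0)

  # rigid rotation + translation: zero within 1e-6
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s1
  xyz <- as.matrix(s1$atoms[, c("x", "y", "z")]) %*% R
  s2$atoms$x <- xyz[, 1] + 3; s2$atoms$y <- xyz[, 2] - 1; s2$atoms$z <- xyz[, 3] + 9
  expect_lt(binding_site_rmsd(s1, s2, site), 1e-6)

  # displaced-atom instances vs the optimisation oracle
  for (k in 1:3) {
    s3 <- s1
    s3$atoms$x[k] <- s3$atoms$x[k] + 3
    got <- binding_site_rmsd(s1, s3, site)
    P <- as.matrix(s1$atoms[, c("x", "y", "z")])
    Q <- as.matrix(s3$atoms[, c("x", "y", "z")])
    expect_equal(got, brute_rmsd(P, Q, seed = 100 + k), tolerance = 1e-6)
    # symmetry
    expect_equal(got, binding_site_rmsd(s3, s1, site), tolerance = 1e-9)
  }

  bad_site <- site
  bad_site$residues$resnum[1] <- 999L
  expect_error(binding_site_rmsd(s1, s1, bad_site), "999",
               class = "gpcrstates_missing_residue")
})

test_that("rank-sum comparison agrees with a permutation oracle", {
  set.seed(21)
  a <- rnorm(100, 0, 1)
  b <- rnorm(100, 3, 1)  # 3-sigma shift
  res <- compare_rmsd_groups(a, b)
  expect_lt(res$p_value, 1e-6)
  # permutation oracle saturates at its resolution for this separation
  expect_lt(perm_ranksum(a, b, n_perm = 2000), 2 / 2000)
  # medians match a direct sort-and-middle computation
  srt <- sort(a)
  expect_equal(res$median_active, (srt[50] + srt[51]) / 2)
  expect_equal(res$median_inactive, median(b))

  # moderate shift: p-values agree within Monte-Carlo error
  a2 <- rnorm(30, 0, 1); b2 <- rnorm(30, 0.7, 1)
  p_pkg <- compare_rmsd_groups(a2, b2)$p_value
  p_perm <- perm_ranksum(a2, b2, n_perm = 10000)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(p_pkg - p_perm), 6 * mc_sd + 0.01)

  same <- c(1, 2, 3, 4, 5)
  res_same <- compare_rmsd_groups(same, same)
  expect_gt(res_same$p_value, 0.9)
  expect_equal(res_same$median_active, res_same$median_inactive)
  expect_error(compare_rmsd_groups(numeric(0), 1:3),
               class = "gpcrstates_validation_error")
})

test_that("the annotate CLI writes the per-frame CSV and verdict JSON", {
  pairs <- default_pairs()
  tpl <- make_templates(pairs)
  dir <- withr::local_tempdir()
  ens <- generate_ensemble(tpl, ensemble_spec(n_frames = 8, sigma = 0.25,
                                              lambda = 1, seed = 13),
                           dir = dir)
  mfile <- file.path(dir, "model.json")
  save_state_model(fixture_model(), mfile)
  out_csv <- file.path(dir, "ann.csv")
  out_json <- file.path(dir, "verdict.json")
  suppressMessages(annotate_main(c(
    "--model", mfile, "--traj", unname(ens$files["trajectory"]),
    "--top", unname(ens$files["topology"]),
    "--mapping", unname(ens$files["mapping"]),
    "--theta", "0.375", "--delta", "0.5", "--window", "5",
    "--out-csv", out_csv, "--out-json", out_json)))
  ann <- read.csv(out_csv)
  expect_equal(nrow(ann), 8L)
  expect_named(ann, c("frame", "time", "score", "smoothed", "label"))
  v <- jsonlite::fromJSON(out_json)
  expect_equal(v$verdict, "active")
  expect_equal(v$n_frames, 8L)
})
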