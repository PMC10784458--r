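# Shared fixtures and independent oracles. Oracles are deliberately naive
# implementations (enumeration / optimisation / counting) kept free of the
# package code paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# builds a gpcr_structure from a list of residues:
#   list(resname=, resnum=, chain=, record=, atoms=list(NAME=c(x,y,z), ...))
toy_structure <- function(residues, source = "toy") {
  rows <- do.call(rbind, lapply(residues, function(r) {
    nm <- names(r$atoms)
    data.frame(record = r$record %||% "ATOM", serial = NA_integer_,
               name = nm, altloc = " ", resname = r$resname %||% "ALA",
               chain = r$chain %||% "A", resnum = r$resnum, icode = " ",
               x = vapply(r$atoms, `[`, numeric(1), 1),
               y = vapply(r$atoms, `[`, numeric(1), 2),
               z = vapply(r$atoms, `[`, numeric(1), 3),
               occupancy = 1, element = substr(nm, 1, 1),
               stringsAsFactors = FALSE)
  }))
  rows$serial <- seq_len(nrow(rows))
  gpcrstates:::new_structure(rows, source = source)
}

# two-pair fixture: residues 5x62, 6x37, 7x49 with simple geometries
tiny_pairs <- function() {
  as_pairlist(data.frame(a = c("5x62", "7x45"), b = c("6x37", "7x49")),
              name = "tiny")
}

tiny_mapping <- function() {
  as_mapping(data.frame(label = c("5x62", "6x37", "7x45", "7x49"),
                        resnum = c(562L, 637L, 745L, 749L), chain = "A"),
             receptor = "toy")
}

tiny_structure <- function(d_5662 = 5, d_4549 = 3) {
  toy_structure(list(
    list(resname = "LYS", resnum = 562L,
         atoms = list(N = c(-1, 5, 0), CA = c(0, 4, 0), CB = c(0, 0, 0),
                      CG = c(2, 0, 0))),                 # side center (1,0,0)
    list(resname = "LEU", resnum = 637L,
         atoms = list(CA = c(2, 9, 0), CB = c(1 + d_5662, 0, 0))),
    list(resname = "GLY", resnum = 745L,
         atoms = list(N = c(9, 1, 0), CA = c(10, 0, 0))), # center = CA
    list(resname = "SER", resnum = 749L,
         atoms = list(CA = c(12, 3, 0), OG = c(10, d_4549, 0)))))
}

# --- oracles ---------------------------------------------------------------

# nearest-centroid classifier: the independent baseline for separable data
centroid_oracle <- function(train_x, train_y, test_x) {
  ca <- colMeans(train_x[train_y == "active", , drop = FALSE])
  ci <- colMeans(train_x[train_y == "inactive", , drop = FALSE])
  da <- rowSums(sweep(test_x, 2, ca)^2)
  di <- rowSums(sweep(test_x, 2, ci)^2)
  ifelse(da < di, "active", "inactive")
}

# brute-force superposition RMSD: direct optimisation over rotations
# (Euler angles) and translations from several starts
brute_rmsd <- function(P, Q, starts = 8L, seed = 42L) {
  rotmat <- function(a) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
    Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    Pt <- P %*% t(rotmat(par[1:3]))
    Pt <- sweep(Pt, 2, -par[4:6])
    sqrt(mean(rowSums((Pt - Q)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(starts)) {
    p0 <- c(runif(3, -pi, pi), colMeans(Q) - colMeans(P))
    fit <- optim(p0, obj, method = "BFGS", control = list(maxit = 500))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# permutation rank-sum test (two-sided, statistic = sum of ranks of group a)
perm_ranksum <- function(a, b, n_perm = 1e4, seed = 7L) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    w <- sum(r[sample.int(length(pooled), na)])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# confusion counting by brute force over the raw label vectors
count_confusion <- function(pred, truth) {
  c(TP = sum(pred == "active" & truth == "active"),
    TN = sum(pred == "inactive" & truth == "inactive"),
    FP = sum(pred == "active" & truth == "inactive"),
    FN = sum(pred == "inactive" & truth == "active"))
}

# binds two frames x atoms x 3 arrays along the frame axis
abind_frames <- function(a, b) {
  out <- array(NA_real_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], 3))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# fabricated dataset stub for split logic (fold assignment only touches
# traj_id and labels)
stub_dataset <- function(n_active, n_inactive, frames_per = 1L) {
  ids <- c(sprintf("act%02d", seq_len(n_active)),
           sprintf("ina%02d", seq_len(n_inactive)))
  labs <- rep(c("active", "inactive"), c(n_active, n_inactive))
  structure(list(
    matrix = matrix(0, length(ids) * frames_per, 2,
                    dimnames = list(NULL, c("5x62:6x37", "7x45:7x49"))),
    labels = rep(labs, each = frames_per),
    traj_id = rep(ids, each = frames_per),
    frame_index = rep(seq_len(frames_per), length(ids)),
    pairs = tiny_pairs()), class = "gpcr_dataset")
}

# small trained model + dataset shared across model tests
fixture_model_env <- new.env()
fixture_model <- function(family = "random_forest") {
  key <- paste0("m_", family)
  if (is.null(fixture_model_env[[key]])) {
    if (is.null(fixture_model_env$ds)) {
      pairs <- default_pairs()
      entries <- generate_state_ensembles(4, 4, pairs, sigma = 0.25,
                                          n_frames = 20, seed = 11)
      fixture_model_env$ds <- build_dataset(entries, pairs, sampling_plan(2, 100))
      fixture_model_env$folds <- assign_folds(fixture_model_env$ds, 6, 2, seed = 2)
    }
    fixture_model_env[[key]] <- train_state_model(
      fixture_model_env$ds, fixture_model_env$folds, family = family,
      seed = 5, cv_k = 0)
  }
  fixture_model_env[[key]]
}
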