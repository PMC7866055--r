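test_that("superposition removes rigid-body motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  w <- runif(10, 1, 16)
  # identity
  s <- superpose(ref, ref, w)
  expect_lt(s$rmsd_after, 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  # pure translation
  s <- superpose(sweep(ref, 2, c(1, 2, 3), "+"), ref, w)
  expect_lt(s$rmsd_after, 1e-12)
  # random rotation + translation across many draws
  for (i in 1:20) {
    R <- random_rotation()
    mob <- sweep(ref %*% t(R), 2, rnorm(3), "+")
    s <- superpose(mob, ref, w)
    expect_lt(s$rmsd_after, 1e-9)
    expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  }
})

test_that("superposition matches the exhaustive rotational-grid oracle", {
  set.seed(2)
  for (i in 1:3) {
    ref <- matrix(rnorm(30), 10, 3)
    mob <- matrix(rnorm(30), 10, 3)  # genuinely different clouds
    s <- superpose(mob, ref)
    oracle <- grid_rmsd_oracle(mob, ref)
    expect_lte(s$rmsd_after, oracle + 1e-6)
    expect_equal(s$rmsd_after, oracle, tolerance = 1e-3)
  }
})

test_that("degenerate geometries are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
})

test_that("RMSD series is zero for rigid motion and matches hand arithmetic", {
  top <- topology(c("CA", "CA", "CA"), rep("GLY", 3), 1:3,
                  mass = c(2, 1, 1))
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  moved <- sweep(ref %*% t(random_rotation()), 2, c(0.3, -0.2, 1), "+")
  tr <- trajectory(top, list(ref, moved), c(10, 10, 10))
  sel <- select_atoms(top, "name CA")
  r <- rmsd_series(tr, sel)
  expect_equal(r$rmsd_nm, c(0, 0), tolerance = 1e-9)

  # hand case: frame 2 displaces atom 1 by d along x only; optimal
  # superposition is computed, so compare against the unfitted weighted
  # formula via reference = frame itself in a no-rotation scenario:
  # displace ALL atoms by known per-atom offsets with zero net
  # translation/rotation is hard by hand, so instead verify the
  # mass-weighted formula directly on the unsuperposed residual of a
  # symmetric two-atom-swap that Kabsch cannot improve.
  top2 <- topology(rep("CA", 4), rep("GLY", 4), 1:4, mass = c(1, 1, 1, 1))
  sq <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  # stretch along x: optimal alignment is identity by symmetry
  st <- rbind(c(1.2, 0, 0), c(-1.2, 0, 0), c(0, 1, 0), c(0, -1, 0))
  tr2 <- trajectory(top2, list(sq, st), c(10, 10, 10))
  r2 <- rmsd_series(tr2, select_atoms(top2, "name CA"))
  expect_equal(r2$rmsd_nm[2], sqrt((2 * 0.2^2) / 4), tolerance = 1e-9)
})

test_that("RMSD is symmetric under swapping mobile and reference", {
  set.seed(3)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.1), 8, 3)
  w <- runif(8, 1, 12)
  expect_equal(superpose(a, b, w)$rmsd_after, superpose(b, a, w)$rmsd_after,
               tolerance = 1e-9)
})

test_that("RMSF recovers a known oscillation and is rotation invariant", {
  # heavy anchor atoms pin the mass-weighted superposition, so the light
  # atom oscillating +-d along x about fixed neighbours has RMSF = d
  top <- topology(rep("CA", 4), rep("GLY", 4), 1:4,
                  mass = c(1, 1e4, 1e4, 1e4))
  base <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  d <- 0.1
  f1 <- base
  f2 <- base
  f1[1, 1] <- f1[1, 1] + d
  f2[1, 1] <- f2[1, 1] - d
  tr <- trajectory(top, list(f1, f2), c(10, 10, 10))
  sel <- select_atoms(top, "name CA")
  prof <- rmsf_profile(tr, sel)
  expect_equal(prof$rmsf_nm[1], d, tolerance = 1e-4)
  expect_equal(prof$resid, 1:4)

  # static trajectory: all zeros
  tr0 <- trajectory(top, list(base, base, base), c(10, 10, 10))
  expect_true(all(rmsf_profile(tr0, sel)$rmsf_nm < 1e-12))

  # one global rotation applied to every frame changes nothing
  R <- random_rotation()
  trR <- trajectory(top, list(f1 %*% t(R), f2 %*% t(R)), c(10, 10, 10))
  expect_equal(rmsf_profile(trR, sel)$rmsf_nm,
               prof$rmsf_nm, tolerance = 1e-9)
  expect_error(rmsf_profile(subset_frames(tr, 1), sel), "single frame")
})

test_that("pooled PCA satisfies the trace identity and recovers known modes", {
  # Gaussian ensemble with three orthogonal internal modes of variance
  # 4, 1, 0.25 nm^2. Modes are built orthogonal to the rigid-body
  # subspace (translations + infinitesimal rotations) of the base
  # geometry, so superposition leaves them intact and the covariance
  # eigenvalues recover the generating variances.
  set.seed(4)
  n_at <- 10
  top <- topology(rep("CA", n_at), rep("GLY", n_at), 1:n_at)
  base <- matrix(rnorm(3 * n_at, sd = 8), n_at, 3)
  cen <- sweep(base, 2, colMeans(base))
  rigid <- matrix(0, 3 * n_at, 6)
  for (k in 1:3) rigid[seq(k, 3 * n_at, by = 3), k] <- 1  # translations
  for (k in 1:3) {                                        # rotations
    ek <- diag(3)[k, ]
    rigid[, 3 + k] <- as.vector(t(cen %*% rbind(
      c(0, ek[3], -ek[2]), c(-ek[3], 0, ek[1]), c(ek[2], -ek[1], 0))))
  }
  Q <- qr.Q(qr(cbind(rigid, matrix(rnorm(3 * n_at * 3), ncol = 3))))
  modes <- t(Q[, 7:9])          # orthonormal, perpendicular to rigid
  sds <- c(2, 1, 0.5)
  nfr <- 5000
  frames <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    disp <- colSums(modes * rnorm(3, sd = sds))
    frames[[i]] <- base + matrix(disp, n_at, 3, byrow = TRUE)
  }
  tr <- trajectory(top, frames, c(100, 100, 100))
  sel <- select_atoms(top, "name CA")
  pca <- common_pca(list(tr), sel, mass_weighted = FALSE)
  expect_equal(sum(pca$eigenvalues), pca$total_variance, tolerance = 1e-8)
  expect_equal(pca$eigenvalues[1:3], c(4, 1, 0.25), tolerance = 0.1)
  expect_lt(pca$eigenvalues[4] / pca$eigenvalues[1], 0.02)
  # components orthonormal
  G <- pca$components[1:4, ] %*% t(pca$components[1:4, ])
  expect_equal(G, diag(4), tolerance = 1e-8)
  # projections of the pooled mean at the origin
  expect_equal(mean(pca$projections$pc1), 0, tolerance = 1e-9)
  expect_equal(mean(pca$projections$pc2), 0, tolerance = 1e-9)
})

test_that("rank-1 ensembles have a single non-zero eigenvalue", {
  # heavy anchors keep the superposition at identity, so frames stay on
  # an exact line in conformation space
  top <- topology(rep("CA", 4), rep("GLY", 4), 1:4,
                  mass = c(1e4, 1, 1e4, 1e4))
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  frames <- lapply(seq(-1, 1, length.out = 40), function(a) {
    f <- base
    f[2, 2] <- f[2, 2] + a
    f
  })
  tr <- trajectory(top, frames, c(20, 20, 20))
  pca <- common_pca(list(tr), select_atoms(top, "name CA"))
  expect_lt(sum(pca$eigenvalues[-1]) / sum(pca$eigenvalues), 1e-8)
})

test_that("selection size mismatch across trajectories errors", {
  top1 <- topology(rep("CA", 4), rep("GLY", 4), 1:4)
  top2 <- topology(rep("CA", 5), rep("GLY", 5), 1:5)
  tr1 <- trajectory(top1, list(matrix(rnorm(12), 4, 3)), c(9, 9, 9))
  tr2 <- trajectory(top2, list(matrix(rnorm(15), 5, 3)), c(9, 9, 9))
  expect_error(suppressWarnings(
    common_pca(list(tr1, tr2),
               list(select_atoms(top1, "name CA"),
                    select_atoms(top2, "name CA")))),
    "selection size")
})

test_that("convex-hull span area matches closed forms and brute force", {
  expect_equal(pc_span_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  # duplicated points change nothing
  expect_equal(pc_span_area(rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 0),
                                  c(1, 0))), 0.5)
  expect_warning(a <- pc_span_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "collinear")
  expect_equal(a, 0)
  # brute-force oracle: max over all triangle fans is the hull area for
  # points in convex position; use exhaustive triangle sum over hull
  set.seed(5)
  pts <- matrix(rnorm(200), 100, 2)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, ]
  # fan triangulation from vertex 1 (independent arithmetic)
  fan <- 0
  for (i in 2:(nrow(hp) - 1)) {
    v1 <- hp[i, ] - hp[1, ]
    v2 <- hp[i + 1, ] - hp[1, ]
    fan <- fan + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  expect_equal(pc_span_area(pts), fan, tolerance = 1e-9)
})
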