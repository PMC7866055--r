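test_that("density profile is flat for a uniform fill and conserves counts", {
  set.seed(6)
  n <- 4000
  box <- c(4, 4, 4)
  # uniform fill of the full box; analysis cylinder radius 1 about centre
  top <- water_topology(n)
  xyz <- array(runif(n * 3, 0, 4), dim = c(n, 3, 1))
  tr <- trajectory(top, xyz, box)
  w <- select_atoms(top, "water")
  prof <- z_density_profile(tr, w, axis_center = c(2, 2),
                            lateral_radius = 1, bin_width = 0.25)
  rho <- n / prod(box)
  vol_bin <- pi * 1 * 0.25
  for (i in seq_len(nrow(prof))) {
    se <- sqrt(rho * vol_bin) / vol_bin  # Poisson SE per bin
    expect_lt(abs(prof$density_per_nm3[i] - rho), 3.5 * se)
  }
  # integral over bins x bin volume = mean count in region (exact)
  integral <- sum(prof$density_per_nm3) * pi * 1 * attr(prof, "bin_width")
  expect_equal(integral, attr(prof, "mean_count"), tolerance = 1e-9)
  # refinement leaves the integral unchanged
  prof2 <- z_density_profile(tr, w, axis_center = c(2, 2),
                             lateral_radius = 1, bin_width = 0.125)
  integral2 <- sum(prof2$density_per_nm3) * pi * 1 * attr(prof2, "bin_width")
  expect_equal(integral2, integral, tolerance = 1e-9)
})

test_that("empty regions give zero density and empty selections error", {
  top <- water_topology(3)
  xyz <- array(rep(c(0.2, 0.2, 0.2), each = 3), dim = c(3, 3, 1))
  tr <- trajectory(top, xyz, c(6, 6, 6))
  w <- select_atoms(top, "water")
  prof <- z_density_profile(tr, w, axis_center = c(5, 5), lateral_radius = 1)
  expect_true(all(prof$density_per_nm3[prof$z_nm > 1] == 0))
  expect_error(z_density_profile(tr, as_sel <- integer(0),
                                 axis_center = c(1, 1)), "empty")
})

test_that("occupancy grid reports exact presence fractions", {
  top <- water_topology(1)
  # atom in a fixed voxel for 10 of 50 frames, elsewhere otherwise
  frames <- lapply(seq_len(50), function(i) {
    if (i <= 10) matrix(c(0.55, 0.55, 0.55), 1) else matrix(c(3.5, 3.5, 3.5), 1)
  })
  tr <- trajectory(top, frames, c(4, 4, 4))
  sel <- select_atoms(top, "water")
  grid <- occupancy_grid(tr, sel, region = list(min = c(0, 0, 0),
                                                max = c(4, 4, 4)),
                         spacing = 0.5)
  expect_equal(max(grid$values[2, 2, 2]), 0.2)
  expect_equal(grid$values[8, 8, 8], 0.8)
  expect_equal(sum(grid$values > 0), 2)
  # static single atom: exactly one voxel at 1.0
  tr2 <- subset_frames(tr, 1:10)
  g2 <- occupancy_grid(tr2, sel, list(min = c(0, 0, 0), max = c(4, 4, 4)),
                       spacing = 0.5)
  expect_equal(sum(g2$values == 1), 1)
  expect_equal(sum(g2$values), 1)
  expect_error(occupancy_grid(tr, sel, list(min = c(0, 0, 0),
                                            max = c(9, 4, 4))),
               "outside")
})

test_that("grid occupancy equals a brute-force voxel recount", {
  set.seed(7)
  top <- water_topology(20)
  nf <- 15
  frames <- lapply(seq_len(nf), function(i) matrix(runif(60, 0, 2), 20, 3))
  tr <- trajectory(top, frames, c(2, 2, 2))
  sel <- select_atoms(top, "water")
  sp <- 0.5
  grid <- occupancy_grid(tr, sel, list(min = c(0, 0, 0), max = c(2, 2, 2)),
                         spacing = sp)
  brute <- array(0, dim = c(4, 4, 4))
  for (i in seq_len(nf)) {
    seen <- array(FALSE, dim = c(4, 4, 4))
    for (a in seq_len(20)) {
      v <- pmin(4, 1 + floor(frames[[i]][a, ] / sp))
      seen[v[1], v[2], v[3]] <- TRUE
    }
    brute <- brute + seen
  }
  expect_equal(grid$values, brute / nf)
})

test_that("channel continuity matches an independent flood fill", {
  flood_oracle <- function(occ) {
    nd <- dim(occ)
    lab <- array(0L, nd)
    nc <- 0L
    for (z in 1:nd[3]) for (y in 1:nd[2]) for (x in 1:nd[1]) {
      if (!occ[x, y, z] || lab[x, y, z] != 0) next
      nc <- nc + 1L
      stack <- list(c(x, y, z))
      lab[x, y, z] <- nc
      while (length(stack) > 0) {
        c0 <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in 1:3) for (s in c(-1, 1)) {
          nb <- c0
          nb[k] <- nb[k] + s
          if (any(nb < 1) || any(nb > nd)) next
          if (occ[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0) {
            lab[nb[1], nb[2], nb[3]] <- nc
            stack[[length(stack) + 1]] <- nb
          }
        }
      }
    }
    spans <- FALSE
    if (nc > 0) {
      for (cc in seq_len(nc)) {
        zs <- which(apply(lab == cc, 3, any))
        if (zs[1] == 1 && zs[length(zs)] == nd[3]) spans <- TRUE
      }
    }
    list(continuous = spans, n = nc)
  }
  # full column -> continuous
  g <- list(origin = c(0, 0, 0), spacing = c(0.5, 0.5, 0.5),
            values = array(0, c(3, 3, 5)))
  g$values[2, 2, ] <- 1
  class(g) <- "OccupancyGrid"
  r <- is_channel_continuous(g, 0.2)
  expect_true(r$continuous)
  expect_equal(r$n_components, 1)
  # one empty slab -> two components, not continuous
  g$values[2, 2, 3] <- 0
  r2 <- is_channel_continuous(g, 0.2)
  expect_false(r2$continuous)
  expect_equal(r2$n_components, 2)
  # random grids against the oracle
  set.seed(8)
  for (i in 1:5) {
    vals <- array(runif(4 * 4 * 6) < 0.4, c(4, 4, 6)) * 1
    gr <- structure(list(origin = c(0, 0, 0), spacing = rep(0.5, 3),
                         values = vals), class = "OccupancyGrid")
    mine <- is_channel_continuous(gr, 0.5)
    orac <- flood_oracle(vals >= 0.5)
    expect_equal(mine$continuous, orac$continuous)
    expect_equal(mine$n_components, orac$n)
  }
  expect_error(is_channel_continuous(g, 0), "isovalue")
})

test_that("OpenDX output round-trips dimensions and values", {
  set.seed(9)
  vals <- array(runif(24), c(2, 3, 4))
  g <- structure(list(origin = c(0.1, 0.2, 0.3), spacing = rep(0.5, 3),
                      values = vals), class = "OccupancyGrid")
  path <- withr::local_tempfile(fileext = ".dx")
  write_opendx(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "counts 2 3 4")
  nums <- as.numeric(unlist(strsplit(paste(
    lines[(grep("data follows", lines) + 1):(grep("attribute", lines) - 1)],
    collapse = " "), " +")))
  nums <- nums[!is.na(nums)]
  expect_length(nums, 24)
  # dx order: z fastest
  expect_equal(nums[1:4], vals[1, 1, 1:4], tolerance = 1e-6)
})

test_that("crossing counter reproduces hand-traced event sequences", {
  box <- c(4, 4, 10)
  top <- water_topology(1)
  zl <- 4
  zu <- 6
  mk <- function(zs, xs = rep(2, length(zs))) {
    trajectory(top, lapply(seq_along(zs), function(i) {
      matrix(c(xs[i], 2, zs[i]), 1)
    }), box)
  }
  # complete up crossing
  r <- count_crossings(mk(c(3, 4.5, 5.5, 7)), 1L, zl, zu, 1.5,
                       axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(1L, 0L))
  # complete down crossing
  r <- count_crossings(mk(c(7, 5.5, 4.5, 3)), 1L, zl, zu, 1.5,
                       axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(0L, 1L))
  # abort: enters from below, retreats below
  r <- count_crossings(mk(c(3, 5, 5.8, 5, 3)), 1L, zl, zu, 1.5,
                       axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(0L, 0L))
  # lateral exit mid-transit voids the crossing
  r <- count_crossings(mk(c(3, 4.5, 5, 5.5, 7),
                          xs = c(2, 2, 3.9, 2, 2)), 1L, zl, zu, 1.5,
                       axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(0L, 0L))
  # re-entry after abort still counts a later full crossing
  r <- count_crossings(mk(c(3, 5, 3, 4.5, 5.5, 7)), 1L, zl, zu, 1.5,
                       axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(1L, 0L))
  # static molecule: nothing
  r <- count_crossings(mk(rep(5, 4)), 1L, zl, zu, 1.5, axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(0L, 0L))
  # periodic wrap far from the planes is not a crossing
  r <- count_crossings(mk(c(9.8, 0.1, 9.9, 0.2)), 1L, zl, zu, 1.5,
                       axis_center = c(2, 2))
  expect_equal(c(r$n_up, r$n_down), c(0L, 0L))
  expect_error(count_crossings(mk(c(3, 4)), 1L, 6, 4, 1.5,
                               axis_center = c(2, 2)), "z_lower")
})

test_that("open pore crossings grow linearly with trajectory length", {
  # long enough that the half-trajectory expectation is ~200 events and
  # the Poisson noise on the 2T/T ratio is well inside the band
  spec2 <- synthetic_spec("pore", seed = 21, n_frames = 36000)
  sys2 <- make_pore_system(spec2)
  tr2 <- sys2$trajectory
  w <- select_atoms(tr2$topology, "water")
  ctr <- spec2$box[3] / 2
  h <- spec2$pore$half_length
  cr_half <- count_crossings(subset_frames(tr2, 1:18000), w, ctr - h, ctr + h,
                             lateral_radius = 1)
  cr_full <- count_crossings(tr2, w, ctr - h, ctr + h, lateral_radius = 1)
  n1 <- cr_half$n_up + cr_half$n_down
  n2 <- cr_full$n_up + cr_full$n_down
  expect_gte(n1, 25)
  expect_gt(n2 / n1, 1.6)
  expect_lt(n2 / n1, 2.4)
})
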