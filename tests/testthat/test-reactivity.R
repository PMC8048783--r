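# helper: tiny hand-built trajectory around an acceptor at the origin
manual_nac_traj <- function(frames) {
  # frames: list of lists with h (list of 3-vectors) and c (3-vector)
  n_h <- length(frames[[1]]$h)
  ros <- tibble::tibble(
    serial = seq_len(2 + n_h),
    name = c("OFE", "C1", paste0("H", seq_len(n_h))),
    element = c("O", "C", rep("H", n_h)),
    resname = c("CPI", rep("STR", 1 + n_h)),
    resnum = c(500L, rep(400L, 1 + n_h)), chain = "X")
  coords <- array(NA_real_, c(2 + n_h, 3, length(frames)))
  for (f in seq_along(frames)) {
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- frames[[f]]$c
    for (j in seq_len(n_h)) coords[2 + j, , f] <- frames[[f]]$h[[j]]
  }
  trajectory(ros, coords)
}

test_that("a hydrogen inside both criteria scores NAC; distant hydrogens never do", {
  # H at 2.0 A from O, C placed collinearly behind H -> angle C-H...O = 180
  good <- list(h = list(c(2, 0, 0)), c = c(3.09, 0, 0))
  far <- list(h = list(c(6.5, 0, 0)), c = c(7.59, 0, 0))
  tr <- manual_nac_traj(list(good, far))
  crit <- nac_criterion(acceptor = 1, sites = list(
    site_definition("16a", hydrogens = 3, carbon = 2)))
  cls <- classify_frames(tr, crit)
  expect_identical(cls$nac, c(TRUE, FALSE))
  expect_equal(cls$distance, c(2.0, 6.5))
  expect_equal(cls$angle[1], 180)

  # single NAC frame -> 100 %
  pct <- nac_percentages(manual_nac_traj(list(good)), crit)
  expect_equal(pct$nac_percent, 100)
})

test_that("angle outside the tolerance defeats a short distance", {
  h <- c(2, 0, 0)
  # carbon at 90 degrees: C-H...O angle = 90, outside 180 +/- 20
  bent <- list(h = list(h), c = c(2, 1.09, 0))
  tr <- manual_nac_traj(list(bent))
  crit <- nac_criterion(1, list(site_definition("s", 3, 2)))
  expect_false(classify_frames(tr, crit)$nac)
})

test_that("equivalent hydrogens combine by any-satisfies with min-distance reporting", {
  fr <- list(h = list(c(4, 0, 0), c(2.2, 0, 0), c(0, 5, 0)),
             c = c(3.29, 0, 0))
  tr <- manual_nac_traj(list(fr))
  crit <- nac_criterion(1, list(site_definition("21", 3:5, 2)))
  cls <- classify_frames(tr, crit)
  expect_true(cls$nac)          # the 2.2 A hydrogen is collinear with C
  expect_equal(cls$distance, 2.2)
  expect_equal(cls$hydrogen, 4) # roster index of the closest hydrogen

  trace <- min_distance_trace(tr, site_definition("21", 3:5, 2), 1)
  expect_equal(trace$distance, 2.2)
})

test_that("random-frame classification equals the brute-force oracle", {
  gen <- gen_reactive_trajectory(reactive_trajectory_spec(
    n_frames = 300,
    sites = list(list("16a", 1, 0.3), list("21", 3, 0.1), list("12b", 2, 0.5)),
    seed = 31))
  got <- classify_frames(gen$trajectory, gen$criterion)
  want <- oracle_classify(gen$trajectory, gen$criterion)
  expect_equal(got$nac, want$nac)
  expect_equal(got$frame, want$frame)
  expect_equal(got$site, want$site)
})

test_that("nac percentages are deterministic and preserve site order", {
  gen <- gen_reactive_trajectory(reactive_trajectory_spec(
    n_frames = 100, sites = list(list("21", 3, 0.42), list("16a", 1, 0)),
    seed = 32))
  p1 <- nac_percentages(gen$trajectory, gen$criterion)
  p2 <- nac_percentages(gen$trajectory, gen$criterion)
  expect_identical(p1, p2)
  expect_equal(p1$site, c("21", "16a"))
  expect_equal(p1$nac_percent, c(42, 0))
  expect_equal(p1$total_frames, c(100L, 100L))
})

test_that("nac percentages are invariant under per-frame rigid motion", {
  withr::with_seed(33, {
    gen <- gen_reactive_trajectory(reactive_trajectory_spec(
      n_frames = 120, sites = list(list("16a", 2, 0.25)), seed = 34))
    base <- nac_percentages(gen$trajectory, gen$criterion)
    moved <- gen$trajectory
    for (f in seq_len(n_frames(moved))) {
      rot <- random_rotation()
      moved$coords[, , f] <- sweep(moved$coords[, , f] %*% rot, 2,
                                   -rnorm(3, sd = 20))
    }
    expect_equal(nac_percentages(moved, gen$criterion)$nac_percent,
                 base$nac_percent, tolerance = 1e-10)
  })
})

test_that("widening the criterion never lowers a NAC percentage", {
  for (seed in 35:38) {
    gen <- gen_reactive_trajectory(reactive_trajectory_spec(
      n_frames = 150, sites = list(list("16a", 1, 0.2), list("21", 3, 0.4)),
      seed = seed))
    crit <- gen$criterion
    narrow <- nac_criterion(crit$acceptor, crit$sites, d_max = 2.5,
                            theta_tol = 10)
    wide_d <- nac_criterion(crit$acceptor, crit$sites, d_max = 3.0,
                            theta_tol = 10)
    wide_t <- nac_criterion(crit$acceptor, crit$sites, d_max = 2.5,
                            theta_tol = 30)
    p0 <- nac_percentages(gen$trajectory, narrow)$nac_percent
    expect_true(all(nac_percentages(gen$trajectory, wide_d)$nac_percent >= p0))
    expect_true(all(nac_percentages(gen$trajectory, wide_t)$nac_percent >= p0))
  }
})

test_that("streaming sum of per-frame classifications equals the batch count", {
  gen <- gen_reactive_trajectory(reactive_trajectory_spec(
    n_frames = 80, sites = list(list("21", 3, 0.3)), seed = 39))
  cls <- classify_frames(gen$trajectory, gen$criterion)
  pct <- nac_percentages(gen$trajectory, gen$criterion)
  expect_equal(sum(cls$nac), pct$nac_frames)
})

test_that("criterion validation catches bad configurations", {
  expect_error(nac_criterion(1, list()), "configuration")
  s <- site_definition("a", 2, 3)
  expect_error(nac_criterion(2, list(s)), "acceptor")
  expect_error(nac_criterion(1, list(s, site_definition("a", 4, 5))),
               "duplicate")
  expect_error(site_definition("x", integer(0), 2), "hydrogen")
  expect_error(site_definition("x", 2, 2), "distinct")
  expect_error(nac_criterion(1, list(s), d_max = -1), "d_max")
})

test_that("min-distance trace equals the per-frame brute-force minimum", {
  withr::with_seed(40, {
    tr <- random_trajectory(12, 60)
    site <- site_definition("s", hydrogens = c(3, 5, 9), carbon = 2)
    trace <- min_distance_trace(tr, site, acceptor = 1)
    want <- vapply(seq_len(60), function(f) {
      xyz <- frame_coords(tr, f)
      min(sqrt(rowSums(sweep(xyz[c(3, 5, 9), ], 2, xyz[1, ])^2)))
    }, numeric(1))
    expect_equal(trace$distance, want)
  })
})
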