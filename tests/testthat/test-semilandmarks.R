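test_that("patch sampling returns the requested count, evenly, on the patch", {
  tpl <- fix_template3()
  pts <- sample_patch(tpl$shell, "lower_occipital", 52, seed = 3)
  expect_equal(nrow(pts), 52)
  # all sampled points sit on faces labelled with the requested patch
  cp <- closest_point_on_mesh(tpl$shell, pts)
  expect_lt(max(cp$distance), 1e-9)
  expect_true(all(tpl$shell$patch_labels[cp$face] == "lower_occipital"))

  # seeded determinism
  expect_identical(pts, sample_patch(tpl$shell, "lower_occipital", 52, seed = 3))
  expect_false(identical(pts,
                         sample_patch(tpl$shell, "lower_occipital", 52,
                                      seed = 4)))

  # farthest-point thinning keeps nearest-neighbour spacing tight
  nn <- apply(as.matrix(stats::dist(pts)), 1, function(r) min(r[r > 0]))
  expect_lt(stats::sd(nn) / mean(nn), 0.5)

  expect_error(sample_patch(tpl$shell, "nonexistent", 10), "patch")
})

test_that("mirroring is an involution that fixes the plane and lands on the
           symmetric mesh", {
  plane <- list(point = c(0, 1, 2), normal = c(1, 0, 0))
  set.seed(5)
  pts <- matrix(rnorm(30), 10, 3) * 10
  m <- mirror_points(pts, plane)
  expect_lt(max(abs(mirror_points(m, plane) - pts)), 1e-12)
  on_plane <- cbind(0, rnorm(5), rnorm(5))
  expect_lt(max(abs(mirror_points(on_plane, plane) - on_plane)), 1e-12)
  expect_error(mirror_points(pts, list(point = c(0, 0, 0),
                                       normal = c(0, 0, 0))), "zero")

  # the synthetic skull is bilaterally symmetric: mirrored surface samples
  # stay on the surface
  tpl <- fix_template3()
  mid <- midsagittal_plane(tpl$landmarks)
  smp <- sample_patch(tpl$shell, "calvarial", 40, seed = 9)
  mirrored <- mirror_points(smp, mid)
  expect_lt(max(closest_point_on_mesh(tpl$shell, mirrored)$distance), 1e-6)

  # landmark-set mirroring flips side tags
  lm_m <- mirror_points(tpl$landmarks, mid)
  expect_identical(lm_m$side[tpl$landmarks$side == "L"],
                   rep("R", sum(tpl$landmarks$side == "L")))
})

test_that("template construction validates counts and surface contact", {
  stl <- fix_slm_small()
  counts <- slm_region_counts(stl)
  expect_equal(unname(counts["total"]), 2 * (15 + 60 + 8))
  expect_equal(unname(counts["midface"]), 30)
  expect_equal(unname(counts["neurocranium"]), 136)
  expect_equal(sum(stl$side == "L"), sum(stl$side == "R"))
  d <- closest_point_on_mesh(fix_template3()$shell, stl$points)$distance
  expect_lt(max(d), 1e-6)
})

test_that("template projection is exact on the reference and equivariant
           under rigid motion", {
  tpl <- fix_template3()
  stl <- fix_slm_small()
  init <- project_slm_template(stl, tpl$shell, tpl$landmarks)
  expect_lt(max(abs(init - stl$points)), 1e-8)

  R <- random_rotation(17)
  tvec <- c(30, -12, 4)
  move <- function(x) x %*% R + matrix(tvec, nrow(x), 3, byrow = TRUE)
  shell_m <- cm_mesh(move(tpl$shell$vertices), tpl$shell$faces,
                     patch_labels = tpl$shell$patch_labels)
  lms_m <- tpl$landmarks
  lms_m$coords[] <- move(tpl$landmarks$coords)
  init_m <- project_slm_template(stl, shell_m, lms_m)
  expect_lt(max(abs(init_m - move(stl$points))), 1e-6)

  # a different-age target still receives on-surface semilandmarks
  sp <- grow_skull(tpl, 1200, "M", noise_sd = 0)
  init2 <- project_slm_template(stl, sp$shell, sp$landmarks)
  expect_lt(max(closest_point_on_mesh(sp$shell, init2)$distance), 1e-8)

  missing <- lm_subset(sp$landmarks, 1:80)
  expect_error(project_slm_template(stl, sp$shell, missing), "missing")
})

test_that("sliding lowers bending energy monotonically and stays on the
           surface", {
  tpl <- fix_template3()
  stl <- fix_slm_small()

  # target = reference: nothing to do, energy already zero
  init <- project_slm_template(stl, tpl$shell, tpl$landmarks)
  res0 <- slide_semilandmarks(init, tpl$shell, tpl$landmarks, stl)
  expect_lt(res0$energy_trace[1], 1e-12)
  expect_lt(max(abs(res0$slm - stl$points)), 1e-6)

  # grown target: the trace never increases and the result stays on-surface
  sp <- grow_skull(tpl, 1100, "F", noise_sd = 0)
  init2 <- project_slm_template(stl, sp$shell, sp$landmarks)
  res <- slide_semilandmarks(init2, sp$shell, sp$landmarks, stl,
                             max_iter = 4)
  tr <- res$energy_trace
  expect_true(all(diff(tr) <= 1e-9 * max(tr[1], 1)))
  expect_lt(max(closest_point_on_mesh(sp$shell, res$slm)$distance), 1e-6)
  expect_lt(tr[length(tr)], tr[1] + 1e-12)
})

test_that("projection plus sliding is equivariant under rigid motion of the
           target", {
  tpl <- fix_template3()
  stl <- fix_slm_small()
  sp <- grow_skull(tpl, 400, "F", noise_sd = 0)
  R <- random_rotation(23)
  tvec <- c(-8, 15, 40)
  move <- function(x) x %*% R + matrix(tvec, nrow(x), 3, byrow = TRUE)
  shell_m <- cm_mesh(move(sp$shell$vertices), sp$shell$faces)
  lms_m <- sp$landmarks
  lms_m$coords[] <- move(sp$landmarks$coords)

  s1 <- slide_semilandmarks(project_slm_template(stl, sp$shell, sp$landmarks),
                            sp$shell, sp$landmarks, stl)
  s2 <- slide_semilandmarks(project_slm_template(stl, shell_m, lms_m),
                            shell_m, lms_m, stl)
  expect_lt(max(abs(move(s1$slm) - s2$slm)), 1e-6)
})
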