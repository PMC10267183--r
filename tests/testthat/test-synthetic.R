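test_that("the template skull carries 88 named landmarks on a closed shell", {
  tpl <- fix_template3()
  expect_equal(nrow(tpl$landmarks$coords), 88)
  expect_false(anyDuplicated(rownames(tpl$landmarks$coords)) > 0)
  expect_equal(sum(tpl$landmarks$gpa_excluded), 2)
  expect_setequal(rownames(tpl$landmarks$coords)[tpl$landmarks$gpa_excluded],
                  c("Euryon_L", "Euryon_R"))
  expect_identical(sort(rownames(tpl$landmarks$coords)),
                   sort(landmark_roster()$name))

  wt <- mesh_watertight(tpl$shell)
  expect_true(wt$watertight)
  # genus 0: V - E + F = 2
  nv <- nrow(tpl$shell$vertices); nf <- nrow(tpl$shell$faces)
  expect_equal(nv - (3 * nf / 2) + nf, 2)

  expect_error(make_template_skull(1), "resolution")
})

test_that("the outer shell volume matches the analytic ellipsoid", {
  tpl4 <- fixture("tpl4", function() make_template_skull(4))
  semi <- tpl4$template$shell_semi
  expect_lt(abs(closed_mesh_volume(tpl4$shell) - 4 / 3 * pi * prod(semi)) /
              (4 / 3 * pi * prod(semi)), 0.01)
})

test_that("growing at the reference age reproduces the template and sizes
           follow the growth curve", {
  tpl <- fix_template2()
  p <- tpl$params
  sp <- grow_skull(tpl, tpl$age_days, "F", noise_sd = 0)
  expect_lt(max(abs(sp$landmarks$coords - tpl$landmarks$coords)), 1e-9)
  expect_lt(max(abs(sp$shell$vertices - tpl$shell$vertices)), 1e-9)

  sp0 <- grow_skull(tpl, 0, "F", noise_sd = 0)
  sp48 <- grow_skull(tpl, 1460, "F", noise_sd = 0)
  want <- size_curve_eval(p, age_to_months(1460)) / size_curve_eval(p, 0)
  expect_equal(centroid_size(sp48$landmarks) / centroid_size(sp0$landmarks),
               want, tolerance = 1e-10)

  # male specimens carry the size-for-age offset, shared shape trajectory
  spM <- grow_skull(tpl, 600, "M", noise_sd = 0)
  spF <- grow_skull(tpl, 600, "F", noise_sd = 0)
  expect_equal(centroid_size(spM$landmarks) / centroid_size(spF$landmarks),
               p$sex_size_offset, tolerance = 1e-6)

  expect_error(grow_skull(tpl, -1, "F"), "negative")
  expect_error(grow_skull(tpl, 2000, "F"), "beyond")
  expect_error(grow_skull(tpl, 100, "F", noise_sd = -1), "noise_sd")
})

test_that("specimen noise is seeded, reproducible bitwise and has the
           expected magnitude", {
  tpl <- fix_template2()
  a <- grow_skull(tpl, 700, "M", rng_seed = 99, with_mesh = FALSE)
  b <- grow_skull(tpl, 700, "M", rng_seed = 99, with_mesh = FALSE)
  expect_identical(a$landmarks$coords, b$landmarks$coords)
  c <- grow_skull(tpl, 700, "M", rng_seed = 100, with_mesh = FALSE)
  expect_false(identical(a$landmarks$coords, c$landmarks$coords))

  # RMS displacement over >= 1000 points approaches noise_sd * sqrt(3)
  sd0 <- 1.5
  disp2 <- unlist(lapply(1:12, function(i) {
    clean <- grow_skull(tpl, 500, "F", noise_sd = 0, with_mesh = FALSE)
    noisy <- grow_skull(tpl, 500, "F", noise_sd = sd0, rng_seed = 1e5 + i,
                        with_mesh = FALSE)
    rowSums((noisy$landmarks$coords - clean$landmarks$coords)^2)
  }))
  expect_gt(length(disp2), 1000)
  expect_lt(abs(sqrt(mean(disp2)) - sd0 * sqrt(3)) / (sd0 * sqrt(3)), 0.05)
})

test_that("true cavity volumes equal the growth curves exactly and cavities
           stay inside the shell", {
  tpl <- fix_template2()
  p <- tpl$params
  for (d in c(0, 200, 700, 1460)) {
    sp <- grow_skull(tpl, d, "F", noise_sd = 0, with_mesh = FALSE)
    want <- volume_curves_eval(p, age_to_months(d))
    expect_equal(unname(sp$true_volumes$volumes), unname(want),
                 tolerance = 1e-9)
    # sampled cavity surface points stay strictly inside the shell
    semi <- tpl$template$shell_semi * sp$cs / tpl$cs
    u <- icosphere(1)$vertices
    for (nm in names(sp$cavity_geometry)) {
      g <- sp$cavity_geometry[[nm]]
      pts <- sweep(sweep(u, 2, g$semi, "*"), 2, g$center, "+")
      expect_lt(max(rowSums(sweep(pts, 2, semi, "/")^2)), 1)
    }
  }
})

test_that("cohorts honour the requested sex split and are reproducible", {
  tpl <- fix_template2()
  coh <- generate_cohort(217, sex_ratio = 123 / 217, seed = 3,
                         with_mesh = FALSE, template = tpl)
  expect_equal(sum(coh$metadata$sex == "M"), 123)
  expect_equal(sum(coh$metadata$sex == "F"), 94)
  expect_true(all(coh$metadata$age_days >= 0 & coh$metadata$age_days <= 1460))
  expect_equal(coh$metadata$age_months, coh$metadata$age_days / 30.41)

  a <- generate_cohort(10, seed = 5, with_mesh = FALSE, template = tpl)
  b <- generate_cohort(10, seed = 5, with_mesh = FALSE, template = tpl)
  expect_identical(lapply(a$specimens, function(s) s$landmarks$coords),
                   lapply(b$specimens, function(s) s$landmarks$coords))
  expect_identical(a$metadata, b$metadata)

  expect_error(generate_cohort(1, template = tpl), "at least 2")
  expect_error(generate_cohort(10, sex_ratio = 1.2, template = tpl),
               "sex_ratio")

  skew <- generate_cohort(400, age_sampler = "paper_like", seed = 8,
                          with_mesh = FALSE, template = tpl)
  # the paper-like sampler front-loads the first year of life
  frac_y1 <- mean(skew$metadata$age_days < 365)
  expect_gt(frac_y1, 0.30)
  expect_lt(mean(skew$metadata$age_days >= 1095), 0.20)
})

test_that("cohorts write a complete, readable bundle", {
  tpl <- fix_template2()
  coh <- generate_cohort(3, seed = 12, resolution = 2, template = tpl)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_length(list.files(dir, pattern = "\\.ply$"), 3)
  expect_length(list.files(dir, pattern = "_landmarks\\.csv$"), 3)
  lm1 <- read_landmarks_csv(file.path(dir, "syn0001_landmarks.csv"))
  expect_equal(lm1$coords, coh$specimens[[1]]$landmarks$coords,
               tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(truth$params$landmark_noise_sd,
               coh$params$landmark_noise_sd)
})
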