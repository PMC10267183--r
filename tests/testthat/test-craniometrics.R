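test_that("the measurement panel yields 47 dimensions that match direct
           recomputation and bilateral symmetry", {
  tpl <- fix_template3()
  dims <- linear_dimensions(tpl$landmarks, tpl$shell)
  expect_length(dims, 47)
  expect_true(all(is.finite(dims)) && all(dims > 0))

  # independent recomputation of a few entries from raw coordinates
  cc <- tpl$landmarks$coords
  expect_equal(unname(dims["max_cranial_breadth"]),
               sqrt(sum((cc["Euryon_L", ] - cc["Euryon_R", ])^2)),
               tolerance = 1e-12)
  expect_equal(unname(dims["basion_bregma_height"]),
               sqrt(sum((cc["Basion", ] - cc["Bregma", ])^2)),
               tolerance = 1e-12)

  # noise-free specimens are bilaterally symmetric
  expect_equal(unname(dims["orbital_breadth_left"]),
               unname(dims["orbital_breadth_right"]), tolerance = 1e-9)
  expect_equal(unname(dims["orbital_height_left"]),
               unname(dims["orbital_height_right"]), tolerance = 1e-9)

  # the circumference entry needs the mesh and exceeds the glabella chord
  expect_gt(unname(dims["cranial_circumference"]),
            2 * unname(dims["max_cranial_length"]))

  short <- lm_subset(tpl$landmarks, 1:40)
  expect_error(linear_dimensions(short, tpl$shell), "missing landmark")
})

test_that("indices follow their defining formulas on hand-computable input", {
  dims <- c(max_cranial_breadth = 90, max_cranial_length = 90,
            basion_bregma_height = 90, bizygomatic_breadth = 72,
            upper_facial_height = 36, orbital_height_left = 27,
            orbital_breadth_left = 30, nasal_breadth = 12, nasal_height = 24,
            internal_palatal_width = 22, max_palatal_length = 40,
            foramen_magnum_breadth = 24, foramen_magnum_length = 30)
  idx <- index_panel(dims)
  expect_equal(unname(idx["CM"]), 90)
  expect_equal(unname(idx["CI"]), 100)
  expect_equal(unname(idx["CFI"]), 80)
  expect_equal(unname(idx["UFI"]), 50)
  expect_equal(unname(idx["LOI"]), 90)
  expect_equal(unname(idx["NI"]), 50)
  expect_equal(unname(idx["PI"]), 55)
  expect_equal(unname(idx["FMI"]), 80)

  expect_error(index_panel(dims[c(1, 3)]), "not found")
  dims["max_cranial_length"] <- 0
  expect_error(index_panel(dims), "zero denominator")
})

test_that("volume sets carry exact cube-root and proportional views", {
  vs <- volume_set(1000, 8, 27, 64)
  expect_equal(unname(vs$cvols), c(10, 2, 3, 4))
  expect_equal(unname(vs$cpvols), 100 * c(10, 2, 3, 4) / 19,
               tolerance = 1e-12)

  eq <- volume_set(5e5, 5e5, 5e5, 5e5)
  expect_equal(unname(eq$cpvols), rep(25, 4))

  set.seed(8)
  for (i in 1:5) {
    v <- stats::runif(4, 1e3, 1e6)
    vs_i <- volume_set(v[1], v[2], v[3], v[4])
    expect_equal(sum(vs_i$cpvols), 100, tolerance = 1e-9)
    expect_true(all(order(vs_i$volumes) == order(vs_i$cvols)))
  }
  expect_error(volume_set(-1, 2, 3, 4), "positive")
})

test_that("measurements scale as lengths, volumes and dimensionless ratios", {
  tpl <- fix_template2()
  sp <- grow_skull(tpl, 500, "F", noise_sd = 0)
  s <- 1.7
  scaled_lms <- sp$landmarks
  scaled_lms$coords <- scaled_lms$coords * s
  scaled_shell <- cm_mesh(sp$shell$vertices * s, sp$shell$faces)
  d1 <- linear_dimensions(sp$landmarks, sp$shell)
  d2 <- linear_dimensions(scaled_lms, scaled_shell)
  expect_equal(d2, s * d1, tolerance = 1e-9)
  i1 <- index_panel(d1); i2 <- index_panel(d2)
  # the cranial module is a length (mm) and scales; the 7 ratios do not
  expect_equal(unname(i2["CM"]), s * unname(i1["CM"]), tolerance = 1e-9)
  expect_equal(i2[names(i2) != "CM"], i1[names(i1) != "CM"],
               tolerance = 1e-9)

  scaled_mesh <- cm_mesh(sp$mesh$vertices * s, sp$mesh$faces,
                         patch_labels = sp$mesh$patch_labels)
  spec <- cavity_spec("icv", sp$cavity_geometry$icv$center * s)
  v1 <- cavity_volume(sp$mesh, cavity_spec("icv", sp$cavity_geometry$icv$center))
  v2 <- cavity_volume(scaled_mesh, spec)
  expect_equal(v2, s^3 * v1, tolerance = 1e-9)
  vs1 <- volume_set(v1, 2, 3, 4); vs2 <- volume_set(v2, 2 * s^3, 3 * s^3, 4 * s^3)
  expect_equal(unname(vs2$cvols), s * unname(vs1$cvols), tolerance = 1e-9)
  expect_equal(unname(vs2$cpvols), unname(vs1$cpvols), tolerance = 1e-9)
})

test_that("cavity extraction recovers closed-form ellipsoid volumes", {
  # free-standing ellipsoid cavity with a small aperture
  geom <- list(center = c(10, -5, 2), semi = c(60, 45, 50),
               dir = c(0, 0, 1), half_angle = 18)
  cav <- craniomorph:::make_cavity_mesh(geom, subdiv = 4)
  vol <- cavity_volume(cav, cavity_spec("toy", geom$center))
  want <- 4 / 3 * pi * 60 * 45 * 50
  expect_lt(abs(vol - want) / want, 0.02)

  # spherical cavity whose aperture removes ~5% of the surface area:
  # cap area fraction (1 - cos a) / 2 = 5% at a ~ 25.8 degrees
  geo2 <- list(center = c(0, 0, 0), semi = c(30, 30, 30),
               dir = c(0, 0, 1), half_angle = 25.8)
  cav2 <- craniomorph:::make_cavity_mesh(geo2, subdiv = 4)
  vol2 <- cavity_volume(cav2, cavity_spec("sphere", c(0, 0, 0)))
  want2 <- 4 / 3 * pi * 30^3
  expect_lt(abs(vol2 - want2) / want2, 0.02)

  # rigid motion leaves the measured volume unchanged
  R <- random_rotation(29)
  moved <- cm_mesh(cav$vertices %*% R + matrix(c(5, 8, -12), nrow(cav$vertices),
                                              3, byrow = TRUE), cav$faces)
  ctr_m <- as.vector(geom$center %*% R) + c(5, 8, -12)
  vol_m <- cavity_volume(moved, cavity_spec("toy", ctr_m))
  expect_equal(vol_m, vol, tolerance = 1e-9)

  expect_error(cavity_volume(cav, cavity_spec("outside", c(500, 0, 0))),
               "not inside")
})

test_that("left and right orbital volumes agree on symmetric specimens", {
  tpl <- fix_template3()
  sp <- grow_skull(tpl, 800, "F", noise_sd = 0)
  mv <- measure_cavity_volumes(sp, include_right_orbit = TRUE)
  lov <- mv$volumes$volumes[["lov"]]
  expect_lt(abs(mv$rov - lov) / lov, 0.005)
})

test_that("the per-specimen measurement panel binds up correctly", {
  tpl <- fix_template2()
  sp <- grow_skull(tpl, 365, "F", noise_sd = 0)
  row <- measurement_panel(sp, measure_volumes = FALSE)
  expect_equal(nrow(row), 1)
  # 47 dims + 8 indices + 4 volumes + 4 cvols + 4 cpvols + age/sex columns
  expect_equal(ncol(row), 47 + 8 + 12 + 3)
  expect_equal(row$icv, unname(sp$true_volumes$volumes["icv"]))
  expect_equal(row$sex, "F")
})
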