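#' Growth parameters for the synthetic skull generator
#'
#' The generator emulates the structure of early craniofacial ontogeny:
#' a shared male/female allometric shape vector, fast-then-slow growth in
#' centroid size, saturating (logistic) intracranial and orbital volume
#' growth, linear nasal-cavity and intraoral volume growth, a male
#' size-for-age offset (heterochrony by size only), and i.i.d. Gaussian
#' landmark noise standing in for measurement error and individual
#' variation.
#'
#' Curves (age `t` in months, 1 month = 30.41 days):
#' * centroid size: `cs(t) = s0 + s1 * (1 - exp(-t / tau))` (mm), strictly
#'   increasing;
#' * ICV, LOV: `V(t) = V_max / (1 + exp(-k (t - t0)))` (mm^3), nondecreasing
#'   and bounded by `V_max`;
#' * NCV, UIV: `V(t) = intercept + slope * t` (mm^3).
#'
#' `trajectory_divergence_deg` injects an angle between the sexes'
#' allometric vectors; the default 0 encodes a shared trajectory and the
#' knob exists solely for power studies of the angle test.
#'
#' @param size_curve list `(s0, s1, tau)`.
#' @param sex_size_offset multiplicative male size factor, `>= 1`.
#' @param allometric_scale magnitude of shape displacement per unit Ln(CS).
#' @param icv_curve,lov_curve lists `(V_max, k, t0)`.
#' @param ncv_curve,uiv_curve lists `(intercept, slope)`.
#' @param landmark_noise_sd mm.
#' @param trajectory_divergence_deg degrees between sex allometric vectors.
#' @return object of class `cm_growth_params`.
#' @export
growth_params <- function(size_curve = list(s0 = 550, s1 = 210, tau = 9),
                          sex_size_offset = 1.05,
                          allometric_scale = 0.28,
                          icv_curve = list(V_max = 9e5, k = 0.15, t0 = 5),
                          lov_curve = list(V_max = 2.6e4, k = 0.12, t0 = -2.6),
                          ncv_curve = list(intercept = 1.0e4, slope = 450),
                          uiv_curve = list(intercept = 2.0e4, slope = 600),
                          landmark_noise_sd = 1.5,
                          trajectory_divergence_deg = 0) {
  stopifnot(size_curve$s1 > 0, size_curve$tau > 0, size_curve$s0 > 0)
  if (sex_size_offset < 1) stop("sex_size_offset must be >= 1")
  if (landmark_noise_sd < 0) stop("landmark_noise_sd must be >= 0")
  for (cv in list(icv_curve, lov_curve))
    stopifnot(cv$V_max > 0, cv$k > 0)
  for (cv in list(ncv_curve, uiv_curve))
    stopifnot(cv$intercept > 0, cv$slope >= 0)
  structure(list(size_curve = size_curve,
                 sex_size_offset = sex_size_offset,
                 allometric_scale = allometric_scale,
                 icv_curve = icv_curve, lov_curve = lov_curve,
                 ncv_curve = ncv_curve, uiv_curve = uiv_curve,
                 landmark_noise_sd = landmark_noise_sd,
                 trajectory_divergence_deg = trajectory_divergence_deg),
            class = "cm_growth_params")
}

DAYS_PER_MONTH <- 30.41

#' Convert age in days to months (1 month = 30.41 days)
#' @param age_days numeric.
#' @export
age_to_months <- function(age_days) age_days / DAYS_PER_MONTH

#' Evaluate the centroid-size growth curve (mm)
#' @param params a `cm_growth_params`.
#' @param months age in months.
#' @export
size_curve_eval <- function(params, months) {
  with(params$size_curve, s0 + s1 * (1 - exp(-months / tau)))
}

logistic_eval <- function(curve, months) {
  with(curve, V_max / (1 + exp(-k * (months - t0))))
}

affine_eval <- function(curve, months) {
  with(curve, intercept + slope * months)
}

#' Evaluate the four cavity-volume growth curves (mm^3)
#' @param params a `cm_growth_params`.
#' @param months age in months.
#' @return named vector (icv, lov, ncv, uiv).
#' @export
volume_curves_eval <- function(params, months) {
  c(icv = logistic_eval(params$icv_curve, months),
    lov = logistic_eval(params$lov_curve, months),
    ncv = affine_eval(params$ncv_curve, months),
    uiv = affine_eval(params$uiv_curve, months))
}

# ---- template geometry constants -------------------------------------------
# all in the template frame before global scaling; shell centred at origin,
# +x = subject's left, +y = anterior, +z = superior

shell_semi_base <- c(70, 88, 66)

cavity_base <- list(
  icv = list(center = c(0, -16, 14), ratio = c(1.20, 1.38, 0.95),
             dir = c(0, -0.25, -1), half_angle = 14),
  lov = list(center = c(29, 52, -4), ratio = c(1.00, 1.05, 1.10),
             dir = c(0, 0.97, 0.24), half_angle = 25),
  rov = list(center = c(-29, 52, -4), ratio = c(1.00, 1.05, 1.10),
             dir = c(0, 0.97, 0.24), half_angle = 25),
  ncv = list(center = c(0, 58, -18), ratio = c(0.90, 0.90, 0.95),
             dir = c(0, 1, -0.25), half_angle = 18),
  uiv = list(center = c(0, 34, -44), ratio = c(1.50, 1.00, 0.58),
             dir = c(0, 0.35, -1), half_angle = 16))

# the right orbit mirrors the left and shares its volume curve
cavity_volume_key <- c(icv = "icv", lov = "lov", rov = "lov",
                       ncv = "ncv", uiv = "uiv")

# cavity geometry at a given age: centres scale with the linear size factor,
# semi-axes are set so the analytic ellipsoid volume equals the growth curve
cavity_geometry_at <- function(params, months, lin_scale) {
  vols <- volume_curves_eval(params, months)
  out <- list()
  for (nm in names(cavity_base)) {
    cb <- cavity_base[[nm]]
    V <- vols[[cavity_volume_key[[nm]]]]
    s_v <- (V * 3 / (4 * pi * prod(cb$ratio)))^(1 / 3)
    out[[nm]] <- list(center = cb$center * lin_scale,
                      semi = cb$ratio * s_v,
                      dir = cb$dir / sqrt(sum(cb$dir^2)),
                      half_angle = cb$half_angle,
                      volume = unname(V))
  }
  out
}

# ellipsoid cavity mesh with a polar aperture cut in sphere-parameter space
make_cavity_mesh <- function(geom, subdiv) {
  sph <- icosphere(subdiv)
  cen <- mesh_centroids(sph)
  u <- cen / sqrt(rowSums(cen^2))
  ang <- acos(pmin(1, pmax(-1, as.vector(u %*% geom$dir)))) * 180 / pi
  keep <- which(ang > geom$half_angle)
  open_sph <- subset_mesh(sph, keep)
  v <- sweep(sweep(open_sph$vertices, 2, geom$semi, "*"), 2, geom$center, "+")
  cm_mesh(v, open_sph$faces)
}

# point on the aperture rim of a cavity, azimuth psi (deg) about the
# aperture axis in sphere-parameter space; psi = 0 toward +x
cavity_rim_point <- function(geom, psi_deg) {
  d <- geom$dir
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  a <- geom$half_angle * pi / 180
  psi <- psi_deg * pi / 180
  u <- cos(a) * d + sin(a) * (cos(psi) * e1 + sin(psi) * e2)
  geom$center + geom$semi * u
}

point_on_ellipsoid <- function(dir, semi) {
  d <- dir / sqrt(sum(dir^2))
  t <- 1 / sqrt(sum((d / semi)^2))
  t * d
}

# ---- the 88-landmark template definition -----------------------------------
# midline entries place a point on the shell along a direction (or on a
# midline cavity rim); paired entries define the left (+x) member, the right
# is its exact mirror. Numbers follow the roster CSV.

landmark_definitions <- function() {
  M <- function(number, name, type, p1, p2 = NA, p3 = NA)
    data.frame(number = number, name = name, side = "midline", type = type,
               p1 = p1, p2 = p2, p3 = p3)
  P <- function(number_l, number_r, name, type, p1, p2 = NA, p3 = NA)
    rbind(data.frame(number = number_l, name = paste0(name, "_L"), side = "L",
                     type = type, p1 = p1, p2 = p2, p3 = p3),
          data.frame(number = number_r, name = paste0(name, "_R"), side = "R",
                     type = type, p1 = p1, p2 = p2, p3 = p3))
  rbind(
    M(1,  "Glabella",        "shell", 0, 0.95, 0.35),
    M(2,  "Ophryon",         "shell", 0, 0.90, 0.45),
    M(3,  "Metopion",        "shell", 0, 0.80, 0.62),
    M(4,  "Nasion",          "shell", 0, 0.98, 0.22),
    M(5,  "Rhinion",         "shell", 0, 1.00, 0.05),
    M(6,  "Nasospinale",     "shell", 0, 1.00, -0.12),
    M(7,  "Subspinale",      "shell", 0, 1.00, -0.20),
    M(8,  "Prosthion",       "shell", 0, 0.98, -0.32),
    M(9,  "Orale",           "uiv_rim", 90),
    M(10, "Staphylion",      "uiv_rim", 270),
    M(11, "Hormion",         "shell", 0, 0.35, -0.95),
    M(12, "Sphenobasion",    "shell", 0, 0.15, -1.00),
    M(13, "Basion",          "icv_rim", 270),
    M(14, "Opisthion",       "icv_rim", 90),
    M(15, "Inion",           "shell", 0, -0.90, -0.35),
    M(16, "Obelion",         "shell", 0, -0.50, 0.85),
    M(17, "Vertex",          "shell", 0, 0.00, 1.00),
    M(48, "Bregma",          "shell", 0, 0.30, 0.95),
    M(49, "Lambda",          "shell", 0, -0.85, 0.50),
    M(50, "Opisthocranion",  "shell", 0, -1.00, 0.05),
    P(18, 19, "Euryon",              "shell", 1.00, -0.05, 0.10),
    P(20, 21, "Frontotemporale",     "shell", 0.62, 0.60, 0.42),
    P(22, 23, "Stephanion",          "shell", 0.70, 0.35, 0.62),
    P(24, 25, "Coronale",            "shell", 0.82, 0.20, 0.50),
    P(26, 27, "Pterion",             "shell", 0.90, 0.45, 0.20),
    P(28, 29, "Maxillofrontale",     "lov_rim", 160),
    P(30, 31, "Ectoconchion",        "lov_rim", 0),
    P(32, 33, "Supraorbitale",       "lov_rim", 80),
    P(34, 35, "Orbitale",            "lov_rim", 280),
    P(36, 37, "Dacryon",             "lov_rim", 120),
    P(38, 39, "Zygoorbitale",        "lov_rim", 320),
    P(40, 41, "Frontomalare_orbitale", "lov_rim", 40),
    P(42, 43, "Frontomalare_temporale", "shell", 0.72, 0.62, 0.18),
    P(44, 45, "Alare",               "ncv_rim", 0),
    P(46, 47, "Nariale",             "ncv_rim", 55),
    P(51, 56, "Auriculare",          "shell", 0.98, -0.10, -0.15),
    P(52, 53, "Sphenion",            "shell", 0.88, 0.50, 0.40),
    P(54, 55, "Krotaphion",          "shell", 0.92, 0.35, 0.35),
    P(57, 62, "Porion",              "shell", 0.95, -0.05, -0.30),
    P(58, 59, "Entomion",            "shell", 0.90, -0.40, 0.00),
    P(60, 61, "Asterion",            "shell", 0.85, -0.60, -0.20),
    P(63, 64, "Zygion",              "shell", 0.98, 0.50, -0.25),
    P(65, 66, "Zygomaxillare",       "shell", 0.72, 0.85, -0.30),
    P(67, 68, "Jugale",              "shell", 0.85, 0.62, -0.12),
    P(69, 70, "Zygotemporale",       "shell", 0.95, 0.30, -0.20),
    P(71, 72, "Malare",              "shell", 0.80, 0.75, -0.10),
    P(73, 74, "Infratemporale",      "shell", 0.85, 0.40, -0.45),
    P(75, 76, "Ectomolare",          "uiv_rim", 15),
    P(77, 78, "Endomolare",          "uiv_inner", 15),
    P(79, 80, "Mastoidale",          "shell", 0.85, -0.30, -0.60),
    P(81, 82, "Condylion_laterale",  "icv_rim", 210),
    P(83, 84, "Foramen_magnum_laterale", "icv_rim", 180),
    P(85, 86, "Parietale",           "shell", 0.75, -0.55, 0.55),
    P(87, 88, "Supraporion",         "shell", 0.97, 0.00, 0.05))
}

# landmark coordinates given shell semi-axes and cavity geometry
place_landmarks <- function(defs, shell_semi, cavities) {
  mirror_x <- function(p) c(-p[1], p[2], p[3])
  coords <- matrix(NA_real_, nrow(defs), 3)
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    p <- switch(d$type,
      shell = point_on_ellipsoid(c(d$p1, d$p2, d$p3), shell_semi),
      icv_rim = cavity_rim_point(cavities$icv, d$p1),
      ncv_rim = cavity_rim_point(cavities$ncv, d$p1),
      lov_rim = cavity_rim_point(cavities$lov, d$p1),
      uiv_rim = cavity_rim_point(cavities$uiv, d$p1),
      uiv_inner = {
        rp <- cavity_rim_point(cavities$uiv, d$p1)
        cavities$uiv$center + 0.75 * (rp - cavities$uiv$center)
      },
      stop("unknown landmark type: ", d$type))
    if (d$side == "R") p <- mirror_x(p)
    coords[i, ] <- p
  }
  ord <- order(defs$number)
  landmark_set(coords[ord, , drop = FALSE],
               names = defs$name[ord],
               role = "LM",
               side = defs$side[ord],
               gpa_excluded = grepl("^Euryon", defs$name[ord]))
}

# smooth anterior (facial) weight in [0,1]; len is the shell y semi-axis
facial_weight <- function(points, center, len) {
  qy <- (points[, 2] - center[2]) / len
  1 / (1 + exp(-(qy - 0.35) / 0.20))
}

superior_weight <- function(points, center, len) {
  qz <- (points[, 3] - center[3]) / len
  1 / (1 + exp(-(qz - 0.20) / 0.20))
}

weighted_radial_field <- function(points, center, w) {
  u <- sweep(points, 2, center)
  r <- sqrt(rowSums(u^2))
  r[r == 0] <- 1
  (u / r) * w
}

shell_patch_labels <- function(mesh, shell_semi) {
  cen <- mesh_centroids(mesh)
  q <- sweep(cen, 2, shell_semi, "/")
  lab <- rep(NA_character_, nrow(cen))
  side <- q[, 1] > 0
  lab[side & q[, 3] > 0.18] <- "calvarial"
  lab[side & q[, 3] <= 0.18 & q[, 2] > 0.55] <- "midfacial"
  lab[side & q[, 3] <= -0.15 & q[, 2] < -0.55] <- "lower_occipital"
  lab
}

#' Build the reference (template) synthetic skull
#'
#' Constructs the noise-free female specimen at the reference age of 12
#' months: a closed triaxial-ellipsoid outer shell carrying the facial,
#' calvarial and lower-occipital patch labels on its left side, five
#' internal ellipsoid cavity surfaces (intracranial, left and right orbital,
#' nasal, upper intraoral) each opened by a small polar aperture, and the 88
#' named landmarks placed at analytic surface features (shell poles and
#' equator points, cavity aperture rims). The Euryon pair carries the
#' `gpa_excluded` flag exercised by the 86-landmark superimposition rule.
#'
#' The whole construction is scaled so the landmark centroid size equals the
#' size curve at the reference age.
#'
#' @param resolution icosphere subdivision level of the shell (>= 2).
#' @param params a `cm_growth_params`.
#' @return object of class `cm_specimen` with template extras (allometric
#'   fields, resolution, growth params).
#' @export
make_template_skull <- function(resolution = 3, params = growth_params()) {
  if (!is.numeric(resolution) || resolution < 2)
    stop("invalid resolution: need an integer subdivision level >= 2")
  resolution <- as.integer(resolution)
  age_days <- 365L
  months <- age_to_months(age_days)
  target_cs <- size_curve_eval(params, months)
  g <- 1
  for (iter in 1:12) {
    semi <- shell_semi_base * g
    cav <- cavity_geometry_at(params, months, lin_scale = g)
    lms <- place_landmarks(landmark_definitions(), semi, cav)
    cs <- centroid_size(lms)
    g <- g * target_cs / cs
  }
  semi <- shell_semi_base * g
  cav <- cavity_geometry_at(params, months, lin_scale = g)
  defs <- landmark_definitions()
  lms <- place_landmarks(defs, semi, cav)

  shell <- ellipsoid_mesh(semi, c(0, 0, 0), subdiv = resolution)
  shell$patch_labels <- shell_patch_labels(shell, semi)
  cav_meshes <- lapply(cav, make_cavity_mesh, subdiv = resolution)
  for (nm in names(cav_meshes))
    cav_meshes[[nm]]$patch_labels <- rep(paste0("cavity_", nm),
                                         nrow(cav_meshes[[nm]]$faces))
  mesh <- merge_meshes(c(list(shell = shell), cav_meshes))

  # allometric displacement fields, unit-norm over the 88 landmarks
  ctr <- colMeans(lms$coords)
  w1 <- facial_weight(lms$coords, ctr, semi[2])
  f1 <- weighted_radial_field(lms$coords, ctr, w1)
  w2 <- superior_weight(lms$coords, ctr, semi[2])
  f2 <- weighted_radial_field(lms$coords, ctr, w2)
  n1 <- sqrt(sum(f1^2))
  f1u <- f1 / n1
  f2o <- f2 - sum(f2 * f1u) * f1u
  n2 <- sqrt(sum(f2o^2))
  f2u <- f2o / n2

  wv1 <- facial_weight(shell$vertices, ctr, semi[2])
  g1 <- weighted_radial_field(shell$vertices, ctr, wv1) / n1
  wv2 <- superior_weight(shell$vertices, ctr, semi[2])
  g2raw <- weighted_radial_field(shell$vertices, ctr, wv2)
  # same orthogonalisation coefficients as for the landmark field
  g2 <- (g2raw - sum(f2 * f1u) * g1) / n2

  structure(list(mesh = mesh, shell = shell, landmarks = lms,
                 cavity_geometry = cav,
                 age_days = age_days, age_months = months,
                 sex = "F",
                 true_volumes = volume_set(cav$icv$volume, cav$lov$volume,
                                           cav$ncv$volume, cav$uiv$volume),
                 cs = centroid_size(lms),
                 template = list(resolution = resolution,
                                 shell_semi = semi,
                                 scale = g,
                                 center = ctr,
                                 allo_lm = f1u, allo2_lm = f2u,
                                 allo_vert = g1, allo2_vert = g2),
                 params = params),
            class = "cm_specimen")
}

#' @export
print.cm_specimen <- function(x, ...) {
  cat(sprintf("cm_specimen: sex %s, age %d days (%.2f months), CS %.1f mm\n",
              x$sex, x$age_days, x$age_months, centroid_size(x$landmarks)))
  invisible(x)
}

# run fn with a locally-seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Grow a specimen from the template
#'
#' Produces the synthetic specimen at `age_days` and `sex`: the template
#' unit shape is displaced along the (sex-specific) allometric vector in
#' proportion to `Ln(CS) - Ln(CS_template)`, rescaled exactly to the target
#' centroid size `size_curve(age) * sex factor`, and Gaussian landmark noise
#' of `params$landmark_noise_sd` mm is added. Shell vertices follow the same
#' scale-plus-allometry map (noise-free); cavity ellipsoids are regenerated
#' so their analytic volumes equal the four growth curves at this age
#' exactly.
#'
#' @param template a template `cm_specimen` from [make_template_skull()].
#' @param age_days integer in `[0, 1460]`.
#' @param sex `"F"` or `"M"`.
#' @param params growth parameters (defaults to the template's).
#' @param rng_seed integer seed for the landmark noise; the caller's RNG
#'   stream is left untouched.
#' @param noise_sd override for `params$landmark_noise_sd` (mm).
#' @param with_mesh build the specimen meshes (disable for landmark-only
#'   cohorts, which is much faster).
#' @return a `cm_specimen`.
#' @export
grow_skull <- function(template, age_days, sex = c("F", "M"),
                       params = template$params, rng_seed = NULL,
                       noise_sd = params$landmark_noise_sd,
                       with_mesh = TRUE) {
  sex <- match.arg(sex)
  if (age_days < 0) stop("negative age")
  if (age_days > 1460) stop("age beyond 48 months (1460 days)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  tp <- template$template
  months <- age_to_months(age_days)
  target_cs <- size_curve_eval(params, months) *
    if (sex == "M") params$sex_size_offset else 1
  delta <- log(target_cs) - log(template$cs)
  v_lm <- tp$allo_lm
  v_vert <- tp$allo_vert
  div <- params$trajectory_divergence_deg
  if (sex == "M" && div != 0) {
    a <- div * pi / 180
    v_lm <- cos(a) * tp$allo_lm + sin(a) * tp$allo2_lm
    v_vert <- cos(a) * tp$allo_vert + sin(a) * tp$allo2_vert
  }
  U0 <- sweep(template$landmarks$coords, 2, tp$center) / template$cs
  U <- U0 + params$allometric_scale * v_lm * delta
  ctr_u <- colMeans(U)
  U <- sweep(U, 2, ctr_u)
  s_norm <- 1 / sqrt(sum(U^2))
  lm_coords_new <- U * s_norm * target_cs
  lm_coords_new <- sweep(lm_coords_new, 2, tp$center, "+")
  if (noise_sd > 0) {
    noise <- with_local_seed(rng_seed, function()
      matrix(stats::rnorm(length(lm_coords_new), 0, noise_sd),
             ncol = 3))
    lm_coords_new <- lm_coords_new + noise
  }
  lms <- template$landmarks
  lms$coords[] <- lm_coords_new

  lin_scale <- tp$scale * target_cs / template$cs
  cav <- cavity_geometry_at(params, months, lin_scale = lin_scale)
  vols <- volume_set(cav$icv$volume, cav$lov$volume,
                     cav$ncv$volume, cav$uiv$volume)

  mesh <- NULL; shell <- NULL
  if (with_mesh) {
    V0 <- sweep(template$shell$vertices, 2, tp$center) / template$cs
    V <- V0 + params$allometric_scale * v_vert * delta
    V <- sweep(V, 2, ctr_u)
    vert_new <- sweep(V * s_norm * target_cs, 2, tp$center, "+")
    shell <- cm_mesh(vert_new, template$shell$faces,
                     patch_labels = template$shell$patch_labels)
    cav_meshes <- lapply(cav, make_cavity_mesh,
                         subdiv = tp$resolution)
    for (nm in names(cav_meshes))
      cav_meshes[[nm]]$patch_labels <- rep(paste0("cavity_", nm),
                                           nrow(cav_meshes[[nm]]$faces))
    mesh <- merge_meshes(c(list(shell = shell), cav_meshes))
  }
  structure(list(mesh = mesh, shell = shell, landmarks = lms,
                 cavity_geometry = cav,
                 age_days = as.integer(age_days), age_months = months,
                 sex = sex, true_volumes = vols,
                 cs = target_cs,
                 template = tp, params = params),
            class = "cm_specimen")
}

#' Sample specimen ages (days)
#'
#' `"uniform"` draws ages uniformly on 0..1460 days. `"paper_like"` draws
#' from a piecewise-uniform distribution over the four year-of-life bands
#' with weights 88:60:48:21, mimicking the age skew typical of clinical
#' archives (many infants, few 3-4 year olds).
#'
#' @param n number of draws.
#' @param sampler distribution name.
#' @export
sample_ages <- function(n, sampler = c("uniform", "paper_like")) {
  sampler <- match.arg(sampler)
  if (sampler == "uniform") {
    return(as.integer(floor(stats::runif(n, 0, 1461))))
  }
  band <- sample.int(4, n, replace = TRUE, prob = c(88, 60, 48, 21))
  lo <- c(0, 365, 730, 1095)[band]
  as.integer(floor(lo + stats::runif(n, 0, 365)))
}

#' Generate a synthetic skull cohort
#'
#' Draws `n` specimens with ages from `age_sampler` and a fixed male
#' fraction (`round(n * sex_ratio)` males, so a 217-specimen cohort at the
#' default ratio has 123 males and 94 females). One global RNG stream seeded
#' by `seed` drives age and sex assignment; each specimen's landmark noise
#' uses its own counter-derived seed, so cohorts are reproducible and
#' insensitive to generation order.
#'
#' @param n cohort size (>= 2).
#' @param age_sampler `"uniform"` or `"paper_like"` (see [sample_ages()]).
#' @param sex_ratio male fraction in (0, 1).
#' @param params a `cm_growth_params`.
#' @param seed integer.
#' @param resolution shell subdivision for [make_template_skull()].
#' @param with_mesh build per-specimen meshes (disable for speed when only
#'   landmarks are analysed).
#' @param template optionally reuse a prebuilt template.
#' @return object of class `cm_cohort`: `specimens` (list), `metadata`
#'   (data.frame id, age_days, age_months, sex), `params` (ground truth),
#'   `template`, `seed`.
#' @export
generate_cohort <- function(n, age_sampler = c("uniform", "paper_like"),
                            sex_ratio = 123 / 217,
                            params = growth_params(), seed = 1,
                            resolution = 3, with_mesh = TRUE,
                            template = NULL) {
  if (n < 2) stop("cohort size must be at least 2")
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("sex_ratio must be in (0, 1)")
  age_sampler <- match.arg(age_sampler)
  if (is.null(template))
    template <- make_template_skull(resolution, params)
  n_m <- round(n * sex_ratio)
  draws <- with_local_seed(seed, function() {
    ages <- sample_ages(n, age_sampler)
    sexes <- sample(c(rep("M", n_m), rep("F", n - n_m)))
    list(ages = ages, sexes = sexes)
  })
  spec_seed <- (seed + 7919 * seq_len(n)) %% 2147483647L
  specimens <- vector("list", n)
  for (i in seq_len(n)) {
    specimens[[i]] <- grow_skull(template, draws$ages[i], draws$sexes[i],
                                 params = params, rng_seed = spec_seed[i],
                                 with_mesh = with_mesh)
  }
  ids <- sprintf("syn%04d", seq_len(n))
  names(specimens) <- ids
  metadata <- data.frame(id = ids,
                         age_days = draws$ages,
                         age_months = age_to_months(draws$ages),
                         sex = draws$sexes)
  structure(list(specimens = specimens, metadata = metadata,
                 params = params, template = template, seed = seed),
            class = "cm_cohort")
}

#' @export
print.cm_cohort <- function(x, ...) {
  cat("cm_cohort:", nrow(x$metadata), "specimens (",
      sum(x$metadata$sex == "M"), "M /", sum(x$metadata$sex == "F"), "F ),",
      sprintf("ages %.1f-%.1f months\n", min(x$metadata$age_months),
              max(x$metadata$age_months)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One PLY mesh and one landmark CSV per specimen, a cohort metadata CSV and
#' a ground-truth JSON with the generator parameters.
#'
#' @param cohort a `cm_cohort`.
#' @param dir output directory (created if needed).
#' @param meshes also write per-specimen PLY meshes.
#' @export
write_cohort <- function(cohort, dir, meshes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$specimens)) {
    sp <- cohort$specimens[[id]]
    write_landmarks_csv(sp$landmarks, file.path(dir, paste0(id, "_landmarks.csv")))
    if (meshes && !is.null(sp$mesh))
      write_ply(sp$mesh, file.path(dir, paste0(id, ".ply")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- cohort$params
  class(truth) <- NULL
  jsonlite::write_json(list(seed = cohort$seed, params = truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
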