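#' Build a validated run configuration
#'
#' Collects every knob of the full analysis battery. Defaults reproduce the
#' standard study settings: semilandmark patch counts 100/1000/52 per side,
#' 1000 permutations, the 9-bin age grouping, bending-energy sliding with 3
#' iterations. A single global seed fans out to fixed named substreams
#' (cohort, template, permutations) so stages are independently
#' reproducible.
#'
#' @param n cohort size.
#' @param seed global integer seed.
#' @param age_sampler `"uniform"` or `"paper_like"`.
#' @param sex_ratio male fraction.
#' @param params a [growth_params()] object.
#' @param resolution shell subdivision level.
#' @param slm_counts named one-side patch counts.
#' @param slide_iter,slide_tol sliding controls.
#' @param age_group_edges months.
#' @param n_permutations for every permutation test.
#' @param output_dir where [run_study()] writes its reports.
#' @param write_meshes write per-specimen PLY meshes and warp meshes.
#' @param cohort_dir optional directory with a previously written cohort
#'   (see [write_cohort()]); when given, the cohort is loaded instead of
#'   generated.
#' @return object of class `cm_run_config`.
#' @export
run_config <- function(n = 40, seed = 1,
                       age_sampler = "uniform",
                       sex_ratio = 123 / 217,
                       params = growth_params(),
                       resolution = 3,
                       slm_counts = c(midfacial = 100, calvarial = 1000,
                                      lower_occipital = 52),
                       slide_iter = 3, slide_tol = 1e-6,
                       age_group_edges = default_age_groups(),
                       n_permutations = 1000,
                       output_dir = "craniomorph_run",
                       write_meshes = FALSE,
                       cohort_dir = NULL) {
  stopifnot(is.numeric(n), length(n) == 1)
  if (is.null(cohort_dir) && n < 2) stop("cohort size must be at least 2")
  if (!age_sampler %in% c("uniform", "paper_like"))
    stop("unknown age sampler: ", age_sampler)
  if (!inherits(params, "cm_growth_params")) stop("params must come from growth_params()")
  if (!all(c("midfacial", "calvarial", "lower_occipital") %in% names(slm_counts)))
    stop("slm_counts must name midfacial, calvarial and lower_occipital")
  if (any(slm_counts < 1)) stop("slm_counts must be >= 1")
  if (any(diff(age_group_edges) <= 0)) stop("age_group_edges must increase")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_sampler = age_sampler, sex_ratio = sex_ratio,
                 params = params, resolution = as.integer(resolution),
                 slm_counts = slm_counts,
                 slide_iter = slide_iter, slide_tol = slide_tol,
                 age_group_edges = age_group_edges,
                 n_permutations = as.integer(n_permutations),
                 output_dir = output_dir,
                 write_meshes = isTRUE(write_meshes),
                 cohort_dir = cohort_dir),
            class = "cm_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `params` is a nested
#' mapping of [growth_params()] arguments.
#'
#' @param path YAML file.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 treats a bare `n` key as a boolean; map it back
  names(y)[names(y) %in% c("FALSE", "no")] <- "n"
  if (!is.null(y$params)) y$params <- do.call(growth_params, y$params)
  if (!is.null(y$slm_counts)) y$slm_counts <- unlist(y$slm_counts)
  if (!is.null(y$age_group_edges)) y$age_group_edges <- as.numeric(y$age_group_edges)
  do.call(run_config, y)
}

load_cohort <- function(dir) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  specimens <- vector("list", nrow(md))
  names(specimens) <- md$id
  for (i in seq_len(nrow(md))) {
    id <- md$id[i]
    lms <- read_landmarks_csv(file.path(dir, paste0(id, "_landmarks.csv")))
    ply <- file.path(dir, paste0(id, ".ply"))
    mesh <- if (file.exists(ply)) read_ply(ply) else NULL
    shell <- NULL
    if (!is.null(mesh) && !is.null(mesh$patch_labels)) {
      shell_faces <- which(is.na(mesh$patch_labels) |
                             !startsWith(mesh$patch_labels, "cavity_"))
      shell <- subset_mesh(mesh, shell_faces)
    }
    specimens[[i]] <- structure(list(mesh = mesh, shell = shell,
                                     landmarks = lms,
                                     cavity_geometry = NULL,
                                     age_days = md$age_days[i],
                                     age_months = md$age_months[i],
                                     sex = md$sex[i], true_volumes = NULL),
                                class = "cm_specimen")
  }
  structure(list(specimens = specimens, metadata = md,
                 params = NULL, template = NULL, seed = NA_integer_),
            class = "cm_cohort")
}

write_report_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full analysis battery on a cohort
#'
#' Executes, in order: cohort generation (or loading), semilandmark
#' template construction, projection and bending-energy sliding over every
#' specimen, generalized Procrustes analysis with the flagged-landmark
#' exclusion, the craniometric measurement panel with cavity volumetry,
#' form-space and volume PCAs, the eight sex-compared multivariate
#' regressions with trajectory-angle permutation tests, the four two-block
#' PLS analyses (cranial / facial / neurocranial shape vs CPVols and form
#' vs CVols), and mean-shape warps with per-face area-change maps. All
#' tabular reports are written as CSV under `config$output_dir` together
#' with a machine-readable provenance JSON.
#'
#' @param config a `cm_run_config`.
#' @return (invisibly) a list with every intermediate result and the paths
#'   of the written reports.
#' @export
run_study <- function(config) {
  if (!inherits(config, "cm_run_config")) stop("config must come from run_config()")
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) load_cohort(config$cohort_dir)
    else generate_cohort(config$n, config$age_sampler, config$sex_ratio,
                         params = config$params, seed = config$seed,
                         resolution = config$resolution, with_mesh = TRUE)
  })
  md <- cohort$metadata

  template <- cohort$template
  if (is.null(template))
    template <- stage("template",
                      make_template_skull(config$resolution, config$params))
  slm_template <- stage("slm_template",
                        build_slm_template(template, config$slm_counts,
                                           seed = config$seed + 1000L))

  configs <- stage("slide", slide_cohort(cohort, slm_template,
                                         max_iter = config$slide_iter,
                                         tol = config$slide_tol))

  gpa_res <- stage("gpa", gpa(configs, exclude_flagged = TRUE))
  fm <- form_matrix(gpa_res)

  measurements <- stage("measurements", {
    do.call(rbind, lapply(names(cohort$specimens), function(id) {
      df <- measurement_panel(cohort$specimens[[id]])
      cbind(id = id, df)
    }))
  })
  write_report_csv(measurements, out_dir, "measurements.csv")
  write_report_csv(md, out_dir, "metadata.csv")

  cvols <- as.matrix(measurements[, c("cicv", "clov", "cncv", "cuiv")])
  cpvols <- as.matrix(measurements[, c("cpicv", "cplov", "cpncv", "cpuiv")])

  groups <- assign_age_groups(md$age_months, config$age_group_edges)

  pca_form <- stage("pca_form", cm_pca(fm))
  pca_cvols <- stage("pca_cvols", cm_pca(cvols))
  pca_summary <- data.frame(
    analysis = c(rep("form", min(5, length(pca_form$variance_fractions))),
                 rep("cvols", min(4, length(pca_cvols$variance_fractions)))),
    component = c(seq_len(min(5, length(pca_form$variance_fractions))),
                  seq_len(min(4, length(pca_cvols$variance_fractions)))),
    variance_fraction = c(pca_form$variance_fractions[seq_len(min(5, length(pca_form$variance_fractions)))],
                          pca_cvols$variance_fractions[seq_len(min(4, length(pca_cvols$variance_fractions)))]))
  pca_summary$lncs_loading <- NA_real_
  pca_summary$lncs_loading[pca_summary$analysis == "form"] <-
    abs(pca_form$loadings[ncol(fm), seq_len(sum(pca_summary$analysis == "form"))])
  write_report_csv(pca_summary, out_dir, "pca_summary.csv")

  form_means <- group_means(pca_form$scores[, 1:2, drop = FALSE], groups,
                            sex = md$sex)
  names(form_means)[3:4] <- c("PC1", "PC2")
  write_report_csv(form_means, out_dir, "form_pca_group_means.csv")

  # the eight sex-compared regressions (Table-1 analog)
  tbl <- stage("regressions", {
    iF <- md$sex == "F"; iM <- md$sex == "M"
    np <- config$n_permutations
    rows <- list(
      list(name = "shape_vs_lncs", Y = gpa_res$shape_matrix, x = gpa_res$ln_cs),
      list(name = "shape_vs_age", Y = gpa_res$shape_matrix, x = md$age_months),
      list(name = "form_vs_lncs", Y = fm, x = gpa_res$ln_cs),
      list(name = "form_vs_age", Y = fm, x = md$age_months),
      list(name = "cvols_vs_lncs", Y = cvols, x = gpa_res$ln_cs),
      list(name = "cvols_vs_age", Y = cvols, x = md$age_months),
      list(name = "cpvols_vs_lncs", Y = cpvols, x = gpa_res$ln_cs),
      list(name = "cpvols_vs_age", Y = cpvols, x = md$age_months))
    do.call(rbind, lapply(seq_along(rows), function(j) {
      r <- rows[[j]]
      regF <- multivariate_regression(r$Y[iF, , drop = FALSE], r$x[iF],
                                      n_perm = np, seed = config$seed + 2000L + j)
      regM <- multivariate_regression(r$Y[iM, , drop = FALSE], r$x[iM],
                                      n_perm = np, seed = config$seed + 3000L + j)
      ang <- trajectory_angle_test(r$Y[iF, , drop = FALSE], r$x[iF],
                                   r$Y[iM, , drop = FALSE], r$x[iM],
                                   n_perm = np, seed = config$seed + 4000L + j,
                                   labels = c("F", "M"))
      data.frame(regression = r$name,
                 r2_female = regF$r_squared, p_female = regF$p_value,
                 r2_male = regM$r_squared, p_male = regM$p_value,
                 angle_deg = ang$angle_deg, p_angle = ang$p_value)
    }))
  })
  write_report_csv(tbl, out_dir, "table1_analog.csv")

  # PLS battery
  pls_tbl <- stage("pls", {
    pt_names <- gpa_res$names
    patch_of <- c(stats::setNames(rep("lm", length(rownames(template$landmarks$coords))),
                                  rownames(template$landmarks$coords)),
                  stats::setNames(slm_template$patch,
                                  sprintf("SLM%04d", seq_len(nrow(slm_template$points)))))
    col_patch <- rep(patch_of[pt_names], each = 3)
    face_cols <- which(col_patch == "midfacial")
    neuro_cols <- which(col_patch %in% c("calvarial", "lower_occipital"))
    np <- config$n_permutations
    specs <- list(
      list(name = "cranial_shape_vs_cpvols", b1 = gpa_res$shape_matrix, b2 = cpvols),
      list(name = "facial_shape_vs_cpvols",
           b1 = gpa_res$shape_matrix[, face_cols, drop = FALSE], b2 = cpvols),
      list(name = "neurocranial_shape_vs_cpvols",
           b1 = gpa_res$shape_matrix[, neuro_cols, drop = FALSE], b2 = cpvols),
      list(name = "form_vs_cvols", b1 = fm, b2 = cvols))
    do.call(rbind, lapply(seq_along(specs), function(j) {
      s <- specs[[j]]
      pls <- two_block_pls(s$b1, s$b2, n_perm = np,
                           seed = config$seed + 5000L + j)
      data.frame(analysis = s$name, r_axis1 = pls$r[1],
                 pct_covariance_axis1 = pls$pct_covariance[1],
                 pct_var_block1 = pls$pct_var_block1,
                 p_value = pls$p_value)
    }))
  })
  write_report_csv(pls_tbl, out_dir, "pls_summary.csv")

  # mean-shape warps along the pooled allometric regression + area map
  warp_info <- stage("warps", {
    reg <- multivariate_regression(gpa_res$shape_matrix, gpa_res$ln_cs)
    lo <- min(gpa_res$ln_cs); hi <- max(gpa_res$ln_cs)
    shape_lo <- warp_along_regression(reg, lo)
    shape_hi <- warp_along_regression(reg, hi)
    ref_all <- rbind(template$landmarks$coords,
                     `rownames<-`(slm_template$points,
                                  sprintf("SLM%04d",
                                          seq_len(nrow(slm_template$points)))))
    ref_lms <- ref_all[gpa_res$names, , drop = FALSE]
    mesh_lo <- cm_mesh(tps_apply(tps_fit(ref_lms, shape_lo),
                                 template$shell$vertices),
                       template$shell$faces)
    mesh_hi <- cm_mesh(tps_apply(tps_fit(ref_lms, shape_hi),
                                 template$shell$vertices),
                       template$shell$faces)
    amap <- area_change_map(mesh_lo, mesh_hi)
    if (config$write_meshes) {
      write_ply(mesh_lo, file.path(out_dir, "warp_min_lncs.ply"))
      write_ply(mesh_hi, file.path(out_dir, "warp_max_lncs.ply"),
                face_scalar = amap$percent)
    }
    write_report_csv(data.frame(quantity = c("area_change_min_pct",
                                             "area_change_max_pct"),
                                value = amap$range),
                     out_dir, "area_change_summary.csv")
    list(range = amap$range)
  })

  if (config$write_meshes) stage("meshes", write_cohort(cohort, file.path(out_dir, "cohort")))

  cfg_plain <- config
  class(cfg_plain) <- NULL
  cfg_plain$params <- unclass(cfg_plain$params)
  cfg_plain$output_dir <- NULL  # keep provenance path-independent
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("craniomorph")),
         config = cfg_plain,
         slm_counts_realised = as.list(slm_region_counts(slm_template)),
         n_points_superimposed = length(gpa_res$names)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(cohort = cohort, template = template,
                 slm_template = slm_template, configs = configs,
                 gpa = gpa_res, form_matrix = fm,
                 measurements = measurements,
                 pca_form = pca_form, pca_cvols = pca_cvols,
                 table1 = tbl, pls = pls_tbl, warp = warp_info,
                 output_dir = out_dir))
}
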