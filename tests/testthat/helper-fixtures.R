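# Shared fixtures, built once per test run. Everything is generated in code;
# no stored data beyond the package's roster/dimension-table CSVs.

.fix_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- builder()
  .fix_env[[name]]
}

fix_template2 <- function() fixture("tpl2", function() make_template_skull(2))
fix_template3 <- function() fixture("tpl3", function() make_template_skull(3))

# landmark-only cohort under default study conditions
fix_cohort <- function() fixture("coh", function()
  generate_cohort(60, seed = 42, with_mesh = FALSE, template = fix_template2()))

fix_gpa <- function() fixture("gpa", function()
  gpa(lapply(fix_cohort()$specimens, `[[`, "landmarks")))

# small semilandmark template on the resolution-3 reference
fix_slm_small <- function() fixture("slm_small", function()
  build_slm_template(fix_template3(),
                     counts = c(midfacial = 15, calvarial = 60,
                                lower_occipital = 8), seed = 7))

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# 12-triangle axis-aligned unit cube, outward wound
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),          # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),          # z = 1 (+z)
    c(1, 2, 5), c(2, 6, 5),          # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),          # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),          # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))          # x = 1 (+x)
  cm_mesh(v, f)
}
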