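sch <- fdi_schema()

test_that("phantom generation is deterministic and complete", {
  a <- generate_phantom(default_dentition(seed = 9))
  b <- generate_phantom(default_dentition(seed = 9))
  expect_identical(unclass_dim(a$map), unclass_dim(b$map))
  expect_equal(a$truth, b$truth)

  expect_equal(length(setdiff(unique(as.vector(a$map)), 0L)), 32L)
  expect_equal(nrow(a$truth), 32L)

  miss <- generate_phantom(default_dentition(seed = 9, missing = "36"))
  expect_equal(length(setdiff(unique(as.vector(miss$map)), 0L)), 31L)
  expect_false("36" %in% miss$truth$fdi_code)

  c2 <- generate_phantom(default_dentition(seed = 10))
  expect_false(identical(unclass_dim(a$map), unclass_dim(c2$map)))
})

test_that("zero noise and no hooks reproduce the base angulation table", {
  s1 <- default_dentition(seed = 1, angle_noise_sd = 0, hook_prob = 0)
  s2 <- default_dentition(seed = 999, angle_noise_sd = 0, hook_prob = 0)
  expect_equal(s1$teeth$true_angle_deg, s2$teeth$true_angle_deg)
  expect_true(all(s1$teeth$apical_hook_angle_deg == 0))
})

test_that("rasterized teeth have the requested orientation", {
  straight <- tooth_spec("13", c(260, 300), 100, 12, 0)
  mask <- rasterize_tooth(straight, c(512, 1024), sch)
  expect_lt(abs(as.numeric(measure_angle(mask_instance(mask)))), 0.3)

  # hook biases the full-region orientation more than the shaft alone
  hooked <- tooth_spec("13", c(260, 300), 100, 12, 8,
                       apical_hook_angle_deg = 30)
  shaft <- tooth_spec("13", c(260, 300), 100, 12, 8)
  ang_hook <- as.numeric(measure_angle(mask_instance(
    rasterize_tooth(hooked, c(512, 1024), sch))))
  ang_shaft <- as.numeric(measure_angle(mask_instance(
    rasterize_tooth(shaft, c(512, 1024), sch))))
  expect_gt(abs(ang_hook - 8), abs(ang_shaft - 8))

  absent <- tooth_spec("13", c(260, 300), 100, 12, 0, present = FALSE)
  expect_equal(sum(rasterize_tooth(absent, c(512, 1024), sch)), 0)

  oob <- tooth_spec("13", c(5, 5), 100, 12, 0)
  expect_error(rasterize_tooth(oob, c(512, 1024), sch), "out of image bounds")
})

test_that("overlapping tooth specs are rejected", {
  teeth <- dplyr::bind_rows(
    tooth_spec("13", c(260, 300), 100, 12, 0),
    tooth_spec("14", c(260, 305), 100, 12, 0))
  expect_error(generate_phantom(phantom_spec(teeth, schema = sch)),
               "overlapping")
})

test_that("maxillary apices point up and mandibular apices point down", {
  up <- tooth_spec("13", c(260, 300), 100, 12, 0)   # maxillary
  dn <- tooth_spec("33", c(260, 300), 100, 12, 0)   # mandibular
  m_up <- mask_instance(rasterize_tooth(up, c(512, 1024), sch))
  m_dn <- mask_instance(rasterize_tooth(dn, c(512, 1024), sch))
  expect_lt(min(m_up$coords[, 1]), 260 - 80)  # extends toward row 0
  expect_gt(max(m_dn$coords[, 1]), 260 + 80)  # extends toward last row
})

test_that("acquisition perturbation updates map and truth consistently", {
  ph <- generate_phantom(default_dentition(seed = 21, hook_prob = 0))

  ident <- perturb_acquisition(ph$map, ph$truth, rotation_deg = 0)
  expect_identical(unclass_dim(ident$map), unclass_dim(ph$map))
  expect_equal(ident$truth$true_angle_deg, ph$truth$true_angle_deg)

  rot <- perturb_acquisition(ph$map, ph$truth, rotation_deg = 3)
  expect_equal(rot$truth$true_angle_deg - ph$truth$true_angle_deg,
               rep(3, 32), tolerance = 1e-9)
  r0 <- measure_image(ph$map)
  r1 <- measure_image(rot$map)
  m <- merge(r0, r1, by = "fdi_code")
  expect_equal(nrow(m), 20L)
  expect_true(all(abs(m$angle_deg.y - m$angle_deg.x - 3) < 0.5))

  # two perturbed repeats: sensitivity reflects the rotation difference
  rot2 <- perturb_acquisition(ph$map, ph$truth, rotation_deg = -2)
  sens <- repeat_sensitivity(r1, measure_image(rot2$map))
  expect_lt(abs(sens$mean_abs_diff - 5), 0.5)

  # shear updates truth via its Jacobian
  sh <- perturb_acquisition(ph$map, ph$truth, rotation_deg = 0, shear = 0.1)
  th0 <- ph$truth$true_angle_deg * pi / 180
  expected <- atan2(sin(th0) + 0.1 * cos(th0), cos(th0)) * 180 / pi
  expect_equal(sh$truth$true_angle_deg, expected, tolerance = 1e-9)
})

test_that("straight-root phantoms recover ground truth within a degree", {
  n_bad <- 0L; n_tot <- 0L
  for (seed in 1:8) {
    ph <- generate_phantom(default_dentition(seed = seed, hook_prob = 0))
    rec <- measure_image(ph$map)
    m <- merge(rec, ph$truth, by = "fdi_code")
    n_tot <- n_tot + nrow(m)
    n_bad <- n_bad + sum(abs(m$angle_deg - m$true_angle_deg) >= 1)
  }
  expect_gte(1 - n_bad / n_tot, 0.95)
})
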