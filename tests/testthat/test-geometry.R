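test_that("nearest-red pairing obeys the distance cutoff", {
  g <- data.frame(x_nm = c(0, 2000), y_nm = c(0, 0))
  r <- data.frame(x_nm = c(0, 1400), y_nm = c(0, 0))
  res <- pair_to_nearest(g, r, cutoff_nm = 500)
  expect_equal(res$pairs$distance_nm, 0)       # coincident pair kept
  expect_equal(res$unpaired_green, 2L)          # 600 nm from nearest: dropped
  # empty red set: everything unpaired, not an error
  none <- pair_to_nearest(g, r[0, ], 500)
  expect_equal(none$unpaired_green, c(1L, 2L))
  expect_equal(nrow(none$pairs), 0)
})

test_that("pairing equals exhaustive nearest-neighbour search on small scenes", {
  set.seed(1)
  for (rep in 1:25) {
    ng <- sample(1:8, 1); nr <- sample(0:8, 1)
    g <- data.frame(x_nm = runif(ng, 0, 3000), y_nm = runif(ng, 0, 3000))
    r <- data.frame(x_nm = runif(nr, 0, 3000), y_nm = runif(nr, 0, 3000))
    mine <- pair_to_nearest(g, r, 500)$pairs
    oracle <- brute_force_pairs(g, r, 500)
    expect_equal(mine$green_id, oracle$green_id)
    expect_equal(mine$red_id, oracle$red_id)
    expect_equal(mine$distance_nm, oracle$distance_nm, tolerance = 1e-12)
  }
})

test_that("equidistant red foci break ties to the brighter, then lower (y,x)", {
  g <- data.frame(x_nm = 0, y_nm = 0)
  r <- data.frame(x_nm = c(-100, 100), y_nm = c(0, 0),
                  amplitude = c(5, 50))
  expect_equal(pair_to_nearest(g, r)$pairs$red_id, 2L)
  r$amplitude <- c(50, 50)
  r$y_nm <- c(100, -100); r$x_nm <- c(0, 0)
  expect_equal(pair_to_nearest(g, r)$pairs$red_id, 2L)
})

test_that("line profiles interpolate correctly and validate inputs", {
  img <- matrix(5, 15, 20)
  prof <- sample_line_profile(img, c(600, 450), 0, 65)
  expect_true(all(prof$intensity == 5))
  expect_error(sample_line_profile(img, c(600, 450), 0, 65, step_nm = 0),
               "step")
  expect_error(sample_line_profile(img, c(1e5, 450), 0, 65), "outside")
  # gradient image, horizontal line: linear profile
  gimg <- matrix(rep(seq_len(20), each = 15), 15, 20)
  p2 <- sample_line_profile(gimg, c(9 * 65, 7 * 65), 0, 65,
                            half_length_nm = 130, step_nm = 65)
  expect_equal(p2$intensity, c(8, 9, 10, 11, 12))
})

test_that("profile fits recover a closed-form Gaussian sigma within 1%", {
  px <- 65; s_true <- 150
  img <- analytic_gaussian_image(48, 48, 23 * px, 23 * px, s_true, px)
  # pixel-centre sampling (integer-pixel steps and span) makes the closed
  # form an exact oracle
  prof <- sample_line_profile(img, c(23 * px, 23 * px), 0, px,
                              half_length_nm = 9 * px, step_nm = px)
  fit <- fit_gaussian_1d(prof$position_nm, prof$intensity)
  expect_true(fit$converged)
  expect_lt(abs(fit$sigma - s_true) / s_true, 0.01)
  # quarter-pixel bilinear sampling broadens the fit only slightly
  prof2 <- sample_line_profile(img, c(23 * px, 23 * px), 0, px)
  fit2 <- fit_gaussian_1d(prof2$position_nm, prof2$intensity)
  expect_lt(abs(fit2$sigma - s_true) / s_true, 0.03)
})

test_that("an isotropic spot yields 45 near-equal effective diameters", {
  cfg <- scene_config(image_size_px = c(48, 48), psf_sigma_nm = 150,
                      background_level = 0)
  ctr <- centre_of(cfg)
  sc <- render_scene(cfg, list(emitter(ctr, 1e4, "green")), noise = FALSE)
  pd <- pseudo_diameter(sc$images$green, ctr, cfg$pixel_size_nm)
  expect_equal(pd$n_valid, 45)
  eff <- pd$profiles$effective_diameter_nm
  expect_lt(max(eff) / min(eff) - 1, 0.01)
  expect_equal(pd$argmax_angle_deg %% 4, 0)
})

test_that("an elongated structure's widest angle matches its construction", {
  cfg <- scene_config(image_size_px = c(48, 48), background_level = 0)
  ctr <- centre_of(cfg)
  th <- 30 * pi / 180
  off <- 150 * c(cos(th), sin(th))
  sc <- render_scene(cfg, list(emitter(ctr - off, 5e3, "green"),
                               emitter(ctr + off, 5e3, "green")),
                     noise = FALSE)
  pd <- pseudo_diameter(sc$images$green, ctr, cfg$pixel_size_nm)
  expect_lte(min(abs(pd$argmax_angle_deg - 30),
                 180 - abs(pd$argmax_angle_deg - 30)), 4)
})

test_that("pseudo-diameter is stable under a 90-degree scene rotation", {
  cfg <- scene_config(image_size_px = c(48, 48), background_level = 0)
  ctr <- centre_of(cfg)
  th <- 30 * pi / 180
  off <- 150 * c(cos(th), sin(th))
  sc <- render_scene(cfg, list(emitter(ctr - off, 5e3, "green"),
                               emitter(ctr + off, 5e3, "green")),
                     noise = FALSE)
  img <- sc$images$green
  rot <- t(img)[ncol(img):1, ]   # 90-degree rotation
  pd1 <- pseudo_diameter(img, ctr, cfg$pixel_size_nm)
  pd2 <- pseudo_diameter(rot, ctr, cfg$pixel_size_nm)
  expect_lt(abs(pd2$pseudo_diameter_nm / pd1$pseudo_diameter_nm - 1), 0.02)
})

test_that("measured pseudo-diameter increases strictly with true ring diameter", {
  cfg <- scene_config(image_size_px = c(64, 64), background_level = 0)
  cal <- calibrate_diameter_scale(cfg, c(220, 280, 340, 400))
  expect_true(all(diff(cal$table$measured_pseudo_diameter_nm) > 0))
  # a point emitter is narrower than any ring of true diameter >= 200 nm
  ctr <- centre_of(cfg)
  pt <- render_scene(cfg, list(emitter(ctr, 1e4, "green")), noise = FALSE)
  pd_pt <- pseudo_diameter(pt$images$green, ctr, cfg$pixel_size_nm)
  rg <- render_scene(cfg, structures = list(
    annular_structure(ctr, 200, 1, 1e4, "green")), noise = FALSE)
  pd_rg <- pseudo_diameter(rg$images$green, ctr, cfg$pixel_size_nm)
  expect_lt(pd_pt$pseudo_diameter_nm, pd_rg$pseudo_diameter_nm)
  expect_lt(min(cal$table$measured_pseudo_diameter_nm),
            max(cal$table$measured_pseudo_diameter_nm))
})

test_that("per-line outlier exclusion can flag a structure unmeasurable", {
  img <- matrix(1, 20, 20)  # flat: every Gaussian fit fails
  expect_warning(pd <- pseudo_diameter(img, c(600, 600), 65), "unmeasurable")
  expect_false(pd$valid)
  expect_true(is.na(pd$pseudo_diameter_nm))
})

test_that("metrology aggregation computes mean and s.e.m. per protein", {
  rec <- data.frame(protein_id = c("A", "A", "A", "B", "B"),
                    distance_nm = c(300, 300, 300, 200, 400),
                    pseudo_diameter_nm = c(250, 250, 250, 200, 400))
  m <- aggregate_metrology(rec)
  a <- m[m$protein_id == "A", ]; b <- m[m$protein_id == "B", ]
  expect_equal(a$mean_distance_nm, 300)
  expect_equal(a$sem_distance_nm, 0)
  expect_equal(b$mean_distance_nm, 300)
  expect_equal(b$sem_distance_nm, 100)  # SD 141.42 / sqrt(2)
  expect_error(aggregate_metrology(rec[0, ]), "no metrology")
  expect_warning(aggregate_metrology(
    data.frame(protein_id = "C", distance_nm = 1, pseudo_diameter_nm = 1)),
    "single-cell")
})
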