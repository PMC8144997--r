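test_that("empty field is background only with empty ground truth", {
  p <- sim_field_params(n_cells = 0, puncta_per_cell_AP = 0,
                        puncta_per_cell_AL = 0, seed = 1,
                        image_size = c(64, 64))
  fld <- generate_field(p)
  for (ch in fld$image$channels)
    expect_true(all(ch == p$background_level))
  expect_equal(nrow(fld$truth$nuclei_centroids), 0)
  expect_equal(nrow(fld$truth$puncta), 0)
  expect_equal(fld$truth$n_AP + fld$truth$n_AL, 0)
})

test_that("field generation is seed-deterministic and conserves counts", {
  p <- sim_field_params(n_cells = 4, seed = 42)
  a <- generate_field(p)
  b <- generate_field(p)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  expect_equal(a$truth$n_AP + a$truth$n_AL, nrow(a$truth$puncta))
  # every punctum inside image bounds (0-based)
  expect_true(all(a$truth$puncta$row >= 0 & a$truth$puncta$row <= 255))
  expect_true(all(a$truth$puncta$col >= 0 & a$truth$puncta$col <= 255))
  # noise changes pixels but not the seeded truth
  pn <- p; pn$noise_model <- list(poisson_on = TRUE, gaussian_sd = 6)
  cn <- generate_field(pn)
  expect_identical(cn$truth$puncta[, c("row", "col", "class")],
                   a$truth$puncta[, c("row", "col", "class")])
})

test_that("per-cell puncta counts follow the stated Poisson means", {
  n_ap <- n_al <- numeric(200)
  for (s in seq_len(200)) {
    t <- generate_cohort(
      cohort_spec("c", list(c = c(AP = 1, AL = 1)), n_fields = 1, seed = s),
      sim_field_params(n_cells = 4, puncta_per_cell_AP = 2,
                       puncta_per_cell_AL = 3, image_size = c(128, 128)),
      render = FALSE)$fields[[1]]$truth
    n_ap[s] <- t$n_AP; n_al[s] <- t$n_AL
  }
  # Poisson(4 cells x mean): 8 and 12, allow 3 standard errors
  expect_lt(abs(mean(n_ap) - 8), 3 * sqrt(8 / 200))
  expect_lt(abs(mean(n_al) - 12), 3 * sqrt(12 / 200))
})

test_that("puncta keep the enforced minimum separation and annulus placement", {
  fld <- generate_field(sim_field_params(n_cells = 5, puncta_per_cell_AP = 4,
                                         puncta_per_cell_AL = 4, seed = 9))
  pts <- fld$truth$puncta
  if (nrow(pts) >= 2) {
    d <- as.matrix(dist(pts[, c("row", "col")]))
    expect_gte(min(d[upper.tri(d)]), 3 * 2)  # 3 x sigma, sigma = 2
  }
})

test_that("overcrowded fields are rejected with a clear error", {
  expect_error(generate_field(sim_field_params(n_cells = 400,
                                               image_size = c(64, 64),
                                               seed = 1)),
               "too crowded")
})

test_that("parameter validation rejects out-of-contract settings", {
  expect_error(sim_field_params(image_size = c(32, 32)), "64 x 64")
  expect_error(sim_field_params(green_quench_factor = 1.5), "quench")
  expect_error(sim_field_params(background_level = -1), "nonnegative")
  expect_error(sim_field_params(n_cells = -1), "n_cells")
})

test_that("cohort specs reject duplicates and identity multipliers match base", {
  expect_error(cohort_spec(c("a", "a"),
                           list(a = c(AP = 1, AL = 1)), seed = 1),
               "duplicate")
  expect_error(cohort_spec("a", list(a = c(AP = 0, AL = 1)), seed = 1),
               "positive")
  # identity multiplier: same Poisson means as the base settings
  tab <- truth_table_for(list(ctrl = c(AP = 1, AL = 1)), seed = 3,
                         n_fields = 40)
  base <- sim_field_params(n_cells = 8)
  exp_ap <- base$puncta_per_cell_AP
  expect_lt(abs(mean(tab$per_cell_AP) - exp_ap),
            3 * sqrt(exp_ap / (8 * 40)))
})

test_that("cohort generation writes images, truth JSON and a sample sheet", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(c("control", "drug"),
                      list(control = c(AP = 1, AL = 1),
                           drug = c(AP = 1, AL = 3)),
                      n_fields = 2, seed = 5)
  co <- generate_cohort(spec, sim_field_params(n_cells = 3,
                                               image_size = c(128, 128)))
  write_cohort(co, dir)
  sheet <- read.csv(file.path(dir, "sample_sheet.csv"))
  expect_equal(nrow(sheet), 4)
  expect_setequal(names(sheet), c("file", "condition", "timepoint", "seed"))
  expect_true(all(file.exists(file.path(dir, sheet$file))))
  # TIFF round trip preserves the rendered pixels at 16-bit resolution
  img <- read_field_tiff(file.path(dir, sheet$file[1]))
  orig <- co$fields[[1]]$image
  expect_lt(max(abs(img$channels$red - orig$channels$red)), 1)
  # truth JSON matches the in-memory truth
  tj <- jsonlite::read_json(file.path(dir, sub("[.]tif$", "_truth.json",
                                               sheet$file[1])),
                            simplifyVector = TRUE)
  expect_equal(tj$n_AP, co$fields[[1]]$truth$n_AP)
  expect_equal(tj$channel_order, c("nuclei", "green", "red"))
})

test_that("render = FALSE ground truth matches the rendered path", {
  spec <- cohort_spec("c", list(c = c(AP = 1, AL = 1)), n_fields = 3, seed = 8)
  base <- sim_field_params(n_cells = 4, image_size = c(128, 128))
  a <- generate_cohort(spec, base, render = TRUE)
  b <- generate_cohort(spec, base, render = FALSE)
  for (i in seq_along(a$fields))
    expect_identical(a$fields[[i]]$truth, b$fields[[i]]$truth)
})

test_that("Ct tables invert exactly without noise and recover truth with noise", {
  # fold change 1 everywhere -> all fold changes exactly 1
  ct0 <- generate_ct_table("G1", c("ctrl", "trt"), list(),
                           noise_sd = 0, n_replicates = 3, seed = 1)
  r0 <- delta_delta_ct(ct0, control_condition = "ctrl")
  expect_equal(r0$fold_change, rep(1, nrow(r0)))
  # true log2 FC +2 -> fold change exactly 4
  ct2 <- generate_ct_table("G1", c("ctrl", "trt"), list(G1 = 2),
                           noise_sd = 0, n_replicates = 3, seed = 1)
  r2 <- delta_delta_ct(ct2, control_condition = "ctrl")
  expect_identical(r2$fold_change[r2$condition == "trt"], 4)
  # noisy recovery: mean recovered fold change within 10% of truth
  fc <- vapply(seq_len(100), function(s) {
    ct <- generate_ct_table("G1", c("ctrl", "trt"), list(G1 = 2),
                            noise_sd = 0.2, n_replicates = 6, seed = s)
    r <- delta_delta_ct(ct, control_condition = "ctrl")
    r$fold_change[r$condition == "trt"]
  }, numeric(1))
  expect_lt(abs(mean(fc) - 4) / 4, 0.1)
})

test_that("Ct generator enforces its preconditions", {
  expect_error(generate_ct_table("G1", c("a", "b"), list(), n_replicates = 1),
               "n_replicates")
  expect_error(generate_ct_table("G1", c("a", "b"), list(SDHA = 1)),
               "reference")
})

test_that("xenograft cohorts honour arm parameters and are reproducible", {
  arms <- data.frame(label = "combo", n_fish = 5, mean_pct_change = 0, sd = 0)
  rec <- generate_xeno_cohort(arms, seed = 3)
  expect_equal(rec$volume_followup, rec$volume_baseline)
  rec2 <- generate_xeno_cohort(arms, seed = 3)
  expect_identical(rec, rec2)
  expect_error(generate_xeno_cohort(
    data.frame(label = "a", n_fish = 3, mean_pct_change = 0, sd = -1)), "sd")
  expect_error(generate_xeno_cohort(
    data.frame(label = "a", n_fish = 0, mean_pct_change = 0, sd = 0)),
    "n_fish")
})
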