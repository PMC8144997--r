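test_that("blank or constant nuclei channels give zero count with a qc flag", {
  blank <- matrix(0, 64, 64)
  res <- count_nuclei(blank)
  expect_equal(res$count, 0)
  expect_true("no nuclei" %in% res$qc_flags)
  res2 <- count_nuclei(matrix(7, 64, 64))
  expect_equal(res2$count, 0)
  expect_true("no nuclei" %in% res2$qc_flags)
})

test_that("well-separated disk nuclei are counted exactly and deterministically", {
  fld <- generate_field(sim_field_params(n_cells = 12, puncta_per_cell_AP = 0,
                                         puncta_per_cell_AL = 0, seed = 21))
  res <- count_nuclei(fld$image$channels$nuclei)
  expect_equal(res$count, 12)
  expect_length(res$qc_flags, 0)
  # centroids land near the true centres
  tru <- fld$truth$nuclei_centroids
  d <- sqrt(outer(res$centroids[, "row"], tru[, "row"], `-`)^2 +
              outer(res$centroids[, "col"], tru[, "col"], `-`)^2)
  expect_lt(max(apply(d, 2, min)), 2)
  expect_identical(res, count_nuclei(fld$image$channels$nuclei))
})

test_that("spot detection returns empty for featureless inputs", {
  expect_equal(nrow(detect_puncta(matrix(0, 64, 64))), 0)
  expect_equal(nrow(detect_puncta(matrix(50, 64, 64))), 0)
  expect_error(detect_puncta(matrix(-1, 64, 64)), "negative")
  expect_error(detect_puncta(matrix(NaN, 8, 8)), "finite")
})

test_that("isolated Gaussian spots are detected with sub-pixel accurate centroids", {
  set.seed(11)
  img <- matrix(10, 128, 128)
  centers <- cbind(row = c(20, 20, 60, 64, 100, 90, 30, 70, 110, 45) + runif(10),
                   col = c(20, 80, 40, 100, 20, 70, 55, 15, 90, 118) + runif(10))
  sigma <- 2
  for (i in seq_len(10)) {
    rs <- pmax(1, round(centers[i, 1]) - 8):pmin(128, round(centers[i, 1]) + 8)
    cs <- pmax(1, round(centers[i, 2]) - 8):pmin(128, round(centers[i, 2]) + 8)
    d2 <- outer((rs - centers[i, 1])^2, (cs - centers[i, 2])^2, `+`)
    img[rs, cs] <- img[rs, cs] + 120 * exp(-d2 / (2 * sigma^2))
  }
  det <- detect_puncta(img)
  expect_equal(nrow(det), 10)
  tru <- data.frame(row = centers[, 1] - 1, col = centers[, 2] - 1)
  cnt <- spot_f1_counts(det, tru, tol = 1)
  expect_equal(unname(cnt["tp"]), 10)
  # output ordering contract: sorted by (row, col)
  expect_identical(order(det$row, det$col), seq_len(nrow(det)))
})

test_that("classification handles the degenerate list cases", {
  red <- data.frame(row = c(1, 5, 9), col = c(1, 5, 9))
  none <- data.frame(row = numeric(0), col = numeric(0))
  r1 <- classify_vesicles(red, none, coloc_radius_px = 2)
  expect_equal(c(r1$n_AP, r1$n_AL, r1$n_green_only), c(0, 3, 0))
  r2 <- classify_vesicles(red, red, coloc_radius_px = 2)
  expect_equal(c(r2$n_AP, r2$n_AL, r2$n_green_only), c(3, 0, 0))
  expect_error(classify_vesicles(red, red, coloc_radius_px = -1), "> 0")
})

test_that("greedy matching agrees with the brute-force assignment oracle", {
  n_checked <- 0; n_greedy_equal <- 0
  for (s in 1:40) {
    set.seed(s)
    red <- data.frame(row = runif(5, 0, 12), col = runif(5, 0, 12))
    green <- data.frame(row = runif(3, 0, 12), col = runif(3, 0, 12))
    radius <- 4
    g <- classify_vesicles(red, green, radius)
    b <- brute_force_matching(red, green, radius)
    # greedy never produces an invalid or over-counted matching
    expect_true(all(g$matching$dist <= radius))
    expect_equal(anyDuplicated(g$matching$red_idx), 0)
    expect_equal(anyDuplicated(g$matching$green_idx), 0)
    expect_lte(g$n_AP, b$size)
    expect_equal(g$n_AP + g$n_AL, 5)
    n_checked <- n_checked + 1
    # where greedy attains the optimal size and total, the pair sets agree
    if (g$n_AP == b$size &&
        isTRUE(all.equal(sum(g$matching$dist), b$total))) {
      n_greedy_equal <- n_greedy_equal + 1
      gp <- g$matching[order(g$matching$red_idx), c("red_idx", "green_idx")]
      bp <- b$pairs[order(b$pairs$red_idx), ]
      expect_equal(as.matrix(gp), as.matrix(bp), ignore_attr = TRUE)
    }
  }
  # greedy and optimal coincide on most random instances; the remainder
  # (documented greedy/optimal disagreement) is a small minority
  expect_gte(n_greedy_equal / n_checked, 0.7)
})

test_that("quantified oracle fields reproduce ground-truth per-cell counts", {
  for (s in c(3, 14)) {
    fld <- generate_field(oracle_params(seed = s, n_cells = 4,
                                        puncta_per_cell_AP = 1,
                                        puncta_per_cell_AL = 2))
    fq <- quantify_field(fld$image)
    expect_equal(fq$n_nuclei, nrow(fld$truth$nuclei_centroids))
    expect_equal(fq$n_AP, fld$truth$n_AP)
    expect_equal(fq$n_AL, fld$truth$n_AL)
    expect_equal(fq$per_cell_AP, fld$truth$n_AP / fq$n_nuclei)
    expect_equal(fq$per_cell_AL, fld$truth$n_AL / fq$n_nuclei)
  }
})

test_that("empty fields quantify to zero with a qc flag and NA per-cell values", {
  img <- field_image(matrix(0, 64, 64), matrix(0, 64, 64), matrix(0, 64, 64))
  fq <- quantify_field(img)
  expect_equal(c(fq$n_nuclei, fq$n_red_total, fq$n_AP, fq$n_AL), c(0, 0, 0, 0))
  expect_true("no nuclei" %in% fq$qc_flags)
  expect_true(is.na(fq$per_cell_AP) && is.na(fq$per_cell_AL))
})

test_that("conservation holds on a fuzz suite of noisy fields", {
  for (s in 1:25) {
    fld <- generate_field(sim_field_params(
      n_cells = sample(0:6, 1), image_size = c(128, 128), seed = 1000 + s,
      puncta_per_cell_AP = runif(1, 0, 4), puncta_per_cell_AL = runif(1, 0, 4),
      noise_model = list(poisson_on = s %% 2 == 0, gaussian_sd = 3)))
    fq <- quantify_field(fld$image)
    expect_identical(fq$n_AP + fq$n_AL, fq$n_red_total)
  }
})

test_that("autophagosome count is monotone in the colocalization radius", {
  fld <- generate_field(sim_field_params(n_cells = 6, seed = 77,
                                         noise_model = moderate_noise))
  red <- detect_puncta(fld$image$channels$red)
  green <- detect_puncta(fld$image$channels$green)
  radii <- c(0.5, 1, 2, 3, 5, 8)
  ap <- vapply(radii, function(r) classify_vesicles(red, green, r)$n_AP,
               numeric(1))
  al <- vapply(radii, function(r) classify_vesicles(red, green, r)$n_AL,
               numeric(1))
  expect_true(all(diff(ap) >= 0))
  expect_true(all(diff(al) <= 0))
})

test_that("classification is invariant to the order of detected puncta", {
  fld <- generate_field(sim_field_params(n_cells = 6, seed = 55,
                                         noise_model = moderate_noise))
  red <- detect_puncta(fld$image$channels$red)
  green <- detect_puncta(fld$image$channels$green)
  ref <- classify_vesicles(red, green, 2)
  set.seed(1)
  for (i in 1:5) {
    sh <- classify_vesicles(red[sample(nrow(red)), ],
                            green[sample(nrow(green)), ], 2)
    expect_equal(c(sh$n_AP, sh$n_AL, sh$n_green_only),
                 c(ref$n_AP, ref$n_AL, ref$n_green_only))
  }
})

test_that("batch quantification tolerates missing files and keeps sheet order", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec("control", list(control = c(AP = 1, AL = 1)),
                      n_fields = 3, seed = 4)
  co <- generate_cohort(spec, sim_field_params(n_cells = 4,
                                               image_size = c(128, 128)))
  write_cohort(co, dir)
  sheet <- read.csv(file.path(dir, "sample_sheet.csv"))
  # empty sheet -> empty results, success
  out0 <- quantify_batch(sheet[0, ], dir)
  expect_equal(nrow(out0$results), 0)
  expect_equal(nrow(out0$errors), 0)
  # one missing file -> other rows survive, error recorded
  sheet2 <- sheet
  sheet2$file[2] <- "does_not_exist.tif"
  out <- quantify_batch(sheet2, dir)
  expect_equal(nrow(out$results), 2)
  expect_equal(out$errors$file, "does_not_exist.tif")
  expect_match(out$errors$message, "not found")
  expect_equal(out$results$source_id, sheet$file[c(1, 3)])
})

test_that("batch per-condition means track ground truth within 10%", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(c("control", "drug"),
                      list(control = c(AP = 1, AL = 1),
                           drug = c(AP = 1, AL = 3)),
                      n_fields = 8, seed = 6)
  base <- sim_field_params(n_cells = 6, image_size = c(192, 192),
                           noise_model = moderate_noise)
  co <- generate_cohort(spec, base)
  write_cohort(co, dir)
  out <- quantify_batch(file.path(dir, "sample_sheet.csv"), dir)
  expect_equal(nrow(out$errors), 0)
  tru <- cohort_truth_table(co)
  for (cond in c("control", "drug")) {
    for (col in c("per_cell_AP", "per_cell_AL")) {
      t_mean <- mean(tru[[col]][tru$condition == cond])
      d_mean <- mean(out$results[[col]][out$results$condition == cond])
      expect_lt(abs(d_mean - t_mean) / t_mean, 0.1)
    }
  }
})
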