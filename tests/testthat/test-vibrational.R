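test_that("frequency scaling is elementwise and drops imaginary modes", {
  expect_equal(apply_scale(c(1000, 2000), 0.96), c(960, 1920))
  expect_equal(apply_scale(c(615, 2900), 1), c(615, 2900))
  expect_warning(out <- apply_scale(c(-50, 1000), 0.96), "imaginary")
  expect_equal(out, 960)
  expect_error(apply_scale(1000, 0), "positive")
  expect_error(apply_scale(1000, -1), "positive")
})

test_that("band lists validate, sort, and round-trip through CSV", {
  bl <- band_list(c(1160, 615, 895), c(1160, 615, 895),
                  assignment = c("C-O-C", "CH2", "C-H"), source = "exp")
  expect_equal(bl$lo, c(615, 895, 1160))
  expect_equal(bl$assignment, c("CH2", "C-H", "C-O-C"))
  expect_error(band_list(0, 1), "0 < lo")
  expect_error(band_list(100, 50), "lo <= hi")
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_list(bl, path)
  back <- read_band_list(path, source = "exp")
  expect_equal(as.data.frame(back), as.data.frame(bl))
})

test_that("assignment pairs by monotone matching with interval overlap rule", {
  exp <- band_list(c(615, 1030), c(615, 1160), source = "exp")
  model <- band_list(c(637, 1022), c(637, 1117), source = "model")
  ar <- assign_bands(model, exp, tol = 100)
  expect_equal(nrow(ar$pairs), 2)
  expect_equal(ar$pairs$residual, c(22, 0))  # 637 vs 615; overlapping intervals
  expect_equal(nrow(ar$unmatched_model), 0)

  # identical lists: all residuals zero
  self <- assign_bands(exp, exp, tol = 100)
  expect_true(all(self$pairs$residual == 0))

  # a pair beyond tolerance dissolves into the unmatched lists
  far <- assign_bands(band_list(500), band_list(700), tol = 100)
  expect_equal(nrow(far$pairs), 0)
  expect_equal(far$unmatched_model$lo, 500)
  expect_equal(far$unmatched_exp$lo, 700)

  # absent bands (printed "-") never participate
  with_absent <- band_list(c(615, 1640), present = c(TRUE, FALSE), source = "m")
  ar2 <- assign_bands(with_absent, band_list(c(615, 1640)), tol = 100)
  expect_equal(nrow(ar2$pairs), 1)
  expect_equal(ar2$unmatched_exp$lo, 1640)
})

test_that("matching never crosses and is residual-symmetric for single-valued lists", {
  set.seed(21)
  for (i in 1:20) {
    a <- band_list(sort(runif(6, 400, 3800)))
    b <- band_list(sort(runif(8, 400, 3800)))
    ar <- assign_bands(a, b, tol = 300)
    if (nrow(ar$pairs) > 1) {
      expect_true(all(diff(ar$pairs$model_lo) > 0))
      expect_true(all(diff(ar$pairs$exp_lo) > 0))
    }
    # swapping the arguments preserves the multiset of residuals
    ba <- assign_bands(b, a, tol = 300)
    expect_equal(sort(ar$pairs$residual), sort(ba$pairs$residual))
  }
})

test_that("model error over the reference tables matches hand-summed deviations", {
  exp <- ref_ir_experimental()
  models <- ref_ir_models()
  # seven single-valued bands shared by experiment and every computed column
  b3 <- model_error(assign_bands(models[["B3LYP/3-21G"]], exp, tol = Inf))
  expect_equal(b3$mad, 131 / 7)  # |637-615|+|890-895|+...+|3388-3345| = 131
  expect_equal(b3$n_scored, 7)
  hf <- model_error(assign_bands(models[["HF/3-21G"]], exp, tol = Inf))
  expect_equal(hf$mad, 142 / 7)
  expect_lte(b3$mad, b3$rmsd)

  ar0 <- assign_bands(exp, exp, tol = 100)
  s0 <- model_error(ar0)
  expect_equal(s0$mad, 0)
  expect_equal(s0$rmsd, 0)
})

test_that("model ranking places B3LYP/3-21G first over all eleven columns", {
  exp <- ref_ir_experimental()
  models <- ref_ir_models()
  scores <- lapply(names(models), function(tag)
    model_error(assign_bands(models[[tag]], exp, tol = Inf), model = tag))
  ranked <- rank_models(scores)
  expect_equal(ranked$model[1], "B3LYP/3-21G")
  expect_equal(ranked$model[2], "HF/3-21G")
  expect_true(all(diff(ranked$mad) >= 0))

  single <- rank_models(scores[[3]])
  expect_equal(nrow(single), 1)

  # equal MADs fall back to RMSD
  mk <- function(m, mad, rmsd) structure(list(model = m, mad = mad, rmsd = rmsd,
                                              n_matched = 5, n_scored = 5),
                                         class = "model_score")
  tie <- rank_models(list(mk("b", 10, 12), mk("a", 10, 11)))
  expect_equal(tie$model, c("a", "b"))
})

test_that("scale estimation recovers noiseless factors and is scale-equivariant", {
  calc <- c(600, 1200, 2400, 3600)
  expect_equal(estimate_scale(calc, 0.96 * calc), 0.96)
  expect_equal(estimate_scale(calc, calc), 1.0)
  expect_error(estimate_scale(calc, calc[-1]), "equal length")
  expect_error(estimate_scale(1, 1), "at least two")
  set.seed(31)
  exp <- 0.93 * calc + rnorm(4, 0, 3)
  s <- estimate_scale(calc, exp)
  expect_equal(estimate_scale(2 * calc, exp), s / 2)
})

test_that("differential band detection isolates the new carbonyl band", {
  db <- diff_bands(ref_ir_experimental(), ref_ir_composite(), tol = 50)
  expect_equal(db$new$lo, 1710)
  expect_equal(db$new$assignment, "COOH of GO")
  expect_equal(nrow(db$lost), 0)
  # functionalization shifts every matched band to equal or lower wavenumber
  expect_true(all(db$shifted$shift <= 0))
  single <- db$shifted[db$shifted$both_single, ]
  expect_equal(single[single$a_lo == 3345, "shift"], -20)
  expect_equal(single[single$a_lo == 2900, "shift"], -20)

  same <- diff_bands(ref_ir_experimental(), ref_ir_experimental(), tol = 50)
  expect_equal(nrow(same$new), 0)
  expect_equal(nrow(same$lost), 0)
  expect_true(all(same$shifted$shift == 0))
})
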