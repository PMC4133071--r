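test_that("zero-noise, zero-offset simulation yields baseline Cq exactly", {
  d <- study_design(ages = c(30L, 60L), temperatures = c("Low", "High"),
                    samples_per_cell = 3L,
                    reference_genes = c("A", "B"), target_genes = "T",
                    plates = 2L, calibrators = 1L, seed = 7L)
  tr <- cq_truth(d, baseline = c(A = 18, B = 20, T = 26),
                 tech_sd = 0, sample_sd = 0, loading_sd = 0, plate_sd = 0)
  sim <- simulate_cq_dataset(d, tr)
  base <- c(A = 18, B = 20, T = 26)
  expect_equal(sim$records$cq, unname(base[sim$records$gene]))
})

test_that("default design produces the expected record counts", {
  d <- study_design()
  expect_equal(nrow(d$groups), 24L)
  sim <- simulate_cq_dataset(d)
  study <- sim$records[!sim$records$is_calibrator, ]
  expect_equal(length(unique(study$sample)), 240L)
  expect_equal(nrow(study), 240L * 12L * 2L)
  cal <- sim$records[sim$records$is_calibrator, ]
  expect_equal(nrow(cal), 12L * d$plates * d$calibrators * 3L)
  # every plate carries every calibrator for every gene
  tab <- table(cal$gene, cal$plate)
  expect_true(all(tab == d$calibrators * 3L))
})

test_that("group regulation offsets are recovered empirically", {
  d <- study_design(ages = 30L, temperatures = c("Low", "High"),
                    samples_per_cell = 1000L,
                    reference_genes = c("A", "B"), target_genes = character(0),
                    plates = 2L, calibrators = 1L, seed = 11L)
  off <- matrix(c(0, 1.5), nrow = 1,
                dimnames = list("A", c("30_Low", "30_High")))
  tr <- cq_truth(d, baseline = c(A = 20, B = 21), tech_sd = 0.2,
                 sample_sd = 0.3, loading_sd = 0.4, plate_sd = 0,
                 group_offsets = off)
  sim <- simulate_cq_dataset(d, tr)
  st <- sim$records[!sim$records$is_calibrator & sim$records$gene == "A", ]
  st$grp <- sim$metadata$group[match(st$sample, sim$metadata$sample)]
  gap <- mean(st$cq[st$grp == "30_High"]) - mean(st$cq[st$grp == "30_Low"])
  expect_equal(gap, 1.5, tolerance = 0.05)
})

test_that("per-gene SD converges to the variance-component prediction", {
  d <- study_design(ages = 30L, temperatures = "Normal",
                    samples_per_cell = 10000L,
                    reference_genes = c("A", "B"),
                    target_genes = character(0),
                    plates = 1L, calibrators = 1L, seed = 13L)
  tr <- cq_truth(d, baseline = c(A = 20, B = 21), tech_sd = 0.2,
                 sample_sd = 0.4, loading_sd = 0.3, plate_sd = 0)
  sim <- simulate_cq_dataset(d, tr)
  mat <- preprocess_cq(sim$records, sim$metadata,
                       calibrate = FALSE)$matrix
  # duplicate averaging halves the technical variance
  expected <- sqrt(0.3^2 + 0.4^2 + 0.2^2 / 2)
  expect_equal(unname(sd(mat$cq[, "A"])), expected, tolerance = 0.05)
})

test_that("co-regulated pairs show the predicted Pearson correlation", {
  d <- study_design(ages = 30L, temperatures = "Normal",
                    samples_per_cell = 4000L,
                    reference_genes = c("A", "B"),
                    target_genes = character(0),
                    plates = 1L, calibrators = 1L, seed = 17L)
  tr <- cq_truth(d, baseline = c(A = 20, B = 21), tech_sd = 0.2,
                 sample_sd = 0.4, loading_sd = 0.5, plate_sd = 0,
                 coreg = data.frame(gene1 = "A", gene2 = "B", sd = 0.6))
  sim <- simulate_cq_dataset(d, tr)
  mat <- preprocess_cq(sim$records, sim$metadata,
                       calibrate = FALSE)$matrix
  shared <- 0.5^2 + 0.6^2
  rest <- 0.4^2 + 0.2^2 / 2
  pred <- shared / (shared + rest)
  expect_equal(unname(cor(mat$cq[, "A"], mat$cq[, "B"])), pred,
               tolerance = 0.05)
})

test_that("invalid truth and design parameters are rejected", {
  d <- study_design(ages = 30L, temperatures = "Normal",
                    samples_per_cell = 3L,
                    reference_genes = c("A", "B"),
                    target_genes = character(0))
  expect_error(cq_truth(d, baseline = c(A = 20, B = 21), tech_sd = -1),
               "SD")
  expect_error(study_design(reference_genes = character(0)), "non-empty")
  expect_error(study_design(samples_per_cell = 1), "samples_per_cell")
  expect_error(curve_truth(E0 = 2.3), "E0")
  expect_error(curve_truth(E0 = 1), "E0")
  expect_error(curve_truth(cycles = 10), "cycles")
})

test_that("amplification curves follow the efficiency-decay recursion", {
  # far from plateau, noiseless and baseline-free: geometric growth at E0
  tr <- curve_truth(E0 = 1.9, F0 = 1e-6, Fmax = 1e9, baseline = 0,
                    drift = 0, noise_sd = 0)
  cv <- simulate_amp_curve(tr)
  ratio <- cv$fluorescence[2:15] / cv$fluorescence[1:14]
  expect_equal(ratio, rep(1.9, 14), tolerance = 1e-6)

  # perfect doubling: slope of log2(F) is 1 in the exponential window
  tr2 <- curve_truth(E0 = 2, F0 = 1e-6, Fmax = 1e9, baseline = 0,
                     drift = 0, noise_sd = 0)
  cv2 <- simulate_amp_curve(tr2)
  s <- diff(log2(cv2$fluorescence[1:15]))
  expect_equal(s, rep(1, 14), tolerance = 1e-6)

  # threshold crossing is consistent with Cq = log(thr / F0) / log(E0)
  tr3 <- curve_truth(E0 = 1.9, F0 = 0.02, Fmax = 30000, baseline = 0,
                     drift = 0, noise_sd = 0)
  cv3 <- simulate_amp_curve(tr3)
  thr <- 1500   # 5% of plateau: still near-geometric growth
  cq_pred <- log(thr / tr3$F0) / log(1.9)
  crossing <- min(which(cv3$fluorescence > thr))
  expect_lt(abs(crossing - cq_pred), 1.5)
})

test_that("curves never exceed the plateau-plus-noise bound", {
  tr <- curve_truth(E0 = 2, noise_sd = 40)
  for (i in 1:20) {
    cv <- simulate_amp_curve(tr, seed = i)
    bound <- tr$Fmax + tr$baseline + tr$drift * tr$cycles + 5 * tr$noise_sd
    expect_true(all(cv$fluorescence <= bound))
  }
})

test_that("fixture suite is deterministic and correctly structured", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  p1 <- make_fixture_suite(d1, seed = 42L)
  p2 <- make_fixture_suite(d2, seed = 42L)
  for (nm in names(p1)) {
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
                     label = nm)
  }
  tru <- read.csv(p1[["stable5_shifted1_truth.csv"]])
  shifted <- unique(tru$gene[tru$offset != 0])
  expect_length(shifted, 1L)
  curves <- read.csv(p1[["curves_recovery.csv"]])
  expect_equal(length(unique(curves$well)), 300L)
  expect_setequal(unique(curves$gene),
                  c("E0_1.80", "E0_1.90", "E0_2.00"))
  unlink(c(d1, d2), recursive = TRUE)
})
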