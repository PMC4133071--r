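test_that("efficiency correction matches the closed form", {
  expect_equal(efficiency_correct(20, 2), 20)
  expect_equal(efficiency_correct(20, 1.9), 20 * log(1.9) / log(2))
  # linear in Cq at fixed E
  cqs <- c(5, 10, 20, 40)
  expect_equal(efficiency_correct(cqs, 1.85), cqs * log(1.85) / log(2))
  expect_error(efficiency_correct(20, 1), "E")
  expect_error(efficiency_correct(20, 0.9), "E")
  expect_error(efficiency_correct(-1, 1.9), "Cq")
})

make_norm_fixture <- function() {
  meta <- data.frame(sample = paste0("S", 1:6),
                     group = rep(c("a", "b"), each = 3),
                     sex = rep(c("F", "M"), 3), stringsAsFactors = FALSE)
  refs <- cbind(R1 = c(20, 20, 20, 20, 20, 20),
                R2 = c(22, 22, 22, 22, 22, 22))
  tg <- cbind(T1 = c(25, 25, 25, 25, 25, 25))
  list(x = cq_matrix(refs, meta), tg = cq_matrix(tg, meta))
}

test_that("delta-Cq normalization reproduces the arithmetic example", {
  fx <- make_norm_fixture()
  nrm <- normalize_targets(fx$x, fx$tg, combo = c("R1", "R2"),
                           center = FALSE)
  # target 25 vs refs {20, 22}: delta = 25 - 21 = 4
  expect_equal(unname(nrm$dcq[, "T1"]), rep(4, 6))
  # with centering a constant column collapses to zero
  nrm2 <- normalize_targets(fx$x, fx$tg, combo = c("R1", "R2"))
  expect_equal(unname(nrm2$dcq[, "T1"]), rep(0, 6))
})

test_that("targets identical to the reference normalize to zero", {
  meta <- data.frame(sample = paste0("S", 1:4), group = "a",
                     stringsAsFactors = FALSE)
  v <- c(20.5, 21.2, 19.8, 22.0)
  x <- cq_matrix(cbind(R1 = v), meta)
  tg <- cq_matrix(cbind(T1 = v), meta)
  nrm <- normalize_targets(x, tg, combo = "R1")
  expect_equal(unname(nrm$dcq[, "T1"]), rep(0, 4))
})

test_that("centered output has zero mean and full provenance", {
  set.seed(12)
  meta <- data.frame(sample = paste0("S", 1:10), group = "a",
                     stringsAsFactors = FALSE)
  x <- cq_matrix(cbind(R1 = rnorm(10, 20)), meta)
  tg <- cq_matrix(cbind(T1 = rnorm(10, 26), T2 = rnorm(10, 28)), meta)
  nrm <- normalize_targets(x, tg, combo = "R1",
                           efficiencies = c(R1 = 1.9, T1 = 1.85, T2 = 1.95))
  expect_lt(max(abs(colMeans(nrm$dcq))), 1e-9)
  expect_equal(nrm$provenance$combo, "R1")
  expect_equal(nrm$provenance$efficiency_source, "per-gene mean E")
  expect_error(normalize_targets(x, tg, combo = "R1",
                                 efficiencies = c(R1 = 1.9, T1 = 1.85)),
               "T2")
})

test_that("all-E-equal-2 reduces to classic delta-Cq", {
  set.seed(21)
  meta <- data.frame(sample = paste0("S", 1:8), group = "a",
                     stringsAsFactors = FALSE)
  x <- cq_matrix(cbind(R1 = rnorm(8, 20), R2 = rnorm(8, 21)), meta)
  tg <- cq_matrix(cbind(T1 = rnorm(8, 26)), meta)
  a <- normalize_targets(x, tg, combo = c("R1", "R2"))
  b <- normalize_targets(x, tg, combo = c("R1", "R2"),
                         efficiencies = c(R1 = 2, R2 = 2, T1 = 2))
  expect_equal(a$dcq, b$dcq)
  classic <- tg$cq[, "T1"] - rowMeans(x$cq)
  classic <- classic - mean(classic)
  expect_equal(unname(a$dcq[, "T1"]), unname(classic))
})

test_that("output is invariant to sample and combo ordering", {
  set.seed(33)
  meta <- data.frame(sample = paste0("S", 1:8), group = "a",
                     stringsAsFactors = FALSE)
  x <- cq_matrix(cbind(R1 = rnorm(8, 20), R2 = rnorm(8, 21)), meta)
  tg <- cq_matrix(cbind(T1 = rnorm(8, 26)), meta)
  efc <- c(R1 = 1.9, R2 = 1.88, T1 = 1.93)
  a <- normalize_targets(x, tg, combo = c("R1", "R2"), efficiencies = efc)
  b <- normalize_targets(x, tg, combo = c("R2", "R1"), efficiencies = efc)
  expect_equal(a$dcq, b$dcq)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  xp <- subset_cq(x, samples = perm)
  tgp <- subset_cq(tg, samples = perm)
  cp <- normalize_targets(xp, tgp, combo = c("R1", "R2"),
                          efficiencies = efc)
  expect_equal(cp$dcq[rownames(a$dcq), ], a$dcq[, 1],
               ignore_attr = TRUE)
})

test_that("higher efficiency scale widens group mean differences", {
  meta <- data.frame(sample = paste0("S", 1:8),
                     group = rep(c("a", "b"), each = 4),
                     stringsAsFactors = FALSE)
  x <- cq_matrix(cbind(R1 = rep(20, 8)), meta)
  tg <- cq_matrix(cbind(T1 = c(25, 25, 25, 25, 28, 28, 28, 28)), meta)
  lo <- normalize_targets(x, tg, combo = "R1",
                          efficiencies = c(R1 = 1.85, T1 = 1.85))
  hi <- normalize_targets(x, tg, combo = "R1",
                          efficiencies = c(R1 = 1.97, T1 = 1.97))
  gap <- function(nrm) {
    gs <- group_summary(nrm, "group")
    abs(diff(gs$mean))
  }
  expect_gt(gap(hi), gap(lo))
})

test_that("group summaries report means, SDs and degenerate groups", {
  meta <- data.frame(sample = paste0("S", 1:5),
                     group = c("a", "a", "b", "b", "solo"),
                     stringsAsFactors = FALSE)
  x <- cq_matrix(cbind(R1 = rep(20, 5)), meta)
  tg <- cq_matrix(cbind(T1 = c(25, 25, 27, 27, 26)), meta)
  nrm <- normalize_targets(x, tg, combo = "R1", center = FALSE)
  gs <- group_summary(nrm, "group")
  expect_equal(gs$mean[gs$group == "b"] - gs$mean[gs$group == "a"], 2)
  expect_equal(gs$sd[gs$group %in% c("a", "b")], c(0, 0))
  expect_true(is.na(gs$sd[gs$group == "solo"]))
  # pooled mean of centered values is zero
  nrmc <- normalize_targets(x, tg, combo = "R1")
  gsc <- group_summary(nrmc, "group")
  expect_equal(sum(gsc$mean * gsc$n), 0, tolerance = 1e-12)
})

test_that("a co-regulated reference shrinks the target's group SD", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 40
    shared <- rnorm(n, 0, 1.2)       # latent shared by target and bad ref
    tgt <- 26 + shared + rnorm(n, 0, 0.3)
    coreg_ref <- 19 + shared + rnorm(n, 0, 0.3)
    stable_ref <- 20 + rnorm(n, 0, 0.3)
    meta <- data.frame(sample = paste0("S", 1:n), group = "a",
                       stringsAsFactors = FALSE)
    x <- cq_matrix(cbind(CR = coreg_ref, SR = stable_ref), meta)
    tg <- cq_matrix(cbind(T1 = tgt), meta)
    sd_cr <- sd(normalize_targets(x, tg, combo = "CR")$dcq[, 1])
    sd_sr <- sd(normalize_targets(x, tg, combo = "SR")$dcq[, 1])
    if (sd_cr < sd_sr) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
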