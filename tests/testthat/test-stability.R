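test_that("comparative delta-Ct reproduces the hand-worked example", {
  res <- delta_ct_stability(toy_matrix3())
  expect_equal(unname(res$values[c("g1", "g2", "g3")]), c(0.5, 0.5, 1.0))
  expect_equal(res$ranking[3], "g3")
  # identical columns contribute a zero pairwise term
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 1, 9))
  res2 <- delta_ct_stability(m)
  expect_equal(unname(res2$values["a"]), unname(res2$values["b"]))
})

test_that("delta-Ct and M-values are invariant to per-gene and per-sample shifts", {
  x <- rand_cqm(n = 15, k = 4, seed = 3)
  base_d <- delta_ct_stability(x)$values
  base_g <- genorm(x)$values
  shifted <- x$cq
  shifted[, 2] <- shifted[, 2] + 5        # per-gene constant
  expect_equal(delta_ct_stability(shifted)$values[names(base_d)], base_d)
  expect_equal(genorm(shifted)$values[names(base_g)], base_g)
  persample <- x$cq + rnorm(nrow(x$cq))   # per-sample constant
  expect_equal(delta_ct_stability(persample)$values[names(base_d)], base_d)
  expect_equal(genorm(persample)$values[names(base_g)], base_g)
})

test_that("BestKeeper SD/CV match direct formulas and flag unstable genes", {
  m <- cbind(G1 = c(20, 21, 22), G2 = c(21, 22, 23))
  res <- bestkeeper(m)
  expect_equal(unname(res$values["G1"]), 1.0)
  expect_equal(unname(res$cv["G1"]), 100 / 21, tolerance = 1e-12)
  # perfectly correlated pair: r = 1
  expect_equal(res$correlation$r["G1", "G2"], 1.0)
  expect_length(res$flagged, 0L)
  # SD 1.12 exceeds the conventional cutoff of 1
  m2 <- cbind(G1 = c(20, 21, 22), G2 = 21 + c(-1.12, 0, 1.12))
  res2 <- bestkeeper(m2)
  expect_equal(unname(sd(m2[, "G2"])), 1.12)
  expect_true("G2" %in% res2$flagged)
})

test_that("BestKeeper SD is not invariant to per-sample shifts", {
  x <- rand_cqm(n = 15, k = 4, seed = 5)
  base <- bestkeeper(x)$values
  persample <- x$cq + seq(0, 7, length.out = nrow(x$cq))
  shifted <- bestkeeper(persample)$values
  expect_false(isTRUE(all.equal(shifted[names(base)], base)))
  # but a per-gene constant changes nothing
  pergene <- x$cq
  pergene[, 1] <- pergene[, 1] + 3
  expect_equal(bestkeeper(pergene)$values[names(base)], base)
})

test_that("delta-Ct values equal brute-force mean pairwise SD", {
  for (s in 1:10) {
    x <- rand_cqm(n = 20, k = 5, seed = 100 + s)
    expect_equal(delta_ct_stability(x)$values[colnames(x$cq)],
                 brute_mean_pairwise_sd(x$cq), tolerance = 1e-12)
    expect_equal(genorm(x)$initial_m[colnames(x$cq)],
                 brute_mean_pairwise_sd(x$cq), tolerance = 1e-12)
  }
})

test_that("model-based stability requires at least two groups", {
  m <- matrix(rep(c(20, 21, 22, 23), times = 3), nrow = 3, byrow = TRUE)
  m <- m + c(0.5, -0.2, 0.1)   # per-sample loading only
  colnames(m) <- paste0("G", 1:4)
  rownames(m) <- paste0("S", 1:3)
  x <- cq_matrix(m, data.frame(sample = rownames(m),
                               group = c("a", "a", "a")))
  expect_error(normfinder(x), "group")
})

test_that("model-based stability handles groups and degenerate input", {
  m <- rbind(c(20, 21, 22), c(20, 21, 22), c(20, 21, 22), c(20, 21, 22))
  m <- m + c(0.5, -0.2, 0.1, 0.4)
  colnames(m) <- paste0("G", 1:3)
  rownames(m) <- paste0("S", 1:4)
  x <- cq_matrix(m, data.frame(sample = rownames(m),
                               group = c("a", "a", "b", "b")))
  res <- normfinder(x)
  expect_equal(unname(res$values), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(res$intra), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(res$inter), rep(0, 3), tolerance = 1e-12)
  # group with a single sample is rejected by name
  bad <- cq_matrix(m, data.frame(sample = rownames(m),
                                 group = c("a", "a", "a", "solo")))
  expect_error(normfinder(bad), "solo")
})

test_that("a group-regulated gene is ranked last by the model-based method", {
  last <- 0L
  for (s in 1:20) {
    mat <- shifted_panel_sim(seed = 900 + s)
    res <- normfinder(mat)
    if (res$ranking[6] == "G6") last <- last + 1L
  }
  expect_gte(last, 19L)
})

test_that("reported inter-group variation grows with the injected offset", {
  inter <- sapply(c(0.3, 0.8, 1.5), function(delta) {
    mat <- shifted_panel_sim(seed = 321, offset = delta)
    normfinder(mat)$inter[["G6"]]
  })
  expect_true(all(diff(inter) > 0))
})

test_that("stepwise exclusion reproduces the toy example and cutoff", {
  res <- genorm(toy_matrix3())
  expect_equal(res$exclusion_order, "g3")
  expect_setequal(res$final_pair, c("g1", "g2"))
  expect_equal(res$final_m, 0)
  expect_true(res$acceptable)     # 0 < 1.5
  expect_equal(res$ranking[1:2], c("g1", "g2"))
})

test_that("stepwise-exclusion ties are broken by input order and logged", {
  # two duplicated pairs: every gene has the same round-1 M, so the
  # whole panel is tied and the gene latest in column order must go first
  set.seed(9)
  z1 <- rnorm(10)
  z2 <- rnorm(10)
  m <- cbind(G1 = z1, G2 = z1, G3 = z2, G4 = z2)
  res <- genorm(m)
  expect_equal(res$exclusion_order, c("G4", "G3"))
  expect_setequal(res$final_pair, c("G1", "G2"))
  expect_equal(res$final_m, 0)
  expect_gte(length(res$ties), 1L)
})

test_that("exclusion never splits the most correlated equal-variance pair", {
  for (s in 1:10) {
    set.seed(400 + s)
    shared <- rnorm(30)
    pair1 <- shared + rnorm(30, sd = 0.2)
    pair2 <- shared + rnorm(30, sd = 0.2)
    outlier <- rnorm(30, sd = 2)
    other <- rnorm(30, sd = 0.8)
    m <- cbind(P1 = pair1, P2 = pair2, O1 = other, X = outlier)
    res <- genorm(m)
    expect_true(all(c("P1", "P2") %in% res$final_pair) ||
                  !any(c("P1", "P2") %in% res$exclusion_order[1]))
    expect_setequal(res$final_pair, c("P1", "P2"))
  }
})

test_that("set-wise M generalizes the final-pair M", {
  x <- rand_cqm(n = 20, k = 5, seed = 77)
  g <- genorm(x)
  expect_equal(set_m_value(x, g$final_pair), g$final_m, tolerance = 1e-12)
})

test_that("normalization-factor comparison behaves on constructed cases", {
  n <- 12
  set.seed(31)
  r1 <- rnorm(n, 20, 1)
  refs <- cbind(R1 = r1, R2 = r1)        # duplicated reference
  tgt <- cbind(T1 = r1 + 3)              # perfectly co-regulated target
  meta <- data.frame(sample = paste0("S", 1:n),
                     group = rep(c("a", "b", "c"), each = 4),
                     sex = rep(c("F", "M"), times = 6),
                     stringsAsFactors = FALSE)
  x <- cq_matrix(refs, meta)
  tg <- cq_matrix(tgt, meta)
  out <- compare_normalization_factors(x, tg, combos = list("R1"),
                                       target_genes = "T1")
  expect_equal(out$intragroup_sd, 0, tolerance = 1e-12)
  expect_equal(out$intergroup_sd, 0, tolerance = 1e-12)
  # mean of duplicated references equals the single reference
  out2 <- compare_normalization_factors(x, tg,
                                        combos = list("R1", c("R1", "R2")),
                                        target_genes = "T1")
  expect_equal(out2[1, -1], out2[2, -1], ignore_attr = TRUE)
  expect_error(compare_normalization_factors(x, tg, combos = list(character(0)),
                                             target_genes = "T1"),
               "empty")
})

test_that("normalizing by a regulated reference induces intergroup spread", {
  n_per <- 20
  groups <- rep(c("a", "b"), each = n_per)
  set.seed(55)
  flat_t <- rnorm(2 * n_per, 25, 0.1)
  reg_ref <- rnorm(2 * n_per, 20, 0.1) + ifelse(groups == "b", 1.5, 0)
  stable_ref <- rnorm(2 * n_per, 20, 0.1)
  meta <- data.frame(sample = paste0("S", 1:(2 * n_per)), group = groups,
                     stringsAsFactors = FALSE)
  x <- cq_matrix(cbind(REG = reg_ref, STA = stable_ref), meta)
  tg <- cq_matrix(cbind(T1 = flat_t), meta)
  out <- compare_normalization_factors(x, tg,
                                       combos = list("REG", "STA"),
                                       target_genes = "T1")
  reg_row <- out[out$combo == "REG", ]
  sta_row <- out[out$combo == "STA", ]
  # intergroup SD of the regulated-normalized target ~ offset / sqrt(2)
  expect_equal(reg_row$intergroup_sd, 1.5 / sqrt(2), tolerance = 0.1)
  expect_lt(sta_row$intergroup_sd, 0.1)
})
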