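# Shared fixtures and independent oracles for the test suite.

# Three-gene toy with hand-computed pairwise SDs:
# sd(g1-g2) = 0, sd(g1-g3) = sd(c(0,-1,1)) = 1, sd(g2-g3) = 1.
toy_matrix3 <- function() {
  m <- cbind(g1 = c(20, 21, 22), g2 = c(20, 21, 22), g3 = c(20, 22, 21))
  rownames(m) <- paste0("S", 1:3)
  m
}

rand_cqm <- function(n = 20, k = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * k, mean = 20, sd = 1.5), nrow = n,
              dimnames = list(paste0("S", seq_len(n)),
                              paste0("G", seq_len(k))))
  cq_matrix(m)
}

# Brute-force oracle: mean over partner genes of sd of paired differences,
# written as explicit loops, independent of the package internals.
brute_mean_pairwise_sd <- function(m) {
  genes <- colnames(m)
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in genes) {
    sds <- c()
    for (h in setdiff(genes, g)) {
      sds <- c(sds, stats::sd(m[, g] - m[, h]))
    }
    out[g] <- mean(sds)
  }
  out
}

pure_exp_curve <- function(E0, f0 = 0.001, baseline = 0, cycles = 40) {
  cyc <- seq_len(cycles)
  structure(list(cycle = cyc, fluorescence = f0 * E0^cyc + baseline,
                 sample = NA_character_, gene = NA_character_,
                 well = NA_character_, truth = NULL),
            class = "amp_curve")
}

# Deterministic noise-free panel in which every gene's variation is a
# distinct multiple of one shared sample profile: all stability rankings
# are exact and invariant under any within-group subsetting. Five genes,
# not six: with an even panel the two middle genes of the sorted scale
# always tie exactly in total pairwise distance.
separated_panel <- function(groups = 24, per_group = 4) {
  cg <- c(G1 = 0.2, G2 = 0.5, G3 = 1.0, G4 = 1.9, G5 = 2.7)
  x <- rep(seq(-1, 1, length.out = per_group), times = groups)
  grp <- rep(paste0("grp", seq_len(groups)), each = per_group)
  m <- outer(x, cg) + matrix(rep(c(18, 19, 20, 21, 22), each = length(x)),
                             ncol = length(cg))
  colnames(m) <- names(cg)
  rownames(m) <- sprintf("S%03d", seq_along(x))
  cq_matrix(m, data.frame(sample = rownames(m), group = grp,
                          stringsAsFactors = FALSE))
}

# Simulated six-gene panel: five stable genes plus one carrying a fixed
# Cq offset in the high-temperature groups.
shifted_panel_sim <- function(seed, offset = 1.5, samples_per_cell = 6L) {
  d <- study_design(ages = c(30L, 60L, 90L, 120L),
                    temperatures = c("Low", "High"),
                    samples_per_cell = samples_per_cell,
                    reference_genes = paste0("G", 1:6),
                    target_genes = character(0),
                    plates = 2L, calibrators = 2L, seed = seed)
  off <- matrix(0, nrow = 1, ncol = nrow(d$groups),
                dimnames = list("G6", d$groups$group))
  off["G6", d$groups$group[d$groups$temperature == "High"]] <- offset
  tr <- cq_truth(d, baseline = setNames(18:23, paste0("G", 1:6)),
                 tech_sd = 0.15, sample_sd = 0.3, loading_sd = 0.8,
                 plate_sd = 0, group_offsets = off)
  sim <- simulate_cq_dataset(d, tr)
  preprocess_cq(sim$records, sim$metadata)$matrix
}
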