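# A small, fast configuration used throughout: 2 chromosomes of 10 Mb,
# 40 EMS + 40 background SNPs, 60 F2 individuals, pools of 20.
small_config <- function(...) {
  sim_config(n_chromosomes = 2, chrom_length_bp = 1e7, n_ems_snps = 40,
             n_background_snps = 40, n_f2_individuals = 60,
             pool_size = 20, ...)
}

test_that("the same seed reproduces the simulation bit-identically", {
  s1 <- simulate_cross(small_config(seed = 21))
  s2 <- simulate_cross(small_config(seed = 21))
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$genotypes, s2$truth$genotypes)
  s3 <- simulate_cross(small_config(seed = 22))
  expect_false(identical(s1$table, s3$table))
})

test_that("pool A is exactly fixed at the causal SNP without sequencing error", {
  for (seed in 1:5) {
    sim <- simulate_cross(small_config(seq_error_rate = 0, seed = seed))
    ci <- causal_row(sim)
    expect_equal(sim$table$snp_index_a[ci], 1.0)
    # truth invariants: pool A all dosage 2, pool B dosage 0 or 1
    dosage <- sim$truth$genotypes[, sim$truth$causal$genotype_col]
    expect_true(all(dosage[sim$truth$pool_a] == 2))
    expect_true(all(dosage[sim$truth$pool_b] %in% c(0, 1)))
  }
})

test_that("fixed background differences sit near index 1 in both pools and cancel", {
  sim <- simulate_cross(small_config(seed = 23))
  bg <- paste(sim$table$chrom, sim$table$pos) %in%
    paste(sim$truth$snps$chrom,
          sim$truth$snps$pos)[sim$truth$snps$type == "background"]
  expect_gt(mean(sim$table$snp_index_a[bg], na.rm = TRUE), 0.98)
  expect_gt(mean(sim$table$snp_index_b[bg], na.rm = TRUE), 0.98)
  expect_lt(mean(abs(sim$table$delta[bg]), na.rm = TRUE), 0.02)
})

test_that("unselected F2 genotype frequencies fit 1:2:1", {
  truth <- simulate_f2(sim_config(n_chromosomes = 1, n_ems_snps = 8,
                                  n_background_snps = 0,
                                  n_f2_individuals = 4000, pool_size = 10,
                                  seed = 24))
  # pick a non-causal SNP; selection has not touched the population
  col <- setdiff(seq_len(ncol(truth$genotypes)),
                 truth$causal$genotype_col)[1]
  counts <- table(factor(truth$genotypes[, col], levels = 0:2))
  p <- chisq.test(counts, p = c(1, 2, 1) / 4)$p.value
  expect_gt(p, 0.001)
})

test_that("a large F2 segregates 3:1 and tiny populations count exactly", {
  truth <- simulate_f2(sim_config(n_chromosomes = 2, n_ems_snps = 20,
                                  n_background_snps = 0,
                                  n_f2_individuals = 10000, pool_size = 50,
                                  seed = 25))
  ratio <- phenotype_ratio(truth)
  # 2 SE of the ratio under binomial sampling at p = 1/4
  n <- length(truth$phenotype_mutant)
  p_hat <- mean(truth$phenotype_mutant)
  se_ratio <- sqrt(p_hat * (1 - p_hat) / n) / p_hat^2
  expect_lt(abs(ratio - 3), 2 * se_ratio)
  # exact count on a tiny truth object
  tiny <- truth
  tiny$phenotype_mutant <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(phenotype_ratio(tiny), 3)
})

test_that("the F2 population grows until both pools can be filled", {
  # 60 individuals give ~15 mutants on average; pools of 20 force growth
  sim <- simulate_cross(small_config(seed = 26))
  expect_gte(sum(sim$truth$phenotype_observed), 20)
  expect_gte(sum(!sim$truth$phenotype_observed), 20)
  expect_error(
    simulate_f2(small_config(resample_to_fill = FALSE, seed = 26)),
    "pool_size")
})

test_that("delta decays with distance from the causal SNP", {
  # one long chromosome with the causal SNP at its left end, averaged over
  # replicates: binned delta by distance must decrease monotonically from
  # the causal expectation towards 0
  bins <- c(0, 2e6, 8e6, 3e7)
  acc <- matrix(0, nrow = 20, ncol = 3)
  for (i in 1:20) {
    sim <- simulate_cross(sim_config(
      n_chromosomes = 1, chrom_length_bp = 3e7, n_ems_snps = 60,
      n_background_snps = 0, n_f2_individuals = 60, pool_size = 20,
      causal_index = 1, seed = 300 + i))
    d <- abs(sim$table$pos - sim$truth$causal$pos)
    bin <- cut(d, bins, include.lowest = TRUE)
    acc[i, ] <- tapply(sim$table$delta, bin, mean, na.rm = TRUE)
  }
  profile <- colMeans(acc, na.rm = TRUE)
  expect_true(all(diff(profile) < 0))
  expect_gt(profile[1], 0.4)  # tightly linked bin carries real signal
  expect_lt(profile[3], 0.2)  # loci tens of cM away are near-unlinked
})

test_that("selfed pedigrees segregate as expected and verify phenotypes", {
  truth <- simulate_f2(small_config(seed = 27, pheno_error_rate = 0.15))
  truth <- advance_generation(truth, n_progeny = 40)
  parent <- truth$genotypes[, truth$causal$genotype_col]
  # homozygotes breed true
  expect_true(all(truth$pedigrees[parent == 2, ] == 2))
  expect_true(all(truth$pedigrees[parent == 0, ] == 0))
  # heterozygous parents segregate about 1:2:1
  het_prog <- as.vector(truth$pedigrees[parent == 1, ])
  counts <- table(factor(het_prog, levels = 0:2))
  p <- chisq.test(counts, p = c(1, 2, 1) / 4)$p.value
  expect_gt(p, 0.001)
  # pedigree-verified phenotype matches the genotype despite the noisy
  # single-plant observations
  expect_equal(truth$phenotype_verified, parent == 2)
})

test_that("pedigree confirmation reduces delta variance under phenotyping error", {
  # paired comparison on the same F2 populations: pools drawn from noisy
  # single-plant phenotypes versus pedigree-verified classes
  deltas <- matrix(NA_real_, nrow = 60, ncol = 2)
  for (i in 1:60) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e6,
                      n_ems_snps = 10, n_background_snps = 0,
                      n_f2_individuals = 200, pool_size = 25,
                      pheno_error_rate = 0.15, causal_index = 5,
                      seed = 400 + i)
    truth <- simulate_f2(cfg)
    t_obs <- pool_and_sequence(draw_pools(truth, cfg), cfg)
    t_ver <- advance_generation(truth, cfg, n_progeny = 30)
    t_ver <- pool_and_sequence(draw_pools(t_ver, cfg), cfg)
    ci <- which(t_obs$pos == truth$causal$pos)
    deltas[i, ] <- c(t_obs$delta[ci], t_ver$delta[ci])
  }
  err_obs <- mean((deltas[, 1] - 2 / 3)^2)
  err_ver <- mean((deltas[, 2] - 2 / 3)^2)
  expect_lt(err_ver, err_obs)
})

test_that("draw_pools refuses undersized classes", {
  truth <- simulate_f2(small_config(seed = 28))
  truth$phenotype_observed[] <- FALSE  # no mutants observed
  expect_error(draw_pools(truth, small_config(seed = 28)), "pool_size")
})
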