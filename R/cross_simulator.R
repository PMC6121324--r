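#' Simulator configuration for the two-pool bulked-segregant design
#'
#' Models the mapping design: an EMS mutant crossed to its pre-mutagenesis
#' progenitor line, the F1 selfed, the segregating F2 phenotyped (with the
#' option of pedigree confirmation via [advance_generation()]), and DNA of
#' `pool_size` mutant-phenotype plants (pool A) and `pool_size`
#' wild-phenotype plants (pool B) pooled in equal ratio and sequenced at
#' `mean_depth` coverage per pool. Both parents differ from the public
#' reference genome at `n_background_snps` fixed positions, which therefore
#' sit near SNP index 1 in both pools and cancel in the delta -- the
#' rationale for aligning both pools to the reference.
#'
#' @param n_chromosomes Number of chromosomes (default 12).
#' @param chrom_length_bp Length of each chromosome in bp (default 30 Mb).
#' @param n_ems_snps Number of mutagen-induced SNPs, homozygous in the
#'   mutant parent and absent from the progenitor (default 500).
#' @param n_background_snps Number of fixed parental-line-versus-reference
#'   differences, homozygous alternate in both parents (default 2000).
#' @param causal_index Which EMS SNP (in genome order) is causal; `NULL`
#'   (default) picks one at random under the seed.
#' @param recomb_rate Recombination rate in cM/Mb (default 4).
#' @param n_f2_individuals Initial F2 population size (default 100). When
#'   `resample_to_fill` is `TRUE` and a phenotype class is smaller than
#'   `pool_size`, additional F2 individuals are grown in batches of this
#'   size until both classes are large enough -- mirroring field practice,
#'   where more plants are screened than are finally pooled.
#' @param pool_size Plants per pool (default 50).
#' @param mean_depth Mean sequencing depth per pool at each SNP; read
#'   depth is Poisson with this mean (default 30).
#' @param seq_error_rate Per-read probability that a read reports the
#'   wrong allele (default 0.002).
#' @param ems_gc_at_fraction Fraction of EMS SNPs drawn as canonical
#'   G:C>A:T transitions (default 0.7).
#' @param pheno_error_rate Probability that a plant's phenotype is
#'   misclassified (default 0; see [advance_generation()] for pedigree
#'   confirmation, which mitigates a nonzero rate).
#' @param resample_to_fill Grow extra F2 individuals until both phenotype
#'   classes reach `pool_size` (default `TRUE`); with `FALSE`, a shortfall
#'   is an error.
#' @param seed Integer seed; the same seed reproduces the simulation
#'   bit-identically.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 12, chrom_length_bp = 3e7,
                       n_ems_snps = 500, n_background_snps = 2000,
                       causal_index = NULL, recomb_rate = 4,
                       n_f2_individuals = 100, pool_size = 50,
                       mean_depth = 30, seq_error_rate = 0.002,
                       ems_gc_at_fraction = 0.7, pheno_error_rate = 0,
                       resample_to_fill = TRUE, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp >= 1000,
            n_ems_snps >= 1, n_background_snps >= 0,
            recomb_rate > 0, n_f2_individuals >= 4, pool_size >= 1,
            mean_depth > 0, seq_error_rate >= 0, seq_error_rate < 0.5,
            ems_gc_at_fraction >= 0, ems_gc_at_fraction <= 1,
            pheno_error_rate >= 0, pheno_error_rate < 0.5)
  if (!is.null(causal_index)) {
    stopifnot(causal_index >= 1, causal_index <= n_ems_snps)
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_ems_snps = as.integer(n_ems_snps),
                 n_background_snps = as.integer(n_background_snps),
                 causal_index = causal_index,
                 recomb_rate = recomb_rate,
                 n_f2_individuals = as.integer(n_f2_individuals),
                 pool_size = as.integer(pool_size),
                 mean_depth = mean_depth,
                 seq_error_rate = seq_error_rate,
                 ems_gc_at_fraction = ems_gc_at_fraction,
                 pheno_error_rate = pheno_error_rate,
                 resample_to_fill = isTRUE(resample_to_fill),
                 seed = as.integer(seed)),
            class = "sim_config")
}

SUBSTITUTIONS <- expand.grid(ref = c("A", "C", "G", "T"),
                             alt = c("A", "C", "G", "T"),
                             stringsAsFactors = FALSE)
SUBSTITUTIONS <- SUBSTITUTIONS[SUBSTITUTIONS$ref != SUBSTITUTIONS$alt, ]

draw_substitutions <- function(n, canonical_fraction) {
  canon <- stats::runif(n) < canonical_fraction
  ref <- character(n)
  alt <- character(n)
  g2a <- stats::runif(n) < 0.5
  ref[canon] <- ifelse(g2a[canon], "G", "C")
  alt[canon] <- ifelse(g2a[canon], "A", "T")
  if (any(!canon)) {
    others <- SUBSTITUTIONS[!(SUBSTITUTIONS$ref %in% c("G", "C") &
                                SUBSTITUTIONS$alt %in% c("A", "T") &
                                (SUBSTITUTIONS$ref == "G") ==
                                  (SUBSTITUTIONS$alt == "A")), ]
    pick <- sample.int(nrow(others), sum(!canon), replace = TRUE)
    ref[!canon] <- others$ref[pick]
    alt[!canon] <- others$alt[pick]
  }
  list(ref = ref, alt = alt)
}

draw_positions <- function(n, config, taken = character(0)) {
  chrom_names <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  out_chrom <- character(0)
  out_pos <- integer(0)
  while (length(out_pos) < n) {
    k <- n - length(out_pos)
    chrom <- chrom_names[sample.int(config$n_chromosomes, k, replace = TRUE)]
    pos <- sample.int(config$chrom_length_bp, k, replace = TRUE)
    key <- paste(chrom, pos)
    ok <- !key %in% taken & !duplicated(key)
    taken <- c(taken, key[ok])
    out_chrom <- c(out_chrom, chrom[ok])
    out_pos <- c(out_pos, pos[ok])
  }
  list(chrom = out_chrom, pos = out_pos, taken = taken)
}

# F2 gametes along one chromosome under the Haldane model (Poisson
# crossovers, no interference): inheritance at ordered loci is a Markov
# chain whose switch probability between adjacent loci is the
# recombination fraction r = (1 - exp(-2d))/2 at map distance d Morgans.
f2_dosages <- function(n_individuals, pos_bp, recomb_rate) {
  m <- length(pos_bp)
  g <- 2L * n_individuals
  alleles <- matrix(0L, nrow = g, ncol = m)
  alleles[, 1] <- stats::rbinom(g, 1, 0.5)
  if (m > 1) {
    d_morgans <- diff(pos_bp) * recomb_rate / 100 / 1e6
    r <- 0.5 * (1 - exp(-2 * d_morgans))
    switches <- matrix(stats::rbinom(g * (m - 1), 1, rep(r, each = g)),
                       nrow = g)
    for (j in 2:m) {
      alleles[, j] <- (alleles[, j - 1] + switches[, j - 1]) %% 2L
    }
  }
  alleles[seq_len(n_individuals), , drop = FALSE] +
    alleles[n_individuals + seq_len(n_individuals), , drop = FALSE]
}

make_f2_batch <- function(n, snps, config) {
  ems <- snps[snps$type == "ems", , drop = FALSE]
  geno <- matrix(0L, nrow = n, ncol = nrow(ems))
  for (cn in unique(ems$chrom)) {
    idx <- which(ems$chrom == cn)
    geno[, idx] <- f2_dosages(n, ems$pos[idx], config$recomb_rate)
  }
  geno
}

observe_phenotype <- function(true_mutant, pheno_error_rate) {
  if (pheno_error_rate <= 0) return(true_mutant)
  flip <- stats::runif(length(true_mutant)) < pheno_error_rate
  xor(true_mutant, flip)
}

#' Simulate an F2 mapping population
#'
#' Simulates the mutant x progenitor cross: the mutant parent is
#' homozygous alternate at every EMS SNP, the F1 heterozygous, and each F2
#' individual receives two independent gametes with Poisson crossovers
#' (Haldane model, no interference). Background SNPs are homozygous
#' alternate in both parents and thus in every individual. The phenotype
#' is mutant iff the causal dosage is 2; observed phenotypes are optionally
#' misclassified at `pheno_error_rate`. If a phenotype class is smaller
#' than `pool_size`, additional individuals are grown (see
#' [sim_config()]'s `resample_to_fill`).
#'
#' Seeds the RNG from `config$seed`; downstream steps
#' ([advance_generation()], [draw_pools()], [pool_and_sequence()]) continue
#' the stream, so a fixed config reproduces the whole pipeline
#' bit-identically.
#'
#' @param config A [sim_config()].
#' @return A `cross_truth` list: `snps` (tibble with `chrom`, `pos`, `ref`,
#'   `alt`, `type`, `is_causal`, `genotype_col`), `genotypes` (individuals
#'   x EMS-SNP dosage matrix; background SNPs are constant dosage 2 and not
#'   stored), `causal` (chrom, pos, genotype column), `phenotype_mutant`
#'   (true), `phenotype_observed`, and `config`.
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ems_pos <- draw_positions(config$n_ems_snps, config)
  bg_pos <- draw_positions(config$n_background_snps, config,
                           taken = ems_pos$taken)
  ems_sub <- draw_substitutions(config$n_ems_snps,
                                config$ems_gc_at_fraction)
  bg_sub <- draw_substitutions(config$n_background_snps, 0.25)
  snps <- tibble::tibble(
    chrom = c(ems_pos$chrom, bg_pos$chrom),
    pos = c(ems_pos$pos, bg_pos$pos),
    ref = c(ems_sub$ref, bg_sub$ref),
    alt = c(ems_sub$alt, bg_sub$alt),
    type = rep(c("ems", "background"),
               c(config$n_ems_snps, config$n_background_snps)))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  ems_rows <- which(snps$type == "ems")
  snps$genotype_col <- NA_integer_
  snps$genotype_col[ems_rows] <- seq_along(ems_rows)
  causal_ems <- if (is.null(config$causal_index)) {
    sample.int(config$n_ems_snps, 1)
  } else {
    config$causal_index
  }
  causal_row <- ems_rows[causal_ems]
  snps$is_causal <- seq_len(nrow(snps)) == causal_row
  causal_col <- snps$genotype_col[causal_row]

  geno <- make_f2_batch(config$n_f2_individuals, snps, config)
  mutant <- geno[, causal_col] == 2L
  observed <- observe_phenotype(mutant, config$pheno_error_rate)
  tries <- 0L
  while (min(sum(observed), sum(!observed)) < config$pool_size) {
    if (!config$resample_to_fill) {
      stop("phenotype class smaller than pool_size (",
           sum(observed), " mutant, ", sum(!observed), " wild); ",
           "set resample_to_fill = TRUE or lower pool_size", call. = FALSE)
    }
    tries <- tries + 1L
    if (tries > 200L) {
      stop("could not fill both pools after 200 extra batches", call. = FALSE)
    }
    extra <- make_f2_batch(config$n_f2_individuals, snps, config)
    geno <- rbind(geno, extra)
    extra_mutant <- extra[, causal_col] == 2L
    mutant <- c(mutant, extra_mutant)
    observed <- c(observed,
                  observe_phenotype(extra_mutant, config$pheno_error_rate))
  }
  structure(list(snps = snps, genotypes = geno,
                 causal = list(chrom = snps$chrom[causal_row],
                               pos = snps$pos[causal_row],
                               genotype_col = causal_col),
                 phenotype_mutant = mutant,
                 phenotype_observed = observed,
                 phenotype_verified = NULL,
                 pedigrees = NULL,
                 pool_a = NULL, pool_b = NULL,
                 config = config),
            class = "cross_truth")
}

#' Self the F2 into pedigrees and verify phenotypes
#'
#' Each F2 individual is selfed into an F2:3 pedigree of `n_progeny`
#' plants; because homozygotes breed true, the pedigree's segregation
#' pattern at the causal locus identifies the parent's phenotype class far
#' more reliably than a single observation. The parent is classed mutant
#' when more than half of its (error-prone) progeny phenotype observations
#' are mutant. Subsequent [draw_pools()] calls use the verified classes.
#'
#' @param truth A `cross_truth` from [simulate_f2()].
#' @param config The [sim_config()] used.
#' @param n_progeny Pedigree size used for phenotype confirmation
#'   (default 24).
#' @return The updated `cross_truth`, with `pedigrees` (progeny causal
#'   dosage matrix, individuals x progeny) and `phenotype_verified`.
#' @export
advance_generation <- function(truth, config = truth$config,
                               n_progeny = 24) {
  stopifnot(inherits(truth, "cross_truth"), n_progeny >= 2)
  n <- nrow(truth$genotypes)
  parent_dosage <- truth$genotypes[, truth$causal$genotype_col]
  progeny <- matrix(0L, nrow = n, ncol = n_progeny)
  progeny[parent_dosage == 2L, ] <- 2L
  het <- which(parent_dosage == 1L)
  if (length(het) > 0) {
    progeny[het, ] <- stats::rbinom(length(het) * n_progeny, 2, 0.5)
  }
  obs_mutant <- matrix(
    observe_phenotype(as.vector(progeny == 2L), config$pheno_error_rate),
    nrow = n)
  truth$pedigrees <- progeny
  truth$phenotype_verified <- rowMeans(obs_mutant) > 0.5
  truth
}

#' Assign plants to the two pools
#'
#' Draws `pool_size` plants without replacement from the mutant-phenotype
#' class (pool A) and from the wild-phenotype class (pool B), using
#' pedigree-verified phenotypes when [advance_generation()] has been run
#' and the single observed phenotypes otherwise.
#'
#' @inheritParams advance_generation
#' @return The updated `cross_truth` with `pool_a` and `pool_b` (row
#'   indices into `genotypes`).
#' @export
draw_pools <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "cross_truth"))
  pheno <- if (!is.null(truth$phenotype_verified)) {
    truth$phenotype_verified
  } else {
    truth$phenotype_observed
  }
  mutants <- which(pheno)
  wilds <- which(!pheno)
  if (length(mutants) < config$pool_size ||
      length(wilds) < config$pool_size) {
    stop("phenotype class smaller than pool_size (", length(mutants),
         " mutant, ", length(wilds), " wild)", call. = FALSE)
  }
  truth$pool_a <- sort(sample(mutants, config$pool_size))
  truth$pool_b <- sort(sample(wilds, config$pool_size))
  truth
}

#' Sequence the two pools
#'
#' Computes each pool's true alternate-allele frequency `f` at every SNP
#' (mean dosage over pooled plants / 2; background SNPs are fixed at 1),
#' then samples per-pool read counts: total depth is Poisson(`mean_depth`)
#' and alternate reads are Binomial(depth, `f'`) with
#' `f' = f (1 - e) + (1 - f) e`, `e = seq_error_rate`.
#'
#' @inheritParams advance_generation
#' @param min_depth Depth cutoff below which a pool's SNP index is
#'   undefined (default 10).
#' @return A variant table (see [as_variant_table()]).
#' @export
pool_and_sequence <- function(truth, config = truth$config,
                              min_depth = 10) {
  stopifnot(inherits(truth, "cross_truth"),
            !is.null(truth$pool_a), !is.null(truth$pool_b))
  snps <- truth$snps
  pool_freq <- function(pool) {
    f <- rep(1, nrow(snps))
    ems <- !is.na(snps$genotype_col)
    f[ems] <- colMeans(truth$genotypes[pool, snps$genotype_col[ems],
                                       drop = FALSE]) / 2
    f
  }
  e <- config$seq_error_rate
  sample_pool <- function(f) {
    f_eff <- f * (1 - e) + (1 - f) * e
    depth <- stats::rpois(length(f), config$mean_depth)
    alt <- stats::rbinom(length(f), depth, f_eff)
    list(ref = depth - alt, alt = alt)
  }
  reads_a <- sample_pool(pool_freq(truth$pool_a))
  reads_b <- sample_pool(pool_freq(truth$pool_b))
  as_variant_table(
    tibble::tibble(chrom = snps$chrom, pos = snps$pos,
                   ref = snps$ref, alt = snps$alt,
                   a_ref = reads_a$ref, a_alt = reads_a$alt,
                   b_ref = reads_b$ref, b_alt = reads_b$alt),
    min_depth = min_depth)
}

#' Simulate the full two-pool bulked-segregant experiment
#'
#' Runs [simulate_f2()], [draw_pools()] and [pool_and_sequence()] under one
#' seed. At the causal SNP the expected SNP indices are 1 (pool A) and 1/3
#' (pool B), hence an expected delta of 2/3; unlinked SNPs sit at 1/2 in
#' both pools (delta 0) and fixed background SNPs near 1 in both (delta 0).
#'
#' @param config A [sim_config()].
#' @param min_depth Depth cutoff for SNP indices (default 10).
#' @return A list with `table` (variant table) and `truth` (`cross_truth`).
#' @export
#' @examples
#' sim <- simulate_cross(sim_config(n_chromosomes = 2, n_ems_snps = 40,
#'                                  n_background_snps = 40, seed = 7))
#' causal <- sim$table$pos == sim$truth$causal$pos &
#'   sim$table$chrom == sim$truth$causal$chrom
#' sim$table[causal, c("snp_index_a", "snp_index_b", "delta")]
simulate_cross <- function(config = sim_config(), min_depth = 10) {
  truth <- simulate_f2(config)
  truth <- draw_pools(truth, config)
  table <- pool_and_sequence(truth, config, min_depth = min_depth)
  list(table = table, truth = truth)
}

#' Phenotype segregation ratio of the simulated F2
#'
#' @param truth A `cross_truth`.
#' @return `n_dominant / n_recessive` over all simulated individuals,
#'   using true (genotype-derived) phenotypes; 3 is expected for a single
#'   recessive causal gene.
#' @export
phenotype_ratio <- function(truth) {
  stopifnot(inherits(truth, "cross_truth"))
  n_rec <- sum(truth$phenotype_mutant)
  if (n_rec == 0) stop("no recessive individuals simulated", call. = FALSE)
  sum(!truth$phenotype_mutant) / n_rec
}

#' Write a variant table as a minimal two-sample VCF
#'
#' Emits VCF 4.2 with an `AD:DP` FORMAT for the two pools -- the dialect
#' [read_vcf()] consumes, so simulated tables can exercise the VCF path.
#'
#' @param table A variant table.
#' @param path Output path.
#' @param pool_a_sample,pool_b_sample Sample names to write.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(table, path, pool_a_sample = "poolA",
                          pool_b_sample = "poolB") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mutmapr_simulator",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", pool_a_sample, pool_b_sample, sep = "\t"))
  body <- paste(table$chrom, table$pos, ".", table$ref, table$alt, ".",
                "PASS", ".", "AD:DP",
                paste0(table$a_ref, ",", table$a_alt, ":",
                       table$a_ref + table$a_alt),
                paste0(table$b_ref, ",", table$b_alt, ":",
                       table$b_ref + table$b_alt),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
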