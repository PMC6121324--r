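# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

BASES <- c("A", "C", "G", "T")

# A small two-exon plus-strand gene on a 200 bp chromosome:
# exon1 11-40 (5'UTR 11-19, CDS 20-40), intron 41-60,
# exon2 61-100 (CDS 61-87, 3'UTR 88-100); CDS = 16 codons.
make_test_gene <- function() {
  cds_bases <- c("ATG", "GCG", "CGA", "AAA", "CCC", "GGG", "TTT", "GCG",
                 "ACA", "CAT", "GAC", "TCA", "AGC", "TGC", "CGT", "TAA")
  seq <- rep("T", 200)
  cds_seq <- strsplit(paste(cds_bases, collapse = ""), "")[[1]]
  seq[20:40] <- cds_seq[1:21]
  seq[61:87] <- cds_seq[22:48]
  genome <- c(chr1 = paste(seq, collapse = ""))
  model <- gene_model("G1", "chr1", "+",
                      exons = data.frame(start = c(11, 61),
                                         end = c(40, 100)),
                      cds = data.frame(start = c(20, 61), end = c(40, 87)))
  list(genome = genome, model = model, cds_bases = cds_bases)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# reverse-complement mirror of a gene (and its genome) on an L bp chromosome
mirror_gene <- function(gene, L = 200) {
  mir <- function(x) L - x + 1
  flip <- function(df) {
    if (is.null(df)) return(NULL)
    data.frame(start = mir(df$end), end = mir(df$start))
  }
  model <- gene$model
  list(genome = c(chr1 = revcomp(gene$genome[["chr1"]])),
       model = gene_model(model$gene_id, model$chrom,
                          if (model$strand == "+") "-" else "+",
                          exons = flip(model$exons),
                          cds = flip(model$cds)))
}

# brute-force codon translation oracle, independent of Biostrings
oracle_translate <- function(codon) {
  toupper(seqinr::translate(strsplit(tolower(codon), "")[[1]],
                            ambiguous = FALSE))
}

# brute-force position-by-position IUPAC matcher (forward strand only)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

brute_iupac_find <- function(sequence, site) {
  sequence <- strsplit(toupper(sequence), "")[[1]]
  site <- strsplit(toupper(site), "")[[1]]
  m <- length(site)
  n <- length(sequence)
  if (n < m) return(integer(0))
  hits <- integer(0)
  for (start in seq_len(n - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!sequence[start + j - 1] %in% IUPAC_SETS[[site[j]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

# brute-force windowed mean: rescan the full table for every window
brute_window_means <- function(table, chrom_lengths, window, step,
                               min_snps = 1) {
  out <- list()
  for (cn in names(chrom_lengths)) {
    starts <- seq(1, chrom_lengths[[cn]], by = step)
    for (s in starts) {
      in_win <- table$chrom == cn & table$pos >= s &
        table$pos < s + window & !is.na(table$delta)
      n <- sum(in_win)
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, start = s, n_snps = n,
        mean_delta = if (n >= min_snps) mean(table$delta[in_win])
                     else NA_real_)
    }
  }
  do.call(rbind, out)
}

# random small variant table (caller controls the RNG seed)
random_variant_table <- function(n, chroms = c("chr01", "chr02"),
                                 max_pos = 1e6, max_depth = 60,
                                 min_depth = 10) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
  pos <- sample.int(max_pos, n, replace = FALSE)
  as_variant_table(
    tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                   pos = pos, ref = ref, alt = unname(alt),
                   a_ref = stats::rpois(n, max_depth / 3),
                   a_alt = stats::rpois(n, max_depth / 3),
                   b_ref = stats::rpois(n, max_depth / 3),
                   b_alt = stats::rpois(n, max_depth / 3)),
    min_depth = min_depth)
}

# a small hand-written VCF exercising AD parsing, indel/multiallelic skips
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "poolA", "poolB", sep = "\t"),
    "chr01\t100\t.\tG\tA\t50\tPASS\t.\tGT:AD:DP\t1/1:0,28:28\t0/1:18,9:27",
    "chr01\t200\t.\tG\tA,T\t50\tPASS\t.\tGT:AD:DP\t1/1:0,10,5:15\t0/1:10,5,2:17",
    "chr01\t300\t.\tGTT\tG\t50\tPASS\t.\tGT:AD:DP\t1/1:0,12:12\t0/1:8,4:12",
    "chr02\t50\t.\tC\tT\t50\tPASS\t.\tGT:AD:DP\t1/1:2,3:5\t0/1:20,20:40"),
    path)
  path
}

# default-condition simulation table + truth, cached per test file run
causal_row <- function(sim) {
  which(sim$table$chrom == sim$truth$causal$chrom &
          sim$table$pos == sim$truth$causal$pos)
}

default_chrom_lengths <- function(config = sim_config()) {
  stats::setNames(rep(config$chrom_length_bp, config$n_chromosomes),
                  sprintf("chr%02d", seq_len(config$n_chromosomes)))
}
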