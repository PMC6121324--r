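test_that("the canonical EMS missense case is reproduced (GCG -> ACG, A -> T)", {
  gene <- make_test_gene()
  # codon 2 is GCG at genomic 23-25; G>A at its first base
  ann <- classify_effect("chr1", 23, "G", "A", list(gene$model),
                         gene$genome)
  expect_equal(ann$effect, "missense")
  expect_equal(ann$codon_change, "GCG>ACG")
  expect_equal(ann$aa_change, "A2T")   # alanine to threonine
  expect_true(ann$ems_canonical)
})

test_that("a C>T in an arginine codon creates a stop (nonsense, R>*)", {
  gene <- make_test_gene()
  # codon 3 is CGA at genomic 26-28; C>T gives TGA
  ann <- classify_effect("chr1", 26, "C", "T", list(gene$model),
                         gene$genome)
  expect_equal(ann$effect, "nonsense")
  expect_equal(ann$aa_change, "R3*")
  expect_equal(ann$codon_change, "CGA>TGA")
  expect_true(ann$ems_canonical)
})

test_that("third-position GCG>GCA is synonymous", {
  gene <- make_test_gene()
  ann <- classify_effect("chr1", 25, "G", "A", list(gene$model),
                         gene$genome)
  expect_equal(ann$effect, "synonymous")
  expect_equal(ann$aa_change, "A2A")
})

test_that("non-coding classes are assigned by gene geometry", {
  gene <- make_test_gene()
  cases <- list(list(pos = 5, effect = "intergenic"),
                list(pos = 15, effect = "five_prime_utr"),
                list(pos = 50, effect = "intron"),
                list(pos = 42, effect = "splice_region"),  # 2 bp into intron
                list(pos = 95, effect = "three_prime_utr"))
  for (case in cases) {
    ref <- substr(gene$genome[["chr1"]], case$pos, case$pos)
    alt <- setdiff(BASES, ref)[1]
    ann <- classify_effect("chr1", case$pos, ref, alt, list(gene$model),
                           gene$genome)
    expect_equal(ann$effect, case$effect)
    expect_true(is.na(ann$aa_change))
  }
})

test_that("every position of the model maps to exactly one class", {
  gene <- make_test_gene()
  span <- gene$model$span
  effects <- vapply(span[1]:span[2], function(p) {
    ref <- substr(gene$genome[["chr1"]], p, p)
    classify_effect("chr1", p, ref, setdiff(BASES, ref)[1],
                    list(gene$model), gene$genome)$effect
  }, character(1))
  expect_length(effects, span[2] - span[1] + 1)
  expect_true(all(effects %in% c("intron", "splice_region",
                                 "five_prime_utr", "three_prime_utr",
                                 "synonymous", "missense", "nonsense")))
})

test_that("reference mismatches and frame errors are rejected", {
  gene <- make_test_gene()
  expect_error(
    classify_effect("chr1", 23, "C", "A", list(gene$model), gene$genome),
    "mismatch at chr1:23")
  expect_error(
    classify_effect("chr1", 9999, "G", "A", list(gene$model), gene$genome),
    "outside")
  expect_error(
    gene_model("bad", "chr1", "+",
               exons = data.frame(start = 1, end = 100),
               cds = data.frame(start = 10, end = 20)),
    "not a multiple of 3")
})

test_that("translation matches an independent oracle for all single-base substitutions", {
  # build a gene whose CDS enumerates all 64 codons, mutate every codon
  # position to every alternate base, and compare against seqinr
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  cds <- paste(codons, collapse = "")
  genome <- c(chrT = paste0(strrep("T", 10), cds, strrep("T", 10)))
  model <- gene_model("T1", "chrT", "+",
                      exons = data.frame(start = 11,
                                         end = 10 + nchar(cds)),
                      cds = data.frame(start = 11,
                                       end = 10 + nchar(cds)))
  for (ci in seq_along(codons)) {
    codon <- codons[ci]
    for (offset in 1:3) {
      pos <- 10 + (ci - 1) * 3 + offset
      ref <- substr(codon, offset, offset)
      for (alt in setdiff(BASES, ref)) {
        ann <- classify_effect("chrT", pos, ref, alt, list(model), genome)
        mutated <- codon
        substr(mutated, offset, offset) <- alt
        aa_ref <- oracle_translate(codon)
        aa_alt <- oracle_translate(mutated)
        expected <- if (aa_ref == aa_alt) "synonymous"
                    else if (aa_alt == "*") "nonsense"
                    else "missense"
        expect_equal(ann$effect, expected,
                     label = paste(codon, offset, alt, ann$effect))
        expect_equal(ann$aa_change, paste0(aa_ref, ci, aa_alt))
      }
    }
  }
})

test_that("a gene and its reverse-complement mirror give identical effects", {
  gene <- make_test_gene()
  mirrored <- mirror_gene(gene)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  withr::local_seed(14)
  positions <- sample(gene$model$span[1]:gene$model$span[2], 40)
  for (pos in positions) {
    ref <- substr(gene$genome[["chr1"]], pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    fwd <- classify_effect("chr1", pos, ref, alt, list(gene$model),
                           gene$genome)
    rev_pos <- 200 - pos + 1
    rev <- classify_effect("chr1", rev_pos, comp[[ref]], comp[[alt]],
                           list(mirrored$model), mirrored$genome)
    expect_equal(rev$effect, fwd$effect, label = paste("pos", pos))
    expect_equal(rev$aa_change, fwd$aa_change)
  }
})

test_that("EMS transition flagging is strand symmetric and specific", {
  expect_true(flag_ems_transition("G", "A"))
  expect_true(flag_ems_transition("C", "T"))
  expect_false(flag_ems_transition("T", "G"))  # as in the published list
  expect_false(flag_ems_transition("A", "G"))
  expect_equal(flag_ems_transition(c("G", "T"), c("A", "G")),
               c(TRUE, FALSE))
})

test_that("GFF3 models round-trip through the annotator", {
  gene <- make_test_gene()
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t100\t.\t+\t.\tID=G1",
    "chr1\ttest\tmRNA\t11\t100\t.\t+\t.\tID=G1.1;Parent=G1",
    "chr1\ttest\texon\t11\t40\t.\t+\t.\tID=e1;Parent=G1.1",
    "chr1\ttest\texon\t61\t100\t.\t+\t.\tID=e2;Parent=G1.1",
    "chr1\ttest\tfive_prime_UTR\t11\t19\t.\t+\t.\tParent=G1.1",
    "chr1\ttest\tCDS\t20\t40\t.\t+\t0\tParent=G1.1",
    "chr1\ttest\tCDS\t61\t87\t.\t+\t0\tParent=G1.1",
    "chr1\ttest\tthree_prime_UTR\t88\t100\t.\t+\t.\tParent=G1.1"), gff)
  models <- read_gene_models(gff)
  expect_length(models, 1)
  expect_equal(models[[1]]$gene_id, "G1")
  ann <- classify_effect("chr1", 23, "G", "A", models, gene$genome)
  expect_equal(ann$effect, "missense")
  expect_equal(ann$codon_change, "GCG>ACG")
})

test_that("the screen pipeline applies both filter steps with an attrition log", {
  gene <- make_test_gene()
  # six SNPs: one out-of-band delta, one intergenic, one synonymous,
  # three qualifying (missense 23, nonsense 26, intron 50)
  tbl <- as_variant_table(tibble::tibble(
    chrom = "chr1",
    pos = c(23L, 26L, 50L, 5L, 25L, 35L),
    ref = c("G", "C", "T", "T", "G", "C"),
    alt = c("A", "T", "A", "A", "A", "T"),
    a_ref = 0L, a_alt = 30L,
    b_ref = c(20L, 20L, 20L, 20L, 20L, 27L),
    b_alt = c(10L, 10L, 10L, 10L, 10L, 3L)))
  # delta = 2/3 for all but pos 35 (delta = 0.9)
  res <- screen_pipeline(tbl, gene_models = list(gene$model),
                         genome = gene$genome)
  expect_equal(res$attrition$removed, c(1, 2))
  expect_equal(res$attrition$remaining, c(5, 3))
  expect_setequal(res$worklist$pos, c(23, 26, 50))
  expect_true(all(res$worklist$flank_start ==
                    pmax(1, res$worklist$pos - 250)))
  expect_equal(count_candidate_genes(res), 1)
  # empty input passes through empty
  empty <- screen_pipeline(tbl[0, ], gene_models = list(gene$model),
                           genome = gene$genome)
  expect_equal(nrow(empty$worklist), 0)
  expect_equal(empty$attrition$removed, c(0, 0))
})

test_that("the published 19-SNP example survives the screen in 12 genes", {
  snps <- wb1_candidate_snps()
  expect_equal(nrow(snps), 19)
  expect_equal(max(snps$delta), 0.758)

  res <- screen_pipeline(snps, annotations = snps)
  expect_equal(nrow(res$worklist), 19)           # all printed SNPs retained
  expect_equal(count_candidate_genes(res), 12)   # in twelve genes
  expect_equal(res$attrition$removed, c(0, 0))
})
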