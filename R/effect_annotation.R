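COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

EFFECT_CLASSES <- c("intergenic", "intron", "splice_region",
                    "five_prime_utr", "three_prime_utr",
                    "synonymous", "missense", "nonsense")

#' Construct a gene model
#'
#' A gene model is the exon/CDS/UTR structure of one transcript, with
#' 1-based inclusive coordinates on the forward strand of its chromosome.
#'
#' @param gene_id Gene identifier used in annotations.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`, `end` (non-overlapping; sorted
#'   internally).
#' @param cds Data frame with `start`, `end` and optionally `phase`; must
#'   lie inside exons, total length divisible by 3, and phase 0 at the
#'   first coding segment in transcription order.
#' @param utr5,utr3 Optional data frames with `start`, `end`. When omitted,
#'   exonic non-coding positions are assigned to the 5' or 3' UTR by their
#'   position relative to the CDS and the strand.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds,
                       utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            is.data.frame(cds), all(c("start", "end") %in% names(cds)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$end < exons$start) ||
      (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))) {
    stop("gene model ", gene_id, ": exons must be non-overlapping intervals",
         call. = FALSE)
  }
  if (is.null(cds$phase)) cds$phase <- 0L
  cds <- cds[order(cds$start), c("start", "end", "phase"), drop = FALSE]
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
  }, logical(1))
  if (!all(in_exon)) {
    stop("gene model ", gene_id, ": CDS segments must lie inside exons",
         call. = FALSE)
  }
  total <- sum(cds$end - cds$start + 1)
  if (total %% 3 != 0) {
    stop("gene model ", gene_id, ": CDS length ", total,
         " is not a multiple of 3 (frame inconsistency)", call. = FALSE)
  }
  first <- if (strand == "+") 1L else nrow(cds)
  if (!is.na(cds$phase[first]) && cds$phase[first] != 0) {
    stop("gene model ", gene_id, ": first coding segment has phase ",
         cds$phase[first], "; only complete CDS (phase 0) are supported",
         call. = FALSE)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                 span = c(min(exons$start), max(exons$end))),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Builds one [gene_model()] per transcript (`mRNA`/`transcript` feature)
#' from its `exon`, `CDS`, `five_prime_UTR` and `three_prime_UTR` children;
#' the model's `gene_id` is the transcript's parent gene ID when present.
#' Transcripts without CDS are skipped.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @return A named list of `gene_model` objects, keyed by transcript ID.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path)
  df <- as.data.frame(g)
  df$parent <- vapply(as.list(g$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(tx))) {
    tx_id <- tx$ID[i]
    kids <- df[!is.na(df$parent) & df$parent == tx_id, , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(cds) == 0) next
    exons <- kids[kids$type == "exon", , drop = FALSE]
    if (nrow(exons) == 0) {
      # derive the exon set from the coding and UTR segments
      exons <- kids[kids$type %in%
                      c("CDS", "five_prime_UTR", "three_prime_UTR"), ,
                    drop = FALSE]
      exons <- merge_touching_intervals(exons)
    }
    utr5 <- kids[kids$type == "five_prime_UTR", c("start", "end"),
                 drop = FALSE]
    utr3 <- kids[kids$type == "three_prime_UTR", c("start", "end"),
                 drop = FALSE]
    models[[tx_id]] <- gene_model(
      gene_id = if (is.na(tx$parent[i])) tx_id else tx$parent[i],
      chrom = as.character(tx$seqnames[i]),
      strand = as.character(tx$strand[i]),
      exons = exons[, c("start", "end"), drop = FALSE],
      cds = data.frame(start = cds$start, end = cds$end,
                       phase = if ("phase" %in% names(cds)) {
                         ifelse(is.na(cds$phase), 0L, cds$phase)
                       } else 0L),
      utr5 = if (nrow(utr5) > 0) utr5 else NULL,
      utr3 = if (nrow(utr3) > 0) utr3 else NULL)
  }
  models
}

merge_touching_intervals <- function(df) {
  df <- df[order(df$start), , drop = FALSE]
  out <- df[1, c("start", "end"), drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$start[i] <= out$end[last] + 1) {
      out$end[last] <- max(out$end[last], df$end[i])
    } else {
      out <- rbind(out, df[i, c("start", "end")])
    }
  }
  out
}

#' Flag canonical EMS transitions
#'
#' EMS (ethyl methanesulfonate) alkylates guanine and induces
#' predominantly G:C to A:T transitions; on the forward strand these read
#' as G>A or C>T substitutions.
#'
#' @param ref,alt Reference and alternate bases (vectorized).
#' @return Logical: `TRUE` for G>A or C>T.
#' @export
#' @examples
#' flag_ems_transition("G", "A")  # TRUE
#' flag_ems_transition("T", "G")  # FALSE
flag_ems_transition <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

normalize_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
    genome <- seqs
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  toupper(genome)
}

# 1-based position of `pos` within the spliced CDS, in transcription order;
# NA when pos is not coding.
cds_position <- function(pos, model) {
  cds <- model$cds
  ord <- if (model$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  offset <- 0L
  for (i in ord) {
    len <- cds$end[i] - cds$start[i] + 1L
    if (pos >= cds$start[i] && pos <= cds$end[i]) {
      within <- if (model$strand == "+") pos - cds$start[i] + 1L
                else cds$end[i] - pos + 1L
      return(as.integer(offset + within))
    }
    offset <- offset + len
  }
  NA_integer_
}

# genomic position of the k-th spliced CDS base (transcription order)
genomic_position <- function(k, model) {
  cds <- model$cds
  ord <- if (model$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  offset <- 0L
  for (i in ord) {
    len <- cds$end[i] - cds$start[i] + 1L
    if (k <= offset + len) {
      within <- k - offset
      return(as.integer(if (model$strand == "+") cds$start[i] + within - 1
                        else cds$end[i] - within + 1))
    }
    offset <- offset + len
  }
  stop("CDS coordinate ", k, " beyond gene model ", model$gene_id,
       call. = FALSE)
}

in_intervals <- function(pos, df) {
  !is.null(df) && nrow(df) > 0 && any(df$start <= pos & pos <= df$end)
}

# distance (bp) of an intronic position from the nearest exon boundary
# (1 = first intron base); Inf when the gene has a single exon
intron_boundary_distance <- function(pos, model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2) return(Inf)
  d <- c(pos - ex$end[-n], ex$start[-1] - pos)
  min(c(d[d > 0], Inf))
}

classify_one <- function(pos, ref, alt, model, chrom_seq,
                         splice_exonic = 3, splice_intronic = 8) {
  ex <- model$exons
  exon_i <- which(ex$start <= pos & pos <= ex$end)
  base_at <- function(p) substr(chrom_seq, p, p)
  ann <- list(gene_id = model$gene_id, effect = NA_character_,
              aa_change = NA_character_, codon_change = NA_character_)
  if (length(exon_i) == 0) {
    # intronic: within splice_intronic bp of a flanking exon -> splice region
    d <- intron_boundary_distance(pos, model)
    ann$effect <- if (d <= splice_intronic) "splice_region" else "intron"
    return(ann)
  }
  near_splice <- {
    i <- exon_i[1]
    n <- nrow(ex)
    d_up <- if (i > 1) pos - ex$start[i] + 1 else Inf    # acceptor side
    d_dn <- if (i < n) ex$end[i] - pos + 1 else Inf      # donor side
    min(d_up, d_dn) <= splice_exonic
  }
  cds_pos <- cds_position(pos, model)
  if (is.na(cds_pos)) {
    # exonic, non-coding: UTR (explicit intervals first, else inferred)
    effect <- if (in_intervals(pos, model$utr5)) {
      "five_prime_utr"
    } else if (in_intervals(pos, model$utr3)) {
      "three_prime_utr"
    } else {
      before_cds <- pos < min(model$cds$start)
      if (before_cds == (model$strand == "+")) "five_prime_utr"
      else "three_prime_utr"
    }
    ann$effect <- if (near_splice) "splice_region" else effect
    return(ann)
  }
  codon_idx <- (cds_pos - 1) %/% 3 + 1
  within <- (cds_pos - 1) %% 3 + 1
  codon_genomic <- vapply((codon_idx - 1) * 3 + 1:3, genomic_position,
                          integer(1), model = model)
  bases <- vapply(codon_genomic, base_at, character(1))
  if (model$strand == "-") bases <- unname(COMPLEMENT[bases])
  codon_ref <- paste(bases, collapse = "")
  alt_tx <- if (model$strand == "+") alt else unname(COMPLEMENT[alt])
  bases[within] <- alt_tx
  codon_alt <- paste(bases, collapse = "")
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  effect <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "nonsense"
            else "missense"
  # a splice-adjacent exonic change only outranks low-impact classes
  if (near_splice && effect == "synonymous") effect <- "splice_region"
  ann$effect <- effect
  if (effect %in% c("synonymous", "missense", "nonsense")) {
    ann$aa_change <- paste0(aa_ref, codon_idx, aa_alt)
    ann$codon_change <- paste0(codon_ref, ">", codon_alt)
  } else {
    ann$aa_change <- NA_character_
    ann$codon_change <- NA_character_
  }
  ann
}

#' Classify the effect of each SNP against gene models
#'
#' Each variant receives one annotation per overlapping gene model
#' (`intergenic` when none overlaps). Coding effects substitute the
#' alternate base into the strand-corrected codon and translate with the
#' standard genetic code; the effect vocabulary is `intergenic`, `intron`,
#' `splice_region`, `five_prime_utr`, `three_prime_utr`, `synonymous`,
#' `missense`, `nonsense`. Splice regions follow the SnpEff-style
#' convention: intronic positions within 8 bp of an exon boundary, or
#' exonic positions within 3 bp of an exon/intron boundary (where they
#' outrank intron and synonymous calls but not missense/nonsense).
#'
#' @param table A data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models A list of [gene_model()] objects (see
#'   [read_gene_models()]).
#' @param genome Genome sequence: FASTA path, `DNAStringSet`, or named
#'   character vector keyed by chromosome.
#' @return A tibble with one row per (variant, overlapping gene):
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `effect`, `aa_change`,
#'   `codon_change` (e.g. `"GCG>ACG"`), `ems_canonical`.
#' @export
classify_effects <- function(table, gene_models, genome) {
  genome <- normalize_genome(genome)
  rows <- vector("list", nrow(table))
  for (v in seq_len(nrow(table))) {
    chrom <- table$chrom[v]
    pos <- table$pos[v]
    ref <- toupper(table$ref[v])
    alt <- toupper(table$alt[v])
    if (!chrom %in% names(genome) || pos < 1 ||
        pos > nchar(genome[[chrom]])) {
      stop("variant ", chrom, ":", pos, " outside the declared genome",
           call. = FALSE)
    }
    have <- substr(genome[[chrom]], pos, pos)
    if (have != ref) {
      stop("reference mismatch at ", chrom, ":", pos, ": genome has ",
           have, ", variant claims ", ref, call. = FALSE)
    }
    hits <- Filter(function(m) {
      m$chrom == chrom && m$span[1] <= pos && pos <= m$span[2]
    }, gene_models)
    anns <- if (length(hits) == 0) {
      list(list(gene_id = NA_character_, effect = "intergenic",
                aa_change = NA_character_, codon_change = NA_character_))
    } else {
      unname(lapply(hits, classify_one, pos = pos, ref = ref, alt = alt,
                    chrom_seq = genome[[chrom]]))
    }
    rows[[v]] <- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      gene_id = vapply(anns, `[[`, "", "gene_id"),
      effect = vapply(anns, `[[`, "", "effect"),
      aa_change = vapply(anns, `[[`, "", "aa_change"),
      codon_change = vapply(anns, `[[`, "", "codon_change"),
      ems_canonical = flag_ems_transition(ref, alt))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene_id = character(), effect = character(),
                          aa_change = character(),
                          codon_change = character(),
                          ems_canonical = logical()))
  }
  do.call(rbind, rows)
}

#' Classify a single SNP
#'
#' Convenience wrapper around [classify_effects()] for one variant.
#'
#' @param chrom,pos,ref,alt The variant.
#' @inheritParams classify_effects
#' @return A tibble with one row per overlapping gene model.
#' @export
classify_effect <- function(chrom, pos, ref, alt, gene_models, genome) {
  classify_effects(tibble::tibble(chrom = chrom, pos = pos,
                                  ref = ref, alt = alt),
                   gene_models, genome)
}

#' Three-step candidate-SNP screen
#'
#' Step (i) retains SNPs whose delta SNP index lies inside the
#' [screen_config()] band (default 0.6-0.8). Step (ii) annotates the
#' survivors against gene models and removes SNPs that are intergenic or
#' synonymous in *every* overlapping gene. Step (iii), independent
#' confirmation by Sanger sequencing, is a wet-lab step; it is represented
#' by the returned validation worklist of surviving SNPs with flanking
#' coordinates for primer design.
#'
#' @param table A variant table with computed `delta`.
#' @inheritParams classify_effects
#' @param config A [screen_config()].
#' @param annotations Optional precomputed annotations (a data frame with
#'   `chrom`, `pos`, `gene_id`, `effect`), used instead of
#'   [classify_effects()] -- e.g. when gene structures are not available
#'   but published effect labels are.
#' @param flank Flank width (bp) on each side of a SNP in the worklist.
#' @return A `mutmap_screen` list: `variants` (annotated survivors, one row
#'   per qualifying annotation, with delta), `attrition` (per-step removed
#'   and remaining counts), `worklist`.
#' @export
screen_pipeline <- function(table, gene_models = NULL, genome = NULL,
                            config = screen_config(), annotations = NULL,
                            flank = 250) {
  n0 <- nrow(table)
  s1 <- screen_delta(table, config)
  key <- function(d) paste(d$chrom, d$pos)
  if (is.null(annotations)) {
    if (is.null(gene_models) || is.null(genome)) {
      stop("screen_pipeline: provide gene_models and genome, ",
           "or precomputed annotations", call. = FALSE)
    }
    ann <- classify_effects(s1, gene_models, genome)
  } else {
    stopifnot(all(c("chrom", "pos", "gene_id", "effect") %in%
                    names(annotations)))
    ann <- annotations[key(annotations) %in% key(s1), , drop = FALSE]
  }
  bad <- setdiff(unique(ann$effect), EFFECT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown effect class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[, intersect(c("chrom", "pos", "ref", "alt", "gene_id",
                           "effect", "aa_change", "codon_change",
                           "ems_canonical"), names(ann)), drop = FALSE]
  qual <- ann[!ann$effect %in% c("intergenic", "synonymous"), , drop = FALSE]
  survivors <- s1[key(s1) %in% key(qual), , drop = FALSE]
  variants <- merge(as.data.frame(qual),
                    as.data.frame(survivors[, c("chrom", "pos", "delta")]),
                    by = c("chrom", "pos"), sort = FALSE)
  variants <- tibble::as_tibble(variants[order(variants$chrom,
                                               variants$pos), ,
                                         drop = FALSE])
  attrition <- tibble::tibble(
    step = c("delta_range", "effect_class"),
    removed = c(n0 - nrow(s1), nrow(s1) - nrow(survivors)),
    remaining = c(nrow(s1), nrow(survivors)))
  worklist <- tibble::tibble(
    chrom = survivors$chrom, pos = survivors$pos,
    ref = survivors$ref, alt = survivors$alt,
    flank_start = pmax(1L, as.integer(survivors$pos - flank)),
    flank_end = as.integer(survivors$pos + flank))
  structure(list(variants = variants, attrition = attrition,
                 worklist = worklist, config = config),
            class = "mutmap_screen")
}

#' @export
print.mutmap_screen <- function(x, ...) {
  cat("Candidate-SNP screen: ", nrow(x$worklist), " SNP(s) in ",
      count_candidate_genes(x), " gene(s) survive\n", sep = "")
  print(x$attrition)
  invisible(x)
}

#' Count distinct candidate genes among screened SNPs
#'
#' @param x A `mutmap_screen` result or an annotation data frame with
#'   `gene_id` and `effect` columns.
#' @return Number of distinct gene IDs among non-intergenic annotations.
#' @export
count_candidate_genes <- function(x) {
  if (inherits(x, "mutmap_screen")) x <- x$variants
  ids <- x$gene_id[!is.na(x$gene_id) & x$effect != "intergenic"]
  length(unique(ids))
}

#' Published candidate SNPs for the rice white-belly endosperm mutant
#'
#' The 19 candidate SNPs (in 12 genes on chromosome 4) reported for the
#' rice *wb1* white-belly endosperm mutant mapped with this two-pool
#' design: delta SNP index, position, alleles and effect label as printed,
#' transcribed into this package's effect vocabulary. Useful as a worked
#' example and as a screening-filter fixture; the underlying gene
#' structures are not included, so effects are the published labels, not
#' recomputed ones.
#'
#' @return A tibble with `delta`, `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `effect`, `aa_change`, `gene_annotation`.
#' @export
wb1_candidate_snps <- function() {
  path <- system.file("extdata", "rice_wb1_candidate_snps.tsv",
                      package = "mutmapr", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciccdcccc", progress = FALSE)
}
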