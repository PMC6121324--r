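#' Variant tables with per-pool allelic depths
#'
#' A variant table is a tibble with one row per biallelic SNP and columns
#' `chrom`, `pos` (1-based), `ref`, `alt` (single bases), the per-pool read
#' counts `a_ref`, `a_alt`, `b_ref`, `b_alt` (pool A carries the mutant
#' phenotype, pool B the wild phenotype), and the derived statistics
#' `snp_index_a`, `snp_index_b` and `delta`. Indices are `NA` wherever the
#' pool's total depth is below `min_depth`; `delta` is defined only where
#' both indices are.
#'
#' @param x A data frame with at least the eight raw columns above.
#' @param min_depth Minimum per-pool total depth for a SNP index to be
#'   defined (reads). Default 10.
#' @return A tibble sorted by `(chrom, pos)` with indices computed.
#' @export
as_variant_table <- function(x, min_depth = 10) {
  need <- c("chrom", "pos", "ref", "alt", "a_ref", "a_alt", "b_ref", "b_alt")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(x[need])
  tbl$chrom <- as.character(tbl$chrom)
  tbl$pos <- as.integer(tbl$pos)
  tbl$ref <- toupper(as.character(tbl$ref))
  tbl$alt <- toupper(as.character(tbl$alt))
  for (col in c("a_ref", "a_alt", "b_ref", "b_alt")) {
    tbl[[col]] <- as.integer(tbl[[col]])
    bad <- which(is.na(tbl[[col]]) | tbl[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative or missing read count in column '", col,
           "' at row ", bad[1], call. = FALSE)
    }
  }
  bases <- c("A", "C", "G", "T")
  bad <- which(!(tbl$ref %in% bases) | !(tbl$alt %in% bases) |
                 tbl$ref == tbl$alt)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": ref/alt must be distinct single bases in ",
         "A/C/G/T (got ", tbl$ref[bad[1]], "/", tbl$alt[bad[1]], ")",
         call. = FALSE)
  }
  tbl <- tbl[order(tbl$chrom, tbl$pos, tbl$alt), , drop = FALSE]
  key <- paste(tbl$chrom, tbl$pos, tbl$alt)
  if (anyDuplicated(key) > 0) {
    stop("duplicate variant at ", key[anyDuplicated(key)], call. = FALSE)
  }
  compute_indices(tbl, min_depth = min_depth)
}

#' Compute SNP indices and delta for a variant table
#'
#' @param tbl A variant table (see [as_variant_table()]).
#' @inheritParams as_variant_table
#' @return `tbl` with `snp_index_a`, `snp_index_b` and `delta` (re)computed.
#' @export
compute_indices <- function(tbl, min_depth = 10) {
  stopifnot(min_depth >= 0)
  tot_a <- tbl$a_ref + tbl$a_alt
  tot_b <- tbl$b_ref + tbl$b_alt
  tbl$snp_index_a <- ifelse(tot_a >= pmax(min_depth, 1),
                            tbl$a_alt / tot_a, NA_real_)
  tbl$snp_index_b <- ifelse(tot_b >= pmax(min_depth, 1),
                            tbl$b_alt / tot_b, NA_real_)
  tbl$delta <- tbl$snp_index_a - tbl$snp_index_b
  tbl
}

#' Read pooled allelic depths from a two-sample VCF
#'
#' Retains biallelic SNP records only; indels and multi-allelic records are
#' skipped (a message reports how many). Allelic depths are taken from the
#' per-sample `AD` FORMAT field.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param pool_a_sample,pool_b_sample Sample names of the mutant-phenotype
#'   pool (A) and wild-phenotype pool (B).
#' @inheritParams as_variant_table
#' @return A variant table (see [as_variant_table()]). The number of skipped
#'   records is attached as attribute `"skipped"`, the source path as
#'   attribute `"source"`.
#' @export
read_vcf <- function(path, pool_a_sample, pool_b_sample, min_depth = 10) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(pool_a_sample, pool_b_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not found in ", path, " (samples: ",
           paste(samples, collapse = ", "), ")", call. = FALSE)
    }
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  bases <- c("A", "C", "G", "T")
  keep <- ref %in% bases & alt %in% bases
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip,
            " indel or multi-allelic record(s)")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  parse_ad <- function(x, chrom, pos) {
    missing <- is.na(x) | x == "." | x == ""
    if (any(missing)) {
      i <- which(missing)[1]
      stop("missing AD field at ", chrom[i], ":", pos[i], call. = FALSE)
    }
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1)),
         alt = as.integer(vapply(parts, `[`, "", 2)))
  }
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  ad_a <- parse_ad(ad[keep, pool_a_sample], chrom, pos)
  ad_b <- parse_ad(ad[keep, pool_b_sample], chrom, pos)
  out <- as_variant_table(
    tibble::tibble(chrom = chrom, pos = pos,
                   ref = ref[keep], alt = alt[keep],
                   a_ref = ad_a$ref, a_alt = ad_a$alt,
                   b_ref = ad_b$ref, b_alt = ad_b$alt),
    min_depth = min_depth
  )
  attr(out, "source") <- path
  attr(out, "skipped") <- n_skip
  out
}

#' Read pooled allelic depths from a tab-separated counts table
#'
#' Expects a header with columns `chrom, pos, ref, alt, a_ref, a_alt,
#' b_ref, b_alt` (extra columns, e.g. previously written indices, are
#' ignored and recomputed). Rows are re-sorted by `(chrom, pos)`.
#'
#' @param path Path to a TSV file.
#' @inheritParams as_variant_table
#' @return A variant table (see [as_variant_table()]).
#' @export
read_counts_table <- function(path, min_depth = 10) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "a_ref", "a_alt", "b_ref", "b_alt")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # line number = data row + 1 (header)
  for (col in c("pos", "a_ref", "a_alt", "b_ref", "b_alt")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad) > 0) {
      stop(path, ": line ", bad[1] + 1, ": column '", col,
           "' must be a non-negative integer (got '",
           raw[[col]][bad[1]], "')", call. = FALSE)
    }
  }
  out <- as_variant_table(raw[need], min_depth = min_depth)
  attr(out, "source") <- path
  out
}

#' Write a variant table to TSV
#'
#' Writes all columns, with undefined values (e.g. SNP indices below the
#' depth cutoff) as empty cells, never `.`. The file round-trips through
#' [read_counts_table()].
#'
#' @param table A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  readr::write_tsv(table, path, na = "", progress = FALSE)
  invisible(path)
}
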