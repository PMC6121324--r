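#' Sliding-window scan configuration
#'
#' @param window_size Window width in bp (default 50 kb).
#' @param step_size Walking step in bp (default 10 kb); must not exceed
#'   `window_size`.
#' @param min_snps_per_window Minimum number of SNPs with a defined delta
#'   for a window mean to be reported (default 1; sparser windows are
#'   undefined, never zero, so they cannot suppress a region).
#' @param region_threshold Windowed delta level at or above which windows
#'   enter a candidate region (default 0.5 -- between the unlinked
#'   expectation 0 and the causal expectation 2/3).
#' @param max_gap_windows Number of consecutive *defined* below-threshold
#'   windows tolerated inside one region. Undefined (SNP-free) windows
#'   never interrupt a region. The default, `window_size / step_size`
#'   (one full window width; 5 at the default sizes), lets a region absorb
#'   one noisy sub-threshold SNP cluster rather than fragmenting, since at
#'   realistic pool depths a single SNP's delta estimate is noisy enough
#'   to dip below the threshold inside a genuinely linked region. Set 0
#'   for strict runs.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_size = 50000, step_size = 10000,
                        min_snps_per_window = 1, region_threshold = 0.5,
                        max_gap_windows = NULL) {
  if (is.null(max_gap_windows)) {
    max_gap_windows <- window_size %/% step_size
  }
  stopifnot(window_size > 0, step_size > 0, step_size <= window_size,
            min_snps_per_window >= 1, max_gap_windows >= 0)
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 min_snps_per_window = as.integer(min_snps_per_window),
                 region_threshold = region_threshold,
                 max_gap_windows = as.integer(max_gap_windows)),
            class = "scan_config")
}

#' Read chromosome lengths
#'
#' Accepts a two-column TSV (`name`, `length`) with or without a header,
#' including the first two columns of a FASTA `.fai` index.
#'
#' @param path Path to the file.
#' @return A named integer vector of chromosome lengths, in file order.
#' @export
read_chrom_lengths <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop(path, ": expected at least two columns",
                          call. = FALSE)
  if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) {
    raw <- raw[-1, , drop = FALSE]  # header line
  }
  len <- as.numeric(raw[[2]])
  if (any(is.na(len) | len <= 0)) {
    stop(path, ": chromosome lengths must be positive numbers",
         call. = FALSE)
  }
  stats::setNames(len, raw[[1]])
}

#' Drop fixed parental-versus-reference differences before scanning
#'
#' Aligning both pools to a public reference genome (rather than a parental
#' assembly) makes fixed differences between the parental line and the
#' reference appear at SNP index near 1 in *both* pools. Such SNPs cancel
#' in the delta by construction and carry no linkage information -- a
#' recessive causal SNP cannot exceed index 1/3 in the wild-phenotype pool
#' -- so they only dilute windowed means and fragment candidate regions.
#' This filter removes SNPs whose indices are defined and at least
#' `min_both_index` in both pools; segregating (mutagen-induced) SNPs are
#' untouched.
#'
#' @param table A variant table with computed indices.
#' @param min_both_index Index level above which a SNP in both pools is
#'   treated as a fixed difference (default 0.9).
#' @return The filtered table.
#' @export
drop_fixed_differences <- function(table, min_both_index = 0.9) {
  fixed <- !is.na(table$snp_index_a) & !is.na(table$snp_index_b) &
    table$snp_index_a >= min_both_index &
    table$snp_index_b >= min_both_index
  table[!fixed, , drop = FALSE]
}

normalize_chrom_lengths <- function(chrom_lengths) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths[[2]]),
                                     as.character(chrom_lengths[[1]]))
  }
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0))
  chrom_lengths
}

#' Sliding-window means of the delta SNP index
#'
#' Tiles each chromosome with windows of `window_size` bp anchored at
#' position 1 and advancing by `step_size` bp; window membership is
#' half-open, `start <= pos < end` with `end = start + window_size`. Each
#' window's `mean_delta` is the unweighted mean of the delta SNP index over
#' member SNPs; SNPs with undefined delta contribute to neither the mean
#' nor `n_snps`. Windows with fewer than `min_snps_per_window` usable SNPs
#' have `mean_delta = NA`.
#'
#' @param table A variant table with a `delta` column.
#' @param chrom_lengths Named numeric vector (or two-column data frame) of
#'   chromosome lengths covering every variant; see [read_chrom_lengths()].
#' @param config A [scan_config()].
#' @return A tibble with `chrom`, `start`, `end`, `n_snps`, `mean_delta`,
#'   one row per window, in genome order.
#' @export
sliding_windows <- function(table, chrom_lengths, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  chrom_lengths <- normalize_chrom_lengths(chrom_lengths)
  bad_chrom <- setdiff(unique(table$chrom), names(chrom_lengths))
  if (length(bad_chrom) > 0) {
    stop("no declared length for chromosome(s): ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  beyond <- which(table$pos > chrom_lengths[table$chrom] | table$pos < 1)
  if (length(beyond) > 0) {
    i <- beyond[1]
    stop("variant ", table$chrom[i], ":", table$pos[i],
         " lies beyond the declared chromosome length (",
         chrom_lengths[table$chrom[i]], ")", call. = FALSE)
  }
  w <- config$window_size
  s <- config$step_size
  res <- lapply(names(chrom_lengths), function(cn) {
    n_win <- floor((chrom_lengths[[cn]] - 1) / s) + 1
    starts <- 1 + (seq_len(n_win) - 1) * s
    sub <- table[table$chrom == cn & !is.na(table$delta), , drop = FALSE]
    sums <- numeric(n_win)
    counts <- integer(n_win)
    if (nrow(sub) > 0) {
      # window j (0-based) covers pos iff 1 + j*s <= pos < 1 + j*s + w
      j_last <- pmin((sub$pos - 1) %/% s, n_win - 1)
      j_first <- pmax((sub$pos - w - 1) %/% s + 1, 0)
      n_cover <- j_last - j_first + 1
      win <- rep(j_first, n_cover) + sequence(n_cover) - 1
      val <- rep(sub$delta, n_cover)
      sums <- as.numeric(rowsum(val, win, reorder = TRUE))
      hit <- sort(unique(win))
      counts[hit + 1] <- tabulate(factor(win, levels = hit),
                                  nbins = length(hit))
      full <- numeric(n_win)
      full[hit + 1] <- sums
      sums <- full
    }
    mean_delta <- ifelse(counts >= config$min_snps_per_window,
                         sums / counts, NA_real_)
    tibble::tibble(chrom = cn, start = as.integer(starts),
                   end = as.integer(starts + w), n_snps = counts,
                   mean_delta = mean_delta)
  })
  do.call(rbind, res)
}

#' Call candidate regions from windowed delta values
#'
#' A candidate region is a maximal run of defined windows with
#' `mean_delta >= region_threshold` on one chromosome. Undefined (SNP-free)
#' windows are transparent: they never interrupt a run. Up to
#' `max_gap_windows` consecutive defined below-threshold windows are
#' tolerated inside a run. Regions are returned sorted by their peak
#' windowed delta, descending.
#'
#' @param windows Output of [sliding_windows()].
#' @param config The [scan_config()] used for the scan.
#' @param table Optional variant table used to count the SNPs contained in
#'   each region span; without it `n_snps` is `NA`.
#' @return A tibble with `chrom`, `start`, `end`, `peak_start`, `peak_end`,
#'   `peak_delta`, `n_windows` and `n_snps`.
#' @export
call_candidate_regions <- function(windows, config = scan_config(),
                                   table = NULL) {
  stopifnot(inherits(config, "scan_config"))
  out <- list()
  for (cn in unique(windows$chrom)) {
    wc <- windows[windows$chrom == cn & !is.na(windows$mean_delta), ,
                  drop = FALSE]
    if (nrow(wc) == 0) next
    qual <- wc$mean_delta >= config$region_threshold
    if (!any(qual)) next
    qi <- which(qual)
    # split where more than max_gap_windows defined windows fail in between
    breaks <- c(0, cumsum(diff(qi) - 1 > config$max_gap_windows))
    for (grp in split(qi, breaks)) {
      members <- wc[grp, , drop = FALSE]
      peak <- which.max(members$mean_delta)
      span_start <- members$start[1]
      span_end <- members$end[nrow(members)]
      n_snps <- if (is.null(table)) {
        NA_integer_
      } else {
        sum(table$chrom == cn & table$pos >= span_start &
              table$pos < span_end)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = cn, start = span_start, end = span_end,
        peak_start = members$start[peak], peak_end = members$end[peak],
        peak_delta = members$mean_delta[peak],
        n_windows = length(grp), n_snps = n_snps)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), peak_start = integer(),
                          peak_end = integer(), peak_delta = numeric(),
                          n_windows = integer(), n_snps = integer()))
  }
  res <- do.call(rbind, out)
  res[order(-res$peak_delta), , drop = FALSE]
}

#' Genome-cumulative coordinates for a Manhattan plot
#'
#' One row per defined window with a cumulative x-coordinate (`cum_pos`,
#' the window midpoint offset by the total length of preceding
#' chromosomes), ready for plotting or export.
#'
#' @param windows Output of [sliding_windows()].
#' @param chrom_lengths Optional chromosome lengths used for the offsets
#'   (recommended); without them each chromosome's extent is taken from its
#'   last window end.
#' @return A tibble with `chrom`, `start`, `end`, `n_snps`, `mean_delta`,
#'   `cum_pos`.
#' @export
manhattan_table <- function(windows, chrom_lengths = NULL) {
  chroms <- unique(windows$chrom)
  if (is.null(chrom_lengths)) {
    lens <- vapply(chroms, function(cn) {
      max(windows$end[windows$chrom == cn]) - 1
    }, numeric(1))
  } else {
    chrom_lengths <- normalize_chrom_lengths(chrom_lengths)
    chroms <- intersect(names(chrom_lengths), chroms)
    lens <- chrom_lengths[chroms]
  }
  offsets <- stats::setNames(cumsum(c(0, lens[-length(lens)])), chroms)
  def <- windows[!is.na(windows$mean_delta) & windows$chrom %in% chroms, ,
                 drop = FALSE]
  def$cum_pos <- unname(offsets[def$chrom]) + (def$start + def$end - 1) / 2
  tibble::as_tibble(def)
}

#' Plot the windowed delta SNP index along the genome
#'
#' Convenience Manhattan plot of [manhattan_table()] output; requires
#' ggplot2.
#'
#' @inheritParams manhattan_table
#' @param threshold Optional horizontal reference line (e.g. the region
#'   threshold).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(windows, chrom_lengths = NULL, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_manhattan() requires the ggplot2 package", call. = FALSE)
  }
  mt <- manhattan_table(windows, chrom_lengths)
  p <- ggplot2::ggplot(mt, ggplot2::aes(
    x = cum_pos, y = mean_delta, colour = chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position (bp, cumulative)",
                  y = "windowed delta SNP index") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}
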