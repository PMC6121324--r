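IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Built-in restriction enzyme registry
#'
#' A small registry of enzymes usable for CAPS (cleaved amplified
#' polymorphic sequence) genotyping. Sites are IUPAC degenerate strings;
#' `cut_offset` is the number of site bases 5' of the top-strand cut (HaeII
#' RGCGC^Y cuts after the fifth base).
#'
#' @return A tibble with `enzyme`, `site`, `cut_offset`.
#' @export
restriction_enzymes <- function() {
  tibble::tribble(
    ~enzyme,   ~site,     ~cut_offset,
    "HaeII",   "RGCGCY",  5L,
    "HaeIII",  "GGCC",    2L,
    "EcoRI",   "GAATTC",  1L,
    "HindIII", "AAGCTT",  1L,
    "TaqI",    "TCGA",    1L,
    "AluI",    "AGCT",    2L
  )
}

#' Resolve a recognition site
#'
#' @param site An enzyme name from [restriction_enzymes()], a degenerate
#'   site string, or a list with `site` and optionally `enzyme`,
#'   `cut_offset`.
#' @param cut_offset Optional override of the cut position.
#' @return A `recognition_site` list with `enzyme`, `site`, `cut_offset`.
#' @export
recognition_site <- function(site, cut_offset = NULL) {
  reg <- restriction_enzymes()
  if (inherits(site, "recognition_site")) {
    out <- unclass(site)
  } else if (is.list(site)) {
    out <- list(enzyme = if (is.null(site$enzyme)) NA_character_
                         else site$enzyme,
                site = toupper(site$site),
                cut_offset = site$cut_offset)
  } else if (site %in% reg$enzyme) {
    i <- match(site, reg$enzyme)
    out <- list(enzyme = reg$enzyme[i], site = reg$site[i],
                cut_offset = reg$cut_offset[i])
  } else if (all(strsplit(toupper(site), "")[[1]] %in% IUPAC_LETTERS)) {
    out <- list(enzyme = NA_character_, site = toupper(site),
                cut_offset = NULL)
  } else {
    stop("unknown enzyme or invalid site '", site, "'; registered enzymes: ",
         paste(reg$enzyme, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cut_offset)) out$cut_offset <- as.integer(cut_offset)
  bad <- setdiff(strsplit(out$site, "")[[1]], IUPAC_LETTERS)
  if (length(bad) > 0) {
    stop("non-IUPAC character(s) in recognition site: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(out$cut_offset) &&
      (out$cut_offset < 0 || out$cut_offset > nchar(out$site))) {
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  }
  structure(out, class = "recognition_site")
}

#' Find recognition-site matches in a sequence
#'
#' Matches a degenerate (IUPAC) recognition site on the forward strand;
#' non-palindromic sites are additionally scanned as their reverse
#' complement, so every double-stranded occurrence is reported by its
#' forward-strand start. Matching is case-insensitive; `N` in the sequence
#' never matches a degenerate code.
#'
#' @param sequence A DNA string over A/C/G/T (possibly with N).
#' @param site An enzyme name, site string, or [recognition_site()].
#' @return Sorted integer vector of 1-based match start positions.
#' @export
#' @examples
#' find_sites("TTAGCGCCTT", "HaeII")  # 3 (AGCGCC: R=A, Y=C)
find_sites <- function(sequence, site) {
  site <- recognition_site(site)
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(site$site)) return(integer(0))
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(site$site)
  # fixed = "subject": degenerate codes in the pattern act as wildcards,
  # while N in the subject stays literal and matches nothing degenerate
  hits <- Biostrings::start(
    Biostrings::matchPattern(pat, subj, fixed = "subject"))
  rc <- Biostrings::reverseComplement(pat)
  if (as.character(rc) != as.character(pat)) {
    hits <- c(hits, Biostrings::start(
      Biostrings::matchPattern(rc, subj, fixed = "subject")))
  }
  sort(unique(as.integer(hits)))
}

#' Classify the CAPS consequence of a SNP
#'
#' Compares recognition-site matches overlapping the SNP between the
#' reference amplicon and the alternate-substituted amplicon: a marker is
#' informative when the substitution destroys (`site_lost`) or creates
#' (`site_gained`) a site, so that digestion distinguishes the alleles on a
#' gel.
#'
#' @param amplicon Amplicon sequence (e.g. a PCR product around the SNP).
#' @param snp_offset 1-based position of the SNP within `amplicon`.
#' @param ref_base,alt_base The two alleles; `amplicon` must carry
#'   `ref_base` at `snp_offset`.
#' @param site An enzyme name, site string, or [recognition_site()].
#' @return `"site_lost"`, `"site_gained"` or `"no_change"`.
#' @export
caps_check <- function(amplicon, snp_offset, ref_base, alt_base, site) {
  site <- recognition_site(site)
  amplicon <- toupper(amplicon)
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  stopifnot(snp_offset >= 1, snp_offset <= nchar(amplicon))
  if (substr(amplicon, snp_offset, snp_offset) != ref_base) {
    stop("amplicon has ", substr(amplicon, snp_offset, snp_offset),
         " at offset ", snp_offset, ", not the stated reference base ",
         ref_base, call. = FALSE)
  }
  alt_amplicon <- amplicon
  substr(alt_amplicon, snp_offset, snp_offset) <- alt_base
  len <- nchar(site$site)
  overlapping <- function(starts) {
    sum(starts <= snp_offset & snp_offset <= starts + len - 1)
  }
  n_ref <- overlapping(find_sites(amplicon, site))
  n_alt <- overlapping(find_sites(alt_amplicon, site))
  if (n_alt < n_ref) "site_lost"
  else if (n_alt > n_ref) "site_gained"
  else "no_change"
}

#' Predict digestion fragment lengths
#'
#' Cuts the amplicon at every recognition-site match (top-strand cut after
#' `cut_offset` site bases) and returns the fragment lengths in order along
#' the amplicon. Lengths always sum to the amplicon length; an uncut
#' amplicon yields a single fragment.
#'
#' @inheritParams caps_check
#' @param cut_offset Optional override of the enzyme's cut position within
#'   the site (bases 5' of the cut on the forward strand).
#' @return Integer vector of fragment lengths.
#' @export
#' @examples
#' fragment_lengths(strrep("A", 337), "HaeII")  # uncut: 337
fragment_lengths <- function(amplicon, site, cut_offset = NULL) {
  site <- recognition_site(site, cut_offset = cut_offset)
  if (is.null(site$cut_offset)) {
    stop("no cut_offset known for this site; supply one", call. = FALSE)
  }
  amplicon <- toupper(amplicon)
  len <- nchar(amplicon)
  starts <- find_sites(amplicon, site)
  cuts <- starts + site$cut_offset - 1
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < len]))
  frags <- diff(c(0L, cuts, len))
  as.integer(frags[frags > 0])
}
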