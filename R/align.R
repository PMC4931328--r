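revcomp_many <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

#' Unique best-stratum alignment of short reads
#'
#' Scans every position of every contig, both strands, for matches with at
#' most `max_mismatch` substitutions (no indels). Hits are stratified by
#' mismatch count (stratum 0 = exact, stratum 1 = one mismatch, ...); a
#' read is accepted only if its best non-empty stratum contains exactly one
#' hit, otherwise it is reported as a multimapper (or unmapped when no
#' stratum is populated). This emulates best-stratum unique mapping with
#' one allowed mismatch on toy-scale references.
#'
#' With `bisulfite = TRUE`, matching is performed on three-letter collapsed
#' sequences for directional (transcript-strand) bisulfite reads: read and
#' forward reference are collapsed C->T, and for minus-strand placement the
#' reverse-complemented read and the reference are collapsed G->A. Reported
#' coordinates refer to the original reference.
#'
#' @param reads Character vector of read sequences.
#' @param genome A `Genome`.
#' @param max_mismatch Maximum substitutions per hit.
#' @param bisulfite Use three-letter collapsed matching.
#' @return A data frame, one row per read: `read`, `status`
#'   (`aligned`/`multimapper`/`unmapped`), `contig`, `strand`, `start0`
#'   (0-based leftmost genomic position), `first_aligned_pos` (0-based
#'   genomic position of the read's 5'-most base in transcript sense),
#'   `width` and `mismatches`.
#' @export
align_unique <- function(reads, genome, max_mismatch = 1L,
                         bisulfite = FALSE) {
  stopifnot(inherits(genome, "Genome"))
  n <- length(reads)
  uniq <- unique(reads)
  q_fwd <- uniq
  q_rev <- revcomp_many(uniq)
  if (bisulfite) {
    q_fwd <- chartr("C", "T", q_fwd)
    q_rev <- chartr("G", "A", q_rev)
  }
  scans <- list()
  for (ct in names(genome)) {
    subj <- genome[[ct]]
    s_fwd <- if (bisulfite) chartr("C", "T", subj) else subj
    s_rev <- if (bisulfite) chartr("G", "A", subj) else subj
    scans[[paste0(ct, "|+")]] <- .scan_best_stratum(s_fwd, q_fwd,
                                                    max_mismatch)
    scans[[paste0(ct, "|-")]] <- .scan_best_stratum(s_rev, q_rev,
                                                    max_mismatch)
  }
  nu <- length(uniq)
  best_mm <- rep(NA_integer_, nu)
  for (sc in scans) {
    has <- sc$n_best > 0L
    best_mm[has] <- pmin(best_mm[has], sc$best_mm[has], na.rm = TRUE)
  }
  n_at_best <- integer(nu)
  pick_scan <- rep(NA_integer_, nu)
  for (k in seq_along(scans)) {
    sc <- scans[[k]]
    at <- sc$n_best > 0L & !is.na(best_mm) & sc$best_mm == best_mm
    n_at_best[at] <- n_at_best[at] + sc$n_best[at]
    pick_scan[at & is.na(pick_scan)] <- k
  }
  status <- ifelse(is.na(best_mm), "unmapped",
                   ifelse(n_at_best == 1L, "aligned", "multimapper"))
  contig <- strand <- rep(NA_character_, nu)
  start0 <- fap <- rep(NA_integer_, nu)
  ok <- which(status == "aligned")
  if (length(ok)) {
    keys <- strsplit(names(scans)[pick_scan[ok]], "|", fixed = TRUE)
    contig[ok] <- vapply(keys, `[`, "", 1L)
    strand[ok] <- vapply(keys, `[`, "", 2L)
    start0[ok] <- vapply(seq_along(ok), function(j) {
      scans[[pick_scan[ok[j]]]]$best_pos[ok[j]]
    }, integer(1))
    w <- nchar(uniq[ok])
    fap[ok] <- ifelse(strand[ok] == "+", start0[ok], start0[ok] + w - 1L)
  }
  udf <- data.frame(read = uniq, status = status, contig = contig,
                    strand = strand, start0 = start0,
                    first_aligned_pos = fap, width = nchar(uniq),
                    mismatches = best_mm, stringsAsFactors = FALSE)
  udf[match(reads, uniq), , drop = FALSE]
}
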