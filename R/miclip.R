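#' Parse the split-UMI barcode layout of raw miCLIP reads
#'
#' The reverse-transcription primer places a six-nucleotide random barcode
#' (UMI) at read positions 1-3 and 8-10 around a four-nucleotide sample
#' barcode at positions 4-7 (1-based); the insert starts at position 11.
#' Reads shorter than 10 nt cannot be parsed and are discarded (counted).
#'
#' @param reads Character vector of raw read sequences.
#' @return A list: `parsed` (data frame with `umi`, `sample_barcode`,
#'   `insert`) and `n_short` (number of discarded reads).
#' @export
parse_barcode <- function(reads) {
  ok <- nchar(reads) >= 10L
  r <- reads[ok]
  parsed <- data.frame(
    umi = paste0(substr(r, 1L, 3L), substr(r, 8L, 10L)),
    sample_barcode = substr(r, 4L, 7L),
    insert = substr(r, 11L, nchar(r)),
    stringsAsFactors = FALSE)
  list(parsed = parsed, n_short = sum(!ok))
}

#' Demultiplex on the sample barcode and collapse PCR duplicates
#'
#' Retains reads whose sample barcode matches `expected_barcode` exactly,
#' then collapses PCR duplicates: reads with identical insert and identical
#' UMI represent the same PCR product, so each unique insert is assigned a
#' cDNA count equal to the number of distinct UMIs observed with it.
#'
#' @param parsed Data frame from [parse_barcode()].
#' @param expected_barcode 4-nt sample barcode of the library.
#' @return A list: `cdna` (data frame with `insert`, `cdna_count`),
#'   `n_matched`, `n_mismatched`.
#' @export
demultiplex_and_dedup <- function(parsed, expected_barcode) {
  keep <- parsed$sample_barcode == expected_barcode
  p <- parsed[keep, , drop = FALSE]
  if (nrow(p) == 0L) {
    cdna <- data.frame(insert = character(), cdna_count = integer(),
                       stringsAsFactors = FALSE)
  } else {
    pairs <- unique(p[c("insert", "umi")])
    tab <- table(pairs$insert)
    cdna <- data.frame(insert = names(tab),
                       cdna_count = as.integer(tab),
                       stringsAsFactors = FALSE)
  }
  list(cdna = cdna, n_matched = sum(keep), n_mismatched = sum(!keep))
}

count_suffix_mismatches <- function(insert, adapter, k) {
  a <- substr(insert, nchar(insert) - k + 1L, nchar(insert))
  b <- substr(adapter, 1L, k)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Trim 3' adapter read-through from inserts
#'
#' Removes the longest insert suffix that matches a prefix of the adapter
#' with at least `min_overlap` bases and at most
#' `floor(max_error_rate * overlap)` mismatches (substitutions only, no
#' indels). If no suffix qualifies the insert is returned unchanged.
#'
#' @param inserts Character vector of insert sequences.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum matched bases.
#' @param max_error_rate Mismatch budget per matched base.
#' @return Character vector of trimmed inserts.
#' @export
trim_adapter <- function(inserts, adapter = "AGATCGGAAGAGCGGTTCAG",
                         min_overlap = 4L, max_error_rate = 0.06) {
  stopifnot(nzchar(adapter))
  vapply(inserts, function(ins) {
    kmax <- min(nchar(ins), nchar(adapter))
    for (k in rev(seq_len(kmax))) {
      if (k < min_overlap) break
      mm <- count_suffix_mismatches(ins, adapter, k)
      if (mm <= floor(max_error_rate * k)) {
        return(substr(ins, 1L, nchar(ins) - k))
      }
    }
    ins
  }, character(1), USE.NAMES = FALSE)
}

#' Drop cDNA records with short inserts
#'
#' @param records cDNA record data frame (`insert`, `cdna_count`).
#' @param min_len Minimum retained insert length (nt).
#' @return A list: `records` (filtered) and `n_dropped`.
#' @export
length_filter <- function(records, min_len = 18L) {
  keep <- nchar(records$insert) >= min_len
  list(records = records[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Assign aligned truncation positions to cytosines
#'
#' The reverse transcriptase stalls at the crosslink adduct, leaving the
#' read to start one base 3' of the modified cytosine; the stall position
#' is therefore one base 5' (transcript sense) of the read's first aligned
#' base. Each stall is assigned to the nearest transcript-sense cytosine
#' within +/-2 nt; equidistant candidates are resolved towards the 5' side
#' (the side the adduct biases). Stalls with no cytosine in the window are
#' left unassigned.
#'
#' @param alignments Data frame from [align_unique()] (aligned rows only
#'   are used).
#' @param genome A `Genome`.
#' @param window Search half-width around the stall (nt).
#' @return The alignment data frame with added columns `site0` (0-based
#'   genomic coordinate of the assigned cytosine, transcript sense) and
#'   `assigned`.
#' @export
assign_truncation <- function(alignments, genome, window = 2L) {
  al <- alignments
  al$site0 <- NA_integer_
  al$assigned <- FALSE
  rows <- which(al$status == "aligned")
  for (i in rows) {
    ct <- al$contig[i]
    len <- nchar(genome[[ct]])
    plus <- al$strand[i] == "+"
    stall0 <- if (plus) al$first_aligned_pos[i] - 1L else
      al$first_aligned_pos[i] + 1L
    cand0 <- stall0 + seq(-window, window)
    cand0 <- cand0[cand0 >= 0L & cand0 < len]
    if (length(cand0) == 0L) next
    base <- substring(genome[[ct]], cand0 + 1L, cand0 + 1L)
    want <- if (plus) "C" else "G"  # transcript-sense cytosine
    cand0 <- cand0[base == want]
    if (length(cand0) == 0L) next
    d <- cand0 - stall0
    # 5' side in transcript sense: lower coordinate on +, higher on -
    ord <- order(abs(d), if (plus) d else -d)
    al$site0[i] <- cand0[ord[1L]]
    al$assigned[i] <- TRUE
  }
  al
}

aggregate_sites <- function(assigned, counts) {
  df <- data.frame(contig = assigned$contig, strand = assigned$strand,
                   site0 = assigned$site0, cdna_count = counts,
                   stringsAsFactors = FALSE)
  stats::aggregate(cdna_count ~ contig + strand + site0, data = df,
                   FUN = sum)
}

annotate_positions <- function(contig, pos0, strand, annotations) {
  if (nrow(annotations) == 0L) return(rep(NA_character_, length(pos0)))
  sites <- GenomicRanges::GRanges(contig,
                                  IRanges::IRanges(pos0 + 1L, pos0 + 1L),
                                  strand = strand)
  genes <- GenomicRanges::GRanges(annotations$contig,
                                  IRanges::IRanges(annotations$start + 1L,
                                                   annotations$end),
                                  strand = annotations$strand)
  hits <- GenomicRanges::findOverlaps(sites, genes)
  out <- rep(NA_character_, length(pos0))
  out[S4Vectors::queryHits(hits)] <-
    annotations$gene_id[S4Vectors::subjectHits(hits)]
  out
}

#' Build the per-cytosine miCLIP site table across replicates
#'
#' Computes per-replicate cDNA counts and RPM (cDNA counts per million
#' uniquely mapped cDNA counts of that replicate) for every observed site,
#' and flags high-confidence sites: RPM strictly above `threshold_rpm` in
#' at least `min_replicates` replicates.
#'
#' @param replicate_sites List (one element per replicate) of data frames
#'   with `contig`, `strand`, `site0`, `cdna_count`.
#' @param totals Integer vector of per-replicate uniquely mapped cDNA
#'   totals (RPM denominators); defaults to each replicate's summed site
#'   counts.
#' @param annotations Optional annotation data frame for gene labelling.
#' @param threshold_rpm RPM threshold (strict `>`).
#' @param min_replicates Replicates required above threshold.
#' @return A `MiclipSiteTable` data frame: `contig`, `position` (1-based),
#'   `strand`, `gene_id`, `count_rep*`, `rpm_rep*`, `n_replicates_passing`,
#'   `high_confidence`.
#' @export
build_site_table <- function(replicate_sites, totals = NULL,
                             annotations = NULL, threshold_rpm = 50,
                             min_replicates = 2L) {
  nrep <- length(replicate_sites)
  if (min_replicates > nrep) {
    stop("min_replicates exceeds the number of replicates")
  }
  if (is.null(totals)) {
    totals <- vapply(replicate_sites, function(x) sum(x$cdna_count), 0)
  }
  stopifnot(length(totals) == nrep, all(totals > 0))
  keys <- unique(do.call(rbind, lapply(replicate_sites, function(x) {
    x[c("contig", "strand", "site0")]
  })))
  keys <- keys[order(keys$contig, keys$site0), , drop = FALSE]
  tab <- data.frame(contig = keys$contig, position = keys$site0 + 1L,
                    strand = keys$strand, stringsAsFactors = FALSE)
  key_id <- paste(keys$contig, keys$strand, keys$site0)
  rpm_mat <- matrix(0, nrow = nrow(keys), ncol = nrep)
  for (r in seq_len(nrep)) {
    x <- replicate_sites[[r]]
    idx <- match(paste(x$contig, x$strand, x$site0), key_id)
    cnt <- integer(nrow(keys))
    cnt[idx] <- x$cdna_count
    tab[[paste0("count_rep", r)]] <- cnt
    rpm <- cnt / totals[r] * 1e6
    rpm_mat[, r] <- rpm
    tab[[paste0("rpm_rep", r)]] <- rpm
  }
  tab$n_replicates_passing <- rowSums(rpm_mat > threshold_rpm)
  tab$high_confidence <- tab$n_replicates_passing >= min_replicates
  tab$gene_id <- if (!is.null(annotations)) {
    annotate_positions(tab$contig, tab$position - 1L, tab$strand,
                       annotations)
  } else NA_character_
  class(tab) <- c("MiclipSiteTable", class(tab))
  tab
}

#' Per-gene composition of miCLIP cDNA counts
#'
#' Sums cDNA counts (across replicates) per annotated gene and reports each
#' gene's share of all counts mapped to the given contigs, plus its share
#' among tRNA-biotype loci.
#'
#' @param site_table A `MiclipSiteTable`.
#' @param annotations Annotation data frame.
#' @param contigs Contigs to include (default: all in the table).
#' @return Data frame: `gene_id`, `biotype`, `cdna_count`, `share_mapped`,
#'   `share_trna` (NA for non-tRNA genes).
#' @export
composition_report <- function(site_table, annotations, contigs = NULL) {
  tab <- site_table
  if (!is.null(contigs)) tab <- tab[tab$contig %in% contigs, , drop = FALSE]
  cnt_cols <- grep("^count_rep", names(tab), value = TRUE)
  tab$total_count <- rowSums(tab[, cnt_cols, drop = FALSE])
  total_mapped <- sum(tab$total_count)
  if (total_mapped == 0) stop("no mapped cDNA counts in site table")
  annotated <- tab[!is.na(tab$gene_id), , drop = FALSE]
  per_gene <- stats::aggregate(total_count ~ gene_id, data = annotated,
                               FUN = sum)
  per_gene$biotype <- annotations$biotype[match(per_gene$gene_id,
                                                annotations$gene_id)]
  per_gene$share_mapped <- per_gene$total_count / total_mapped
  trna_total <- sum(per_gene$total_count[per_gene$biotype == "tRNA"])
  per_gene$share_trna <- ifelse(per_gene$biotype == "tRNA",
                                per_gene$total_count / trna_total, NA)
  names(per_gene)[names(per_gene) == "total_count"] <- "cdna_count"
  per_gene[order(-per_gene$cdna_count), , drop = FALSE]
}

#' Run the full miCLIP site-calling pipeline
#'
#' Barcode parsing, demultiplexing, PCR deduplication, adapter trimming,
#' length filtering, unique best-stratum alignment, truncation-to-cytosine
#' assignment and site-table construction, for one or more replicate FASTQ
#' files.
#'
#' @param fastq_paths Character vector, one FASTQ per replicate.
#' @param bundle A `ReferenceBundle`.
#' @param barcode 4-nt sample barcode.
#' @param adapter 3' adapter sequence.
#' @param min_len Minimum insert length after trimming.
#' @param max_mismatch Mismatches allowed in alignment.
#' @param window Truncation-to-cytosine search half-width (nt).
#' @param threshold_rpm RPM threshold for high confidence (strict `>`).
#' @param min_replicates Replicates required above threshold.
#' @return A list: `site_table`, `composition`, `counters` (per-replicate
#'   conservation counters), `replicate_sites`, `totals`.
#' @export
miclip_call <- function(fastq_paths, bundle, barcode,
                        adapter = "AGATCGGAAGAGCGGTTCAG", min_len = 18L,
                        max_mismatch = 1L, window = 2L, threshold_rpm = 50,
                        min_replicates = 2L) {
  replicate_sites <- list()
  counters <- list()
  totals <- numeric(length(fastq_paths))
  for (r in seq_along(fastq_paths)) {
    reads <- read_fastq(fastq_paths[r])
    pb <- parse_barcode(reads)
    dd <- demultiplex_and_dedup(pb$parsed, barcode)
    cdna <- dd$cdna
    cdna$insert <- trim_adapter(cdna$insert, adapter)
    # merge records whose inserts coincide after trimming
    cdna <- stats::aggregate(cdna_count ~ insert, data = cdna, FUN = sum)
    lf <- length_filter(cdna, min_len)
    cdna <- lf$records
    al <- align_unique(cdna$insert, bundle$genome, max_mismatch)
    al$cdna_count <- cdna$cdna_count
    aligned <- al[al$status == "aligned", , drop = FALSE]
    asg <- assign_truncation(aligned, bundle$genome, window)
    ok <- asg$assigned
    replicate_sites[[r]] <- aggregate_sites(asg[ok, , drop = FALSE],
                                            asg$cdna_count[ok])
    totals[r] <- sum(aligned$cdna_count)
    counters[[r]] <- c(
      n_raw = length(reads), n_short = pb$n_short,
      n_barcode_matched = dd$n_matched,
      n_barcode_mismatched = dd$n_mismatched,
      n_records = nrow(al) + lf$n_dropped,
      n_dropped_short_insert = lf$n_dropped,
      n_aligned = sum(al$status == "aligned"),
      n_multimapper = sum(al$status == "multimapper"),
      n_unmapped = sum(al$status == "unmapped"),
      n_assigned = sum(ok), n_unassigned = sum(!ok),
      total_unique_cdna = totals[r])
  }
  site_table <- build_site_table(replicate_sites, totals,
                                 bundle$annotations, threshold_rpm,
                                 min_replicates)
  composition <- composition_report(site_table, bundle$annotations)
  list(site_table = site_table, composition = composition,
       counters = counters, replicate_sites = replicate_sites,
       totals = totals)
}

#' Write high-confidence miCLIP sites as BED6
#'
#' @param site_table A `MiclipSiteTable`.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_sites_bed <- function(site_table, path) {
  hc <- site_table[site_table$high_confidence, , drop = FALSE]
  cnt_cols <- grep("^count_rep", names(hc), value = TRUE)
  bed <- data.frame(hc$contig, hc$position - 1L, hc$position,
                    ifelse(is.na(hc$gene_id), ".", hc$gene_id),
                    rowSums(hc[, cnt_cols, drop = FALSE]), hc$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
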