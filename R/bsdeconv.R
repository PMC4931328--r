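CHEMISTRIES <- c("BS", "RedBS", "fCAB")

# Assign aligned reads to the gene whose annotated interval contains the
# aligned span on the matching strand; NA when none does.
assign_gene <- function(alignments, annotations) {
  gene <- rep(NA_character_, nrow(alignments))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    hit <- !is.na(alignments$start0) &
      alignments$contig == a$contig & alignments$strand == a$strand &
      alignments$start0 >= a$start &
      alignments$start0 + alignments$width <= a$end
    gene[hit] <- a$gene_id
  }
  gene
}

#' Per-read conversion matrix for one gene
#'
#' Builds the read-by-cytosine matrix underlying bisulfite heatmaps: one
#' row per aligned read of the gene (input order preserved), one column per
#' transcript-sense reference cytosine, entries `unconverted` (read base
#' C), `converted` (read base T), `other` or `missing` (column not covered
#' by the read).
#'
#' @param alignments Data frame from [align_unique()] with a `gene`
#'   column (see [bs_call()]), or aligned reads of a single gene.
#' @param bundle A `ReferenceBundle`.
#' @param gene_id Gene to tabulate.
#' @return A `ReadMatrix`: character matrix with column names
#'   `c<seq_index>` (0-based positions of the reference cytosines).
#' @export
read_matrix <- function(alignments, bundle, gene_id) {
  ann <- get_annotation(bundle, gene_id)
  gseq <- strsplit(gene_sequence(bundle, gene_id), "")[[1]]
  ccols <- which(gseq == "C") - 1L  # 0-based transcript indices
  al <- alignments
  if (!is.null(al$gene)) al <- al[!is.na(al$gene) & al$gene == gene_id, ,
                                  drop = FALSE]
  m <- matrix("missing", nrow = nrow(al), ncol = length(ccols),
              dimnames = list(NULL, paste0("c", ccols)))
  if (nrow(al)) {
    i0 <- genomic_to_gene(ann, al$first_aligned_pos + 1L)
    for (r in seq_len(nrow(al))) {
      covered <- ccols >= i0[r] & ccols < i0[r] + al$width[r]
      if (!any(covered)) next
      pos_in_read <- ccols[covered] - i0[r] + 1L
      base <- substring(al$read[r], pos_in_read, pos_in_read)
      m[r, covered] <- ifelse(base == "C", "unconverted",
                              ifelse(base == "T", "converted", "other"))
    }
  }
  structure(m, class = c("ReadMatrix", class(m)), gene_id = gene_id)
}

#' Per-cytosine conversion pileup
#'
#' Counts, for every transcript-sense reference cytosine of every gene with
#' aligned reads, the coverage and the number of unconverted (C), converted
#' (T) and other read bases. With `dedup_mode = "with"`, reads identical in
#' both start position and sequence are collapsed to one before counting —
#' the PCR-duplicate heuristic for fragments shorter than the read length.
#'
#' @param alignments Data frame from [align_unique()] with a `gene` column.
#' @param bundle A `ReferenceBundle`.
#' @param chemistry Chemistry label stored with the pileup.
#' @param dedup_mode `"without"` (default) or `"with"`.
#' @return A `ConversionPileup` data frame: `gene_id`, `seq_index`,
#'   `coverage`, `n_unconverted`, `n_converted`, `n_other`, `chemistry`,
#'   `dedup_mode`.
#' @export
pileup <- function(alignments, bundle, chemistry = "BS",
                   dedup_mode = c("without", "with")) {
  dedup_mode <- match.arg(dedup_mode)
  al <- alignments[!is.na(alignments$gene), , drop = FALSE]
  if (dedup_mode == "with") {
    al <- al[!duplicated(al[c("contig", "start0", "read")]), , drop = FALSE]
  }
  out <- list()
  for (g in unique(al$gene)) {
    m <- read_matrix(al, bundle, g)
    if (ncol(m) == 0L) next
    ccols <- as.integer(sub("^c", "", colnames(m)))
    un <- colSums(m == "unconverted")
    cv <- colSums(m == "converted")
    ot <- colSums(m == "other")
    out[[g]] <- data.frame(gene_id = g, seq_index = ccols,
                           coverage = un + cv + ot, n_unconverted = un,
                           n_converted = cv, n_other = ot,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), seq_index = integer(),
               coverage = integer(), n_unconverted = integer(),
               n_converted = integer(), n_other = integer(),
               stringsAsFactors = FALSE)
  res$chemistry <- chemistry
  res$dedup_mode <- dedup_mode
  rownames(res) <- NULL
  class(res) <- c("ConversionPileup", class(res))
  res
}

#' Methylation (non-conversion) levels from a pileup
#'
#' The level at a cytosine is the unconverted fraction
#' `n_unconverted / (n_unconverted + n_converted)`; bases other than C/T
#' are treated as sequencing error and excluded from the denominator.
#' Cytosines covered by fewer than `min_coverage` reads are reported with a
#' missing level.
#'
#' @param pileup A `ConversionPileup`.
#' @param min_coverage Minimum coverage for a reported level.
#' @return The pileup data frame with an added `level` column (NA below
#'   coverage).
#' @export
methylation_level <- function(pileup, min_coverage = 5L) {
  denom <- pileup$n_unconverted + pileup$n_converted
  lvl <- ifelse(denom > 0, pileup$n_unconverted / denom, NA_real_)
  lvl[pileup$coverage < min_coverage] <- NA_real_
  out <- pileup
  out$level <- lvl
  out
}

#' Conversion calling for one bisulfite-family FASTQ
#'
#' Reads a directional bisulfite-family library, aligns it with
#' three-letter collapsed unique best-stratum matching, assigns reads to
#' genes, and returns conversion pileups and per-cytosine levels.
#'
#' @param fastq FASTQ path.
#' @param bundle A `ReferenceBundle`.
#' @param chemistry Chemistry label (`BS`, `RedBS` or `fCAB`).
#' @param dedup_mode `"without"` or `"with"` PCR-duplicate removal.
#' @param min_coverage Minimum coverage for a reported level.
#' @param max_mismatch Mismatches allowed in alignment.
#' @return A list: `levels` (pileup + `level`), `pileup`, `aligned`
#'   (alignment data frame with `gene`), `counters`.
#' @export
bs_call <- function(fastq, bundle, chemistry = "BS",
                    dedup_mode = c("without", "with"), min_coverage = 5L,
                    max_mismatch = 1L) {
  dedup_mode <- match.arg(dedup_mode)
  stopifnot(chemistry %in% CHEMISTRIES)
  reads <- read_fastq(fastq)
  al <- align_unique(unname(reads), bundle$genome, max_mismatch,
                     bisulfite = TRUE)
  al$gene <- NA_character_
  aligned <- al$status == "aligned"
  al$gene[aligned] <- assign_gene(al[aligned, , drop = FALSE],
                                  bundle$annotations)
  pu <- pileup(al, bundle, chemistry, dedup_mode)
  counters <- c(n_reads = length(reads), n_aligned = sum(aligned),
                n_multimapper = sum(al$status == "multimapper"),
                n_unmapped = sum(al$status == "unmapped"),
                n_unassigned_gene = sum(aligned & is.na(al$gene)))
  list(levels = methylation_level(pu, min_coverage), pileup = pu,
       aligned = al, counters = counters)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

binom_se <- function(p, n) ifelse(n > 0, sqrt(p * (1 - p) / n), NA_real_)

#' Three-chemistry deconvolution of m5C(+hm5C) and f5C
#'
#' Plain bisulfite protects only m5C and hm5C, while RedBS and fCAB
#' additionally protect f5C; the per-site difference of non-conversion
#' levels therefore estimates the f5C fraction:
#' `est_f5c_red = clamp(level_redbs - level_bs, 0, 1)` and likewise for
#' fCAB. `est_m5c_hm5c = level_bs` (m5C and hm5C are never separated).
#' When reduction/protection efficiencies are supplied, an
#' efficiency-corrected estimate divides the difference by `rho` (RedBS)
#' or `pi_protect` (fCAB). Binomial standard errors accompany all levels;
#' difference estimates carry the propagated (root-sum-square) error.
#' Missing levels propagate to missing estimates.
#'
#' @param levels_bs,levels_redbs,levels_fcab Level tables from
#'   [methylation_level()] (or `$levels` of [bs_call()]). `levels_fcab` may
#'   be `NULL` for a two-chemistry analysis (and vice versa).
#' @param rho Optional NaBH4 reduction efficiency for correction.
#' @param pi_protect Optional protection efficiency for correction.
#' @return A `DeconvolutionResult` data frame keyed by
#'   (`gene_id`, `seq_index`).
#' @export
deconvolve <- function(levels_bs, levels_redbs = NULL, levels_fcab = NULL,
                       rho = NULL, pi_protect = NULL) {
  if (is.null(levels_redbs) && is.null(levels_fcab)) {
    stop("need at least one of levels_redbs / levels_fcab")
  }
  if (!is.null(rho) && rho == 0) stop("rho = 0: correction undefined")
  if (!is.null(pi_protect) && pi_protect == 0) {
    stop("pi_protect = 0: correction undefined")
  }
  pick <- function(x, suffix) {
    if (is.null(x)) return(NULL)
    n <- x$n_unconverted + x$n_converted
    out <- data.frame(gene_id = x$gene_id, seq_index = x$seq_index,
                      stringsAsFactors = FALSE)
    out[[paste0("level_", suffix)]] <- x$level
    out[[paste0("n_", suffix)]] <- n
    out
  }
  res <- pick(levels_bs, "bs")
  for (part in list(pick(levels_redbs, "redbs"), pick(levels_fcab, "fcab"))) {
    if (!is.null(part)) {
      res <- merge(res, part, by = c("gene_id", "seq_index"), all = TRUE)
    }
  }
  res$est_m5c_hm5c <- res$level_bs
  res$se_bs <- binom_se(res$level_bs, res$n_bs)
  if (!is.null(levels_redbs)) {
    res$est_f5c_red <- clamp01(res$level_redbs - res$level_bs)
    res$se_f5c_red <- sqrt(res$se_bs^2 +
                             binom_se(res$level_redbs, res$n_redbs)^2)
    if (!is.null(rho)) res$est_f5c_red_corrected <-
        clamp01(res$est_f5c_red / rho)
  }
  if (!is.null(levels_fcab)) {
    res$est_f5c_fcab <- clamp01(res$level_fcab - res$level_bs)
    res$se_f5c_fcab <- sqrt(res$se_bs^2 +
                              binom_se(res$level_fcab, res$n_fcab)^2)
    if (!is.null(pi_protect)) res$est_f5c_fcab_corrected <-
        clamp01(res$est_f5c_fcab / pi_protect)
  }
  res <- res[order(res$gene_id, res$seq_index), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("DeconvolutionResult", class(res))
  res
}

#' Per-site differences between two conditions
#'
#' Subtracts levels and f5C estimates of `result_b` (e.g. a mutant) from
#' `result_a` (e.g. wild type) per site, with pooled binomial standard
#' errors. No hypothesis test is attached.
#'
#' @param result_a,result_b `DeconvolutionResult` objects on matched sites.
#' @return Data frame of per-site deltas (`delta_*`) and pooled standard
#'   errors (`se_delta_*`).
#' @export
compare_conditions <- function(result_a, result_b) {
  m <- merge(result_a, result_b, by = c("gene_id", "seq_index"),
             suffixes = c("_a", "_b"))
  out <- m[c("gene_id", "seq_index")]
  for (v in c("level_bs", "level_redbs", "level_fcab", "est_f5c_red",
              "est_f5c_fcab")) {
    va <- paste0(v, "_a")
    vb <- paste0(v, "_b")
    if (va %in% names(m)) out[[paste0("delta_", v)]] <- m[[va]] - m[[vb]]
  }
  if (all(c("se_bs_a", "se_bs_b") %in% names(m))) {
    out$se_delta_level_bs <- sqrt(m$se_bs_a^2 + m$se_bs_b^2)
  }
  for (v in c("se_f5c_red", "se_f5c_fcab")) {
    va <- paste0(v, "_a")
    vb <- paste0(v, "_b")
    if (va %in% names(m)) {
      out[[paste0("se_delta_", sub("^se_", "", v))]] <-
        sqrt(m[[va]]^2 + m[[vb]]^2)
    }
  }
  out
}
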