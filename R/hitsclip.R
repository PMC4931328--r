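#' Count aligned reads per gene by maximal overlap
#'
#' Each uniquely aligned read is assigned to the gene (same contig and
#' strand) with which its aligned span overlaps most; reads tying between
#' two genes, or overlapping none, are left unassigned and counted.
#'
#' @param alignments Data frame from [align_unique()] (aligned rows used).
#' @param annotations Annotation data frame.
#' @return A list: `counts` (data frame `gene_id`, `count`, `cpm`),
#'   `library_total` (number of aligned reads) and `n_unassigned`.
#' @export
count_by_gene <- function(alignments, annotations) {
  al <- alignments[alignments$status == "aligned", , drop = FALSE]
  ng <- nrow(annotations)
  ov <- matrix(0L, nrow = nrow(al), ncol = ng)
  for (j in seq_len(ng)) {
    a <- annotations[j, ]
    same <- al$contig == a$contig & al$strand == a$strand
    lo <- pmax(al$start0, a$start)
    hi <- pmin(al$start0 + al$width, a$end)
    ov[, j] <- ifelse(same, pmax(0L, hi - lo), 0L)
  }
  counts <- integer(ng)
  n_unassigned <- 0L
  if (nrow(al)) {
    best <- apply(ov, 1, max)
    nbest <- rowSums(ov == best & ov > 0L)
    assignable <- best > 0L & nbest == 1L
    n_unassigned <- sum(!assignable)
    idx <- apply(ov[assignable, , drop = FALSE], 1, which.max)
    tab <- tabulate(idx, nbins = ng)
    counts <- tab
  }
  total <- nrow(al)
  df <- data.frame(gene_id = annotations$gene_id, count = counts,
                   cpm = if (total > 0) counts / total * 1e6 else NA_real_,
                   stringsAsFactors = FALSE)
  list(counts = df, library_total = total, n_unassigned = n_unassigned)
}

nb_pair_logprob <- function(s, mu, size) {
  x <- 0:s
  stats::dnbinom(x, size = size, mu = mu, log = TRUE) +
    stats::dnbinom(s - x, size = size, mu = mu, log = TRUE)
}

#' Negative-binomial exact test for a pair of counts
#'
#' Tests whether two counts from libraries of equal effective size share a
#' common negative-binomial mean with fixed dispersion `phi`
#' (variance `mu + phi * mu^2`). Conditioning on the sum `s = a + b`, the
#' two-sided p-value is the total conditional probability of all splits
#' `(x, s - x)` whose joint probability does not exceed that of the
#' observed split. Unequal size factors are handled by rescaling both
#' counts to their common (geometric-mean) effective size before testing —
#' an approximation, stated in the docs, to quantile adjustment.
#'
#' @param a,b Observed counts.
#' @param size_factor_a,size_factor_b Relative library sizes.
#' @param dispersion NB dispersion `phi` (> 0).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(a, b, size_factor_a = 1, size_factor_b = 1,
                          dispersion = 0.1) {
  stopifnot(a >= 0, b >= 0, size_factor_a > 0, size_factor_b > 0,
            dispersion > 0)
  if (size_factor_a != size_factor_b) {
    common <- sqrt(size_factor_a * size_factor_b)
    a <- round(a * common / size_factor_a)
    b <- round(b * common / size_factor_b)
  }
  s <- a + b
  if (s == 0) return(1)
  lp <- nb_pair_logprob(s, mu = s / 2, size = 1 / dispersion)
  obs <- lp[a + 1L]
  # tolerance guards ties against floating-point noise
  p <- sum(exp(lp[lp <= obs + 1e-12])) / sum(exp(lp))
  min(1, p)
}

#' Per-gene enrichment table for a CLIP library versus a control
#'
#' Runs the negative-binomial exact test per gene on case versus control
#' counts (library-size normalised), computes log2 fold changes on
#' per-million normalised counts with a 0.5 pseudocount, adjusts p-values
#' by Benjamini-Hochberg, and ranks genes by p-value.
#'
#' @param case_counts,control_counts Data frames `gene_id`, `count` (e.g.
#'   from [count_by_gene()]).
#' @param case_total,control_total Library totals; default to summed
#'   counts.
#' @param dispersion NB dispersion for the exact test.
#' @return Data frame: `gene_id`, `count_case`, `count_control`, `logFC`,
#'   `p_value`, `p_adj`, `rank`.
#' @export
enrichment_table <- function(case_counts, control_counts,
                             case_total = NULL, control_total = NULL,
                             dispersion = 0.1) {
  m <- merge(case_counts[c("gene_id", "count")],
             control_counts[c("gene_id", "count")], by = "gene_id",
             suffixes = c("_case", "_control"))
  if (is.null(case_total)) case_total <- sum(m$count_case)
  if (is.null(control_total)) control_total <- sum(m$count_control)
  m$p_value <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(m$count_case[i], m$count_control[i],
                  size_factor_a = case_total, size_factor_b = control_total,
                  dispersion = dispersion)
  }, 0)
  norm_case <- m$count_case / case_total * 1e6
  norm_ctrl <- m$count_control / control_total * 1e6
  m$logFC <- log2((norm_case + 0.5) / (norm_ctrl + 0.5))
  m$p_adj <- stats::p.adjust(m$p_value, method = "BH")
  m <- m[order(m$p_value, -abs(m$logFC)), , drop = FALSE]
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m
}

#' HITS-CLIP per-gene enrichment test, FASTQ to table
#'
#' Filters reads to length > 20 nt, aligns them uniquely, counts per gene
#' by maximal overlap and tests case against control with the
#' negative-binomial exact test at fixed dispersion.
#'
#' @param case_fastq,control_fastq FASTQ paths.
#' @param bundle A `ReferenceBundle`.
#' @param dispersion NB dispersion.
#' @param min_len Minimum read length retained (nt; reads longer than 20
#'   nt by default).
#' @return A list: `table` (enrichment table), `case`, `control` (count
#'   objects from [count_by_gene()]).
#' @export
hitsclip_test <- function(case_fastq, control_fastq, bundle,
                          dispersion = 0.1, min_len = 21L) {
  run_one <- function(fq) {
    reads <- read_fastq(fq)
    reads <- reads[nchar(reads) >= min_len]
    al <- align_unique(unname(reads), bundle$genome)
    count_by_gene(al, bundle$annotations)
  }
  case <- run_one(case_fastq)
  control <- run_one(control_fastq)
  tab <- enrichment_table(case$counts, control$counts,
                          case$library_total, control$library_total,
                          dispersion)
  list(table = tab, case = case, control = control)
}
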