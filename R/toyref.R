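# Synthetic toy references. Sequences are seeded-random; designated
# crosslink/methylation cytosines are planted with a C-free +/-4 context so
# that truncation assignment is unambiguous for any offset in the +/-2
# search window.

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

make_gene_seq <- function(len, c_sites, clear_window = 4L) {
  s <- rand_bases(len)
  for (p in c_sites) {  # 0-based
    if (clear_window > 0L) {
      win <- setdiff(seq(p - clear_window, p + clear_window), p)
      win <- win[win >= 0 & win < len]
      s[win + 1L] <- sample(c("A", "G", "T"), length(win), replace = TRUE)
    }
    s[p + 1L] <- "C"
  }
  paste(s, collapse = "")
}

#' Toy mitochondrial reference bundle
#'
#' A single synthetic ~1.1 kb contig (`chrM_toy`) carrying six loci modelled
#' on the mitochondrial genes relevant to wobble-cytosine methylation
#' analysis: four tRNA genes (`MT-TM`, `MT-TQ` on the minus strand,
#' `MT-TL1`, `MT-TS2`) with structural layouts, and two mRNA loci
#' (`MT-ND1`, `MT-CO1`). Each locus has one designated crosslink cytosine
#' (the wobble base for the tRNAs) planted with a C-free +/-4 nt context;
#' the rest of the sequence is seeded-random, so reads of 18 nt and longer
#' map uniquely. The bundle gains a `demo_sites` element giving the
#' designated sites with default relative crosslink weights reflecting a
#' strongly MT-TM-biased mitochondrial composition (MT-TM 26% of
#' mitochondrial reads and 60% of the tRNA-locus reads, MT-ND1 15%, MT-TL1
#' 5%, MT-TS2 4.5%, the remainder split between the fourth tRNA and the
#' large mRNA locus).
#'
#' @param seed Integer seed for the synthetic sequence.
#' @return A `ReferenceBundle` with an extra `demo_sites` data frame
#'   (`gene_id`, `seq_index`, `weight`, `biotype`).
#' @export
toy_mt_bundle <- function(seed = 42L) {
  set.seed(seed)
  spec <- data.frame(
    gene_id = c("MT-TM", "MT-TQ", "MT-TL1", "MT-TS2", "MT-ND1", "MT-CO1"),
    len     = c(69L, 68L, 71L, 66L, 300L, 360L),
    strand  = c("+", "-", "+", "+", "+", "+"),
    biotype = c("tRNA", "tRNA", "tRNA", "tRNA", "mRNA", "mRNA"),
    site    = c(30L, 31L, 32L, 30L, 120L, 150L),
    stringsAsFactors = FALSE)
  # composition: tRNA loci together take 26/0.60 = 43.33% of the library
  trna_total <- 0.26 / 0.60
  spec$weight <- c(0.26, trna_total - 0.26 - 0.05 - 0.045, 0.05, 0.045,
                   0.15, 1 - trna_total - 0.15)
  spacer <- 25L
  contig <- rand_bases(spacer)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    gseq <- make_gene_seq(spec$len[i], spec$site[i])
    start0 <- length(contig)
    genomic <- if (spec$strand[i] == "+") gseq else revcomp(gseq)
    contig <- c(contig, strsplit(genomic, "")[[1]], rand_bases(spacer))
    rows[[i]] <- data.frame(gene_id = spec$gene_id[i], contig = "chrM_toy",
                            start = start0, end = start0 + spec$len[i],
                            strand = spec$strand[i], biotype = spec$biotype[i],
                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  g <- as_genome(c(chrM_toy = paste(contig, collapse = "")))
  trna <- spec$biotype == "tRNA"
  lay <- data.frame(gene_id = spec$gene_id[trna],
                    anticodon_start = spec$site[trna],
                    length = spec$len[trna], stringsAsFactors = FALSE)
  b <- reference_bundle(g, ann, lay)
  b$demo_sites <- data.frame(gene_id = spec$gene_id, seq_index = spec$site,
                             weight = spec$weight, biotype = spec$biotype,
                             stringsAsFactors = FALSE)
  b
}

#' Toy reference of the catalogued methylated mitochondrial tRNAs
#'
#' A synthetic bundle with six tRNA loci carrying the eight cytosine-5
#' methylation positions catalogued for human mitochondrial tRNA: the
#' wobble C34 of mt-tRNA-Met, C49 of mt-tRNA-Glu, C48 of mt-tRNA-Leu(UUR),
#' C48/C49/C50 of mt-tRNA-Ser(AGY), and the variable-region C47 of
#' mt-tRNA-His and mt-tRNA-Phe. Sequential toy indices stand in for the
#' universal numbering. The bundle gains a `catalogue_sites` element with
#' default methylated fractions per site.
#'
#' @param seed Integer seed for the synthetic sequence.
#' @return A `ReferenceBundle` with an extra `catalogue_sites` data frame
#'   (`gene_id`, `seq_index`, `m5c_frac`).
#' @export
toy_trna_catalogue_bundle <- function(seed = 7L) {
  set.seed(seed)
  spec <- list(
    list(gene_id = "MT-TM",  len = 69L, sites = 30L,          frac = 0.30),
    list(gene_id = "MT-TE",  len = 69L, sites = 48L,          frac = 0.60),
    list(gene_id = "MT-TL1", len = 71L, sites = 47L,          frac = 0.50),
    list(gene_id = "MT-TS2", len = 66L, sites = c(47L, 48L, 49L),
         frac = c(0.40, 0.50, 0.60)),
    list(gene_id = "MT-TH",  len = 69L, sites = 46L,          frac = 0.45),
    list(gene_id = "MT-TF",  len = 71L, sites = 46L,          frac = 0.55))
  spacer <- 25L
  contig <- rand_bases(spacer)
  rows <- list()
  sites <- list()
  for (s in spec) {
    gseq <- make_gene_seq(s$len, s$sites, clear_window = 0L)
    start0 <- length(contig)
    contig <- c(contig, strsplit(gseq, "")[[1]], rand_bases(spacer))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = s$gene_id, contig = "chrM_trna_toy", start = start0,
      end = start0 + s$len, strand = "+", biotype = "tRNA",
      stringsAsFactors = FALSE)
    sites[[length(sites) + 1L]] <- data.frame(
      gene_id = s$gene_id, seq_index = s$sites, m5c_frac = s$frac,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  g <- as_genome(c(chrM_trna_toy = paste(contig, collapse = "")))
  lay <- data.frame(gene_id = ann$gene_id, anticodon_start = 30L,
                    length = ann$end - ann$start, stringsAsFactors = FALSE)
  b <- reference_bundle(g, ann, lay)
  b$catalogue_sites <- do.call(rbind, sites)
  b
}
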