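# Shared fixtures and independent oracles, built in code at test time.

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(n) {
    c(paste0(">", n), records[[n]])
  })), path)
  path
}

write_tmp_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# Two-gene fixture: one gene per strand on a 200 nt contig.
two_strand_bundle <- function(seed = 101L) {
  set.seed(seed)
  contig <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  g <- as_genome(c(ctg = contig))
  ann <- data.frame(gene_id = c("gplus", "gminus"), contig = "ctg",
                    start = c(10L, 110L), end = c(79L, 179L),
                    strand = c("+", "-"), biotype = "tRNA",
                    stringsAsFactors = FALSE)
  lay <- data.frame(gene_id = c("gplus", "gminus"), anticodon_start = 30L,
                    length = 69L, stringsAsFactors = FALSE)
  reference_bundle(g, ann, lay)
}

# Independent adapter-trimming oracle: scan every overlap explicitly on
# character vectors (no shared code with trim_adapter()).
trim_oracle <- function(insert, adapter, min_overlap = 4L,
                        max_error_rate = 0.06) {
  ic <- strsplit(insert, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  best <- 0L
  for (k in seq_len(min(length(ic), length(ac)))) {
    suff <- ic[(length(ic) - k + 1L):length(ic)]
    mm <- sum(suff != ac[1:k])
    if (k >= min_overlap && mm <= floor(max_error_rate * k)) best <- k
  }
  paste(ic[seq_len(length(ic) - best)], collapse = "")
}

# Independent NB exact-test oracle: plain probability accumulation.
nb_exact_oracle <- function(a, b, phi) {
  s <- a + b
  if (s == 0) return(1)
  pr <- dnbinom(0:s, size = 1 / phi, mu = s / 2) *
    dnbinom(s:0, size = 1 / phi, mu = s / 2)
  obs <- pr[a + 1]
  sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr)
}

# Brute-force best-stratum unique aligner over both strands, pure R.
align_oracle_status <- function(read, contig) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  count_hits <- function(q, mm_target) {
    n <- nchar(contig)
    m <- nchar(q)
    if (m > n) return(0L)
    qc <- strsplit(q, "")[[1]]
    hits <- 0L
    for (i in 1:(n - m + 1)) {
      w <- strsplit(substr(contig, i, i + m - 1), "")[[1]]
      if (sum(w != qc) == mm_target) hits <- hits + 1L
    }
    hits
  }
  n0 <- count_hits(read, 0L) + count_hits(rc, 0L)
  if (n0 == 1L) return("aligned")
  if (n0 > 1L) return("multimapper")
  n1 <- count_hits(read, 1L) + count_hits(rc, 1L)
  if (n1 == 0L) "unmapped" else if (n1 == 1L) "aligned" else "multimapper"
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
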