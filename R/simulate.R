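# Modification states: unmodified cytosine, 5-methyl-, 5-hydroxymethyl-,
# 5-formyl-cytosine. Molecule matrices use the single-letter codes.
MOD_STATES <- c(C = "C", M5C = "M", HM5C = "H", F5C = "F")

#' Specify the modification-state mixture at one cytosine
#'
#' @param gene_id Gene carrying the site.
#' @param seq_index 0-based transcript-sense position of the cytosine.
#' @param state_probs Named probabilities over `C`, `M5C`, `HM5C`, `F5C`
#'   (missing states default to 0); must sum to 1.
#' @return A `SiteSpec` list.
#' @export
site_spec <- function(gene_id, seq_index, state_probs) {
  p <- c(C = 0, M5C = 0, HM5C = 0, F5C = 0)
  stopifnot(all(names(state_probs) %in% names(p)))
  p[names(state_probs)] <- state_probs
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("state_probs must be non-negative and sum to 1")
  }
  structure(list(gene_id = gene_id, seq_index = as.integer(seq_index),
                 state_probs = p), class = "SiteSpec")
}

#' Conversion chemistry of a bisulfite-family protocol
#'
#' Encodes how each cytosine state reads out after treatment. Plain
#' bisulfite (`BS`) deaminates unmodified C and f5C to U (read T) while m5C
#' and hm5C are protected; `RedBS` first reduces f5C to hm5C with NaBH4
#' (efficiency `rho`), so f5C converts only with probability `1 - rho`;
#' `fCAB` protects f5C with O-ethylhydroxylamine (efficiency `pi`), so f5C
#' converts with probability `1 - pi`. `gamma` is the bisulfite
#' non-conversion rate of unmodified C (an unmodified C survives as C with
#' probability `gamma`).
#'
#' @param name One of `"BS"`, `"RedBS"`, `"fCAB"`.
#' @param rho NaBH4 reduction efficiency (RedBS only).
#' @param pi_protect O-ethylhydroxylamine protection efficiency (fCAB only).
#' @param gamma Bisulfite non-conversion rate for unmodified C.
#' @return A `ChemistrySpec` with element `conv`: per-state probability that
#'   the position reads as T.
#' @export
chemistry_spec <- function(name = c("BS", "RedBS", "fCAB"), rho = 0.9,
                           pi_protect = 0.9, gamma = 0.005) {
  name <- match.arg(name)
  stopifnot(rho >= 0, rho <= 1, pi_protect >= 0, pi_protect <= 1,
            gamma >= 0, gamma <= 1)
  conv <- switch(name,
    BS    = c(C = 1 - gamma, M = 0, H = 0, F = 1),
    RedBS = c(C = 1 - gamma, M = 0, H = 0, F = 1 - rho),
    fCAB  = c(C = 1 - gamma, M = 0, H = 0, F = 1 - pi_protect))
  structure(list(name = name, conv = conv, rho = rho,
                 pi_protect = pi_protect, gamma = gamma),
            class = "ChemistrySpec")
}

#' Default wild-type wobble-base composition for mt-tRNA-Met C34
#'
#' The modification mixture used for wild-type simulations at the wobble
#' cytosine: 30% m5C(+hm5C), 37% f5C, 33% unmodified. See the methods
#' vignette for how these defaults were fixed.
#' @return Named numeric vector of state probabilities.
#' @export
wt_wobble_composition <- function() c(C = 0.33, M5C = 0.30, F5C = 0.37)

#' Draw a ground-truthed population of tRNA molecules
#'
#' Samples `n_per_gene` molecules for every gene that carries at least one
#' [site_spec()]. Each molecule is the transcript-sense gene sequence with
#' per-position modification states: positions named in a site spec draw
#' their state from the spec's mixture, every other position keeps its
#' reference base (cytosines stay unmodified `C`). Realised state fractions
#' are recorded as the ground truth for recovery checks.
#'
#' @param bundle A `ReferenceBundle`.
#' @param site_specs List of [site_spec()] objects.
#' @param n_per_gene Molecules per gene.
#' @param seed Integer seed.
#' @return A `MoleculePopulation`: per gene a state matrix
#'   (`n_per_gene` x gene length) plus a `truth` data frame with realised
#'   and specified fractions per site.
#' @export
sample_molecules <- function(bundle, site_specs, n_per_gene, seed = 1L) {
  stopifnot(n_per_gene >= 1)
  set.seed(seed)
  genes <- unique(vapply(site_specs, `[[`, "", "gene_id"))
  pop <- list()
  truth <- list()
  for (g in genes) {
    seqchr <- strsplit(gene_sequence(bundle, g), "")[[1]]
    states <- matrix(rep(seqchr, each = n_per_gene), nrow = n_per_gene)
    for (sp in site_specs) {
      if (sp$gene_id != g) next
      i <- sp$seq_index
      if (i < 0 || i >= length(seqchr)) {
        stop("site index out of gene ", g)
      }
      if (seqchr[i + 1L] != "C") {
        stop(sprintf("site %s:%d is not a reference C (found %s)",
                     g, i, seqchr[i + 1L]))
      }
      drawn <- sample(MOD_STATES, n_per_gene, replace = TRUE,
                      prob = sp$state_probs)
      states[, i + 1L] <- drawn
      realized <- vapply(MOD_STATES, function(s) mean(drawn == s), 0)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = g, seq_index = i,
        spec_C = sp$state_probs[["C"]], spec_M5C = sp$state_probs[["M5C"]],
        spec_HM5C = sp$state_probs[["HM5C"]],
        spec_F5C = sp$state_probs[["F5C"]],
        frac_C = realized[["C"]], frac_M5C = realized[["M5C"]],
        frac_HM5C = realized[["HM5C"]], frac_F5C = realized[["F5C"]],
        stringsAsFactors = FALSE)
    }
    pop[[g]] <- states
  }
  structure(list(genes = pop, truth = do.call(rbind, truth),
                 n_per_gene = n_per_gene, seed = seed),
            class = "MoleculePopulation")
}

#' Apply a conversion chemistry to molecules
#'
#' Converts per-position modification states into read bases by independent
#' Bernoulli draws: each cytosine state reads T with its chemistry-specific
#' conversion probability and C otherwise; non-cytosine bases pass through
#' unchanged. Accepts a single state vector or a state matrix (rows =
#' molecules). Uses the current RNG stream.
#'
#' @param states Character vector or matrix of state codes
#'   (`A/C/G/T/M/H/F`).
#' @param chem A `ChemistrySpec`.
#' @return Converted sequence(s): character scalar for a vector input,
#'   character vector (one string per molecule) for a matrix.
#' @export
apply_chemistry <- function(states, chem) {
  vec_in <- !is.matrix(states)
  m <- if (vec_in) matrix(states, nrow = 1) else states
  out <- m
  for (st in c("C", "M", "H", "F")) {
    idx <- which(m == st)
    if (length(idx) == 0L) next
    out[idx] <- ifelse(stats::runif(length(idx)) < chem$conv[[st]], "T", "C")
  }
  reads <- apply(out, 1, paste, collapse = "")
  if (vec_in) reads[[1]] else reads
}

# Point sequencing errors: per read, substitute bases independently at
# `rate` with a uniformly chosen different base.
add_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

write_fastq <- function(reads, names, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- names
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))  # constant Q40
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a character vector of sequences
#' @param path FASTQ path (Phred+33, 4-line records).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Simulate a bisulfite-family RNA-Seq library
#'
#' Emits full-length, transcript-strand (directional) reads of the
#' molecules in `population` after treatment with the given chemistry, at
#' constant quality. A truth sidecar (TSV) records the realised per-site
#' state fractions together with the chemistry parameters.
#'
#' @param population A `MoleculePopulation`.
#' @param chem A `ChemistrySpec`.
#' @param coverage Reads per gene; `NULL` (default) sequences every molecule
#'   exactly once, otherwise molecules are resampled with replacement.
#' @param seq_error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param out_fastq Output FASTQ path.
#' @param truth_out Optional truth sidecar TSV path.
#' @return Invisibly, a list with `fastq`, `truth` (data frame) and `reads`.
#' @export
make_bs_library <- function(population, chem, coverage = NULL,
                            seq_error_rate = 0, seed = 1L, out_fastq,
                            truth_out = NULL) {
  set.seed(seed)
  all_reads <- character()
  for (g in names(population$genes)) {
    states <- population$genes[[g]]
    if (!is.null(coverage)) {
      states <- states[sample.int(nrow(states), coverage, replace = TRUE), ,
                       drop = FALSE]
    }
    reads <- apply_chemistry(states, chem)
    all_reads <- c(all_reads, reads)
  }
  all_reads <- add_seq_errors(all_reads, seq_error_rate)
  names(all_reads) <- sprintf("bsread%06d", seq_along(all_reads))
  write_fastq(all_reads, names(all_reads), out_fastq)
  truth <- population$truth
  truth$chemistry <- chem$name
  truth$gamma <- chem$gamma
  truth$rho <- chem$rho
  truth$pi_protect <- chem$pi_protect
  truth$seed <- seed
  if (!is.null(truth_out)) {
    utils::write.table(truth, truth_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(fastq = out_fastq, truth = truth, reads = all_reads))
}

#' Specify a miCLIP library simulation
#'
#' @param crosslink_weights Data frame with columns `gene_id`, `seq_index`,
#'   `weight`: relative crosslink intensity per cytosine.
#' @param truncation_offset_probs Named probabilities over offsets
#'   `-2..2` of the reverse-transcriptase stall relative to the crosslinked
#'   cytosine (names `"-2"` .. `"2"`).
#' @param sample_barcode 4-nt experimental barcode embedded at read
#'   positions 4-7.
#' @param adapter 3' adapter sequence subject to read-through.
#' @param insert_len_range Length-2 integer vector: cDNA insert lengths are
#'   drawn uniformly from this range (clipped at the transcript 3' end),
#'   emulating the variable fragment ends left by partial RNA digestion.
#' @param read_length Maximum raw read length (split UMI + barcode occupy
#'   the first 10 nt; adapter read-through fills short inserts).
#' @param pcr_dup Function `n -> integer` drawing the number of PCR copies
#'   (>= 1) per cDNA; default geometric with mean 2.
#' @param seq_error_rate Per-base substitution error rate.
#' @return A `MiclipSpec` list.
#' @export
miclip_spec <- function(crosslink_weights,
                        truncation_offset_probs = c("-2" = 0.05, "-1" = 0.15,
                                                    "0" = 0.55, "1" = 0.15,
                                                    "2" = 0.10),
                        sample_barcode = "ACCG",
                        adapter = "AGATCGGAAGAGCGGTTCAG",
                        insert_len_range = c(18L, 45L),
                        read_length = 70L,
                        pcr_dup = function(n) 1L + stats::rgeom(n, 0.5),
                        seq_error_rate = 0.001) {
  stopifnot(is.data.frame(crosslink_weights),
            all(c("gene_id", "seq_index", "weight") %in%
                  names(crosslink_weights)),
            all(crosslink_weights$weight >= 0),
            nchar(sample_barcode) == 4L,
            abs(sum(truncation_offset_probs) - 1) < 1e-9,
            identical(sort(as.integer(names(truncation_offset_probs))),
                      -2:2),
            length(insert_len_range) == 2L,
            insert_len_range[1] <= insert_len_range[2])
  structure(list(crosslink_weights = crosslink_weights,
                 truncation_offset_probs = truncation_offset_probs,
                 sample_barcode = sample_barcode, adapter = adapter,
                 insert_len_range = as.integer(insert_len_range),
                 read_length = as.integer(read_length), pcr_dup = pcr_dup,
                 seq_error_rate = seq_error_rate),
            class = "MiclipSpec")
}

random_umis <- function(n) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n * 6L, replace = TRUE), ncol = 6L)
  apply(m, 1, paste, collapse = "")
}

#' Simulate a miCLIP library
#'
#' Draws `n_cdna` cDNAs with crosslink sites sampled proportionally to the
#' spec weights. The reverse transcriptase stalls at the peptide adduct, so
#' the observed insert starts one base 3' of the crosslinked cytosine,
#' jittered by the truncation offset delta: insert start = site + delta + 1
#' in transcript sense. The raw read layout is 3 nt UMI + 4 nt sample
#' barcode + 3 nt UMI + insert, with 3' adapter read-through filling short
#' inserts up to the read length. Each cDNA is emitted `pcr_dup()` times
#' with identical UMI and insert; sequencing errors are applied per emitted
#' read.
#'
#' @param bundle A `ReferenceBundle`.
#' @param spec A [miclip_spec()].
#' @param n_cdna Number of distinct cDNAs.
#' @param seed Integer seed.
#' @param out_fastq Output FASTQ path.
#' @param truth_out Optional truth sidecar TSV path (per-site true cDNA
#'   counts).
#' @return Invisibly, a list with `fastq`, `truth` (per-site cDNA counts),
#'   `cdnas` (per-cDNA table) and `n_raw_reads`.
#' @export
make_miclip_library <- function(bundle, spec, n_cdna, seed = 1L, out_fastq,
                                truth_out = NULL) {
  set.seed(seed)
  w <- spec$crosslink_weights
  for (i in seq_len(nrow(w))) {
    seqg <- gene_sequence(bundle, w$gene_id[i])
    if (substr(seqg, w$seq_index[i] + 1L, w$seq_index[i] + 1L) != "C") {
      stop(sprintf("crosslink weight on non-C position %s:%d",
                   w$gene_id[i], w$seq_index[i]))
    }
  }
  site_idx <- sample.int(nrow(w), n_cdna, replace = TRUE, prob = w$weight)
  offsets <- sample(as.integer(names(spec$truncation_offset_probs)), n_cdna,
                    replace = TRUE, prob = spec$truncation_offset_probs)
  umis <- random_umis(n_cdna)
  gene_seqs <- vapply(unique(w$gene_id), function(g) gene_sequence(bundle, g),
                      character(1))
  ins_max <- spec$read_length - 10L
  lo <- spec$insert_len_range[1]
  hi <- spec$insert_len_range[2]
  inserts <- character(n_cdna)
  for (k in seq_len(n_cdna)) {
    gid <- w$gene_id[site_idx[k]]
    gseq <- gene_seqs[[gid]]
    start0 <- w$seq_index[site_idx[k]] + offsets[k] + 1L  # 0-based
    if (start0 < 0L || start0 >= nchar(gseq)) {
      inserts[k] <- ""
      next
    }
    avail <- nchar(gseq) - start0
    # fragment end from partial digestion: uniform over feasible lengths
    len <- if (avail <= lo) avail else
      sample(seq(lo, min(hi, avail, ins_max)), 1L)
    inserts[k] <- substr(gseq, start0 + 1L, start0 + len)
  }
  dup <- spec$pcr_dup(n_cdna)
  stopifnot(all(dup >= 1L))
  u1 <- substr(umis, 1L, 3L)
  u2 <- substr(umis, 4L, 6L)
  core <- paste0(u1, spec$sample_barcode, u2, inserts)
  fill <- pmax(0L, spec$read_length - nchar(core))
  raw <- paste0(core, substr(spec$adapter, 1L, fill))
  raw <- rep(raw, dup)
  raw <- add_seq_errors(raw, spec$seq_error_rate)
  names(raw) <- sprintf("miclip%07d", seq_along(raw))
  write_fastq(raw, names(raw), out_fastq)
  cdnas <- data.frame(gene_id = w$gene_id[site_idx],
                      seq_index = w$seq_index[site_idx],
                      offset = offsets, umi = umis, insert = inserts,
                      n_copies = dup, stringsAsFactors = FALSE)
  truth <- stats::aggregate(cbind(n_cdna_true = rep(1L, nrow(cdnas))),
                            by = cdnas[c("gene_id", "seq_index")], FUN = sum)
  if (!is.null(truth_out)) {
    utils::write.table(truth, truth_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(fastq = out_fastq, truth = truth, cdnas = cdnas,
                 n_raw_reads = length(raw)))
}

#' Simulate a HITS-CLIP library
#'
#' Per-gene read counts are drawn from a negative binomial with the given
#' means and dispersion (variance mu + dispersion * mu^2); fragments start
#' uniformly within the gene with lengths uniform in `frag_len`, clipped at
#' the gene end — emulating partial micrococcal-nuclease digestion with
#' footprints of roughly 30-60 nt.
#'
#' @param bundle A `ReferenceBundle`.
#' @param per_gene_means Named numeric vector of expected read counts.
#' @param dispersion NB dispersion.
#' @param seed Integer seed.
#' @param out_fastq Output FASTQ path.
#' @param frag_len Length-2 integer vector, fragment length range.
#' @param truth_out Optional truth sidecar TSV path (per-gene true counts).
#' @return Invisibly, a list with `fastq` and `truth`.
#' @export
make_hitsclip_library <- function(bundle, per_gene_means, dispersion = 0.1,
                                  seed = 1L, out_fastq,
                                  frag_len = c(30L, 60L), truth_out = NULL) {
  set.seed(seed)
  stopifnot(!is.null(names(per_gene_means)), dispersion > 0)
  reads <- character()
  counts <- integer(length(per_gene_means))
  names(counts) <- names(per_gene_means)
  for (g in names(per_gene_means)) {
    n <- stats::rnbinom(1L, mu = per_gene_means[[g]], size = 1 / dispersion)
    counts[[g]] <- n
    if (n == 0L) next
    gseq <- gene_sequence(bundle, g)
    L <- nchar(gseq)
    starts <- sample.int(L, n, replace = TRUE)  # 1-based within transcript
    lens <- sample(seq(frag_len[1], frag_len[2]), n, replace = TRUE)
    ends <- pmin(L, starts + lens - 1L)
    reads <- c(reads, substr(rep(gseq, n), starts, ends))
  }
  names(reads) <- sprintf("clip%06d", seq_along(reads))
  write_fastq(reads, names(reads), out_fastq)
  truth <- data.frame(gene_id = names(counts), n_reads_true = unname(counts),
                      stringsAsFactors = FALSE)
  if (!is.null(truth_out)) {
    utils::write.table(truth, truth_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(fastq = out_fastq, truth = truth))
}
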