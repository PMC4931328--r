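test_that("barcode parsing follows the split-UMI layout", {
  pb <- parse_barcode(c("AAACCGGTTTACGT", "ACGTACGTA"))
  expect_equal(pb$n_short, 1L)
  expect_equal(pb$parsed$umi, "AAATTT")
  expect_equal(pb$parsed$sample_barcode, "CCGG")
  expect_equal(pb$parsed$insert, "ACGT")
  # two reads identical except the UMI share the insert
  pb2 <- parse_barcode(c("AAACCGGTTTACGT", "CCCCCGGTTTACGT"))
  expect_equal(unique(pb2$parsed$insert), "ACGT")
  expect_equal(length(unique(pb2$parsed$umi)), 2L)
})

test_that("deduplication counts distinct UMIs per insert", {
  mk <- function(umi, insert) {
    data.frame(umi = umi, sample_barcode = "ACCG", insert = insert,
               stringsAsFactors = FALSE)
  }
  # 5 copies of one (insert, UMI) pair collapse to one cDNA
  dd <- demultiplex_and_dedup(mk(rep("AAAAAA", 5), rep("ACGTACGT", 5)),
                              "ACCG")
  expect_equal(dd$cdna$cdna_count, 1L)
  # distinct UMIs are counted once each
  dd2 <- demultiplex_and_dedup(mk(c("AAAAAA", "CCCCCC", "AAAAAA"),
                                  rep("ACGTACGT", 3)), "ACCG")
  expect_equal(dd2$cdna$cdna_count, 2L)
  # distinct inserts give distinct records; wrong barcodes are counted out
  p3 <- rbind(mk("AAAAAA", "ACGTACGT"), mk("AAAAAA", "TTTTCCCC"),
              mk("GGGGGG", "ACGTACGT"))
  p3$sample_barcode[3] <- "TTTT"
  dd3 <- demultiplex_and_dedup(p3, "ACCG")
  expect_equal(nrow(dd3$cdna), 2L)
  expect_equal(dd3$n_mismatched, 1L)
})

test_that("adapter trimming honours overlap and error budget", {
  ad <- "AGATCGGAAGAGCGGTTCAG"
  expect_equal(trim_adapter(paste0("ACGTACGT", ad), ad), "ACGTACGT")
  # 3-nt adapter prefix is below the minimum overlap
  expect_equal(trim_adapter("TTTTTTAGA", ad), "TTTTTTAGA")
  # 17 matched bases with one mismatch: 1 <= floor(0.06 * 17)
  pre17 <- substr(ad, 1, 17)
  substr(pre17, 9, 9) <- "T"
  expect_equal(trim_adapter(paste0("CCCCCC", pre17), ad), "CCCCCC")
  # 4-base overlap has zero error budget
  expect_equal(trim_adapter("CCCCCCAGAT", ad), "CCCCCC")
  expect_equal(trim_adapter("CCCCCCAGAA", ad), "CCCCCCAGAA")

  # randomised agreement with an independently coded oracle
  set.seed(31)
  for (i in 1:200) {
    ins <- paste0(random_seq(sample(5:30, 1)),
                  if (runif(1) < 0.7) {
                    k <- sample(0:20, 1)
                    p <- substr(ad, 1, k)
                    if (k > 5 && runif(1) < 0.4) {
                      j <- sample(k, 1)
                      substr(p, j, j) <- sample(c("A", "C", "G", "T"), 1)
                    }
                    p
                  } else "")
    expect_identical(trim_adapter(ins, ad), trim_oracle(ins, ad))
  }
})

test_that("length filter drops short inserts", {
  rec <- data.frame(insert = c(strrep("A", 17), strrep("A", 18),
                               strrep("A", 30)),
                    cdna_count = c(1L, 2L, 3L), stringsAsFactors = FALSE)
  lf <- length_filter(rec, 18L)
  expect_equal(nrow(lf$records), 2L)
  expect_equal(lf$n_dropped, 1L)
  empty <- length_filter(rec[0, ], 18L)
  expect_equal(nrow(empty$records), 0L)
})

test_that("unique alignment keeps best-stratum singletons only", {
  set.seed(17)
  core <- random_seq(300)
  dupseg <- random_seq(40)
  g <- as_genome(c(c1 = paste0(core, dupseg, random_seq(50), dupseg)))
  uniq_read <- substr(core, 50, 89)
  al <- align_unique(c(uniq_read, dupseg), g)
  expect_equal(al$status, c("aligned", "multimapper"))
  expect_equal(al$start0[1], 49L)
  expect_equal(al$mismatches[1], 0L)
  # minus-strand reads report the transcript 5'-most base
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(uniq_read)))
  alm <- align_unique(rc, g)
  expect_equal(alm$strand, "-")
  expect_equal(alm$first_aligned_pos, 49L + 39L)
  # an exact hit beats any number of one-mismatch hits
  seg <- substr(core, 100, 129)
  seg_mm <- seg
  substr(seg_mm, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                    substr(seg, 15, 15))[1]
  g2 <- as_genome(c(c1 = paste0(random_seq(30), seg, random_seq(20), seg_mm,
                                random_seq(20), seg_mm)))
  al2 <- align_unique(seg, g2)
  expect_equal(al2$status, "aligned")
  expect_equal(al2$mismatches, 0L)
  expect_equal(al2$start0, 30L)
})

test_that("unique alignment agrees with a brute-force scan", {
  set.seed(23)
  g <- as_genome(c(c1 = random_seq(2000)))
  reads <- vapply(1:300, function(i) {
    if (runif(1) < 0.7) {
      st <- sample(1960, 1)
      r <- substr(g[["c1"]], st, st + 34)
      if (runif(1) < 0.5) {
        r <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(r)))
      }
      if (runif(1) < 0.5) {
        p <- sample(35, 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    } else random_seq(35)
  }, "")
  al <- align_unique(reads, g)
  oracle <- vapply(reads, align_oracle_status, "", contig = g[["c1"]])
  expect_equal(unname(al$status), unname(oracle))
})

test_that("truncation assignment picks the nearest C with 5' tie-break", {
  # enumerate every C/A pattern in the +/-2 window around the stall
  for (strand in c("+", "-")) {
    for (mask in 0:31) {
      pattern <- as.logical(bitwAnd(mask, 2^(0:4)) > 0)  # stall-2 .. stall+2
      base_c <- if (strand == "+") "C" else "G"
      base_bg <- "A"
      contig <- rep(base_bg, 21)
      stall0 <- 10L
      win0 <- stall0 + (-2:2)
      contig[win0 + 1L] <- ifelse(pattern, base_c, base_bg)
      g <- as_genome(c(c1 = paste(contig, collapse = "")))
      fap <- if (strand == "+") stall0 + 1L else stall0 - 1L
      al <- data.frame(read = "NNNN", status = "aligned", contig = "c1",
                       strand = strand, start0 = 0L,
                       first_aligned_pos = fap, width = 4L,
                       mismatches = 0L, stringsAsFactors = FALSE)
      res <- assign_truncation(al, g)
      # independent expectation: nearest by |distance|, ties to the 5' side
      d <- (-2:2)[pattern]
      if (length(d) == 0) {
        expect_false(res$assigned)
      } else {
        dist <- abs(d)
        cand <- d[dist == min(dist)]
        pick <- if (strand == "+") min(cand) else max(cand)
        expect_true(res$assigned)
        expect_equal(res$site0, stall0 + pick)
        # never a non-C (transcript sense), never beyond the window
        expect_identical(substr(g[["c1"]], res$site0 + 1, res$site0 + 1),
                         base_c)
        expect_lte(abs(res$site0 - stall0), 2)
      }
    }
  }
})

test_that("site table computes RPM per replicate and strict thresholds", {
  s1 <- data.frame(contig = "c", strand = "+", site0 = c(9L, 20L),
                   cdna_count = c(1L, 600L))
  s2 <- data.frame(contig = "c", strand = "+", site0 = c(9L, 20L),
                   cdna_count = c(1L, 700L))
  s3 <- data.frame(contig = "c", strand = "+", site0 = 20L,
                   cdna_count = 400L)
  tab <- build_site_table(list(s1, s2, s3), totals = c(1e4, 1e4, 1e4))
  r1 <- tab[tab$position == 10L, ]
  expect_equal(r1$rpm_rep1, 100)           # 1 / 1e4 * 1e6
  expect_equal(r1$n_replicates_passing, 2) # 100 RPM in reps 1-2, absent in 3
  expect_true(r1$high_confidence)
  # exactly 50 RPM never passes the strict threshold
  s50 <- data.frame(contig = "c", strand = "+", site0 = 5L,
                    cdna_count = 500L)
  tab50 <- build_site_table(list(s50, s50, s50), totals = rep(1e7, 3))
  expect_equal(unique(tab50$rpm_rep1), 50)
  expect_false(any(tab50$high_confidence))
  expect_error(build_site_table(list(s1), min_replicates = 2L),
               "min_replicates")
})

test_that("composition report returns simplex shares", {
  tab <- data.frame(contig = "c", position = c(10L, 50L), strand = "+",
                    count_rep1 = c(30L, 30L), rpm_rep1 = c(1, 1),
                    n_replicates_passing = 1, high_confidence = TRUE,
                    gene_id = c("a", "b"), stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("a", "b"), contig = "c",
                    start = c(0L, 40L), end = c(20L, 60L), strand = "+",
                    biotype = c("tRNA", "mRNA"), stringsAsFactors = FALSE)
  comp <- composition_report(tab, ann)
  expect_equal(sum(comp$share_mapped), 1)
  expect_equal(comp$share_mapped, c(0.5, 0.5))
  expect_equal(comp$share_trna[comp$gene_id == "a"], 1)
})

test_that("pipeline counters satisfy conservation and dedup idempotence", {
  b <- toy_mt_bundle()
  spec <- miclip_spec(crosslink_weights = b$demo_sites)
  fq <- tempfile(fileext = ".fastq")
  make_miclip_library(b, spec, 1500, seed = 13, out_fastq = fq)
  mc <- miclip_call(fq, b, barcode = "ACCG", min_replicates = 1L)
  cn <- mc$counters[[1]]
  expect_equal(cn[["n_raw"]], cn[["n_short"]] + cn[["n_barcode_matched"]] +
                 cn[["n_barcode_mismatched"]])
  expect_equal(cn[["n_records"]],
               cn[["n_dropped_short_insert"]] + cn[["n_aligned"]] +
                 cn[["n_multimapper"]] + cn[["n_unmapped"]])
  expect_equal(cn[["n_aligned"]], cn[["n_assigned"]] + cn[["n_unassigned"]])

  # duplicating every raw read leaves the cDNA records unchanged
  reads <- read_fastq(fq)
  pb1 <- parse_barcode(unname(reads))
  pb2 <- parse_barcode(rep(unname(reads), each = 3))
  dd1 <- demultiplex_and_dedup(pb1$parsed, "ACCG")
  dd2 <- demultiplex_and_dedup(pb2$parsed, "ACCG")
  expect_identical(dd1$cdna[order(dd1$cdna$insert), ],
                   dd2$cdna[order(dd2$cdna$insert), ])
})

test_that("a single crosslink site is recovered end-to-end at the true C", {
  b <- toy_mt_bundle()
  spec <- miclip_spec(
    crosslink_weights = data.frame(gene_id = "MT-TM", seq_index = 30,
                                   weight = 1),
    seq_error_rate = 0)
  fqs <- vapply(1:3, function(r) {
    fq <- tempfile(fileext = ".fastq")
    make_miclip_library(b, spec, 800, seed = 100 + r, out_fastq = fq)
    fq
  }, "")
  mc <- miclip_call(fqs, b, barcode = "ACCG")
  hc <- mc$site_table[mc$site_table$high_confidence, ]
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$position, wobble_coordinate(b, "MT-TM"))
  expect_equal(hc$gene_id, "MT-TM")
})
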