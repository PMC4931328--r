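# Small helper: align a set of transcript-sense reads of one toy gene.
bs_fixture <- function(reads, bundle) {
  al <- align_unique(reads, bundle$genome, bisulfite = TRUE)
  al$gene <- NA_character_
  ok <- al$status == "aligned"
  al$gene[ok] <- mtfivec:::assign_gene(al[ok, , drop = FALSE],
                                       bundle$annotations)
  al
}

test_that("pileup counts conversion states and dedups identical reads", {
  b <- two_strand_bundle()
  tx <- gene_sequence(b, "gplus")
  conv <- chartr("C", "T", tx)            # fully converted read
  keep <- tx                               # fully unconverted read
  al <- bs_fixture(rep(keep, 10), b)
  pu <- pileup(al, b, "BS", "without")
  expect_true(all(pu$coverage == 10))
  expect_true(all(pu$n_unconverted == 10))
  expect_true(all(pu$n_converted == 0))

  # 5 identical reads collapse to coverage 1 with dedup
  pu_d <- pileup(bs_fixture(rep(conv, 5), b), b, "BS", "with")
  expect_true(all(pu_d$coverage == 1))
  pu_nd <- pileup(bs_fixture(rep(conv, 5), b), b, "BS", "without")
  expect_true(all(pu_nd$coverage >= pu_d$coverage))

  # a non-C/T base at a reference-C column counts as other
  mut <- keep
  cpos <- regexpr("C", tx)[1]
  substr(mut, cpos, cpos) <- "G"
  pu_o <- pileup(bs_fixture(c(mut, keep, keep), b), b, "BS")
  row <- pu_o[pu_o$seq_index == cpos - 1L, ]
  expect_equal(row$n_other, 1L)
  expect_equal(row$n_unconverted, 2L)
})

test_that("minus-strand genes pile up in transcript coordinates", {
  b <- two_strand_bundle()
  tx <- gene_sequence(b, "gminus")
  al <- bs_fixture(rep(tx, 6), b)
  expect_true(all(al$gene == "gminus"))
  pu <- pileup(al, b, "BS")
  expect_true(all(pu$n_unconverted == 6))
  ccols <- which(strsplit(tx, "")[[1]] == "C") - 1L
  expect_setequal(pu$seq_index, ccols)
})

test_that("methylation level applies the coverage floor", {
  pu <- data.frame(gene_id = "g", seq_index = c(0L, 1L, 2L, 3L),
                   coverage = c(10L, 4L, 100L, 5L),
                   n_unconverted = c(3L, 2L, 0L, 2L),
                   n_converted = c(7L, 2L, 100L, 3L),
                   n_other = 0L)
  lv <- methylation_level(pu, min_coverage = 5L)
  expect_equal(lv$level, c(0.30, NA, 0, 0.4))
})

test_that("read matrix exposes per-read conversion calls", {
  b <- two_strand_bundle()
  tx <- gene_sequence(b, "gplus")
  al <- bs_fixture(tx, b)
  m <- read_matrix(al, b, "gplus")
  expect_true(all(m == "unconverted"))
  # a read not covering a column reports missing
  part <- substr(tx, 31, 69)
  alp <- bs_fixture(c(tx, part), b)
  # partial reads are not gene-assigned by containment? they are: span in gene
  m2 <- read_matrix(alp, b, "gplus")
  ccols <- as.integer(sub("^c", "", colnames(m2)))
  expect_true(all(m2[2, ccols < 30] == "missing"))
  expect_true(all(m2[2, ccols >= 30] == "unconverted"))
})

test_that("deconvolution subtracts chemistries with clamping", {
  mk <- function(level, n = 100L) {
    data.frame(gene_id = "g", seq_index = 0L, coverage = n,
               n_unconverted = round(level * n),
               n_converted = n - round(level * n), n_other = 0L,
               level = level)
  }
  # no chemistry difference: no f5C
  d0 <- deconvolve(mk(0.3), mk(0.3), mk(0.3))
  expect_equal(d0$est_f5c_red, 0)
  expect_equal(d0$est_f5c_fcab, 0)
  # the wild-type arithmetic: 0.66 - 0.30 = 0.36
  d1 <- deconvolve(mk(0.30), mk(0.66))
  expect_equal(d1$est_f5c_red, 0.36)
  expect_equal(d1$est_m5c_hm5c, 0.30)
  # sampling noise below the BS level clamps to zero
  d2 <- deconvolve(mk(0.5), mk(0.4))
  expect_equal(d2$est_f5c_red, 0)
  # efficiency correction divides by rho
  d3 <- deconvolve(mk(0.30), mk(0.66), rho = 0.9)
  expect_equal(d3$est_f5c_red_corrected, 0.4)
  expect_error(deconvolve(mk(0.3), mk(0.4), rho = 0), "rho")
  # monotonicity of the difference estimator
  ests <- vapply(seq(0.3, 0.9, by = 0.1), function(r) {
    deconvolve(mk(0.3), mk(r))$est_f5c_red
  }, 0)
  expect_true(all(diff(ests) >= 0))
  ests_b <- vapply(seq(0.1, 0.6, by = 0.1), function(bl) {
    deconvolve(mk(bl), mk(0.66))$est_f5c_red
  }, 0)
  expect_true(all(diff(ests_b) <= 0))
})

test_that("condition comparison returns zero deltas on identical input", {
  mk <- function(level) {
    data.frame(gene_id = "g", seq_index = 0L, coverage = 100L,
               n_unconverted = round(level * 100),
               n_converted = 100L - round(level * 100), n_other = 0L,
               level = level)
  }
  d <- deconvolve(mk(0.3), mk(0.66), mk(0.68))
  cc <- compare_conditions(d, d)
  expect_equal(cc$delta_level_bs, 0)
  expect_equal(cc$delta_est_f5c_red, 0)
  expect_equal(cc$delta_est_f5c_fcab, 0)
})

test_that("ideal-chemistry deconvolution recovers composition mixtures", {
  b <- toy_mt_bundle()
  compositions <- list(c(C = 0.32, M5C = 0.30, F5C = 0.38),
                       c(C = 0.10, M5C = 0.10, HM5C = 0.10, F5C = 0.70),
                       c(C = 0.70, M5C = 0.25, F5C = 0.05))
  for (k in seq_along(compositions)) {
    comp <- compositions[[k]]
    full <- c(C = 0, M5C = 0, HM5C = 0, F5C = 0)
    full[names(comp)] <- comp
    pop <- sample_molecules(b, list(site_spec("MT-TM", 30, comp)), 1e4,
                            seed = 40 + k)
    lvls <- list()
    for (chem_name in c("BS", "RedBS", "fCAB")) {
      chem <- chemistry_spec(chem_name, rho = 1, pi_protect = 1, gamma = 0)
      fq <- tempfile(fileext = ".fastq")
      make_bs_library(pop, chem, seed = 50 + k, out_fastq = fq)
      lvls[[chem_name]] <- bs_call(fq, b, chem_name)$levels
    }
    d <- deconvolve(lvls$BS, lvls$RedBS, lvls$fCAB)
    row <- d[d$gene_id == "MT-TM" & d$seq_index == 30, ]
    mh <- full[["M5C"]] + full[["HM5C"]]
    protected <- mh + full[["F5C"]]
    se <- function(p) sqrt(p * (1 - p) / 1e4)
    expect_lt(abs(row$level_bs - mh), 3 * se(mh) + 1e-9)
    expect_lt(abs(row$level_redbs - protected), 3 * se(protected) + 1e-9)
    expect_lt(abs(row$est_f5c_red - full[["F5C"]]),
              3 * sqrt(se(mh)^2 + se(protected)^2) + 1e-9)
    expect_lt(abs(row$est_f5c_fcab - full[["F5C"]]),
              3 * sqrt(se(mh)^2 + se(protected)^2) + 1e-9)
  }
})

test_that("an unmodified wobble base shows no f5C and background BS level", {
  b <- toy_mt_bundle()
  gamma <- 0.005
  pop <- sample_molecules(b, list(site_spec("MT-TM", 30, c(C = 1))), 5000,
                          seed = 77)
  lvls <- list()
  for (chem_name in c("BS", "RedBS", "fCAB")) {
    chem <- chemistry_spec(chem_name, gamma = gamma)
    fq <- tempfile(fileext = ".fastq")
    make_bs_library(pop, chem, seed = 78, out_fastq = fq)
    lvls[[chem_name]] <- bs_call(fq, b, chem_name)$levels
  }
  d <- deconvolve(lvls$BS, lvls$RedBS, lvls$fCAB)
  row <- d[d$gene_id == "MT-TM" & d$seq_index == 30, ]
  se_g <- sqrt(gamma * (1 - gamma) / 5000)
  expect_lte(row$level_bs, gamma + 3 * se_g)
  expect_lte(row$est_f5c_red, 3 * row$se_f5c_red)
  expect_lte(row$est_f5c_fcab, 3 * row$se_f5c_fcab)
})
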