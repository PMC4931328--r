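#' Default end-to-end demo configuration
#'
#' Flat, fully explicit configuration for [run_end_to_end()]: every
#' effective parameter appears here and is written back as a resolved copy
#' next to the outputs. Analysis defaults are the protocol values: adapter
#' `AGATCGGAAGAGCGGTTCAG` trimmed with minimum overlap 4 at error rate
#' 0.06, minimum insert length 18 nt, truncation search window +/-2 nt,
#' high confidence above 50 RPM in at least 2 of 3 replicates, minimum
#' bisulfite coverage 5x, exact-test dispersion 0.1.
#'
#' @param outdir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Named list of configuration sections.
#' @export
default_config <- function(outdir = tempfile("mtfivec_run_"), seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    miclip = list(n_replicates = 3L, n_cdna = 4000L, barcode = "ACCG",
                  adapter = "AGATCGGAAGAGCGGTTCAG", min_len = 18L,
                  window = 2L, threshold_rpm = 50, min_replicates = 2L),
    bs = list(n_molecules = 2000L, gamma = 0.005, rho = 0.9,
              pi_protect = 0.9, min_coverage = 5L, dedup_mode = "without"),
    hitsclip = list(dispersion = 0.1, case_target_mean = 400,
                    background_mean = 40, min_len = 21L))
}

validate_config <- function(config) {
  template <- default_config()
  check_keys <- function(x, tpl, where) {
    extra <- setdiff(names(x), names(tpl))
    if (length(extra)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
    missing <- setdiff(names(tpl), names(x))
    if (length(missing)) {
      stop("missing config key(s) in ", where, ": ",
           paste(missing, collapse = ", "))
    }
  }
  check_keys(config, template, "top level")
  for (sec in c("miclip", "bs", "hitsclip")) {
    check_keys(config[[sec]], template[[sec]], sec)
  }
  if (config$miclip$min_replicates > config$miclip$n_replicates) {
    stop("min_replicates exceeds n_replicates")
  }
  invisible(config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full simulate-call-deconvolve demo pipeline
#'
#' Simulates, from the bundled toy mitochondrial reference, three miCLIP
#' replicates, BS/RedBS/fCAB libraries for a wild-type and a
#' methyltransferase-null condition, and a HITS-CLIP case/control pair;
#' then runs every caller and writes the site table, composition shares,
#' per-chemistry level tables, deconvolution and condition-difference
#' tables, the enrichment table, a truth-versus-estimate recovery table
#' and the resolved configuration (YAML) into `config$outdir`. Fully
#' deterministic for a given seed.
#'
#' @param config Configuration list, see [default_config()].
#' @return Invisibly, a list with all result objects and output paths.
#' @export
run_end_to_end <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  seed <- config$seed
  bundle <- toy_mt_bundle(seed = 42L)  # fixed toy reference

  ## miCLIP: three replicates from the demo crosslink composition
  mspec <- miclip_spec(crosslink_weights = bundle$demo_sites)
  fq <- character(config$miclip$n_replicates)
  for (r in seq_len(config$miclip$n_replicates)) {
    fq[r] <- out(sprintf("miclip_rep%d.fastq", r))
    make_miclip_library(bundle, mspec, config$miclip$n_cdna,
                        seed = seed + 100L * r, out_fastq = fq[r],
                        truth_out = out(sprintf("miclip_rep%d_truth.tsv", r)))
  }
  mc <- miclip_call(fq, bundle, barcode = config$miclip$barcode,
                    adapter = config$miclip$adapter,
                    min_len = config$miclip$min_len,
                    window = config$miclip$window,
                    threshold_rpm = config$miclip$threshold_rpm,
                    min_replicates = config$miclip$min_replicates)
  write_tsv(mc$site_table, out("miclip_sites.tsv"))
  write_sites_bed(mc$site_table, out("miclip_sites_highconf.bed"))
  write_tsv(mc$composition, out("miclip_composition.tsv"))

  ## bisulfite family: wt and methyltransferase-null populations at the
  ## MT-TM wobble base
  wob <- bundle$layouts$anticodon_start[bundle$layouts$gene_id == "MT-TM"]
  pops <- list(
    wt = sample_molecules(bundle,
                          list(site_spec("MT-TM", wob,
                                         wt_wobble_composition())),
                          config$bs$n_molecules, seed = seed + 11L),
    mut = sample_molecules(bundle, list(site_spec("MT-TM", wob, c(C = 1))),
                           config$bs$n_molecules, seed = seed + 12L))
  calls <- list()
  k <- 0L
  for (cond in names(pops)) {
    for (chem_name in CHEMISTRIES) {
      k <- k + 1L
      chem <- chemistry_spec(chem_name, rho = config$bs$rho,
                             pi_protect = config$bs$pi_protect,
                             gamma = config$bs$gamma)
      fqb <- out(sprintf("bs_%s_%s.fastq", cond, chem_name))
      make_bs_library(pops[[cond]], chem, seed = seed + 20L + k,
                      out_fastq = fqb,
                      truth_out = out(sprintf("bs_%s_%s_truth.tsv", cond,
                                              chem_name)))
      cl <- bs_call(fqb, bundle, chem_name,
                    dedup_mode = config$bs$dedup_mode,
                    min_coverage = config$bs$min_coverage)
      write_tsv(cl$levels, out(sprintf("levels_%s_%s.tsv", cond, chem_name)))
      calls[[paste(cond, chem_name, sep = "_")]] <- cl
    }
  }
  dec <- list()
  for (cond in names(pops)) {
    dec[[cond]] <- deconvolve(calls[[paste0(cond, "_BS")]]$levels,
                              calls[[paste0(cond, "_RedBS")]]$levels,
                              calls[[paste0(cond, "_fCAB")]]$levels,
                              rho = config$bs$rho,
                              pi_protect = config$bs$pi_protect)
    write_tsv(dec[[cond]], out(sprintf("deconvolution_%s.tsv", cond)))
  }
  delta <- compare_conditions(dec$wt, dec$mut)
  write_tsv(delta, out("wt_vs_mut.tsv"))

  ## truth-vs-estimate recovery at the wobble site
  truth <- pops$wt$truth
  est <- dec$wt[dec$wt$gene_id == "MT-TM" & dec$wt$seq_index == wob, ]
  recovery <- data.frame(
    quantity = c("m5c_hm5c", "f5c_red", "f5c_fcab"),
    truth = c(truth$frac_M5C + truth$frac_HM5C, truth$frac_F5C,
              truth$frac_F5C),
    estimate = c(est$est_m5c_hm5c, est$est_f5c_red, est$est_f5c_fcab))
  write_tsv(recovery, out("recovery_wobble.tsv"))

  ## HITS-CLIP: MT-TM-enriched case vs flat control
  genes <- bundle$annotations$gene_id
  case_means <- stats::setNames(rep(config$hitsclip$background_mean,
                                    length(genes)), genes)
  case_means["MT-TM"] <- config$hitsclip$case_target_mean
  ctrl_means <- stats::setNames(rep(config$hitsclip$background_mean,
                                    length(genes)), genes)
  make_hitsclip_library(bundle, case_means, config$hitsclip$dispersion,
                        seed = seed + 61L, out_fastq = out("clip_case.fastq"))
  make_hitsclip_library(bundle, ctrl_means, config$hitsclip$dispersion,
                        seed = seed + 62L,
                        out_fastq = out("clip_control.fastq"))
  ht <- hitsclip_test(out("clip_case.fastq"), out("clip_control.fastq"),
                      bundle, dispersion = config$hitsclip$dispersion,
                      min_len = config$hitsclip$min_len)
  write_tsv(ht$table, out("hitsclip_enrichment.tsv"))

  yaml::write_yaml(config, out("resolved_config.yaml"))
  invisible(list(config = config, bundle = bundle, miclip = mc,
                 bs_calls = calls, deconvolution = dec, delta = delta,
                 recovery = recovery, hitsclip = ht,
                 outdir = config$outdir))
}
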