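#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a `Genome` object: a named list of
#' uppercase DNA contig sequences. RNA input is accepted — `U` is mapped to
#' `T` at load time so that all downstream logic operates on the DNA
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @param allow_n Allow `N` bases (for user-supplied references). Defaults to
#'   `FALSE`: bundled and simulated references never contain `N`.
#' @return A `Genome` object (named character vector of contig sequences,
#'   names taken from the first word of each FASTA header).
#' @export
load_fasta <- function(path, allow_n = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- nm
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(nm[!nzchar(seqs)], collapse = ", "))
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ", paste(nm[bad], collapse = ", "))
  }
  as_genome(seqs)
}

#' Construct a Genome object from named contig sequences
#'
#' @param contigs Named character vector of contig sequences.
#' @return A `Genome` object.
#' @export
as_genome <- function(contigs) {
  stopifnot(is.character(contigs), !is.null(names(contigs)),
            !anyDuplicated(names(contigs)), all(nzchar(contigs)))
  structure(contigs, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x), "contig(s):\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

contig_length <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  nchar(genome[[contig]])
}

#' Load gene annotations from BED6
#'
#' Parses a BED6 file (0-based half-open intervals; the name column is the
#' gene identifier, the score column is ignored) with an optional seventh
#' column giving the biotype (`tRNA`, `mRNA`, `rRNA` or `other`; default
#' `other`). When a `Genome` is supplied, intervals are validated against
#' contig bounds.
#'
#' @param path Path to a BED file.
#' @param genome Optional `Genome` used for bounds validation.
#' @return A data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` and `biotype`.
#' @export
load_annotations <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_annotations())
  fields <- strsplit(lines, "\t| +")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 6L) {
      stop(sprintf("line %d: expected >= 6 BED columns, got %d", i, length(f)))
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start < 0L || start >= end) {
      stop(sprintf("line %d: invalid interval [%s, %s)", i, f[2L], f[3L]))
    }
    if (!f[6L] %in% c("+", "-")) {
      stop(sprintf("line %d: unknown strand '%s'", i, f[6L]))
    }
    biotype <- if (length(f) >= 7L) f[7L] else "other"
    if (!biotype %in% c("tRNA", "mRNA", "rRNA", "other")) {
      stop(sprintf("line %d: unknown biotype '%s'", i, biotype))
    }
    data.frame(gene_id = f[4L], contig = f[1L], start = start, end = end,
               strand = f[6L], biotype = biotype, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  }
  if (!is.null(genome)) {
    for (i in seq_len(nrow(ann))) {
      len <- contig_length(genome, ann$contig[i])
      if (ann$end[i] > len) {
        stop(sprintf("line %d: end %d beyond contig %s length %d",
                     i, ann$end[i], ann$contig[i], len))
      }
    }
  }
  ann
}

empty_annotations <- function() {
  data.frame(gene_id = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             biotype = character(), stringsAsFactors = FALSE)
}

#' Load tRNA structural layouts
#'
#' Reads a tab-separated table with header columns `gene_id`,
#' `anticodon_start` (0-based sequential index of the first anticodon base —
#' the wobble position, universal position 34 — within the mature tRNA) and
#' `length` (nt).
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `gene_id`, `anticodon_start`, `length`.
#' @export
load_layouts <- function(path) {
  lay <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_layouts(lay)
  lay
}

validate_layouts <- function(lay) {
  req <- c("gene_id", "anticodon_start", "length")
  if (!all(req %in% names(lay))) {
    stop("layout table must have columns: ", paste(req, collapse = ", "))
  }
  bad <- lay$anticodon_start < 0 | lay$anticodon_start > lay$length - 3
  if (any(bad)) {
    stop("anticodon_start out of range for: ",
         paste(lay$gene_id[bad], collapse = ", "))
  }
  invisible(lay)
}

#' Assemble a reference bundle
#'
#' Ties a genome, its gene annotations and tRNA layouts into a single
#' validated object: every layout must resolve to a tRNA annotation whose
#' width matches the layout length, and every annotation must fit its
#' contig.
#'
#' @param genome A `Genome`.
#' @param annotations Annotation data frame (see [load_annotations()]).
#' @param layouts Layout data frame (see [load_layouts()]); may be empty.
#' @return A `ReferenceBundle` (list with elements `genome`, `annotations`,
#'   `layouts`).
#' @export
reference_bundle <- function(genome, annotations,
                             layouts = data.frame(gene_id = character(),
                                                  anticodon_start = integer(),
                                                  length = integer())) {
  stopifnot(inherits(genome, "Genome"))
  for (i in seq_len(nrow(annotations))) {
    len <- contig_length(genome, annotations$contig[i])
    if (annotations$end[i] > len) {
      stop("annotation ", annotations$gene_id[i], " exceeds contig bounds")
    }
  }
  validate_layouts(layouts)
  for (i in seq_len(nrow(layouts))) {
    j <- match(layouts$gene_id[i], annotations$gene_id)
    if (is.na(j)) stop("layout for unknown gene: ", layouts$gene_id[i])
    if (annotations$biotype[j] != "tRNA") {
      stop("layout gene is not a tRNA: ", layouts$gene_id[i])
    }
    width <- annotations$end[j] - annotations$start[j]
    if (width != layouts$length[i]) {
      stop(sprintf("layout length %d != annotation width %d for %s",
                   layouts$length[i], width, layouts$gene_id[i]))
    }
  }
  structure(list(genome = genome, annotations = annotations,
                 layouts = layouts), class = "ReferenceBundle")
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat("ReferenceBundle:", length(x$genome), "contig(s),",
      nrow(x$annotations), "gene(s),", nrow(x$layouts), "tRNA layout(s)\n")
  invisible(x)
}

get_annotation <- function(bundle, gene_id) {
  i <- match(gene_id, bundle$annotations$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  bundle$annotations[i, , drop = FALSE]
}

#' Gene-internal index to genomic coordinate
#'
#' Converts a 0-based sequential position within a gene (transcript sense)
#' to the 1-based genomic coordinate used in reports, strand-aware: on the
#' plus strand base `i` of the transcript sits at `start + i + 1`; on the
#' minus strand at `end - i`.
#'
#' @param annotation A single-row annotation data frame.
#' @param seq_index 0-based index (vectorised) within the gene.
#' @return 1-based genomic coordinate(s).
#' @export
gene_to_genomic <- function(annotation, seq_index) {
  width <- annotation$end - annotation$start
  if (any(seq_index < 0 | seq_index >= width)) {
    stop("seq_index out of gene ", annotation$gene_id,
         " (width ", width, ")")
  }
  if (annotation$strand == "+") {
    annotation$start + seq_index + 1L
  } else {
    annotation$end - seq_index
  }
}

#' Genomic coordinate to gene-internal index
#'
#' Inverse of [gene_to_genomic()]: maps a 1-based genomic coordinate inside
#' a gene to its 0-based transcript-sense index.
#'
#' @param annotation A single-row annotation data frame.
#' @param genomic_pos 1-based genomic coordinate(s).
#' @return 0-based sequential index/indices.
#' @export
genomic_to_gene <- function(annotation, genomic_pos) {
  inside <- genomic_pos >= annotation$start + 1L &
    genomic_pos <= annotation$end
  if (any(!inside)) {
    stop("genomic position outside gene ", annotation$gene_id)
  }
  if (annotation$strand == "+") {
    genomic_pos - annotation$start - 1L
  } else {
    annotation$end - genomic_pos
  }
}

#' Genomic coordinate of a tRNA wobble base
#'
#' Returns the 1-based genomic coordinate of the first anticodon nucleotide
#' (universal tRNA position 34, the wobble base) of a tRNA gene, using the
#' gene's structural layout. For the human mitochondrial methionine tRNA
#' gene MT-TM annotated on the rCRS this is mtDNA position 4432.
#'
#' @param bundle A `ReferenceBundle`.
#' @param gene_id Gene identifier with a tRNA layout.
#' @return 1-based genomic coordinate of the wobble base.
#' @export
wobble_coordinate <- function(bundle, gene_id) {
  i <- match(gene_id, bundle$layouts$gene_id)
  if (is.na(i)) stop("no tRNA layout for gene: ", gene_id)
  ann <- get_annotation(bundle, gene_id)
  gene_to_genomic(ann, bundle$layouts$anticodon_start[i])
}

#' Transcript-sense gene sequence
#'
#' Extracts the mature transcript sequence of a gene (DNA alphabet): the
#' annotated interval on the plus strand, or its reverse complement for
#' minus-strand genes.
#'
#' @param bundle A `ReferenceBundle`.
#' @param gene_id Gene identifier.
#' @return Character scalar, the transcript-sense sequence.
#' @export
gene_sequence <- function(bundle, gene_id) {
  ann <- get_annotation(bundle, gene_id)
  s <- substr(bundle$genome[[ann$contig]], ann$start + 1L, ann$end)
  if (ann$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Reference bundle for the rCRS MT-TM coordinate check (synthetic sequence)
#'
#' Builds a single-contig bundle carrying the human mitochondrial
#' methionine-tRNA gene MT-TM at its published rCRS (NC_012920) boundaries,
#' 4402..4469 on the heavy strand, with the anticodon starting at sequential
#' index 30 so that the wobble base falls on mtDNA position 4432. The contig
#' sequence itself is synthetic (seeded random bases with a cytosine fixed
#' at 4432): the full rCRS sequence is deliberately not bundled, and every
#' coordinate computation on this bundle depends only on the annotation,
#' never on the surrounding sequence. Supply a genuine NC_012920 FASTA via
#' [load_fasta()] for work on real data.
#'
#' @param seed Integer seed for the synthetic filler sequence.
#' @return A `ReferenceBundle` with one gene, `MT-TM`.
#' @export
rcrs_mttm_bundle <- function(seed = 1L) {
  set.seed(seed)
  n <- 4600L
  seq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  seq[4432L] <- "C"
  g <- as_genome(c(chrM_synthetic = paste(seq, collapse = "")))
  ann <- data.frame(gene_id = "MT-TM", contig = "chrM_synthetic",
                    start = 4401L, end = 4469L, strand = "+",
                    biotype = "tRNA", stringsAsFactors = FALSE)
  lay <- data.frame(gene_id = "MT-TM", anticodon_start = 30L, length = 68L,
                    stringsAsFactors = FALSE)
  reference_bundle(g, ann, lay)
}
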