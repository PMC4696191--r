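#' Construct and validate a genome annotation
#'
#' A \code{GenomeAnnotation} couples contig sequences with a strand-aware gene
#' table. Coordinates are 1-based inclusive; \code{cds_start} is always the
#' numerically smaller end of the CDS interval, regardless of strand. The
#' translation start (first base of the start codon) is \code{cds_start} for
#' plus-strand genes and \code{cds_end} for minus-strand genes.
#'
#' @param contigs named character vector of contig DNA sequences (A/C/G/T).
#' @param genes data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{cds_start}, \code{cds_end},
#'   and optionally \code{cog_class} and \code{product}.
#' @param allow_n if \code{TRUE}, \code{N} bases are kept (they mismatch every
#'   consensus base when scanned); otherwise any non-ACGT base is an error.
#' @return an object of class \code{GenomeAnnotation}: a list with elements
#'   \code{contigs} and \code{genes}.
#' @export
genome_annotation <- function(contigs, genes, allow_n = FALSE) {
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    abort("contigs must be a named character vector")
  if (anyDuplicated(names(contigs)))
    abort("duplicate contig ids: ",
          paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(contigs)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, contigs)
  if (any(bad))
    abort("contig ", names(contigs)[bad][1L], " contains invalid bases",
          if (!allow_n) " (set allow_n = TRUE to keep N)" else "")

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "strand", "cds_start", "cds_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) abort("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (!"cog_class" %in% names(genes)) genes$cog_class <- NA_character_
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes <- genes[, c(need, "cog_class", "product")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig_id <- as.character(genes$contig_id)
  genes$strand <- as.character(genes$strand)
  genes$cds_start <- as.integer(genes$cds_start)
  genes$cds_end <- as.integer(genes$cds_end)
  genes$cog_class <- as.character(genes$cog_class)
  genes$product <- as.character(genes$product)

  if (anyDuplicated(genes$gene_id))
    abort("duplicate gene ids: ",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand))
    abort("malformed strand for gene ", genes$gene_id[bad_strand][1L],
          ": '", genes$strand[bad_strand][1L], "' (must be + or -)")
  unknown <- !genes$contig_id %in% names(contigs)
  if (any(unknown))
    abort("gene ", genes$gene_id[unknown][1L], " references missing contig ",
          genes$contig_id[unknown][1L])
  len <- nchar(contigs)[genes$contig_id]
  bad_coord <- is.na(genes$cds_start) | is.na(genes$cds_end) |
    genes$cds_start < 1L | genes$cds_end < genes$cds_start | genes$cds_end > len
  if (any(bad_coord))
    abort("invalid CDS coordinates for gene ", genes$gene_id[bad_coord][1L],
          " (must satisfy 1 <= cds_start <= cds_end <= contig length)")

  structure(list(contigs = contigs, genes = genes), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$contigs), "contig(s),",
      format(sum(nchar(x$contigs)), big.mark = ","), "bp,",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Translation start position of each gene, in contig coordinates
#'
#' @param genome a \code{GenomeAnnotation}.
#' @return named integer vector: \code{cds_start} for plus-strand genes,
#'   \code{cds_end} for minus-strand genes.
#' @export
translation_starts <- function(genome) {
  g <- genome$genes
  ifelse(g$strand == "+", g$cds_start, g$cds_end) |>
    as.integer() |>
    stats::setNames(g$gene_id)
}

#' Read a genome (FASTA contigs + gene table) into a GenomeAnnotation
#'
#' @param fasta_path path to a FASTA file of contig sequences.
#' @param genes_path path to the gene table: either a GFF3 file (CDS features,
#'   gene id taken from the \code{ID} attribute, COG from a \code{cog_class}
#'   attribute when present) or a TSV with header \code{gene_id, contig_id,
#'   strand, cds_start, cds_end, cog_class, product}.
#' @param dialect \code{"tsv"} or \code{"gff3"}.
#' @param allow_n passed to \code{\link{genome_annotation}}.
#' @return a validated \code{GenomeAnnotation}.
#' @export
read_genome <- function(fasta_path, genes_path, dialect = c("tsv", "gff3"),
                        allow_n = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(fasta_path)) abort("FASTA file not found: ", fasta_path)
  if (!file.exists(genes_path)) abort("gene table not found: ", genes_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- stats::setNames(as.character(dna), sub("\\s.*$", "", names(dna)))

  if (dialect == "tsv") {
    genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                               colClasses = "character")
    need <- c("gene_id", "contig_id", "strand", "cds_start", "cds_end")
    miss <- setdiff(need, names(genes))
    if (length(miss))
      abort("gene TSV lacks columns: ", paste(miss, collapse = ", "))
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      abort("reading GFF3 requires the rtracklayer package")
    gr <- as.data.frame(rtracklayer::import(genes_path, format = "gff3"))
    gr <- gr[gr$type == "CDS", , drop = FALSE]
    if (!nrow(gr)) abort("no CDS features in ", genes_path)
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(ids == ""))
      abort("GFF3 CDS features must carry an ID attribute")
    genes <- data.frame(
      gene_id = ids,
      contig_id = as.character(gr$seqnames),
      strand = as.character(gr$strand),
      cds_start = gr$start,
      cds_end = gr$end,
      cog_class = if ("cog_class" %in% names(gr)) as.character(gr$cog_class) else NA_character_,
      product = if ("product" %in% names(gr)) as.character(gr$product) else NA_character_,
      stringsAsFactors = FALSE
    )
    if (any(!genes$strand %in% c("+", "-")))
      abort("GFF3 CDS with strand '",
            genes$strand[!genes$strand %in% c("+", "-")][1L],
            "': only +/- supported")
  }
  genome_annotation(contigs, genes, allow_n = allow_n)
}

#' Write a GenomeAnnotation back to FASTA + gene TSV
#'
#' Inverse of \code{\link{read_genome}} with \code{dialect = "tsv"}; a write
#' followed by a read reproduces the annotation exactly.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param fasta_path,genes_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, genes_path) {
  stopifnot(inherits(genome, "GenomeAnnotation"))
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta_path)
  write_table(genome$genes, genes_path)
  invisible(c(fasta = fasta_path, genes = genes_path))
}

#' Construct and validate a count matrix with its experimental design
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param gene_length_nt named numeric vector of CDS lengths in nucleotides.
#' @param condition_of named character vector mapping each sample id to
#'   \code{"wt"} or \code{"mut"}.
#' @return an object of class \code{CountMatrix}.
#' @export
count_matrix <- function(counts, gene_length_nt, condition_of) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must have gene rownames and sample colnames")
  if (anyNA(counts)) abort("counts contain NA")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    abort("negative count at gene ", rownames(counts)[idx[1L]],
          ", sample ", colnames(counts)[idx[2L]])
  }
  if (any(counts != floor(counts))) {
    idx <- which(counts != floor(counts), arr.ind = TRUE)[1L, ]
    abort("non-integer count at gene ", rownames(counts)[idx[1L]],
          ", sample ", colnames(counts)[idx[2L]])
  }
  storage.mode(counts) <- "double"   # keeps large totals exact enough

  miss <- setdiff(rownames(counts), names(gene_length_nt))
  if (length(miss))
    abort("genes missing from the length table: ",
          paste(utils::head(miss, 5L), collapse = ", "))
  gene_length_nt <- gene_length_nt[rownames(counts)]
  if (any(gene_length_nt < 1)) abort("gene lengths must be >= 1 nt")

  miss_s <- setdiff(colnames(counts), names(condition_of))
  if (length(miss_s))
    abort("samples missing from the design: ", paste(miss_s, collapse = ", "))
  condition_of <- condition_of[colnames(counts)]
  if (any(!condition_of %in% c("wt", "mut")))
    abort("conditions must be 'wt' or 'mut'")
  if (length(unique(condition_of)) < 2L)
    abort("need at least one sample in each of the wt and mut conditions")

  structure(list(counts = counts, gene_length_nt = gene_length_nt,
                 condition_of = condition_of), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      sum(x$condition_of == "wt"), "wt /", sum(x$condition_of == "mut"), "mut )\n")
  invisible(x)
}

#' Read a count matrix and its design from TSV files
#'
#' @param tsv_path counts TSV: first column \code{gene_id}, a
#'   \code{length_nt} column, then one integer column per sample.
#' @param design_path design TSV with columns \code{sample_id} and
#'   \code{condition} (\code{wt}/\code{mut}).
#' @return a validated \code{CountMatrix}.
#' @export
read_counts <- function(tsv_path, design_path) {
  if (!file.exists(tsv_path)) abort("counts file not found: ", tsv_path)
  if (!file.exists(design_path)) abort("design file not found: ", design_path)
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "length_nt") %in% names(tab)))
    abort("counts TSV must have gene_id and length_nt columns")
  des <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(des)))
    abort("design TSV must have sample_id and condition columns")
  sample_cols <- setdiff(names(tab), c("gene_id", "length_nt"))
  if (!length(sample_cols)) abort("counts TSV has no sample columns")
  m <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    abort("non-numeric count at row ", bad[1L, 1L], ", column ",
          sample_cols[bad[1L, 2L]])
  }
  rownames(m) <- tab$gene_id
  count_matrix(m,
               gene_length_nt = stats::setNames(as.numeric(tab$length_nt), tab$gene_id),
               condition_of = stats::setNames(des$condition, des$sample_id))
}

#' Write a result table as TSV with stable formatting
#'
#' Columns keep their order; selected numeric columns are formatted at fixed
#' precision so outputs are byte-stable across runs (log2 fold changes to 3
#' decimals, identity percentages to 1, other reals to 6 significant digits).
#'
#' @param records data.frame (may have zero rows: a header-only file results).
#' @param path output path.
#' @param precision named integer vector of decimal places overriding the
#'   defaults, e.g. \code{c(log2fc = 3, identity_pct = 1)}.
#' @return invisibly, \code{path}.
#' @export
write_table <- function(records, path,
                        precision = c(log2fc = 3, identity_pct = 1,
                                      pct_up = 2, pct_down = 2,
                                      pct_of_significant = 2,
                                      classification_rate_pct = 2)) {
  if (is.null(records)) abort("records must be non-null")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- records
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (nm %in% names(precision)) {
      out[[nm]] <- formatC(out[[nm]], format = "f", digits = precision[[nm]])
    } else if (!all(out[[nm]] == floor(out[[nm]]), na.rm = TRUE)) {
      out[[nm]] <- formatC(out[[nm]], format = "g", digits = 6)
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) abort("cannot write table to ", path, ": ",
                         conditionMessage(ok))
  invisible(path)
}
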