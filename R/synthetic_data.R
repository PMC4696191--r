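#' Generate a random multi-contig genome with strand-alternating genes
#'
#' Contig sequences are i.i.d. bases at the given GC content (default 0.606,
#' typical of rhizobial genomes). Each contig carries
#' \code{genes_per_contig} genes of \code{gene_nt} nt separated (and flanked)
#' by \code{intergenic_nt} nt of intergenic sequence, on alternating strands.
#' The default intergenic spacing of 700 nt keeps the default promoter
#' windows (300 up / 150 down) of neighbouring genes disjoint, so planted
#' motifs never collide.
#'
#' @param n_contigs,genes_per_contig,intergenic_nt,gene_nt layout parameters.
#' @param gc GC content in (0, 1).
#' @param seed RNG seed.
#' @return a \code{GenomeAnnotation}; gene ids are \code{g<contig>_<index>}.
#' @export
generate_genome <- function(n_contigs = 2, genes_per_contig = 30,
                            intergenic_nt = 700, gene_nt = 900,
                            gc = 0.606, seed = 1) {
  if (n_contigs < 1 || genes_per_contig < 1 || intergenic_nt < 1 || gene_nt < 1)
    abort("layout parameters must be positive")
  if (gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contig_len <- intergenic_nt + genes_per_contig * (gene_nt + intergenic_nt)

  contigs <- character(n_contigs)
  genes <- vector("list", n_contigs)
  for (ci in seq_len(n_contigs)) {
    contigs[ci] <- paste(sample(names(probs), contig_len, replace = TRUE,
                                prob = probs), collapse = "")
    start <- intergenic_nt + 1L + (seq_len(genes_per_contig) - 1L) *
      (gene_nt + intergenic_nt)
    genes[[ci]] <- data.frame(
      gene_id = sprintf("g%d_%d", ci, seq_len(genes_per_contig)),
      contig_id = sprintf("contig_%d", ci),
      strand = rep_len(c("+", "-"), genes_per_contig),
      cds_start = start,
      cds_end = start + gene_nt - 1L,
      cog_class = NA_character_,
      product = "synthetic gene",
      stringsAsFactors = FALSE
    )
  }
  genome_annotation(stats::setNames(contigs, sprintf("contig_%d", seq_len(n_contigs))),
                    do.call(rbind, genes))
}

#' Degenerate copy of a consensus with an exact number of mismatches
#'
#' Mutates exactly \code{n_mismatches_outside} distinct non-excluded positions
#' to a different base, so the resulting identity is
#' 100 * (18 - n) / 18 exactly for the default RosR-box (n = 6 gives 66.7,
#' the modal identity of curated genomic matches; n = 5 gives 72.2).
#'
#' @param consensus a \code{\link{consensus_motif}}.
#' @param n_mismatches_outside number of non-excluded positions to mutate.
#' @param seed RNG seed; \code{NULL} continues the current RNG stream.
#' @return DNA string of the consensus length.
#' @export
make_degenerate_motif <- function(consensus = rosr_box(),
                                  n_mismatches_outside = 0, seed = 1) {
  keep <- setdiff(seq_len(consensus$length), consensus$excluded_positions)
  if (n_mismatches_outside < 0 || n_mismatches_outside > length(keep))
    abort("n_mismatches_outside must be in 0..", length(keep))
  s <- strsplit(consensus$sequence, "")[[1]]
  if (n_mismatches_outside > 0) {
    if (!is.null(seed)) set.seed(seed)
    pos <- sample(keep, n_mismatches_outside)
    for (p in pos)
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  }
  paste(s, collapse = "")
}

#' Overwrite genome bases with a motif at a gene-local position
#'
#' Places \code{motif} so that its 5'-most base (in gene orientation) sits at
#' gene-local position \code{distance_nt} (start codon = 0, negative
#' upstream). For \code{strand = "-"} the motif's reverse complement is
#' written in gene orientation, so both-strand scanning recovers it as a
#' minus-strand hit at the same position. Only containment within the contig
#' is checked; whether the position falls inside a scan window is the
#' scanner's concern.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param gene_id target gene.
#' @param motif DNA string to plant.
#' @param distance_nt gene-local position of the motif's 5'-most base.
#' @param strand \code{"+"} or \code{"-"} relative to the gene.
#' @return the modified \code{GenomeAnnotation}.
#' @export
plant_motif <- function(genome, gene_id, motif, distance_nt, strand = "+") {
  stopifnot(inherits(genome, "GenomeAnnotation"))
  motif <- check_dna(motif, "motif")
  if (!strand %in% c("+", "-")) abort("strand must be + or -")
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) abort("unknown gene: ", gene_id)
  g <- genome$genes[i, ]
  L <- nchar(motif)
  # bases written in gene orientation
  oriented <- if (strand == "+") motif else reverse_complement(motif)

  if (g$strand == "+") {
    ts <- g$cds_start
    from <- ts + distance_nt
    to <- from + L - 1L
    written <- oriented
  } else {
    ts <- g$cds_end
    # gene-local d .. d+L-1 maps to contig ts-d-L+1 .. ts-d, reverse strand
    to <- ts - distance_nt
    from <- to - L + 1L
    written <- reverse_complement(oriented)
  }
  contig <- genome$contigs[[g$contig_id]]
  if (from < 1L || to > nchar(contig))
    abort("motif would extend past contig ", g$contig_id,
          " (positions ", from, "-", to, ")")
  substr(contig, from, to) <- written
  genome$contigs[[g$contig_id]] <- contig
  genome
}

#' Simulate a negative-binomial count matrix for a two-condition design
#'
#' count(g, s) ~ NB(mean mu, variance mu + dispersion * mu^2) with
#' mu = lib_factor(s) * base_mean(g) * 2^(true_log2fc(g) * [s is mut]);
#' dispersion 0 degenerates to Poisson. Samples are named
#' \code{wt_1..wt_n, mut_1..mut_n}.
#'
#' @param truth data.frame with columns \code{gene_id}, \code{base_mean},
#'   \code{true_log2fc}, \code{length_nt} (see \code{\link{make_scenario}}).
#' @param n_reps_per_condition replicates per condition (>= 2).
#' @param dispersion NB overdispersion phi >= 0.
#' @param library_sizes per-sample scale factors, length 2 * n_reps (default
#'   all 1).
#' @param seed RNG seed.
#' @return a \code{\link{count_matrix}}.
#' @export
simulate_counts <- function(truth, n_reps_per_condition = 3, dispersion = 0.05,
                            library_sizes = NULL, seed = 1) {
  if (n_reps_per_condition < 2) abort("need >= 2 replicates per condition")
  if (dispersion < 0) abort("dispersion must be >= 0")
  n <- n_reps_per_condition
  samples <- c(paste0("wt_", seq_len(n)), paste0("mut_", seq_len(n)))
  cond <- stats::setNames(rep(c("wt", "mut"), each = n), samples)
  if (is.null(library_sizes)) library_sizes <- rep(1, 2L * n)
  if (length(library_sizes) != 2L * n)
    abort("library_sizes must have one entry per sample")

  set.seed(seed)
  ng <- nrow(truth)
  counts <- matrix(0, ng, 2L * n, dimnames = list(truth$gene_id, samples))
  for (s in seq_len(2L * n)) {
    mu <- library_sizes[s] * truth$base_mean *
      2^(truth$true_log2fc * (cond[s] == "mut"))
    counts[, s] <- if (dispersion == 0) stats::rpois(ng, mu)
                   else stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
  }
  count_matrix(counts,
               gene_length_nt = stats::setNames(truth$length_nt, truth$gene_id),
               condition_of = cond)
}

#' Default synthetic-scenario parameters
#'
#' The defaults emulate the shape of a wild-type vs regulator-mutant RNA-Seq
#' study on a rhizobial genome: 3+3 replicates, ~15 % of genes differentially
#' expressed with 63.2 % of them up-regulated in the mutant, |log2fc| between
#' 2 and 5, negative-binomial dispersion 0.05, base means log-normal with
#' median 1000 (DE genes redrawn until >= 200 so every planted effect is
#' detectable at this depth), GC 0.606, and ~18 % of DE genes made direct
#' targets by planting high-identity consensus copies (0-2 mismatches) in
#' their promoter windows on either strand. Library-size factors are
#' log-normal (sdlog 0.1) to exercise normalization.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    n_contigs = 2, genes_per_contig = 30, intergenic_nt = 700, gene_nt = 900,
    gc = 0.606,
    n_reps = 3, dispersion = 0.05,
    frac_de = 0.15, frac_up = 0.632,
    lfc_range = c(2, 5),
    base_mean_meanlog = log(1000), base_mean_sdlog = 0.7,
    de_min_base_mean = 200,
    lib_sdlog = 0.1,
    frac_direct = 0.18,
    plant_mismatches = 0:2,
    plant_distance_range = c(-280, 100),
    cog_classes = c("J", "K", "L", "M", "N", "O", "C", "G", "E", "F", "H",
                    "I", "P", "Q", "R", "S", "T", "U", "V"),
    frac_cog_assigned = 0.895,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    abort("unknown scenario parameters: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Build a fully consistent synthetic study (genome, truth, counts)
#'
#' Generates a genome, assigns COG classes, chooses DE genes and their fold
#' changes, plants consensus motifs in the promoters of the designated direct
#' targets, and simulates counts. Optionally writes FASTA + TSV fixtures.
#'
#' @param config a \code{\link{scenario_config}} list.
#' @param consensus the motif to plant.
#' @param outdir if non-NULL, write \code{genome.fasta}, \code{genes.tsv},
#'   \code{counts.tsv}, \code{design.tsv}, \code{truth.tsv} there.
#' @return list with \code{genome} (motifs planted), \code{counts}
#'   (a \code{CountMatrix}) and \code{truth} (data.frame: \code{gene_id},
#'   \code{base_mean}, \code{true_log2fc}, \code{is_de}, \code{length_nt},
#'   \code{cog_class}, \code{planted}, \code{planted_sequence},
#'   \code{planted_distance}, \code{planted_strand},
#'   \code{planted_identity_pct}).
#' @export
make_scenario <- function(config = scenario_config(), consensus = rosr_box(),
                          outdir = NULL) {
  set.seed(config$seed)
  genome <- generate_genome(config$n_contigs, config$genes_per_contig,
                            config$intergenic_nt, config$gene_nt,
                            config$gc, seed = config$seed + 1L)
  ids <- genome$genes$gene_id
  ng <- length(ids)

  # COG assignment: ~frac_cog_assigned of genes get 1 class, a few compound
  assigned <- stats::runif(ng) < config$frac_cog_assigned
  cogs <- rep(NA_character_, ng)
  cogs[assigned] <- sample(config$cog_classes, sum(assigned), replace = TRUE)
  compound <- assigned & stats::runif(ng) < 0.1
  cogs[compound] <- paste0(cogs[compound],
                           sample(config$cog_classes, sum(compound), replace = TRUE))
  genome$genes$cog_class <- cogs

  # base means: log-normal, median exp(meanlog); DE genes redrawn to >= floor
  base_mean <- stats::rlnorm(ng, config$base_mean_meanlog, config$base_mean_sdlog)
  n_de <- round(config$frac_de * ng)
  de_idx <- sample.int(ng, n_de)
  is_de <- seq_len(ng) %in% de_idx
  while (any(is_de & base_mean < config$de_min_base_mean)) {
    low <- which(is_de & base_mean < config$de_min_base_mean)
    base_mean[low] <- stats::rlnorm(length(low), config$base_mean_meanlog,
                                    config$base_mean_sdlog)
  }

  lfc <- rep(0, ng)
  up <- stats::runif(n_de) < config$frac_up
  mag <- stats::runif(n_de, config$lfc_range[1], config$lfc_range[2])
  lfc[de_idx] <- ifelse(up, mag, -mag)

  # direct targets: planted motifs among DE genes
  n_direct <- round(config$frac_direct * n_de)
  direct_idx <- de_idx[sample.int(n_de, n_direct)]
  planted <- data.frame(gene_id = ids, planted = FALSE,
                        planted_sequence = NA_character_,
                        planted_distance = NA_integer_,
                        planted_strand = NA_character_,
                        planted_identity_pct = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in direct_idx) {
    mm_pool <- config$plant_mismatches
    nmm <- mm_pool[sample.int(length(mm_pool), 1L)]
    motif <- make_degenerate_motif(consensus, nmm, seed = NULL)
    d_pool <- config$plant_distance_range[1]:config$plant_distance_range[2]
    d <- d_pool[sample.int(length(d_pool), 1L)]
    strand <- sample(c("+", "-"), 1L)
    genome <- plant_motif(genome, ids[i], motif, d, strand)
    planted$planted[i] <- TRUE
    planted$planted_sequence[i] <- motif
    planted$planted_distance[i] <- d
    planted$planted_strand[i] <- strand
    planted$planted_identity_pct[i] <- identity_score(motif, consensus)$identity_pct
  }

  truth <- data.frame(gene_id = ids, base_mean = base_mean,
                      true_log2fc = lfc, is_de = is_de,
                      length_nt = genome$genes$cds_end - genome$genes$cds_start + 1L,
                      cog_class = cogs, stringsAsFactors = FALSE)
  truth <- cbind(truth, planted[, -1L])

  lib <- stats::rlnorm(2L * config$n_reps, 0, config$lib_sdlog)
  counts <- simulate_counts(truth, config$n_reps, config$dispersion,
                            library_sizes = lib, seed = config$seed + 2L)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(outdir, "genome.fasta"),
                 file.path(outdir, "genes.tsv"))
    ctab <- data.frame(gene_id = rownames(counts$counts),
                       length_nt = counts$gene_length_nt,
                       counts$counts, check.names = FALSE,
                       stringsAsFactors = FALSE)
    write_table(ctab, file.path(outdir, "counts.tsv"))
    write_table(data.frame(sample_id = names(counts$condition_of),
                           condition = counts$condition_of,
                           stringsAsFactors = FALSE),
                file.path(outdir, "design.tsv"))
    write_table(truth, file.path(outdir, "truth.tsv"))
  }
  list(genome = genome, counts = counts, truth = truth)
}
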