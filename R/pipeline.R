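#' Default pipeline configuration
#'
#' One flat list holding every tunable of the analysis: promoter window
#' bounds, identity threshold and denominator convention, FDR level, fold
#' change threshold, FPKM pseudocount and seeds. Values are validated against
#' each stage's preconditions before anything runs.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
run_config <- function(...) {
  cfg <- list(
    upstream_nt = 300, downstream_nt = 150,
    min_identity_pct = 50, search_both_strands = TRUE,
    identity_denominator = "excluded",
    alpha = 0.05, lfc_threshold = 0, pseudo_fpkm = 0.5,
    top_n = 100,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    abort("unknown config parameters: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$upstream_nt < 0 || cfg$downstream_nt < 0)
    abort("window extents must be nonnegative")
  if (cfg$min_identity_pct < 0 || cfg$min_identity_pct > 100)
    abort("min_identity_pct must be in [0, 100]")
  if (!cfg$identity_denominator %in% c("excluded", "full"))
    abort("identity_denominator must be 'excluded' or 'full'")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1)")
  if (cfg$lfc_threshold < 0) abort("lfc_threshold must be >= 0")
  if (cfg$pseudo_fpkm < 0) abort("pseudo_fpkm must be >= 0")
  invisible(cfg)
}

#' Run the full regulon analysis and write its tables
#'
#' Chains the stages on an annotated genome and count matrix: FPKM + NB
#' differential expression with BH-FDR, up/down summary, COG breakdown,
#' genome-wide promoter scan for the consensus, regulon integration and
#' repressor scoring. Writes one TSV per stage plus a manifest recording
#' every threshold used, and logs one line per stage to standard error.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param counts a \code{CountMatrix}.
#' @param outdir output directory (created if needed).
#' @param config a \code{\link{run_config}} list.
#' @param consensus the binding-site consensus to scan for.
#' @return invisibly, a list with \code{de}, \code{direction}, \code{cog},
#'   \code{hits}, \code{regulon}, \code{repressor}, \code{top_fpkm} and
#'   \code{manifest}.
#' @export
run_all <- function(genome, counts, outdir, config = run_config(),
                    consensus = rosr_box()) {
  stopifnot(inherits(genome, "GenomeAnnotation"),
            inherits(counts, "CountMatrix"))
  validate_run_config(config)
  missing_genes <- setdiff(rownames(counts$counts), genome$genes$gene_id)
  if (length(missing_genes))
    abort("pre-flight: counts contain genes absent from the genome: ",
          paste(utils::head(missing_genes, 5L), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[rosregulon] ", ...)

  de <- de_test(counts, pseudo_fpkm = config$pseudo_fpkm)
  de <- classify_de(de, alpha = config$alpha,
                    lfc_threshold = config$lfc_threshold)
  write_table(de, file.path(outdir, "de_results.tsv"))
  log_stage("de: ", nrow(de), " genes tested, ",
            sum(de$status != "ns"), " significant")

  direction <- summarize_direction(de)
  write_table(data.frame(n_significant = direction$n_significant,
                         pct_up = direction$pct_up,
                         pct_down = direction$pct_down),
              file.path(outdir, "direction_summary.tsv"))

  cog <- breakdown_by_cog(de, genome)
  write_table(cog$table, file.path(outdir, "cog_summary.tsv"))
  log_stage("cog: ", cog$n_classified, " classified (",
            cog$classification_rate_pct, "%)")

  window <- promoter_window(config$upstream_nt, config$downstream_nt)
  hits <- scan_genome(genome, consensus, window,
                      min_identity_pct = config$min_identity_pct,
                      search_both_strands = config$search_both_strands,
                      denominator = config$identity_denominator)
  write_table(hits, file.path(outdir, "motif_hits.tsv"))
  log_stage("scan: ", nrow(hits), " motif-bearing genes of ",
            nrow(genome$genes))

  regulon <- integrate_regulon(de, hits, genome)
  write_table(regulon, file.path(outdir, "regulon.tsv"))
  rep_score <- if (any(regulon$regulation_class == "direct"))
    repressor_score(regulon) else NULL
  log_stage("regulon: ", nrow(regulon), " records, ",
            sum(regulon$regulation_class == "direct"), " direct")

  fpkm <- compute_fpkm(counts)
  top <- top_n_by_abs_lfc(de, fpkm, n = config$top_n)
  write_table(data.frame(gene_id = rownames(top), top, check.names = FALSE),
              file.path(outdir, "top_fpkm.tsv"))

  manifest <- data.frame(parameter = names(config),
                         value = vapply(config, function(x)
                           paste(format(x), collapse = ","), ""),
                         stringsAsFactors = FALSE)
  manifest <- rbind(manifest,
                    data.frame(parameter = c("consensus", "n_genes", "n_samples"),
                               value = c(consensus$sequence,
                                         nrow(genome$genes),
                                         ncol(counts$counts)),
                               stringsAsFactors = FALSE))
  write_table(manifest, file.path(outdir, "manifest.tsv"))

  invisible(list(de = de, direction = direction, cog = cog, hits = hits,
                 regulon = regulon, repressor = rep_score, top_fpkm = top,
                 manifest = manifest))
}
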