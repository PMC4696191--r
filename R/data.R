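#' Curated RosR-regulon motif records
#'
#' Reported promoter-window matches to the RosR-box for differentially
#' expressed genes of R. leguminosarum bv. trifolii Rt24.2 / Rt2472:
#' gene id, putative product, COG class, log2 fold change (mutant over wild
#' type), the matched sequence as printed 5'-3' (a few records carry '-' gap
#' characters or lengths of 21/23 nt), the reported percent identity to the
#' consensus and the distance of the match to the translation start site.
#' These records are reference inputs for validating the identity metric:
#' most reproduce under the canonical rule (skip the 4 central consensus
#' positions, denominator 18); a minority are consistent with a
#' full-length (/22) denominator instead and are kept as printed.
#'
#' @return data.frame with columns \code{gene_id}, \code{product},
#'   \code{cog_class}, \code{log2fc}, \code{motif}, \code{identity_pct},
#'   \code{distance_nt}.
#' @export
rosr_regulon_records <- function() {
  path <- system.file("extdata", "rosr_regulon_motifs.tsv",
                      package = "rosregulon", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
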