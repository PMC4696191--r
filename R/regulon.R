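#' Join differential expression with promoter motif hits into regulon records
#'
#' One record per significant gene. A gene is a \emph{direct} candidate target
#' when its promoter window carries a qualifying consensus match (a row in
#' \code{hits}); otherwise its regulation is \emph{indirect} (e.g. mediated by
#' another regulator that is itself a direct target). Records are sorted by
#' COG class then descending |log2fc|.
#'
#' @param de classified \code{DEResult} rows (see \code{\link{classify_de}}).
#' @param hits best-hit table from \code{\link{scan_genome}}.
#' @param genome a \code{GenomeAnnotation} supplying product and COG columns.
#' @return data.frame with columns \code{gene_id}, \code{product},
#'   \code{cog_class}, \code{log2fc}, \code{status}, \code{matched_sequence},
#'   \code{match_strand}, \code{identity_pct}, \code{distance_nt},
#'   \code{regulation_class}.
#' @export
integrate_regulon <- function(de, hits, genome) {
  stopifnot(inherits(genome, "GenomeAnnotation"))
  if (anyNA(de$status)) abort("statuses not set; run classify_de first")
  if (anyDuplicated(hits$gene_id))
    abort("duplicate gene_id in hits: ",
          paste(unique(hits$gene_id[duplicated(hits$gene_id)]), collapse = ", "))
  sig <- de[de$status %in% c("up", "down"), , drop = FALSE]
  g <- genome$genes
  idx <- match(sig$gene_id, g$gene_id)
  if (anyNA(idx))
    abort("significant genes missing from the genome: ",
          paste(sig$gene_id[is.na(idx)][1L], collapse = ", "))
  h <- match(sig$gene_id, hits$gene_id)

  rec <- data.frame(
    gene_id = sig$gene_id,
    product = g$product[idx],
    cog_class = g$cog_class[idx],
    log2fc = sig$log2fc,
    status = sig$status,
    matched_sequence = ifelse(is.na(h), NA_character_, hits$matched_sequence[h]),
    match_strand = ifelse(is.na(h), NA_character_, hits$match_strand[h]),
    identity_pct = ifelse(is.na(h), NA_real_, hits$identity_pct[h]),
    distance_nt = ifelse(is.na(h), NA_integer_, hits$distance_nt[h]),
    regulation_class = ifelse(is.na(h), "indirect", "direct"),
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$cog_class, -abs(rec$log2fc), rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Fraction of direct targets up-regulated in the mutant
#'
#' For a repressor, loss of the regulator de-represses its direct targets, so
#' a fraction above 0.5 labels the regulator predominantly repressing.
#'
#' @param records \code{\link{integrate_regulon}} output with >= 1 direct
#'   record.
#' @return list with \code{fraction_up} in [0, 1], \code{n_direct} and
#'   \code{label} (\code{"predominantly repressing"} or
#'   \code{"predominantly activating"}).
#' @export
repressor_score <- function(records) {
  direct <- records[records$regulation_class == "direct", , drop = FALSE]
  if (!nrow(direct)) abort("no direct records: cannot score the regulator")
  frac <- sum(direct$status == "up") / nrow(direct)
  list(fraction_up = frac, n_direct = nrow(direct),
       label = if (frac > 0.5) "predominantly repressing"
               else "predominantly activating")
}
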