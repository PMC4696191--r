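#' Split a COG class label into constituent letters
#'
#' Compound labels such as "NT" contribute to both N and T. NA, "" and "-"
#' mean unclassified.
#' @keywords internal
#' @noRd
cog_letters <- function(x) {
  if (is.na(x) || x == "" || x == "-") return(character())
  strsplit(toupper(x), "")[[1]]
}

#' Functional (COG) breakdown of up- and down-regulated genes
#'
#' Joins significant genes to their COG assignments and counts up- and
#' down-regulated genes per one-letter class. A gene with a compound class
#' (e.g. "NT") is counted once under every constituent letter; genes with no
#' assignment are unclassified. The classification rate is the percentage of
#' significant genes carrying at least one COG letter.
#'
#' @param results classified \code{DEResult} rows (see
#'   \code{\link{classify_de}}).
#' @param genome a \code{GenomeAnnotation} supplying \code{cog_class} per
#'   gene.
#' @return object of class \code{CogBreakdown}: list with \code{table}
#'   (data.frame \code{cog_class}, \code{n_up}, \code{n_down},
#'   \code{pct_of_significant}), \code{n_classified}, \code{n_unclassified},
#'   \code{classification_rate_pct}.
#' @export
breakdown_by_cog <- function(results, genome) {
  stopifnot(inherits(genome, "GenomeAnnotation"))
  if (anyNA(results$status)) abort("statuses not set; run classify_de first")
  sig <- results[results$status %in% c("up", "down"), , drop = FALSE]
  missing <- setdiff(sig$gene_id, genome$genes$gene_id)
  if (length(missing))
    abort("genes in results missing from the genome: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  cogs <- genome$genes$cog_class[match(sig$gene_id, genome$genes$gene_id)]

  n_sig <- nrow(sig)
  letters_per_gene <- lapply(cogs, cog_letters)
  classified <- lengths(letters_per_gene) > 0
  n_classified <- sum(classified)
  n_unclassified <- n_sig - n_classified

  tab <- data.frame(cog_class = character(), n_up = integer(),
                    n_down = integer(), pct_of_significant = numeric(),
                    stringsAsFactors = FALSE)
  if (n_classified > 0) {
    long <- data.frame(
      cog = unlist(letters_per_gene),
      status = rep(sig$status, lengths(letters_per_gene)),
      stringsAsFactors = FALSE
    )
    up <- table(factor(long$cog[long$status == "up"], levels = sort(unique(long$cog))))
    down <- table(factor(long$cog[long$status == "down"], levels = sort(unique(long$cog))))
    tab <- data.frame(cog_class = names(up),
                      n_up = as.integer(up),
                      n_down = as.integer(down),
                      stringsAsFactors = FALSE)
    tab$pct_of_significant <-
      round_half_up(100 * (tab$n_up + tab$n_down) / n_sig, 2)
  }
  structure(list(table = tab, n_classified = n_classified,
                 n_unclassified = n_unclassified,
                 classification_rate_pct = if (n_sig > 0)
                   round_half_up(100 * n_classified / n_sig, 2) else 0),
            class = "CogBreakdown")
}

#' @export
print.CogBreakdown <- function(x, ...) {
  cat("CogBreakdown:", x$n_classified, "classified /", x$n_unclassified,
      "unclassified (", x$classification_rate_pct, "% )\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Dominant regulation direction within one COG class
#'
#' @param breakdown a \code{\link{breakdown_by_cog}} result.
#' @param cog one-letter class.
#' @return list with \code{direction} (\code{"mostly_up"},
#'   \code{"mostly_down"} or \code{"balanced"}) and \code{pct_down}.
#' @export
dominant_direction <- function(breakdown, cog) {
  stopifnot(inherits(breakdown, "CogBreakdown"))
  row <- breakdown$table[breakdown$table$cog_class == cog, , drop = FALSE]
  if (!nrow(row)) abort("COG class not present: ", cog)
  n <- row$n_up + row$n_down
  if (n == 0) abort("COG class ", cog, " has no classified genes")
  frac_up <- row$n_up / n
  dir <- if (frac_up > 0.5) "mostly_up" else if (frac_up < 0.5) "mostly_down" else "balanced"
  list(direction = dir, pct_down = round_half_up(100 * row$n_down / n, 1),
       n_up = row$n_up, n_down = row$n_down)
}
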