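# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except the curated motif records shipped in extdata.

# A deterministic "periodic" contig whose base at position i is known in
# closed form, so coordinate arithmetic can be checked by hand.
periodic_contig <- function(n, period = c("A", "C", "G", "T")) {
  paste(rep_len(period, n), collapse = "")
}

# Tiny two-gene genome on one contig; gene "plus" starts at 1001 (+ strand),
# gene "minus" has its translation start (cds_end) at 2400.
tiny_genome <- function(contig_len = 3000) {
  genome_annotation(
    contigs = c(chr = periodic_contig(contig_len)),
    genes = data.frame(
      gene_id = c("plus", "minus"),
      contig_id = "chr",
      strand = c("+", "-"),
      cds_start = c(1001L, 2001L),
      cds_end = c(1900L, 2400L),
      cog_class = c("K", "NT"),
      product = c("regulator", "chemotaxis protein"),
      stringsAsFactors = FALSE
    )
  )
}

# Count matrix with explicit per-condition count vectors (one vector per
# gene and condition), equal gene lengths and identity-normalizable totals.
counts_from_rows <- function(wt, mut, length_nt = 1000) {
  stopifnot(nrow(wt) == nrow(mut))
  m <- cbind(wt, mut)
  rownames(m) <- sprintf("gene%02d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("wt_", seq_len(ncol(wt))),
                   paste0("mut_", seq_len(ncol(mut))))
  count_matrix(
    m,
    gene_length_nt = stats::setNames(rep(length_nt, nrow(m)), rownames(m)),
    condition_of = stats::setNames(rep(c("wt", "mut"), c(ncol(wt), ncol(mut))),
                                   colnames(m))
  )
}

# Independent per-position identity oracle: a plain loop over positions that
# skips 10-13, kept deliberately separate from the package implementation.
oracle_identity <- function(query, consensus_seq = "CGGAATCTAGGGGTGGATTTCG",
                            excluded = 10:13) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(consensus_seq, "")[[1]]
  n <- 0L
  for (p in seq_along(s)) {
    if (p %in% excluded) next
    if (q[p] == s[p]) n <- n + 1L
  }
  n
}

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
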