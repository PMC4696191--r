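#' The RosR-box binding consensus
#'
#' RosR, a Cys2His2 zinc-finger regulator of Rhizobium leguminosarum bv.
#' trifolii, binds a 22-bp site (the RosR-box). Reported percent identities of
#' genomic matches to this consensus skip its 4 central positions (10-13 of
#' the 22-mer), so the comparison spans 18 positions.
#'
#' @param sequence consensus DNA string.
#' @param name motif name.
#' @param excluded_positions 1-based positions excluded from identity scoring;
#'   default the middle 4 for a 22-mer.
#' @param pseudocount pseudocount for PWM construction (single-sequence
#'   consensus, so every off-consensus base has count 0).
#' @param background per-base background probabilities (named A/C/G/T, sums
#'   to 1).
#' @return an object of class \code{ConsensusMotif}.
#' @export
consensus_motif <- function(sequence = "CGGAATCTAGGGGTGGATTTCG",
                            name = "RosR-box",
                            excluded_positions = NULL,
                            pseudocount = 0.25,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sequence <- check_dna(sequence, "consensus")
  L <- nchar(sequence)
  if (is.null(excluded_positions)) {
    mid <- L %/% 2
    excluded_positions <- (mid - 1L):(mid + 2L)  # 10..13 for L = 22
  }
  excluded_positions <- sort(unique(as.integer(excluded_positions)))
  if (length(excluded_positions) &&
      (min(excluded_positions) < 1L || max(excluded_positions) > L))
    abort("excluded_positions must lie in 1..", L)
  if (length(excluded_positions) >= L)
    abort("cannot exclude every consensus position")
  if (pseudocount < 0) abort("pseudocount must be nonnegative")
  if (!all(c("A", "C", "G", "T") %in% names(background)))
    abort("background must be named with A, C, G, T")
  background <- background[c("A", "C", "G", "T")]
  if (any(background <= 0)) abort("background probabilities must be positive")
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  structure(list(name = name, sequence = sequence, length = L,
                 excluded_positions = excluded_positions,
                 pseudocount = pseudocount, background = background),
            class = "ConsensusMotif")
}

#' @rdname consensus_motif
#' @export
rosr_box <- function() consensus_motif()

#' @export
print.ConsensusMotif <- function(x, ...) {
  cat("ConsensusMotif", x$name, ": 5'-", x$sequence, "-3' (", x$length,
      " nt, positions ", paste(range(x$excluded_positions), collapse = "-"),
      " excluded from identity)\n", sep = "")
  invisible(x)
}

#' Promoter window relative to the translation start
#'
#' The scanned region spans \code{upstream_nt} bases upstream through
#' \code{downstream_nt} bases downstream of the first base of the start codon
#' (gene-local position 0); negative gene-local coordinates are upstream.
#'
#' @param upstream_nt,downstream_nt nonnegative window extents in nt.
#' @return an object of class \code{PromoterWindow}.
#' @export
promoter_window <- function(upstream_nt = 300, downstream_nt = 150) {
  if (upstream_nt < 0 || downstream_nt < 0)
    abort("window extents must be nonnegative")
  structure(list(upstream_nt = as.integer(upstream_nt),
                 downstream_nt = as.integer(downstream_nt)),
            class = "PromoterWindow")
}

#' Percent identity to a consensus, excluding its central positions
#'
#' Counts matching positions between an ungapped query and the consensus over
#' all non-excluded positions (18 of 22 for the RosR-box) and reports
#' \code{100 * matches / n_compared} rounded half-up to one decimal. With
#' \code{denominator = "full"} the percentage is taken over the full motif
#' length instead (matching still skips excluded positions), an alternative
#' convention seen in some reported values.
#'
#' @param query DNA string, same length and orientation as the consensus.
#' @param consensus a \code{\link{consensus_motif}}.
#' @param denominator \code{"excluded"} (default: L - |excluded|) or
#'   \code{"full"} (L).
#' @return list with \code{n_matches}, \code{n_compared}, \code{identity_pct}.
#' @examples
#' identity_score("CGGCTTCAAGGCGCTGAATTCG", rosr_box())  # 12 matches, 66.7
#' @export
identity_score <- function(query, consensus = rosr_box(),
                           denominator = c("excluded", "full")) {
  denominator <- match.arg(denominator)
  if (!is.character(query) || length(query) != 1L)
    abort("query must be a single string")
  query <- toupper(query)
  if (nchar(query) != consensus$length)
    abort("query length ", nchar(query), " != consensus length ",
          consensus$length, " (use gapped_identity for indels)")
  q <- strsplit(query, "")[[1]]
  s <- strsplit(consensus$sequence, "")[[1]]
  keep <- setdiff(seq_len(consensus$length), consensus$excluded_positions)
  n_matches <- sum(q[keep] == s[keep])
  n_compared <- if (denominator == "excluded") length(keep) else consensus$length
  list(n_matches = n_matches, n_compared = n_compared,
       identity_pct = round_half_up(100 * n_matches / n_compared, 1))
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T (N allowed; complements to N).
#' @return the Watson-Crick reverse complement.
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    abort("seq must be a single string")
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) abort("seq contains non-ACGT bases")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a gene's promoter window in gene orientation
#'
#' Returns the sequence covering gene-local positions \code{-upstream_nt}
#' through \code{downstream_nt - 1} (start codon first base = 0), truncated at
#' contig ends. Minus-strand genes yield the reverse complement of the
#' corresponding contig slice, so the returned string always reads 5' to 3'
#' in the gene's own orientation.
#'
#' @param genome a \code{GenomeAnnotation}.
#' @param gene_id gene to extract.
#' @param window a \code{\link{promoter_window}}.
#' @return list with \code{sequence} and \code{offset_of_first_base} (the
#'   gene-local coordinate of the first returned base; \code{-upstream_nt}
#'   when untruncated).
#' @export
extract_promoter_window <- function(genome, gene_id,
                                    window = promoter_window()) {
  stopifnot(inherits(genome, "GenomeAnnotation"))
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) abort("unknown gene: ", gene_id)
  g <- genome$genes[i, ]
  contig <- genome$contigs[[g$contig_id]]
  len <- nchar(contig)
  up <- window$upstream_nt; down <- window$downstream_nt

  if (g$strand == "+") {
    ts <- g$cds_start                       # local d <-> contig ts + d
    dmin <- max(-up, 1L - ts)
    dmax <- min(down - 1L, len - ts)
    if (dmax < dmin) return(list(sequence = "", offset_of_first_base = dmin))
    seq <- substr(contig, ts + dmin, ts + dmax)
  } else {
    ts <- g$cds_end                         # local d <-> contig ts - d
    dmin <- max(-up, ts - len)
    dmax <- min(down - 1L, ts - 1L)
    if (dmax < dmin) return(list(sequence = "", offset_of_first_base = dmin))
    seq <- reverse_complement(substr(contig, ts - dmax, ts - dmin))
  }
  list(sequence = seq, offset_of_first_base = as.integer(dmin))
}

#' Scan one promoter window for consensus matches
#'
#' Slides the consensus-length frame over every position of the window
#' sequence, scoring the forward frame and (optionally) its reverse
#' complement. Frames at or above \code{min_identity_pct} are returned sorted
#' by descending identity, ties by ascending \code{|distance_nt|}, then plus
#' strand first.
#'
#' @param window_seq gene-oriented window sequence.
#' @param offset gene-local coordinate of the first base of \code{window_seq}.
#' @param consensus a \code{\link{consensus_motif}}.
#' @param min_identity_pct retain hits with identity at or above this value.
#' @param search_both_strands also score the reverse complement of each frame.
#' @param denominator see \code{\link{identity_score}}.
#' @return data.frame of hits: \code{matched_sequence} (gene orientation),
#'   \code{match_strand} (relative to the gene), \code{distance_nt} (5'-most
#'   base, start codon = 0), \code{n_compared}, \code{n_matches},
#'   \code{identity_pct}, \code{pwm_logodds}.
#' @export
scan_gene <- function(window_seq, offset, consensus = rosr_box(),
                      min_identity_pct = 50, search_both_strands = TRUE,
                      denominator = c("excluded", "full")) {
  denominator <- match.arg(denominator)
  if (min_identity_pct < 0 || min_identity_pct > 100)
    abort("min_identity_pct must be in [0, 100]")
  L <- consensus$length
  n <- nchar(window_seq)
  empty <- data.frame(matched_sequence = character(), match_strand = character(),
                      distance_nt = integer(), n_compared = integer(),
                      n_matches = integer(), identity_pct = numeric(),
                      pwm_logodds = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)

  seqc <- strsplit(toupper(window_seq), "")[[1]]
  cons <- strsplit(consensus$sequence, "")[[1]]
  comp_cons <- chartr("ACGT", "TGCA", cons)
  keep <- setdiff(seq_len(L), consensus$excluded_positions)
  n_cmp <- if (denominator == "excluded") length(keep) else L
  pwm <- build_pwm(consensus)
  nf <- n - L + 1L                           # number of frames
  frame0 <- seq_len(nf) - 1L
  base_of <- match(seqc, c("A", "C", "G", "T"))  # NA for N

  # Per consensus position p, compare all frames at once: frame i covers
  # window positions i+1 .. i+L, so position p of frame i is seqc[i + p].
  nm_fwd <- integer(nf); nm_rev <- integer(nf)
  po_fwd <- numeric(nf); po_rev <- numeric(nf)
  for (p in keep) {
    sl <- seqc[frame0 + p]
    nm_fwd <- nm_fwd + (sl == cons[p])
    b <- base_of[frame0 + p]
    po_fwd <- po_fwd + ifelse(is.na(b), 0, pwm[p, ][b])
    # reverse-complement frame: its position p is the complement of the
    # frame's base at offset L + 1 - p
    sl_rc <- seqc[frame0 + (L + 1L - p)]
    nm_rev <- nm_rev + (sl_rc == comp_cons[p])
    b_rc <- base_of[frame0 + (L + 1L - p)]
    # rc base at p = complement of sl_rc: complement index = 5 - index
    po_rev <- po_rev + ifelse(is.na(b_rc), 0, pwm[p, ][5L - b_rc])
  }
  pct_fwd <- round_half_up(100 * nm_fwd / n_cmp, 1)
  pct_rev <- round_half_up(100 * nm_rev / n_cmp, 1)

  frame_seq <- function(i) paste(seqc[(i + 1L):(i + L)], collapse = "")
  sel_f <- which(pct_fwd >= min_identity_pct)
  sel_r <- if (search_both_strands) which(pct_rev >= min_identity_pct) else integer()
  if (!length(sel_f) && !length(sel_r)) return(empty)
  hits <- data.frame(
    matched_sequence = vapply(c(sel_f, sel_r) - 1L, frame_seq, ""),
    match_strand = c(rep("+", length(sel_f)), rep("-", length(sel_r))),
    distance_nt = as.integer(offset + c(sel_f, sel_r) - 1L),
    n_compared = rep(as.integer(n_cmp), length(sel_f) + length(sel_r)),
    n_matches = as.integer(c(nm_fwd[sel_f], nm_rev[sel_r])),
    identity_pct = c(pct_fwd[sel_f], pct_rev[sel_r]),
    pwm_logodds = c(po_fwd[sel_f], po_rev[sel_r]),
    stringsAsFactors = FALSE
  )
  ord <- order(-hits$identity_pct, abs(hits$distance_nt),
               hits$match_strand != "+")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Best promoter-window consensus match per gene, genome-wide
#'
#' Applies \code{\link{scan_gene}} to every gene's promoter window and keeps
#' the top hit per gene; genes with no hit at or above the threshold are
#' omitted.
#'
#' @inheritParams scan_gene
#' @param genome a \code{GenomeAnnotation}.
#' @param window a \code{\link{promoter_window}}.
#' @return data.frame with one row per motif-bearing gene: \code{gene_id} plus
#'   the \code{\link{scan_gene}} hit columns.
#' @export
scan_genome <- function(genome, consensus = rosr_box(),
                        window = promoter_window(), min_identity_pct = 50,
                        search_both_strands = TRUE,
                        denominator = c("excluded", "full")) {
  stopifnot(inherits(genome, "GenomeAnnotation"))
  denominator <- match.arg(denominator)
  res <- lapply(genome$genes$gene_id, function(gid) {
    w <- extract_promoter_window(genome, gid, window)
    hits <- scan_gene(w$sequence, w$offset_of_first_base, consensus,
                      min_identity_pct, search_both_strands, denominator)
    if (!nrow(hits)) return(NULL)
    cbind(gene_id = gid, hits[1L, , drop = FALSE], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), matched_sequence = character(),
                      match_strand = character(), distance_nt = integer(),
                      n_compared = integer(), n_matches = integer(),
                      identity_pct = numeric(), pwm_logodds = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Position weight matrix of a consensus motif
#'
#' Log2-odds PWM from the single consensus sequence with pseudocounts:
#' cell (p, b) = log2(((count_b(p) + pseudocount) / (1 + 4 pseudocount)) /
#' background_b). The PWM score of a sequence sums the cells of its bases over
#' non-excluded positions.
#'
#' @param consensus a \code{\link{consensus_motif}}.
#' @return L x 4 numeric matrix, columns A, C, G, T.
#' @export
build_pwm <- function(consensus) {
  stopifnot(inherits(consensus, "ConsensusMotif"))
  pc <- consensus$pseudocount
  if (pc <= 0)
    abort("pseudocount must be positive for a single-sequence consensus")
  bases <- c("A", "C", "G", "T")
  s <- strsplit(consensus$sequence, "")[[1]]
  counts <- outer(s, bases, `==`) * 1
  probs <- (counts + pc) / (1 + 4 * pc)
  pwm <- log2(sweep(probs, 2, consensus$background, `/`))
  dimnames(pwm) <- list(NULL, bases)
  pwm
}

#' PWM log-odds score of a sequence over non-excluded positions
#'
#' @param query DNA string of the consensus length.
#' @param consensus a \code{\link{consensus_motif}}.
#' @return numeric log2-odds score.
#' @export
pwm_score <- function(query, consensus = rosr_box()) {
  query <- toupper(query)
  if (nchar(query) != consensus$length)
    abort("query length must equal consensus length")
  pwm <- build_pwm(consensus)
  q <- strsplit(query, "")[[1]]
  keep <- setdiff(seq_len(consensus$length), consensus$excluded_positions)
  idx <- match(q[keep], c("A", "C", "G", "T"))
  if (anyNA(idx)) abort("query contains non-ACGT bases")
  sum(pwm[cbind(keep, idx)])
}

#' Identity of a near-consensus-length query allowing a small indel
#'
#' Some reported motif matches carry a single-base gap relative to the 22-nt
#' consensus. This aligns a query whose length differs from the consensus by
#' at most \code{max_indels} using a global alignment (match +1, mismatch 0,
#' gap -1, at most \code{max_indels} gaps) and scores identity over the
#' consensus columns with a gap counting as a mismatch; the denominator is
#' unchanged (L - |excluded| for the canonical rule). For equal lengths it
#' reduces to \code{\link{identity_score}}. All admissible gap placements are
#' enumerated (the motif is short); among equal-scoring alignments the
#' rightmost gap is reported, so a deletion inside a homopolymer run is
#' assigned to the run's last position.
#'
#' @param query DNA string of length L-max_indels .. L+max_indels.
#' @param consensus a \code{\link{consensus_motif}}.
#' @param max_indels maximum number of gaps (default 1; only 0/1 supported).
#' @param denominator see \code{\link{identity_score}}.
#' @return list with \code{alignment} (character 2-vector: aligned query,
#'   aligned consensus), \code{n_matches}, \code{n_compared},
#'   \code{identity_pct}.
#' @export
gapped_identity <- function(query, consensus = rosr_box(), max_indels = 1,
                            denominator = c("excluded", "full")) {
  denominator <- match.arg(denominator)
  if (max_indels > 1) abort("only max_indels <= 1 is supported")
  query <- toupper(query)
  L <- consensus$length
  dlen <- nchar(query) - L
  if (abs(dlen) > max_indels)
    abort("query length differs from consensus by ", abs(dlen),
          " (> max_indels = ", max_indels, ")")
  s <- strsplit(consensus$sequence, "")[[1]]
  keep <- setdiff(seq_len(L), consensus$excluded_positions)
  n_cmp <- if (denominator == "excluded") length(keep) else L

  score_cols <- function(qcols) {
    # qcols: query characters aligned to consensus columns 1..L ("-" = gap)
    n_matches <- sum(qcols[keep] == s[keep])
    list(n_matches = n_matches,
         identity_pct = round_half_up(100 * n_matches / n_cmp, 1))
  }

  if (dlen == 0L) {
    q <- strsplit(query, "")[[1]]
    sc <- score_cols(q)
    return(list(alignment = c(query, consensus$sequence),
                n_matches = sc$n_matches, n_compared = n_cmp,
                identity_pct = sc$identity_pct))
  }

  q <- strsplit(query, "")[[1]]
  best <- NULL
  if (dlen == -1L) {
    # deletion in the query: a '-' at one consensus column
    for (g in seq_len(L)) {
      qcols <- append(q, "-", after = g - 1L)
      sc <- score_cols(qcols)
      align_score <- sum(qcols == s) - 1L   # matches +1, one gap -1
      if (is.null(best) || align_score >= best$align_score) {
        best <- list(align_score = align_score, qcols = qcols,
                     scols = s, sc = sc)
      }
    }
  } else {
    # insertion in the query: a '-' at one position of the consensus row
    for (g in seq_len(L + 1L)) {
      scols <- append(s, "-", after = g - 1L)
      qrow <- q
      # consensus columns are the non-gap positions of scols
      cons_cols <- which(scols != "-")
      qcols <- qrow[cons_cols]
      sc <- score_cols(qcols)
      align_score <- sum(qcols == s) - 1L
      if (is.null(best) || align_score >= best$align_score) {
        best <- list(align_score = align_score, qcols = qrow,
                     scols = scols, sc = sc)
      }
    }
  }
  list(alignment = c(paste(best$qcols, collapse = ""),
                     paste(best$scols, collapse = "")),
       n_matches = best$sc$n_matches, n_compared = n_cmp,
       identity_pct = best$sc$identity_pct)
}
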