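test_that("identity metric reproduces curated regulon records", {
  rec <- rosr_regulon_records()
  # the six records whose printed identity follows the canonical rule
  verified <- c(Rt620_77 = 66.7, Rt648_25 = 66.7, Rt620_4 = 66.7,
                Rt794_16 = 66.7, Rt794_99 = 72.2, Rt643_15 = 72.2)
  for (g in names(verified)) {
    m <- rec$motif[rec$gene_id == g]
    expect_equal(identity_score(m)$identity_pct, verified[[g]], label = g)
  }
  expect_equal(identity_score("CGGCTTCAAGGCGCTGAATTCG")$n_matches, 12L)
})

test_that("identity_score agrees with an independent per-position loop", {
  cons <- rosr_box()
  set.seed(101)
  for (i in 1:50) {
    q <- random_dna(22)
    got <- identity_score(q, cons)
    n <- oracle_identity(q)
    expect_equal(got$n_matches, n)
    expect_equal(got$identity_pct, floor(1000 * n / 18 + 0.5) / 10)
  }
})

test_that("excluded positions never affect the score; non-excluded mismatches each cost one step", {
  cons <- rosr_box()
  expect_equal(identity_score(cons$sequence, cons)$identity_pct, 100)
  s <- strsplit(cons$sequence, "")[[1]]
  for (p in 10:13) {
    q <- s; q[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
    expect_equal(identity_score(paste(q, collapse = ""), cons)$identity_pct, 100)
  }
  keep <- setdiff(1:22, 10:13)
  set.seed(7)
  for (k in c(1, 3, 7, 18)) {
    q <- s
    for (p in sample(keep, k)) q[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
    got <- identity_score(paste(q, collapse = ""), cons)
    expect_equal(got$n_matches, 18L - k)
  }
  expect_error(identity_score("ACGT", cons), "length")
})

test_that("full-length denominator convention is exposed", {
  cons <- rosr_box()
  got <- identity_score(cons$sequence, cons, denominator = "full")
  expect_equal(got$n_compared, 22L)
  expect_equal(got$identity_pct, floor(1000 * 18 / 22 + 0.5) / 10)  # 81.8
})

test_that("reverse_complement is a correct involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("CGGAATCTAGGGGTGGATTTCG"),
               "CGAAATCCACCCCTAGATTCCG")
  set.seed(11)
  for (i in 1:10) {
    q <- random_dna(30)
    expect_equal(reverse_complement(reverse_complement(q)), q)
  }
  expect_error(reverse_complement("ACGU"), "non-ACGT")
})

test_that("promoter windows are extracted with correct coordinates and truncation", {
  gen <- tiny_genome()
  w <- extract_promoter_window(gen, "plus")
  expect_equal(nchar(w$sequence), 450L)
  expect_equal(w$offset_of_first_base, -300L)
  # contig is periodic ACGT...: position 1001 - 300 = 701 is 'A' (701 %% 4 = 1)
  expect_equal(w$sequence, substr(gen$contigs[["chr"]], 701, 1150))

  near_edge <- genome_annotation(
    c(chr = periodic_contig(500)),
    data.frame(gene_id = "edge", contig_id = "chr", strand = "+",
               cds_start = 50, cds_end = 400)
  )
  w2 <- extract_promoter_window(near_edge, "edge")
  expect_equal(w2$offset_of_first_base, -49L)
  expect_equal(nchar(w2$sequence), 49L + 150L)
  expect_error(extract_promoter_window(gen, "nope"), "unknown gene")
})

test_that("minus-strand windows are the reverse complement of the mirrored slice", {
  gen <- tiny_genome()
  # translation start of "minus" is cds_end = 2400; window local -300..149
  # covers contig 2251..2700, read on the reverse strand
  w <- extract_promoter_window(gen, "minus")
  expect_equal(w$offset_of_first_base, -300L)
  expect_equal(w$sequence,
               reverse_complement(substr(gen$contigs[["chr"]], 2251, 2700)))
  # plant a recognizable marker upstream of the minus-strand gene and find it
  gen2 <- plant_motif(gen, "minus", "CGGAATCTAGGGGTGGATTTCG", -50, "+")
  w2 <- extract_promoter_window(gen2, "minus")
  expect_equal(substr(w2$sequence, -50 - w2$offset_of_first_base + 1,
                      -50 - w2$offset_of_first_base + 22),
               "CGGAATCTAGGGGTGGATTTCG")
})

test_that("scan_gene finds planted motifs on both strands and honors the threshold", {
  gen <- plant_motif(tiny_genome(), "plus", rosr_box()$sequence, -100, "+")
  w <- extract_promoter_window(gen, "plus")
  hits <- scan_gene(w$sequence, w$offset_of_first_base, min_identity_pct = 95)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity_pct, 100)
  expect_equal(hits$distance_nt, -100L)
  expect_equal(hits$match_strand, "+")

  gen2 <- plant_motif(tiny_genome(), "plus", rosr_box()$sequence, -100, "-")
  w2 <- extract_promoter_window(gen2, "plus")
  hits2 <- scan_gene(w2$sequence, w2$offset_of_first_base, min_identity_pct = 95)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$match_strand, "-")
  expect_equal(hits2$distance_nt, -100L)
  # the stored sequence is in gene orientation: its reverse complement is
  # the consensus itself
  expect_equal(reverse_complement(hits2$matched_sequence), rosr_box()$sequence)

  polyA <- paste(rep("A", 100), collapse = "")
  expect_equal(nrow(scan_gene(polyA, -50, min_identity_pct = 100)), 0L)
  expect_error(scan_gene(polyA, -50, min_identity_pct = 101), "min_identity_pct")
})

test_that("hits re-scored from their stored sequence reproduce identity (strand-aware)", {
  set.seed(23)
  gen <- plant_motif(tiny_genome(), "plus",
                     make_degenerate_motif(n_mismatches_outside = 4, seed = 5),
                     -120, "-")
  w <- extract_promoter_window(gen, "plus")
  hits <- scan_gene(w$sequence, w$offset_of_first_base, min_identity_pct = 0)
  for (i in seq_len(nrow(hits))) {
    seq_i <- if (hits$match_strand[i] == "+") hits$matched_sequence[i]
             else reverse_complement(hits$matched_sequence[i])
    expect_equal(identity_score(seq_i)$identity_pct, hits$identity_pct[i])
  }
  # sorted by identity desc, |distance| asc, plus strand first
  expect_true(all(diff(hits$identity_pct) <= 0))
})

test_that("scan_genome keeps the single best hit per gene and honors the window", {
  gen <- generate_genome(n_contigs = 1, genes_per_contig = 5, seed = 3)
  ids <- gen$genes$gene_id
  gen <- plant_motif(gen, ids[2], rosr_box()$sequence, -150, "+")
  gen <- plant_motif(gen, ids[4], make_degenerate_motif(n_mismatches_outside = 1,
                                                        seed = 2), 40, "-")
  hits <- scan_genome(gen, min_identity_pct = 90)
  expect_setequal(hits$gene_id, ids[c(2, 4)])
  expect_equal(hits$distance_nt[hits$gene_id == ids[2]], -150L)
  expect_equal(hits$distance_nt[hits$gene_id == ids[4]], 40L)
  expect_equal(hits$match_strand[hits$gene_id == ids[4]], "-")

  # a motif planted downstream of the window is invisible to the scan
  gen_out <- plant_motif(generate_genome(n_contigs = 1, genes_per_contig = 5,
                                         seed = 3),
                         ids[3], rosr_box()$sequence, 200, "+")
  hits_out <- scan_genome(gen_out, min_identity_pct = 90)
  expect_false(ids[3] %in% hits_out$gene_id)

  # min identity 0: every gene whose window fits the motif has a record
  all_hits <- scan_genome(gen, min_identity_pct = 0)
  expect_setequal(all_hits$gene_id, ids)
})

test_that("scan results are invariant under reverse-complementing a contig", {
  gen <- generate_genome(n_contigs = 1, genes_per_contig = 4, seed = 17)
  gen <- plant_motif(gen, gen$genes$gene_id[1],
                     make_degenerate_motif(n_mismatches_outside = 2, seed = 9),
                     -80, "+")
  n <- nchar(gen$contigs[[1]])
  flipped <- genome_annotation(
    stats::setNames(reverse_complement(gen$contigs[[1]]), names(gen$contigs)),
    transform(gen$genes,
              cds_start = n - gen$genes$cds_end + 1L,
              cds_end = n - gen$genes$cds_start + 1L,
              strand = ifelse(gen$genes$strand == "+", "-", "+"))
  )
  h1 <- scan_genome(gen, min_identity_pct = 60)
  h2 <- scan_genome(flipped, min_identity_pct = 60)
  expect_equal(h2[order(h2$gene_id), ], h1[order(h1$gene_id), ],
               ignore_attr = TRUE)
})

test_that("PWM cells and scores match the closed form", {
  cons <- rosr_box()
  pwm <- build_pwm(cons)
  s <- strsplit(cons$sequence, "")[[1]]
  for (p in c(1, 5, 13, 22)) {
    expect_equal(unname(pwm[p, s[p]]), log2(2.5))
    off <- setdiff(c("A", "C", "G", "T"), s[p])
    expect_equal(unname(pwm[p, off]), rep(log2(0.5), 3))
  }
  expect_equal(pwm_score(cons$sequence, cons), 18 * log2(2.5))
  # any single non-excluded mismatch lowers the score
  q <- s; q[3] <- "T"
  expect_lt(pwm_score(paste(q, collapse = ""), cons), 18 * log2(2.5))
  expect_error(consensus_motif(background = c(A = 0, C = 0.5, G = 0.25, T = 0.25)),
               "positive")
})

test_that("gapped identity restores single indels and reduces to the ungapped score", {
  cons <- rosr_box()
  s <- strsplit(cons$sequence, "")[[1]]

  # deletion of consensus position 5 -> gap at column 5, 17 matches, 94.4
  del5 <- paste(s[-5], collapse = "")
  g <- gapped_identity(del5, cons)
  expect_equal(g$n_matches, 17L)
  expect_equal(g$identity_pct, 94.4)
  expect_equal(g$alignment[1], paste(append(s[-5], "-", after = 4), collapse = ""))

  # no indel: identical to identity_score
  q <- random_dna(22)
  expect_equal(gapped_identity(q, cons)$identity_pct,
               identity_score(q, cons)$identity_pct)

  expect_error(gapped_identity(random_dna(25), cons), "max_indels")
})

test_that("gapped identity equals a brute-force enumeration of gap placements", {
  cons <- rosr_box()
  s <- strsplit(cons$sequence, "")[[1]]
  # placements ranked by alignment score (match +1, gap -1, rightmost tie);
  # identity then read off the winning alignment over non-excluded columns
  brute_best_deletion <- function(query) {
    q <- strsplit(query, "")[[1]]
    best_score <- -Inf; best_identity <- NA_integer_
    for (g in 1:22) {
      cols <- append(q, "-", after = g - 1L)
      score <- sum(cols == s) - 1L
      if (score >= best_score) {
        best_score <- score
        best_identity <- oracle_identity(paste(cols, collapse = ""))
      }
    }
    best_identity
  }
  set.seed(31)
  for (i in 1:20) {
    q21 <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
    expect_equal(gapped_identity(q21, cons)$n_matches, brute_best_deletion(q21))
  }
  # constructed deletions at every position recover n_matches >= 18 - 1
  for (p in c(1, 6, 11, 18, 22)) {
    del <- paste(s[-p], collapse = "")
    expect_gte(gapped_identity(del, cons)$n_matches, 17L)
  }
  # insertion case: inserting a base into the consensus keeps 18 matches
  ins <- paste(append(s, "A", after = 7), collapse = "")
  expect_equal(gapped_identity(ins, cons)$n_matches, 18L)
})
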