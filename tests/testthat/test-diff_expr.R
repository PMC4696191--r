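test_that("FPKM follows its closed form and conserves totals", {
  m <- matrix(c(10L, 0L, 990L, 20L, 5L, 975L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  # pad to a million reads per sample via gene c
  m[3, ] <- 1e6 - colSums(m[1:2, , drop = FALSE])
  cm <- count_matrix(m, c(a = 1000, b = 500, c = 2000),
                     c(s1 = "wt", s2 = "mut"))
  fpkm <- compute_fpkm(cm)
  expect_equal(fpkm["a", "s1"], 10)      # 10 * 1e9 / (1000 * 1e6)
  expect_equal(fpkm["b", "s1"], 0)       # zero counts stay zero

  set.seed(5)
  m2 <- matrix(rpois(600, 50), 100, 6,
               dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  cm2 <- count_matrix(m2, setNames(sample(200:3000, 100), rownames(m2)),
                      setNames(rep(c("wt", "mut"), each = 3), colnames(m2)))
  fpkm2 <- compute_fpkm(cm2)
  totals <- colSums(cm2$counts)
  recovered <- colSums(fpkm2 * cm2$gene_length_nt) * totals / 1e9
  expect_equal(recovered, totals, tolerance = 1e-12)

  m3 <- m2; m3[, 1] <- 0L
  cm3 <- count_matrix(m3, cm2$gene_length_nt, cm2$condition_of)
  expect_error(compute_fpkm(cm3), "s1")
})

test_that("size factors recover deliberate library scalings", {
  set.seed(9)
  base <- rpois(200, 400)
  scale <- c(1, 1.5, 0.7, 1.2, 0.9, 1.1)
  m <- sapply(scale, function(s) rpois(200, base * s))
  dimnames(m) <- list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6))
  cm <- count_matrix(m, setNames(rep(1000, 200), rownames(m)),
                     setNames(rep(c("wt", "mut"), each = 3), colnames(m)))
  sf <- size_factors(cm)
  expect_equal(unname(sf / sf[1]), scale / scale[1], tolerance = 0.05)
})

test_that("dispersion estimation floors exact replicates and recovers simulated values", {
  cm <- counts_from_rows(matrix(100L, 4, 3), matrix(700L, 4, 3))
  expect_equal(unname(estimate_dispersion(cm)), rep(1e-8, 4))

  truth <- data.frame(gene_id = sprintf("g%04d", 1:1500), base_mean = 4000,
                      true_log2fc = 0, length_nt = 900)
  pois <- simulate_counts(truth, 3, 0, seed = 21)
  expect_lt(mean(estimate_dispersion(pois)), 5e-4)

  nb <- simulate_counts(truth, 3, 0.1, seed = 22)
  expect_equal(mean(estimate_dispersion(nb)), 0.1, tolerance = 0.15)

  two_rep <- counts_from_rows(matrix(100L, 2, 1), matrix(100L, 2, 3))
  expect_error(estimate_dispersion(two_rep), ">= 2 replicates")
})

test_that("de_test fold changes and degenerate cases follow the contract", {
  same <- counts_from_rows(matrix(c(5L, 80L), 2, 3), matrix(c(5L, 80L), 2, 3))
  de <- de_test(same)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p_value, c(1, 1))

  # 100 vs 800 with equal library totals: pad with a balancing gene
  wt <- rbind(rep(100L, 3), rep(900L, 3))
  mut <- rbind(rep(800L, 3), rep(200L, 3))
  cm <- counts_from_rows(wt, mut)
  de2 <- de_test(cm, pseudo_fpkm = 0)
  expect_equal(de2$log2fc[1], 3)

  zeros <- counts_from_rows(rbind(rep(0L, 3), rep(50L, 3)),
                            rbind(rep(0L, 3), rep(50L, 3)))
  de3 <- de_test(zeros)
  expect_equal(de3$p_value[1], 1)  # all-zero gene: no evidence by convention
})

test_that("swapping condition labels negates log2fc and keeps p-values", {
  set.seed(33)
  wt <- matrix(rpois(30, 300), 10, 3)
  mut <- matrix(rpois(30, 500), 10, 3)
  cm <- counts_from_rows(wt, mut)
  swapped <- count_matrix(cm$counts, cm$gene_length_nt,
                          setNames(ifelse(cm$condition_of == "wt", "mut", "wt"),
                                   names(cm$condition_of)))
  d1 <- de_test(cm); d2 <- de_test(swapped)
  expect_equal(d2$log2fc, -d1$log2fc)
  expect_equal(d2$p_value, d1$p_value)
})

test_that("BH step-up matches hand computation and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:5) {
    p <- runif(200)^2
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification thresholds behave as documented", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(3, 5, 1.5),
                    p_value = c(0.001, 0.2, 0.001),
                    q_value = c(0.01, 0.2, 0.01),
                    status = NA_character_)
  got <- classify_de(res)
  expect_equal(got$status, c("up", "ns", "up"))
  strict <- classify_de(res, lfc_threshold = 2)
  expect_equal(strict$status, c("up", "ns", "ns"))
})

test_that("direction summaries count significant genes only", {
  res <- data.frame(status = c("up", "up", "down", "ns"))
  s <- summarize_direction(res)
  expect_equal(s$n_significant, 3L)
  expect_equal(s$pct_up, 66.67)
  expect_equal(s$pct_down, 33.33)
  empty <- summarize_direction(data.frame(status = rep("ns", 5)))
  expect_true(empty$empty)
  expect_equal(empty$n_significant, 0L)
})

test_that("top-N selection ranks by |log2fc| with lexical ties", {
  res <- data.frame(gene_id = c("zeta", "alpha", "mid", "null"),
                    log2fc = c(4, -4, 2, 0.1),
                    status = c("up", "down", "up", "ns"))
  fpkm <- matrix(1, 4, 2, dimnames = list(res$gene_id, c("s1", "s2")))
  expect_equal(rownames(top_n_by_abs_lfc(res, fpkm, 1)), "alpha")
  expect_equal(rownames(top_n_by_abs_lfc(res, fpkm, 2)), c("alpha", "zeta"))
  expect_equal(nrow(top_n_by_abs_lfc(res, fpkm, 50)), 3L)  # ns excluded
})

test_that("planted fold changes are recovered with small bias at high depth", {
  set.seed(55)
  lfc <- rep(seq(-4, 4, by = 1), each = 100)
  truth <- data.frame(gene_id = sprintf("g%03d", seq_along(lfc)),
                      base_mean = 2000, true_log2fc = lfc, length_nt = 900)
  cm <- simulate_counts(truth, 3, 0.05, seed = 56)
  de <- de_test(cm, pseudo_fpkm = 0)
  err <- de$log2fc - lfc
  for (v in unique(lfc)) {
    expect_lt(abs(median(err[lfc == v])), 0.1)
  }
  # power grows with effect size
  p_small <- median(de$p_value[abs(lfc) == 1])
  p_large <- median(de$p_value[abs(lfc) == 4])
  expect_lt(p_large, p_small)
})
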