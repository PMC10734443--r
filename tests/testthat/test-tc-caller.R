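mini_de <- function(fc, pvalue, padj = pvalue, tested = TRUE) {
  data.frame(gene_id = paste0("g", seq_along(fc)), base_mean = 100,
             log2fc = fc_to_lfc(fc), fc = fc, se = 1, stat = 0,
             pvalue = pvalue, padj = padj, tested = tested,
             stringsAsFactors = FALSE)
}

mini_ann <- function(strand, start, end, contig = "chr1") {
  data.frame(gene_id = paste0("g", seq_along(start)), contig = contig,
             strand = strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("candidate selection is inclusive on |fc| and strict on raw p", {
  de <- mini_de(fc = c(2.0, -1.9, 5, -3), pvalue = c(0.049, 0.001, 0.05, 0.01))
  cand <- select_candidates(de)
  expect_setequal(cand$gene_id, c("g1", "g4"))
  expect_equal(cand$direction[cand$gene_id == "g1"], "up")
  expect_equal(cand$direction[cand$gene_id == "g4"], "down")
  # untested genes are never candidates
  de$tested[1] <- FALSE
  expect_false("g1" %in% select_candidates(de)$gene_id)
})

test_that("chaining follows the gap, strand and direction rules", {
  # gaps 99 and 399: one TC {g1,g2}, g3 isolated
  ann <- mini_ann(c("+", "+", "+"), c(100, 600, 1300), c(500, 900, 1500))
  cand <- data.frame(gene_id = c("g1", "g2", "g3"), fc = c(-4, -3, -5),
                     pvalue = 0.01, padj = 0.01,
                     direction = "down", stringsAsFactors = FALSE)
  res <- call_tcs(cand, ann, max_gap = 250)
  expect_equal(nrow(res$tcs), 1)
  expect_equal(res$tcs$members, "g1,g2")
  expect_equal(res$tcs$avg_fc, -3.5)
  expect_equal(res$tcs$max_internal_gap, 99)
  expect_equal(res$isolated, "g3")

  # strand partition: adjacent but opposite strands never chain
  ann2 <- mini_ann(c("+", "-"), c(100, 550), c(500, 800))
  cand2 <- cand[1:2, ]
  res2 <- call_tcs(cand2, ann2, max_gap = 250)
  expect_equal(nrow(res2$tcs), 0)
  expect_setequal(res2$isolated, c("g1", "g2"))

  # direction discordance breaks a chain
  ann3 <- mini_ann(c("+", "+"), c(100, 600), c(500, 900))
  cand3 <- data.frame(gene_id = c("g1", "g2"), fc = c(4, -4),
                      pvalue = 0.01, padj = 0.01,
                      direction = c("up", "down"), stringsAsFactors = FALSE)
  res3 <- call_tcs(cand3, ann3, max_gap = 250)
  expect_equal(nrow(res3$tcs), 0)

  # the gap is measured between candidates: an intervening non-candidate
  # gene does not break the chain if the distance stays below the threshold
  ann4 <- mini_ann(c("+", "+", "+"), c(100, 520, 700), c(500, 650, 900))
  cand4 <- cand[c(1, 3), ]
  cand4$gene_id <- c("g1", "g3")
  res4 <- call_tcs(cand4, ann4, max_gap = 250)
  expect_equal(res4$tcs$members, "g1,g3")

  expect_error(call_tcs(data.frame(gene_id = "missing", fc = 2, pvalue = 0.01,
                                   padj = 0.01, direction = "up"),
                        ann, max_gap = 250),
               "missing")
})

test_that("chaining matches the exhaustive maximal-run oracle on random layouts", {
  set.seed(404)
  for (i in 1:120) {
    lay <- random_layout(max_candidates = 12)
    res <- call_tcs(lay$candidates, lay$annotation, max_gap = 250)
    oracle <- tc_bruteforce(lay$candidates, lay$annotation, max_gap = 250)
    called <- lapply(res$tcs$members, function(m) sort(tc_members(m)))
    expect_setequal(vapply(called, paste, "", collapse = ","),
                    vapply(oracle$clusters, paste, "", collapse = ","))
    expect_equal(res$isolated, oracle$isolated)
    # partition: every candidate in exactly one TC or isolated
    expect_setequal(c(unlist(called), res$isolated), lay$candidates$gene_id)
  }
})

test_that("the rescue rule includes TC members with a significant partner only", {
  ann <- mini_ann(c("+", "+", "-", "+", "+"),
                  c(100, 600, 2000, 5000, 5500),
                  c(500, 900, 2400, 5400, 5900))
  de <- mini_de(fc = c(-4, -3, -6, 3, 2.5),
                pvalue = rep(0.01, 5),
                padj = c(0.01, 0.30, 0.30, 0.30, 0.40))
  cand <- select_candidates(de)
  tcs <- call_tcs(cand, ann, max_gap = 250)
  aff <- apply_rescue(de, cand, tcs, bh_threshold = 0.05)
  g <- aff$genes
  # g1 significant, g2 rescued by g1; isolated g3 excluded;
  # TC {g4,g5} has no significant member and is dropped entirely
  expect_setequal(g$gene_id, c("g1", "g2"))
  expect_equal(g$reason[g$gene_id == "g1"], "bh_significant")
  expect_equal(g$reason[g$gene_id == "g2"], "tc_rescued")
  expect_equal(aff$counts$n_rescued, 1)
  expect_equal(aff$counts$n_tcs, 1)
  # every rescued gene fails BH but passed the raw filters
  rescued <- g[g$reason == "tc_rescued", ]
  expect_true(all(rescued$padj >= 0.05))
  expect_true(all(abs(rescued$fc) >= 2))
})

test_that("affected percentages reproduce integer rounding half away from zero", {
  pct <- affected_percentages(273, 227, 47, 153)
  expect_equal(pct$pct_down, 83)
  expect_equal(pct$pct_up, 17)
  expect_equal(pct$pct_in_tc, 56)
  empty <- affected_percentages(0, 0, 0, 0)
  expect_equal(unlist(empty), c(pct_down = 0, pct_up = 0, pct_in_tc = 0))
})

test_that("summaries of an empty affected set are all zero", {
  ann <- mini_ann("+", 100, 500)
  de <- mini_de(fc = 1.1, pvalue = 0.9)
  cand <- select_candidates(de)
  tcs <- call_tcs(cand, ann)
  aff <- apply_rescue(de, cand, tcs)
  s <- summarize_affected(aff, tcs)
  expect_equal(s$n_affected, 0)
  expect_equal(s$pct_down, 0)
  expect_equal(nrow(s$largest_tcs), 0)
})

test_that("thresholds act monotonically", {
  set.seed(99)
  lay <- random_layout(max_candidates = 12)
  n_in_tc <- vapply(c(50, 150, 250, 500, 1000), function(gap) {
    res <- call_tcs(lay$candidates, lay$annotation, max_gap = gap)
    sum(res$tcs$n_genes)
  }, numeric(1))
  expect_true(all(diff(n_in_tc) >= 0))

  de <- mini_de(fc = rep(c(-4, 3), 5), pvalue = runif(10, 0, 0.04),
                padj = seq(0.01, 0.95, length.out = 10))
  ann <- mini_ann(rep("+", 10), seq(100, 9100, by = 1000),
                  seq(500, 9500, by = 1000))
  cand <- select_candidates(de)
  tcs <- call_tcs(cand, ann)
  n_aff <- vapply(c(0.01, 0.05, 0.2, 0.5, 1), function(bh) {
    apply_rescue(de, cand, tcs, bh_threshold = bh)$counts$n_affected
  }, numeric(1))
  expect_true(all(diff(n_aff) >= 0))
})
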