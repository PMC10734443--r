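test_that("median-of-ratios size factors match hand-computed cases", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  doubled <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(estimate_size_factors(doubled)),
               c(1 / sqrt(2), sqrt(2)))

  single <- matrix(c(10, 40), nrow = 1)
  expect_equal(unname(estimate_size_factors(single)), c(0.5, 2))

  expect_error(estimate_size_factors(matrix(0, 3, 2)), "all-zero")
})

test_that("dispersion estimates track the generating model", {
  set.seed(101)
  conds <- rep(c("wildtype", "mutant"), each = 4)
  # Poisson counts: raw dispersion should be negligible
  pois <- matrix(rpois(1000 * 8, 200), ncol = 8)
  rownames(pois) <- paste0("g", 1:1000)
  d_pois <- estimate_dispersion(pois, conds, rep(1, 8))
  expect_lt(median(d_pois), 0.005)

  # NB counts with d = 0.5
  nb <- matrix(rnbinom(2000 * 8, mu = 200, size = 2), ncol = 8)
  rownames(nb) <- paste0("g", 1:2000)
  d_nb <- estimate_dispersion(nb, conds, rep(1, 8))
  expect_equal(median(d_nb), 0.5, tolerance = 0.2)

  # constant counts within conditions: floored at the minimum
  expect_equal(unname(estimate_dispersion(rbind(g1 = c(rep(5, 4), rep(9, 4))),
                                          conds, rep(1, 8))),
               1e-8)

  expect_error(estimate_dispersion(pois[, c(1, 5)], conds[c(1, 5)], c(1, 1)),
               "2 replicates")
})

test_that("signed fold change and log2 fold change are a bijection", {
  expect_equal(lfc_to_fc(1), 2)
  expect_equal(lfc_to_fc(-1), -2)
  expect_equal(lfc_to_fc(0), 1)
  lfc <- seq(-8, 8, by = 0.25)
  expect_equal(fc_to_lfc(lfc_to_fc(lfc)), lfc)
  fc <- c(-83, -23, -4, 1, 2, 44)
  expect_equal(lfc_to_fc(fc_to_lfc(fc)), fc)
  # -1 and +1 both denote "no change" and share lfc 0
  expect_equal(fc_to_lfc(-1), 0)
  expect_true(all(abs(lfc_to_fc(lfc)) >= 1))
  expect_error(fc_to_lfc(0.5), "magnitude")
})

test_that("all-zero genes are flagged untested and excluded from the BH family", {
  m <- rbind(g1 = c(10L, 12L, 9L, 50L, 55L, 60L),
             g2 = c(0L, 0L, 0L, 0L, 0L, 0L),
             g3 = c(100L, 90L, 110L, 100L, 95L, 105L))
  de <- run_de(m, rep(c("wildtype", "mutant"), each = 3))
  expect_false(de$tested[2])
  expect_equal(de$pvalue[2], 1)
  expect_true(is.na(de$padj[2]))
  expect_equal(de$fc[2], 1)
  # family size 2: adjustment uses only tested genes
  expect_equal(de$padj[c(1, 3)], bh_adjust(de$pvalue[c(1, 3)]))
})

test_that("rescaling one sample moves its size factor, not the fold changes", {
  set.seed(7)
  m <- matrix(rpois(200 * 6, 100), ncol = 6)
  rownames(m) <- paste0("g", 1:200)
  conds <- rep(c("wildtype", "mutant"), each = 3)
  de1 <- run_de(m, conds)
  m2 <- m
  m2[, 1] <- m2[, 1] * 3L
  sf1 <- estimate_size_factors(m)
  sf2 <- estimate_size_factors(m2)
  # the geometric-mean reference itself shifts by 3^(1/n), so the rescaled
  # sample's factor grows by 3^(1-1/n) and the others shrink by 3^(-1/n);
  # relative to any other sample the factor grows by exactly 3
  n <- ncol(m)
  expect_equal(unname(sf2[1] / sf1[1]), 3^(1 - 1 / n))
  expect_equal(unname(sf2[-1] / sf1[-1]), rep(3^(-1 / n), n - 1))
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 3)
  # fold changes are unchanged up to the pseudocount's second-order effect
  de2 <- run_de(m2, conds)
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 1e-3)
})

test_that("BH step-up matches hand-derived examples and p.adjust", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(bh_adjust(c(0.9, 0.95, 1)) <= 1))
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # adjusted values never fall below the raw values
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("the Wald stage recovers planted signed fold changes", {
  cfg <- sim_config(
    n_genes = 150, n_replicates = 6, nb_dispersion = 0.005,
    mean_expression_range = c(200, 2000),
    planted_clusters = list(list(size = 30, strand = "+", fc = -23),
                            list(size = 30, strand = "-", fc = 4)),
    seed = 17
  )
  d <- gen_annotation(cfg)
  counts <- gen_counts(d$annotation, d$truth, cfg)
  de <- run_de(counts)
  est <- setNames(de$fc, de$gene_id)
  truth <- d$truth$fc
  for (g in c(-23, 4)) {
    ids <- names(truth)[truth == g]
    expect_equal(mean(est[ids]), g, tolerance = 0.25)
    expect_true(all(de$pvalue[match(ids, de$gene_id)] < 0.05))
  }
})
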