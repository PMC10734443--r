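base_config <- function(...) {
  sim_config(
    n_genes = 40,
    planted_clusters = list(
      list(size = 3, strand = "+", fc = -4),
      list(size = 4, strand = "-", fc = 8),
      list(size = 2, strand = "+", fc = -23)
    ),
    seed = 11, ...
  )
}

test_that("identical configurations give bitwise identical outputs", {
  cfg <- base_config()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$counts, b$counts)
  expect_identical(a$variants, b$variants)
  expect_identical(a$growth, b$growth)
})

test_that("annotation layout honours the gap construction rules", {
  cfg <- base_config()
  d <- gen_annotation(cfg)
  ann <- d$annotation
  expect_false(is.unsorted(ann$start))
  expect_true(all(ann$end >= ann$start))
  # no same-strand overlaps
  for (s in c("+", "-")) {
    g <- ann[ann$strand == s, ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  gaps <- ann$start[-1] - ann$end[-nrow(ann)] - 1
  cid <- d$truth$cluster_id[ann$gene_id]
  same_cluster <- !is.na(cid[-1]) & !is.na(cid[-length(cid)]) &
    cid[-1] == cid[-length(cid)]
  expect_true(all(gaps[same_cluster] < 250))
  expect_true(all(gaps[same_cluster] >= 20))
  expect_true(all(gaps[!same_cluster] >= 250))
  # planted members share the configured strand
  for (i in seq_len(nrow(d$truth$clusters))) {
    members <- names(cid)[!is.na(cid) & cid == d$truth$clusters$cluster_id[i]]
    expect_setequal(unique(ann$strand[ann$gene_id %in% members]),
                    d$truth$clusters$strand[i])
  }
})

test_that("with no planted clusters every intergenic gap is at or above the threshold", {
  d <- gen_annotation(sim_config(n_genes = 25, seed = 3))
  gaps <- d$annotation$start[-1] - d$annotation$end[-nrow(d$annotation)] - 1
  expect_true(all(gaps >= 250))
})

test_that("a contig too short for the requested genes is a sizing error", {
  expect_error(gen_annotation(sim_config(n_genes = 50, contig_length = 1000, seed = 1)),
               "contig too short")
})

test_that("planted clusters satisfy the TC predicate by construction", {
  cfg <- base_config()
  d <- gen_annotation(cfg)
  truth_cand <- data.frame(
    gene_id = names(d$truth$cluster_id)[!is.na(d$truth$cluster_id)],
    stringsAsFactors = FALSE
  )
  truth_cand$fc <- d$truth$fc[truth_cand$gene_id]
  truth_cand$direction <- ifelse(truth_cand$fc >= 0, "up", "down")
  tcs <- call_tcs(truth_cand, d$annotation, max_gap = cfg$tc_gap)
  rec <- tc_recovery(tcs, d$truth)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_length(tcs$isolated, 0)
})

test_that("count marginals follow the NB variance model var = m + d m^2", {
  cfg <- sim_config(n_genes = 5000, n_replicates = 6, nb_dispersion = 0.1,
                    mean_expression_range = c(100, 100), seed = 5)
  d <- gen_annotation(cfg)
  counts <- gen_counts(d$annotation, d$truth, cfg)
  wt <- counts[, 1:6]
  v <- mean(apply(wt, 1, var))
  expect_equal(v, 100 + 0.1 * 100^2, tolerance = 0.1)
})

test_that("null counts at vanishing dispersion give per-gene ratios near 1", {
  cfg <- sim_config(n_genes = 500, n_replicates = 6, nb_dispersion = 0,
                    mean_expression_range = c(1000, 1000), seed = 8)
  d <- gen_annotation(cfg)
  counts <- gen_counts(d$annotation, d$truth, cfg)
  ratio <- rowMeans(counts[, 7:12]) / rowMeans(counts[, 1:6])
  expect_equal(mean(ratio), 1, tolerance = 0.01)
  expect_lt(max(abs(ratio - 1)), 0.2)
})

test_that("a planted -4 fold change is recovered within sampling error", {
  # keep the planted fraction well below half so that median-of-ratios
  # normalization is anchored by unchanged genes
  cfg <- sim_config(
    n_genes = 1000, n_replicates = 6, nb_dispersion = 0.01,
    mean_expression_range = c(300, 1000),
    planted_clusters = lapply(1:10, function(i) list(size = 20, strand = "+", fc = -4)),
    seed = 21
  )
  d <- gen_annotation(cfg)
  counts <- gen_counts(d$annotation, d$truth, cfg)
  de <- run_de(counts)
  planted <- !is.na(d$truth$cluster_id[de$gene_id])
  expect_equal(mean(de$fc[planted]), -4, tolerance = 0.1)
})

test_that("exact-counts mode is noise free", {
  cfg <- base_config(exact_counts = TRUE, mean_expression_range = c(100, 100))
  d <- gen_annotation(cfg)
  counts <- gen_counts(d$annotation, d$truth, cfg)
  expect_true(all(counts[, 1] == counts[, 2]))
  null_genes <- is.na(d$truth$cluster_id[rownames(counts)])
  expect_true(all(counts[null_genes, 1] == counts[null_genes, 4]))
})

test_that("planted variant tables behave under filter + set difference", {
  cfg <- base_config()
  v <- gen_variants(cfg)
  u <- unique_to_mutant(filter_variants(v$mutant), filter_variants(v$wildtype))
  expect_setequal(variant_keys(u), v$truth)
  expect_equal(nrow(u), cfg$n_unique_variants)

  none <- sim_config(n_unique_variants = 0, n_decoy_variants = 0, seed = 4)
  v0 <- gen_variants(none)
  u0 <- unique_to_mutant(filter_variants(v0$mutant), filter_variants(v0$wildtype))
  expect_equal(nrow(u0), 0)
  expect_length(v0$truth, 0)
})

test_that("noise-free growth encodes the planted pigment effect exactly", {
  cfg <- sim_config(od_noise_sd = 0, pigment_effect = 0.5, seed = 9)
  g <- gen_growth(cfg)
  es <- endpoint_summary(g, control_condition = "O1")
  wt <- es$summary[es$summary$strain == "wildtype", ]
  expect_equal(wt$delta_pmp[wt$condition == "C3"], 0.5)
  expect_equal(wt$delta_pmp[wt$condition == "O1"], 0)
  mut <- es$summary[es$summary$strain == "mutant", ]
  expect_true(all(mut$delta_pmp == 0))

  flat <- gen_growth(sim_config(od_noise_sd = 0, pigment_effect = 0, seed = 9))
  es0 <- endpoint_summary(flat, control_condition = "O1")
  expect_true(all(es0$summary$delta_pmp == 0))
})
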