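# Independent brute-force oracles and random-layout generators used across
# the suite. These deliberately avoid the package's own code paths.

# Brute-force BH adjustment: for each p_i, the smallest p_j * m / rank(p_j)
# over all p_j >= p_i, where rank counts p_k <= p_j (ties take the largest
# rank). Derived directly from the step-up rejection rule.
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(pj) pj * m / sum(p <= pj), numeric(1))
    min(1, cand)
  }, numeric(1))
}

# Exhaustive transcriptional-cluster caller: enumerate every contiguous run
# of same-(contig, strand) candidates sorted by start, keep runs where all
# consecutive gaps are < max_gap and all directions agree, then retain the
# maximal ones. Returns member sets (size >= 2) and isolated ids.
tc_bruteforce <- function(candidates, annotation, max_gap = 250) {
  ann <- annotation[match(candidates$gene_id, annotation$gene_id), ]
  cand <- cbind(candidates, ann[, c("contig", "strand", "start", "end")])
  clusters <- list()
  in_cluster <- character(0)
  for (key in unique(paste(cand$contig, cand$strand))) {
    grp <- cand[paste(cand$contig, cand$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    n <- nrow(grp)
    valid <- function(i, j) {
      if (i < 1 || j > n) return(FALSE)
      if (length(unique(grp$direction[i:j])) > 1) return(FALSE)
      if (j > i) {
        gaps <- grp$start[(i + 1):j] - grp$end[i:(j - 1)] - 1
        if (any(gaps >= max_gap)) return(FALSE)
      }
      TRUE
    }
    for (i in seq_len(n)) for (j in i:n) {
      if (valid(i, j) && !valid(i - 1, j) && !valid(i, j + 1) && j > i) {
        clusters[[length(clusters) + 1]] <- sort(grp$gene_id[i:j])
        in_cluster <- c(in_cluster, grp$gene_id[i:j])
      }
    }
  }
  list(clusters = clusters,
       isolated = sort(setdiff(cand$gene_id, in_cluster)))
}

# Random annotation + candidate layout: up to max_candidates candidate genes
# over 1-2 contigs, gaps mixing values below and above the TC threshold,
# random strands and directions; opposite-strand overlaps allowed.
random_layout <- function(max_candidates = 12) {
  n <- sample(2:max_candidates, 1)
  contig <- sample(c("chrA", "chrB"), n, replace = TRUE)
  ann <- do.call(rbind, lapply(unique(contig), function(ct) {
    k <- sum(contig == ct)
    lens <- sample(100:900, k, replace = TRUE)
    gaps <- sample(c(sample(0:249, k, replace = TRUE),
                     sample(250:1200, k, replace = TRUE)), k)
    starts <- cumsum(c(1, (lens + gaps)[-k]))
    data.frame(gene_id = paste0(ct, "_g", seq_len(k)), contig = ct,
               strand = sample(c("+", "-"), k, replace = TRUE),
               start = starts, end = starts + lens - 1,
               stringsAsFactors = FALSE)
  }))
  candidates <- data.frame(
    gene_id = ann$gene_id,
    fc = sample(c(-1, 1), nrow(ann), replace = TRUE) * runif(nrow(ann), 2, 50),
    pvalue = runif(nrow(ann), 0, 0.049),
    padj = runif(nrow(ann)),
    stringsAsFactors = FALSE
  )
  candidates$direction <- ifelse(candidates$fc >= 0, "up", "down")
  list(annotation = ann, candidates = candidates)
}

# Loop translation oracle (bacterial code, stops TAA/TAG/TGA): protein length
# up to the first in-frame stop, walking codon by codon.
translate_oracle <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(seq) %/% 3
  for (i in seq_len(n)) {
    codon <- substr(seq, 3 * i - 2, 3 * i)
    if (code[[codon]] == "*") return(i - 1)
  }
  n
}

# A 60 nt CDS used by several variant tests: starts ATG, single trailing TAA
# stop (19 aa protein), 7-G homopolymer run at positions 28-34 flanked by T on
# both sides; deleting any one G of the run shifts the frame so a premature
# in-frame stop appears at codon 12 (11 aa protein).
fixture_cds <- function() {
  "ATGGCTAAACCGTTCGAACATATCGTTGGGGGGGTAAACAAATTCCATGTTGCTCCGTAA"
}
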