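round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

pct_int <- function(k, n) if (n > 0) round_half_up(100 * k / n) else 0

#' Select candidate differentially expressed genes
#'
#' A gene is a candidate iff `|fc| >= fc_threshold` (inclusive) and its raw
#' Wald p value is strictly below `raw_p_threshold`. These are the genes that
#' enter transcriptional-cluster calling; the BH filter and the rescue rule
#' are applied afterwards ([apply_rescue()]).
#'
#' @param de data.frame of per-gene records from [run_de()].
#' @param fc_threshold minimum signed fold-change magnitude (default 2).
#' @param raw_p_threshold raw p-value cutoff, strict (default 0.05).
#' @return data.frame with `gene_id`, `fc`, `pvalue`, `padj`, and
#'   `direction` (`"up"` or `"down"`).
#' @export
select_candidates <- function(de, fc_threshold = 2, raw_p_threshold = 0.05) {
  keep <- de$tested & abs(de$fc) >= fc_threshold & de$pvalue < raw_p_threshold
  out <- de[keep, c("gene_id", "fc", "pvalue", "padj"), drop = FALSE]
  out$direction <- ifelse(out$fc >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Call transcriptional clusters among candidate genes
#'
#' Within each (contig, strand), candidates sorted by start coordinate are
#' chained greedily: two consecutive candidates join the same cluster iff the
#' intergenic gap (`next_start - prev_end - 1`) is strictly below `max_gap`
#' and their regulation directions agree. Maximal chains of two or more genes
#' become transcriptional clusters (TCs); singleton chains are reported as
#' isolated. The gap is measured between consecutive candidates, so an
#' intervening non-candidate gene does not by itself break a chain — only the
#' resulting distance does. Greedy chaining of maximal runs is
#' order-independent.
#'
#' @param candidates data.frame from [select_candidates()].
#' @param annotation gene annotation data.frame (`gene_id`, `contig`,
#'   `strand`, `start`, `end`).
#' @param max_gap gap threshold in bp, strict (default 250).
#' @return list with `tcs` (data.frame: `tc_id`, `contig`, `strand`,
#'   `direction`, `n_genes`, `members` (comma-separated in genomic order),
#'   `avg_fc`, `span_start`, `span_end`, `max_internal_gap`) and
#'   `isolated` (character vector of gene ids).
#' @export
call_tcs <- function(candidates, annotation, max_gap = 250) {
  missing <- setdiff(candidates$gene_id, annotation$gene_id)
  if (length(missing))
    stop("candidate gene(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  ann <- annotation[match(candidates$gene_id, annotation$gene_id), ]
  cand <- cbind(candidates, ann[, c("contig", "strand", "start", "end")])

  tcs <- list()
  isolated <- character(0)
  for (key in unique(paste(cand$contig, cand$strand))) {
    grp <- cand[paste(cand$contig, cand$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    if (nrow(grp) == 0) next
    gaps <- if (nrow(grp) > 1) grp$start[-1] - grp$end[-nrow(grp)] - 1 else numeric(0)
    same_dir <- if (nrow(grp) > 1) {
      grp$direction[-1] == grp$direction[-nrow(grp)]
    } else logical(0)
    breaks <- c(TRUE, !(gaps < max_gap & same_dir))
    chain <- cumsum(breaks)
    for (ch in split(seq_len(nrow(grp)), chain)) {
      if (length(ch) >= 2) {
        g <- grp[ch, ]
        tcs[[length(tcs) + 1]] <- data.frame(
          contig = g$contig[1], strand = g$strand[1],
          direction = g$direction[1], n_genes = nrow(g),
          members = paste(g$gene_id, collapse = ","),
          avg_fc = mean(g$fc),
          span_start = min(g$start), span_end = max(g$end),
          max_internal_gap = max(g$start[-1] - g$end[-nrow(g)] - 1),
          stringsAsFactors = FALSE
        )
      } else {
        isolated <- c(isolated, grp$gene_id[ch])
      }
    }
  }
  tcs <- if (length(tcs)) do.call(rbind, tcs) else data.frame(
    contig = character(0), strand = character(0), direction = character(0),
    n_genes = integer(0), members = character(0), avg_fc = numeric(0),
    span_start = integer(0), span_end = integer(0),
    max_internal_gap = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(tcs)) {
    tcs <- tcs[order(tcs$contig, tcs$span_start), , drop = FALSE]
    tcs$tc_id <- sprintf("TC_%03d", seq_len(nrow(tcs)))
    tcs <- tcs[, c("tc_id", setdiff(names(tcs), "tc_id"))]
    rownames(tcs) <- NULL
  } else {
    tcs <- cbind(data.frame(tc_id = character(0), stringsAsFactors = FALSE), tcs)
  }
  list(tcs = tcs, isolated = sort(isolated))
}

#' Split a TC member string into gene ids
#' @param members comma-separated member string(s) from [call_tcs()].
#' @return character vector of gene ids.
#' @export
tc_members <- function(members) unlist(strsplit(members, ",", fixed = TRUE))

#' Apply the BH filter with the transcriptional-cluster rescue rule
#'
#' The affected set is the union of (a) candidates whose BH-adjusted p value
#' is strictly below `bh_threshold` and (b) candidates that fail the BH cut
#' but belong to a TC containing at least one BH-significant member (the
#' rescue rule). Rescued genes therefore always satisfy the raw filters —
#' they are drawn from the candidate set.
#'
#' @param de per-gene records from [run_de()] (supplies BH p values).
#' @param candidates data.frame from [select_candidates()].
#' @param tcs result of [call_tcs()] on these candidates.
#' @param bh_threshold BH-adjusted p-value cutoff, strict (default 0.05).
#' @return list of class `"affected_set"`: `genes` (data.frame `gene_id`,
#'   `fc`, `direction`, `padj`, `reason` in `{bh_significant, tc_rescued}`,
#'   `tc_id` or `NA`) and `counts` (`n_affected`, `n_down`, `n_up`,
#'   `n_in_tc`, `n_tcs`, `n_rescued`).
#' @export
apply_rescue <- function(de, candidates, tcs, bh_threshold = 0.05) {
  padj <- stats::setNames(de$padj, de$gene_id)[candidates$gene_id]
  significant <- !is.na(padj) & padj < bh_threshold

  tc_of <- stats::setNames(rep(NA_character_, nrow(candidates)), candidates$gene_id)
  rescued <- stats::setNames(rep(FALSE, nrow(candidates)), candidates$gene_id)
  if (nrow(tcs$tcs)) {
    for (i in seq_len(nrow(tcs$tcs))) {
      mem <- tc_members(tcs$tcs$members[i])
      tc_of[mem] <- tcs$tcs$tc_id[i]
      if (any(significant[match(mem, candidates$gene_id)]))
        rescued[mem] <- TRUE
    }
  }
  sig <- stats::setNames(significant, candidates$gene_id)
  keep <- sig | rescued
  genes <- data.frame(
    gene_id = candidates$gene_id[keep],
    fc = candidates$fc[keep],
    direction = candidates$direction[keep],
    padj = padj[keep],
    reason = ifelse(sig[keep], "bh_significant", "tc_rescued"),
    tc_id = unname(tc_of[keep]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  affected_tcs <- unique(genes$tc_id[!is.na(genes$tc_id)])
  out <- list(
    genes = genes,
    counts = list(
      n_affected = nrow(genes),
      n_down = sum(genes$direction == "down"),
      n_up = sum(genes$direction == "up"),
      n_in_tc = sum(!is.na(genes$tc_id)),
      n_tcs = length(affected_tcs),
      n_rescued = sum(genes$reason == "tc_rescued")
    )
  )
  class(out) <- "affected_set"
  out
}

#' Integer percentages of an affected-gene tally
#'
#' Pure arithmetic on the headline counts: percent down- and upregulated and
#' percent grouped in transcriptional clusters, rounded half away from zero
#' to integers (the convention used when such results are reported).
#'
#' @param n_affected,n_down,n_up,n_in_tc nonnegative counts.
#' @return list with `pct_down`, `pct_up`, `pct_in_tc`.
#' @export
affected_percentages <- function(n_affected, n_down, n_up, n_in_tc) {
  list(
    pct_down = pct_int(n_down, n_affected),
    pct_up = pct_int(n_up, n_affected),
    pct_in_tc = pct_int(n_in_tc, n_affected)
  )
}

#' Summarize an affected-gene set
#'
#' Headline counts and integer percentages, the number of TCs with at least
#' one affected member, and the largest TCs by size with their average signed
#' fold change.
#'
#' @param affected result of [apply_rescue()].
#' @param tcs result of [call_tcs()].
#' @param n_top how many of the largest TCs to report.
#' @return list with the counts, `pct_down`, `pct_up`, `pct_in_tc`, and
#'   `largest_tcs` (data.frame `tc_id`, `n_genes`, `avg_fc`).
#' @export
summarize_affected <- function(affected, tcs, n_top = 5) {
  cnt <- affected$counts
  pct <- affected_percentages(cnt$n_affected, cnt$n_down, cnt$n_up, cnt$n_in_tc)
  affected_ids <- unique(affected$genes$tc_id[!is.na(affected$genes$tc_id)])
  tt <- tcs$tcs[tcs$tcs$tc_id %in% affected_ids, , drop = FALSE]
  tt <- tt[order(-tt$n_genes, tt$tc_id), c("tc_id", "n_genes", "avg_fc"), drop = FALSE]
  c(cnt, pct, list(largest_tcs = utils::head(tt, n_top)))
}
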