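#' Fold-change profile of a named genomic region
#'
#' A gene belongs to the region when its interval overlaps the region
#' interval by at least 1 bp, or when it is listed explicitly in
#' `region$genes` (which then overrides the interval). The profile reports
#' per-gene fold changes in genomic order, the average signed fold change
#' over the *affected* genes of the region (unaffected genes sit near
#' fc = +/-1 and would dilute the average), per-strand averages, the
#' affected gene with the largest |fc|, the TCs lying fully inside the
#' region, and the number of affected genes in the region that are in no TC
#' (its transcriptional fragmentation).
#'
#' @param region list or one-row data.frame with `name`, `contig`, `start`,
#'   `end`, and optionally `genes` (character vector of gene ids).
#' @param de per-gene records from [run_de()].
#' @param affected result of [apply_rescue()].
#' @param tcs result of [call_tcs()].
#' @param annotation gene annotation data.frame.
#' @return list with `name`, `genes` (data.frame in genomic order: `gene_id`,
#'   `strand`, `start`, `end`, `fc`, `affected`), `avg_fc` (NA when no gene
#'   is affected), `avg_fc_by_strand`, `max_fc_gene`, `max_fc`, `n_tcs_inside`,
#'   `tcs_inside`, `n_isolated_affected`, `n_genes`, `n_affected`.
#' @export
profile_region <- function(region, de, affected, tcs, annotation) {
  region <- as.list(region)
  if (!is.null(region$genes) && length(region$genes) &&
      !all(is.na(region$genes))) {
    sel <- annotation$gene_id %in% unlist(region$genes)
  } else {
    sel <- annotation$contig == region$contig &
      annotation$start <= region$end & annotation$end >= region$start
  }
  genes <- annotation[sel, , drop = FALSE]
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  fc <- stats::setNames(de$fc, de$gene_id)[genes$gene_id]
  aff_ids <- affected$genes$gene_id
  is_aff <- genes$gene_id %in% aff_ids
  tab <- data.frame(
    gene_id = genes$gene_id, strand = genes$strand,
    start = genes$start, end = genes$end,
    fc = unname(fc), affected = is_aff,
    stringsAsFactors = FALSE, row.names = NULL
  )

  aff_fc <- tab$fc[tab$affected]
  avg_fc <- if (length(aff_fc)) mean(aff_fc) else NA_real_
  avg_by_strand <- vapply(c("+", "-"), function(s) {
    v <- tab$fc[tab$affected & tab$strand == s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  max_idx <- if (length(aff_fc)) which(tab$affected)[which.max(abs(aff_fc))] else NA

  inside <- logical(0)
  if (nrow(tcs$tcs)) {
    inside <- vapply(seq_len(nrow(tcs$tcs)), function(i) {
      tcs$tcs$contig[i] == (region$contig %||% tcs$tcs$contig[i]) &&
        all(tc_members(tcs$tcs$members[i]) %in% tab$gene_id)
    }, logical(1))
  }
  tc_of <- stats::setNames(affected$genes$tc_id, affected$genes$gene_id)
  n_isolated <- sum(tab$affected & is.na(tc_of[tab$gene_id]))

  list(
    name = region$name,
    genes = tab,
    avg_fc = avg_fc,
    avg_fc_by_strand = avg_by_strand,
    max_fc_gene = if (!is.na(max_idx)) tab$gene_id[max_idx] else NA_character_,
    max_fc = if (!is.na(max_idx)) tab$fc[max_idx] else NA_real_,
    n_tcs_inside = sum(inside),
    tcs_inside = tcs$tcs$tc_id[inside],
    n_isolated_affected = n_isolated,
    n_genes = nrow(tab),
    n_affected = sum(tab$affected)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Biological-process breakdown of the affected genes
#'
#' Config-driven aggregation: every affected gene is assigned the category
#' given in the user-supplied map (a curated gene -> process table), genes
#' absent from the map fall into `"Unknown"`. Reports per-category counts,
#' integer percentages of the total affected set, and up/down splits, sorted
#' by count descending.
#'
#' @param affected result of [apply_rescue()].
#' @param category_map data.frame with columns `gene_id` and `category`.
#' @return data.frame: `category`, `n`, `pct`, `n_up`, `n_down`.
#' @export
categorize_affected <- function(affected, category_map) {
  genes <- affected$genes
  cat <- category_map$category[match(genes$gene_id, category_map$gene_id)]
  cat[is.na(cat)] <- "Unknown"
  n_tot <- nrow(genes)
  out <- do.call(rbind, lapply(split(seq_len(n_tot), cat), function(idx) {
    data.frame(
      category = cat[idx[1]],
      n = length(idx),
      pct = pct_int(length(idx), n_tot),
      n_up = sum(genes$direction[idx] == "up"),
      n_down = sum(genes$direction[idx] == "down"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out))
    return(data.frame(category = character(0), n = integer(0), pct = numeric(0),
                      n_up = integer(0), n_down = integer(0)))
  out <- out[order(-out$n, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
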