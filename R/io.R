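#' Read a gene annotation from GFF3
#'
#' Imports gene features (any feature type when no `gene` rows are present)
#' and returns them sorted by (contig, start). Same-strand overlapping genes
#' trigger a warning, not an error.
#'
#' @param path GFF3 file.
#' @return data.frame with `gene_id`, `contig`, `strand`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else sprintf("gene_%04d", seq_along(gr))
  ann <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$contig, ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  if (anyDuplicated(ann$gene_id)) stop("gene ids in ", path, " are not unique")
  check_same_strand_overlaps(ann)
  ann
}

check_same_strand_overlaps <- function(ann) {
  for (key in unique(paste(ann$contig, ann$strand))) {
    g <- ann[paste(ann$contig, ann$strand) == key, , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      warning("same-strand overlapping genes on ", key)
  }
  invisible(ann)
}

#' Write a gene annotation as GFF3
#'
#' @param annotation data.frame (`gene_id`, `contig`, `strand`, `start`, `end`).
#' @param path output file.
#' @param contig_length optional length used for the sequence-region pragma.
#' @export
write_annotation_gff3 <- function(annotation, path, contig_length = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
  gr$type <- "gene"
  gr$source <- "redoxreg"
  gr$ID <- annotation$gene_id
  gr$Name <- annotation$gene_id
  if (!is.null(contig_length))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(
      contig_length, unique(annotation$contig))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a counts TSV (gene_id column + one column per sample)
#' @param path counts TSV file.
#' @param conditions_path optional CSV with columns `sample`, `condition`;
#'   when given, the condition labels are attached as `attr(, "conditions")`.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path, conditions_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  if (!is.null(conditions_path)) {
    cc <- utils::read.csv(conditions_path, stringsAsFactors = FALSE)
    attr(counts, "conditions") <- stats::setNames(
      cc$condition, cc$sample)[colnames(counts)]
  }
  counts
}

#' Write a counts matrix as TSV
#' @param counts matrix with gene rownames.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table (TSV or VCF)
#'
#' TSV columns: `contig`, `pos`, `ref`, `alt`, `coverage`, `frequency`.
#' For VCF input, coverage is taken from INFO/DP and frequency from INFO/AF.
#'
#' @param path `.tsv` or `.vcf` file.
#' @return variant data.frame.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    dp <- vcfR::extract.info(v, "DP", as.numeric = TRUE)
    af <- vcfR::extract.info(v, "AF", as.numeric = TRUE)
    data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT,
               coverage = as.integer(dp), frequency = af,
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$pos <- as.integer(df$pos)
    df
  }
}

#' Write a variant table (TSV, or a minimal VCF v4.2 with INFO DP/AF)
#' @param table variant data.frame.
#' @param path output file; `.vcf` selects VCF output.
#' @export
write_variants <- function(table, path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                    table$contig, as.integer(table$pos), table$ref, table$alt,
                    as.integer(table$coverage), table$frequency)
    writeLines(c(header, body), path)
  } else {
    utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read region definitions (BED-like TSV: name, contig, start, end)
#' @param path TSV file with header.
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "contig", "start", "end") %in% names(df)))
  if (anyDuplicated(df$name)) stop("region names must be unique")
  if (any(df$start > df$end)) stop("region start must not exceed end")
  df
}

#' Read a gene -> biological-process category map (TSV: gene_id, category)
#' @param path TSV file with header.
#' @return data.frame with `gene_id`, `category`.
#' @export
read_category_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "category") %in% names(df)))
  df
}

#' Read a growth CSV (condition, strain, replicate, time_h, od660, od880)
#' @param path CSV file.
#' @return growth data.frame.
#' @export
read_growth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "strain", "replicate", "time_h", "od660", "od880")
  stopifnot(all(need %in% names(df)))
  df
}

#' Write the per-gene differential-expression table as TSV
#' @param de data.frame from [run_de()].
#' @param path output file.
#' @export
write_de <- function(de, path) {
  utils::write.table(
    de[, c("gene_id", "base_mean", "log2fc", "fc", "pvalue", "padj")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
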