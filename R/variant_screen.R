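#' Canonical key of a variant record
#'
#' Variant identity is key-based: `contig:pos:ref>alt`. No general indel
#' normalization is attempted, but see [canonicalize_homopolymer_deletions()]
#' for single-base deletions inside homopolymer runs.
#'
#' @param table variant data.frame (`contig`, `pos`, `ref`, `alt`).
#' @return character vector of keys.
#' @export
variant_keys <- function(table) {
  if (!nrow(table)) return(character(0))
  sprintf("%s:%d:%s>%s", table$contig, as.integer(table$pos), table$ref, table$alt)
}

#' Filter variant calls on coverage and alternate-allele frequency
#'
#' Keeps a call iff its read coverage is at least `min_coverage` and its
#' alternate-allele frequency is strictly above `min_frequency` — the screen
#' used before treating calls as true strain differences (low-coverage and
#' low-frequency calls are discarded). The operation is idempotent and
#' tightening either threshold can only shrink the kept set.
#'
#' @param table variant data.frame with `coverage` and `frequency` columns.
#' @param min_coverage inclusive minimum read coverage (default 10).
#' @param min_frequency strict minimum alternate-allele frequency in
#'   \[0, 1\] (default 0.60).
#' @return the filtered data.frame.
#' @export
filter_variants <- function(table, min_coverage = 10, min_frequency = 0.60) {
  keep <- table$coverage >= min_coverage & table$frequency > min_frequency
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Left-align single-base deletions inside homopolymer runs
#'
#' A 1-bp deletion anywhere inside a run of identical bases yields the same
#' mutant sequence; for key-based comparison such records are shifted to the
#' leftmost position of the run. Requires the reference sequence; records
#' that are not single-base deletions are returned unchanged. Deletions are
#' recognized in two spellings: `ref` two bases with `alt` its first base
#' (anchored, VCF style), or `ref` one base with empty `alt`.
#'
#' @param table variant data.frame.
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @return the table with deletion records left-aligned.
#' @export
canonicalize_homopolymer_deletions <- function(table, genome) {
  if (!nrow(table)) return(table)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  for (i in seq_len(nrow(table))) {
    ref <- table$ref[i]; alt <- table$alt[i]
    if (nchar(ref) == 2 && nchar(alt) == 1 && substr(ref, 1, 1) == alt) {
      del_base <- substr(ref, 2, 2); del_pos <- table$pos[i] + 1L  # anchored
    } else if (nchar(ref) == 1 && alt == "") {
      del_base <- ref; del_pos <- table$pos[i]
    } else next
    seq <- genome[[table$contig[i]]]
    if (is.null(seq)) next
    p <- del_pos
    while (p > 1 && substr(seq, p - 1, p - 1) == del_base) p <- p - 1L
    # re-emit in anchored spelling at the leftmost run position
    anchor <- if (p > 1) substr(seq, p - 1, p - 1) else ""
    table$pos[i] <- p - (anchor != "")
    table$ref[i] <- paste0(anchor, del_base)
    table$alt[i] <- if (anchor == "") "" else anchor
  }
  table
}

#' Variant calls unique to the mutant strain
#'
#' Key-based set difference: records whose `(contig, pos, ref, alt)` key
#' occurs in the mutant table but not in the wild-type table. Both tables
#' should have been filtered with the same thresholds first. If a reference
#' genome is supplied, single-base homopolymer deletions are left-aligned in
#' both tables before comparison.
#'
#' @param mutant_table,wildtype_table variant data.frames.
#' @param genome optional reference for homopolymer canonicalization.
#' @return the mutant-unique records (data.frame).
#' @export
unique_to_mutant <- function(mutant_table, wildtype_table, genome = NULL) {
  if (!is.null(genome)) {
    mutant_table <- canonicalize_homopolymer_deletions(mutant_table, genome)
    wildtype_table <- canonicalize_homopolymer_deletions(wildtype_table, genome)
  }
  keep <- !(variant_keys(mutant_table) %in% variant_keys(wildtype_table))
  out <- mutant_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

translate_to_first_stop <- function(seq) {
  n <- 3 * (nchar(seq) %/% 3)
  if (n < 3) return(list(aa_length = 0L, stop_nt = NA_integer_, non_stop = TRUE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1, n)),
    genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE,
    if.fuzzy.codon = "X"
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(aa_length = as.integer(stop_at) - 1L,
         stop_nt = 3L * (as.integer(stop_at) - 1L) + 1L, non_stop = FALSE)
  } else {
    list(aa_length = nchar(aa), stop_nt = NA_integer_, non_stop = TRUE)
  }
}

#' Predict the protein consequence of a coding-sequence edit
#'
#' Applies a substitution/insertion/deletion to a CDS, translates the edited
#' sequence with the bacterial genetic code (stops TAA/TAG/TGA; alternative
#' start codons read as Met) from codon 1, and reports the mutant protein
#' length up to the first stop codon (exclusive), the percent reduction
#' relative to the original protein, and the 1-based nucleotide position of
#' the new stop codon in the mutant CDS. A single-base deletion inside a
#' homopolymer run of length >= 2 is flagged ambiguous: any deleted position
#' within the run yields the identical mutant sequence, so the report is
#' position-independent there.
#'
#' @param cds coding sequence (A/C/G/T string), length divisible by 3,
#'   starting with a start codon (ATG/GTG/TTG) and ending with a stop codon.
#' @param pos 1-based position of the edit in `cds`.
#' @param ref reference allele at `pos` (must match the CDS).
#' @param alt replacement allele (`""` for a deletion).
#' @return list of class `"truncation_report"`: `original_aa`, `mutant_aa`,
#'   `percent_reduction`, `stop_position_nt` (in the mutant CDS; NA when no
#'   stop is reached), `non_stop`, `homopolymer_ambiguous`, `frameshift`.
#' @export
predict_frameshift <- function(cds, pos, ref, alt) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (!substr(cds, 1, 3) %in% c("ATG", "GTG", "TTG"))
    stop("CDS must begin with a bacterial start codon (ATG/GTG/TTG)")
  orig <- translate_to_first_stop(cds)
  if (orig$non_stop || orig$aa_length != nchar(cds) / 3 - 1)
    stop("CDS must end with its only in-frame stop codon")
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) < 1 || substr(cds, pos, pos + nchar(ref) - 1) != ref)
    stop("ref allele does not match the CDS at position ", pos)

  mutant <- paste0(substr(cds, 1, pos - 1), alt,
                   substr(cds, pos + nchar(ref), nchar(cds)))
  res <- translate_to_first_stop(mutant)

  homopolymer <- FALSE
  if (nchar(ref) == 1 && alt == "") {
    left <- if (pos > 1) substr(cds, pos - 1, pos - 1) else ""
    right <- if (pos < nchar(cds)) substr(cds, pos + 1, pos + 1) else ""
    homopolymer <- identical(left, ref) || identical(right, ref)
  }
  out <- list(
    original_aa = orig$aa_length,
    mutant_aa = res$aa_length,
    percent_reduction = percent_reduction(orig$aa_length, res$aa_length),
    stop_position_nt = res$stop_nt,
    non_stop = res$non_stop,
    homopolymer_ambiguous = homopolymer,
    frameshift = (nchar(alt) - nchar(ref)) %% 3 != 0
  )
  class(out) <- "truncation_report"
  out
}

#' Protein length encoded by an open reading frame
#'
#' `nt / 3 - 1` amino acids: the stop codon is not translated. A 546 nt ORF
#' encodes a 181-residue protein.
#'
#' @param orf_length_nt ORF length in nucleotides, divisible by 3, >= 6.
#' @return protein length in amino acids.
#' @export
orf_protein_length <- function(orf_length_nt) {
  if (any(orf_length_nt %% 3 != 0)) stop("ORF length must be divisible by 3")
  if (any(orf_length_nt < 6)) stop("ORF must be at least 6 nt (start + stop)")
  orf_length_nt / 3 - 1
}

#' Percent size reduction of a mutant protein
#'
#' `(1 - mutant / original) * 100`; also applicable to comparing a protein
#' against a longer homolog.
#'
#' @param original_aa,mutant_aa protein lengths (amino acids).
#' @return percent reduction (not rounded).
#' @export
percent_reduction <- function(original_aa, mutant_aa) {
  if (any(original_aa <= 0)) stop("original length must be positive")
  (1 - mutant_aa / original_aa) * 100
}
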