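#' @title Variant and coordinate conventions
#' @name variant-conventions
#' @description
#' All coordinates in the package are 1-based positions on a single genome
#' build (GRCh37 by convention). Every table file carries a `# build=` header
#' comment and [run_pipeline()] refuses to mix builds. Variants are identified
#' by rsID when available and otherwise by `chrom:pos`.
NULL

#' Canonical variant identifier
#'
#' Returns the rsID when present and non-empty, otherwise `chrom:pos`.
#'
#' @param chrom chromosome label(s), e.g. `"6"` or `"chr6"`.
#' @param pos 1-based integer position(s).
#' @param rsid optional rsID(s); `NA` or `""` mean absent.
#' @return character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, rsid = NA_character_) {
  fallback <- paste0(norm_chrom(chrom), ":", as.integer(pos))
  rsid <- rep_len(as.character(rsid), length(fallback))
  ifelse(is.na(rsid) | rsid == "" | rsid == ".", fallback, rsid)
}

# strip a leading "chr" prefix so "chr6" and "6" compare equal
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Test whether variants lie in the MHC region
#'
#' The major histocompatibility complex region is taken as the closed
#' interval chr6:27,000,000-33,000,000 on GRCh37. Boundary positions are
#' inside the region (closed interval convention).
#'
#' @param chrom chromosome label(s).
#' @param pos 1-based position(s).
#' @param interval length-2 numeric, the closed interval in bp.
#' @return logical vector.
#' @examples
#' in_mhc("6", 30e6)        # TRUE
#' in_mhc("chr6", 26999999) # FALSE
#' in_mhc("7", 30e6)        # FALSE
#' @export
in_mhc <- function(chrom, pos, interval = c(27e6, 33e6)) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  norm_chrom(chrom) == "6" & pos >= interval[1] & pos <= interval[2]
}

# Variant-consequence ontology, most severe first, following the standard
# ordering used by variant effect annotation tools. Only the relative rank
# matters here: "missense or more deleterious" means rank <= rank(missense).
.consequence_severity <- c(
  "transcript_ablation",
  "splice_acceptor_variant",
  "splice_donor_variant",
  "stop_gained",
  "frameshift_variant",
  "stop_lost",
  "start_lost",
  "transcript_amplification",
  "feature_elongation",
  "feature_truncation",
  "inframe_insertion",
  "inframe_deletion",
  "missense_variant",
  "protein_altering_variant",
  "splice_donor_5th_base_variant",
  "splice_region_variant",
  "splice_donor_region_variant",
  "splice_polypyrimidine_tract_variant",
  "incomplete_terminal_codon_variant",
  "start_retained_variant",
  "stop_retained_variant",
  "synonymous_variant",
  "coding_sequence_variant",
  "mature_miRNA_variant",
  "5_prime_UTR_variant",
  "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant",
  "intron_variant",
  "NMD_transcript_variant",
  "non_coding_transcript_variant",
  "coding_transcript_variant",
  "upstream_gene_variant",
  "downstream_gene_variant",
  "TFBS_ablation",
  "TFBS_amplification",
  "TF_binding_site_variant",
  "regulatory_region_ablation",
  "regulatory_region_amplification",
  "regulatory_region_variant",
  "intergenic_variant",
  "sequence_variant"
)

#' Consequence severity ranking
#'
#' `consequence_rank()` maps consequence classes to their ordinal severity
#' (1 = most severe) in the embedded consequence ontology;
#' `consequence_classes()` returns the ontology, most severe first.
#' Unknown classes raise an error naming the offending class.
#'
#' @param consequence character vector of consequence classes.
#' @return integer vector of ranks.
#' @export
consequence_rank <- function(consequence) {
  r <- match(consequence, .consequence_severity)
  if (anyNA(r)) {
    bad <- unique(consequence[is.na(r)])
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r
}

#' @rdname consequence_rank
#' @export
consequence_classes <- function() .consequence_severity

# rank of missense_variant, the severity cutoff used throughout
.missense_rank <- match("missense_variant", .consequence_severity)
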