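#' Genotype reference panel
#'
#' Container for an unphased diploid genotype panel: a variant table plus a
#' variants-by-samples integer matrix of counts of `allele_b` (0, 1, 2 or
#' `NA` for missing). Stands in for a population reference panel such as a
#' 1000-Genomes subset.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `allele_a`,
#'   `allele_b` and optionally `rsid`.
#' @param geno integer matrix, `nrow(variants)` x `length(samples)`, values
#'   in \{0, 1, 2, NA\}.
#' @param samples character vector of sample identifiers.
#' @return object of class `"genotype_panel"` with elements `variants`
#'   (including an `id` column), `geno` and `samples`.
#' @export
genotype_panel <- function(variants, geno, samples) {
  stopifnot(is.data.frame(variants), is.matrix(geno))
  req <- c("chrom", "pos", "allele_a", "allele_b")
  missing <- setdiff(req, names(variants))
  if (length(missing)) {
    stop("panel variants lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(geno) != nrow(variants)) {
    stop("geno has ", nrow(geno), " rows but there are ", nrow(variants),
         " variants", call. = FALSE)
  }
  if (ncol(geno) != length(samples)) {
    stop("geno has ", ncol(geno), " columns but there are ", length(samples),
         " samples", call. = FALSE)
  }
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  if (any(variants$allele_a == variants$allele_b)) {
    stop("allele_a and allele_b must differ for every variant", call. = FALSE)
  }
  v <- variants
  v$chrom <- norm_chrom(v$chrom)
  v$pos <- as.integer(v$pos)
  if (is.null(v$rsid)) v$rsid <- NA_character_
  v$id <- variant_id(v$chrom, v$pos, v$rsid)
  if (anyDuplicated(v$id)) {
    stop("duplicate variant id in panel: ", v$id[duplicated(v$id)][1],
         call. = FALSE)
  }
  mode(geno) <- "integer"
  rownames(geno) <- v$id
  colnames(geno) <- samples
  structure(list(variants = v, geno = geno, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "),
      "\n")
  n_miss <- sum(is.na(x$geno))
  if (n_miss > 0) cat("  missing genotypes:", n_miss, "\n")
  invisible(x)
}

#' Read a genotype panel
#'
#' `read_panel()` dispatches on the file extension: `.vcf` goes through the
#' minimal-VCF reader (requires the VariantAnnotation package), anything else
#' is read as the matrix TSV format written by [write_panel()]: comment
#' header, then columns `chrom`, `pos`, `rsid`, `alleles` followed by one
#' column per sample holding 0/1/2 counts of `allele_b` (empty or `.` =
#' missing).
#'
#' @param path panel file.
#' @return a [genotype_panel()] with attribute `build`.
#' @export
read_panel <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    read_panel_vcf(path)
  } else {
    read_panel_tsv(path)
  }
}

#' @rdname read_panel
#' @export
read_panel_tsv <- function(path) {
  raw <- oxi_read_tsv(path)
  df <- raw$df
  require_columns(df, c("chrom", "pos", "rsid", "alleles"), path)
  fl <- raw$first_data_line
  sample_cols <- setdiff(names(df), c("chrom", "pos", "rsid", "alleles"))
  if (length(sample_cols) == 0L) {
    stop("panel TSV has no sample columns: ", path, call. = FALSE)
  }
  pos <- parse_num(df$pos, "pos", fl)
  al <- split_alleles(df$alleles, fl)
  geno <- matrix(NA_integer_, nrow = nrow(df), ncol = length(sample_cols))
  for (j in seq_along(sample_cols)) {
    x <- trimws(df[[sample_cols[j]]])
    x[x == "." | x == ""] <- NA
    g <- suppressWarnings(as.integer(x))
    bad <- (!is.na(x)) & (is.na(g) | !(g %in% 0:2))
    if (any(bad)) {
      stop(sprintf("bad genotype '%s' for sample %s at line %d",
                   x[which(bad)[1]], sample_cols[j], fl + which(bad)[1] - 1L),
           call. = FALSE)
    }
    geno[, j] <- g
  }
  variants <- data.frame(chrom = df$chrom, pos = as.integer(pos),
                         rsid = ifelse(df$rsid %in% c("", "."),
                                       NA_character_, df$rsid),
                         allele_a = al$a, allele_b = al$b,
                         stringsAsFactors = FALSE)
  panel <- genotype_panel(variants, geno, sample_cols)
  attr(panel, "build") <- unname(raw$meta["build"])
  panel
}

#' @rdname read_panel
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF panels requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L)) {
    stop("multi-allelic sites are not supported (variant ",
         names(vcf)[which(n_alt != 1L)[1]], ")", call. = FALSE)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path, call. = FALSE)
  count_alt <- function(s) {
    if (s %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1]]
    if (length(a) != 2L || any(!a %in% c("0", "1"))) {
      stop("unsupported genotype string '", s, "' (diploid GT only)",
           call. = FALSE)
    }
    sum(a == "1")
  }
  geno <- matrix(vapply(gt, count_alt, 1L), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  variants <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    rsid = ifelse(grepl("^rs", names(rr)), names(rr), NA_character_),
    allele_a = as.character(rr$REF),
    allele_b = as.character(unlist(alt)),
    stringsAsFactors = FALSE
  )
  panel <- genotype_panel(variants, geno, colnames(gt))
  attr(panel, "build") <- "GRCh37"
  panel
}

#' @rdname read_panel
#' @param panel a [genotype_panel()].
#' @param build,seed values recorded in the comment header.
#' @export
write_panel <- function(panel, path, build = "GRCh37", seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  geno_chr <- matrix(as.character(panel$geno), nrow = nrow(panel$geno))
  geno_chr[is.na(geno_chr)] <- "."
  df <- data.frame(chrom = v$chrom, pos = v$pos,
                   rsid = ifelse(is.na(v$rsid), ".", v$rsid),
                   alleles = paste0(v$allele_a, "/", v$allele_b),
                   stringsAsFactors = FALSE)
  for (j in seq_along(panel$samples)) df[[panel$samples[j]]] <- geno_chr[, j]
  oxi_write_tsv(df, path, build = build, seed = seed)
}
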