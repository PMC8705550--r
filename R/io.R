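#' @title Table input/output
#' @description
#' All tabular inputs are TSV files with a header row, optionally preceded by
#' `#`-prefixed comment lines of the form `# key=value`. The `build` key
#' declares the genome build of the coordinates in the file; readers attach it
#' as the `"build"` attribute and [run_pipeline()] requires all inputs to
#' agree. Malformed rows raise errors that name the file line.
#' @name table-io
NULL

# -- low-level helpers --------------------------------------------------------

# Read a commented TSV: returns the data.frame (all columns character),
# the key=value metadata from leading comment lines, and the file line number
# of the first data row (for row-level error messages).
oxi_read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^#", lines)
  n_head <- if (any(!is_comment)) which(!is_comment)[1] - 1L else length(lines)
  meta <- character(0)
  if (n_head > 0) {
    kv <- sub("^#\\s*", "", lines[seq_len(n_head)])
    kv <- kv[grepl("=", kv, fixed = TRUE)]
    if (length(kv)) {
      meta <- sub("^[^=]*=\\s*", "", kv)
      names(meta) <- trimws(sub("=.*$", "", kv))
    }
  }
  body <- lines[-seq_len(n_head)]
  if (length(body) < 1L) stop("no header row in ", path, call. = FALSE)
  df <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  list(df = df, meta = meta, first_data_line = n_head + 2L)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# Parse a numeric column, reporting the 1-based file line of the first bad row.
parse_num <- function(x, field, first_line, allow_na = FALSE) {
  blank <- is.na(x) | trimws(x) == ""
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !blank
  if (any(bad)) {
    stop(sprintf("unparsable number in column '%s' at line %d: '%s'",
                 field, first_line + which(bad)[1] - 1L, x[which(bad)[1]]),
         call. = FALSE)
  }
  if (!allow_na && any(blank)) {
    stop(sprintf("missing value in column '%s' at line %d",
                 field, first_line + which(blank)[1] - 1L), call. = FALSE)
  }
  out
}

parse_logical <- function(x, field, first_line) {
  v <- toupper(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO", "")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("unparsable logical in column '%s' at line %d: '%s'",
                 field, first_line + which(is.na(out))[1] - 1L,
                 x[which(is.na(out))[1]]), call. = FALSE)
  }
  out
}

# split an "A/G" alleles field into two columns
split_alleles <- function(alleles, first_line) {
  parts <- strsplit(alleles, "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop(sprintf("alleles field must be 'A/B' at line %d: '%s'",
                 first_line + which(bad)[1] - 1L, alleles[which(bad)[1]]),
         call. = FALSE)
  }
  a <- toupper(vapply(parts, `[`, "", 1L))
  b <- toupper(vapply(parts, `[`, "", 2L))
  same <- a == b
  if (any(same)) {
    stop(sprintf("identical alleles at line %d: '%s'",
                 first_line + which(same)[1] - 1L, alleles[which(same)[1]]),
         call. = FALSE)
  }
  list(a = a, b = b)
}

# Write a data.frame as a commented TSV. Floats are written with 17
# significant digits so a write/read round trip is lossless.
oxi_write_tsv <- function(df, path, build = "GRCh37", seed = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         formatC(out[[j]], digits = 17, format = "g"))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# build=", build), con)
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
#' @rdname table-io
#' @param x object returned by a reader.
get_build <- function(x) attr(x, "build", exact = TRUE)

# -- GWAS hits ----------------------------------------------------------------

#' Read GWAS index hits
#'
#' Reads a TSV of index (top) associations, one row per locus, and applies the
#' intake significance gate: rows with `p_value >= p_max` are dropped and
#' counted in the `"n_dropped"` attribute (the retained set satisfies
#' p < 1e-5 by default).
#'
#' Required columns: `chrom`, `pos`, `alleles` (as `"A/G"`), `risk_allele`,
#' `p_value`, `odds_ratio`, `study_id`; optional `rsid`.
#'
#' @param path TSV file path.
#' @param p_max significance gate; rows at or above it are dropped.
#' @return data.frame with columns `id`, `chrom`, `pos`, `rsid`, `allele_a`,
#'   `allele_b`, `risk_allele`, `p_value`, `odds_ratio`, `study_id`;
#'   attributes `n_dropped` (count of sub-threshold rows) and `build`.
#' @export
read_gwas_hits <- function(path, p_max = 1e-5) {
  raw <- oxi_read_tsv(path)
  df <- raw$df
  require_columns(df, c("chrom", "pos", "alleles", "risk_allele",
                        "p_value", "odds_ratio", "study_id"), path)
  fl <- raw$first_data_line
  pos <- parse_num(df$pos, "pos", fl)
  if (any(pos < 1 | pos != floor(pos))) {
    stop("pos must be a positive integer (line ",
         fl + which(pos < 1 | pos != floor(pos))[1] - 1L, ")", call. = FALSE)
  }
  al <- split_alleles(df$alleles, fl)
  p <- parse_num(df$p_value, "p_value", fl)
  or <- parse_num(df$odds_ratio, "odds_ratio", fl)
  if (any(p <= 0 | p > 1)) {
    stop("p_value must lie in (0, 1] (line ",
         fl + which(p <= 0 | p > 1)[1] - 1L, ")", call. = FALSE)
  }
  if (any(or <= 0)) {
    stop("odds_ratio must be > 0 (line ",
         fl + which(or <= 0)[1] - 1L, ")", call. = FALSE)
  }
  risk <- toupper(trimws(df$risk_allele))
  bad <- risk != al$a & risk != al$b
  if (any(bad)) {
    stop(sprintf("risk_allele not among the variant alleles at line %d",
                 fl + which(bad)[1] - 1L), call. = FALSE)
  }
  rsid <- if ("rsid" %in% names(df)) df$rsid else NA_character_
  hits <- data.frame(
    id = variant_id(df$chrom, pos, rsid),
    chrom = norm_chrom(df$chrom),
    pos = as.integer(pos),
    rsid = ifelse(is.na(rsid) | rsid == "", NA_character_, rsid),
    allele_a = al$a, allele_b = al$b,
    risk_allele = risk,
    p_value = p, odds_ratio = or,
    study_id = df$study_id,
    stringsAsFactors = FALSE
  )
  keep <- hits$p_value < p_max
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "build") <- unname(raw$meta["build"])
  out
}

#' @rdname read_gwas_hits
#' @param hits data.frame of hits as returned by `read_gwas_hits()`.
#' @param build,seed values recorded in the file's comment header.
#' @export
write_gwas_hits <- function(hits, path, build = "GRCh37", seed = NULL) {
  df <- data.frame(chrom = hits$chrom, pos = hits$pos,
                   rsid = ifelse(is.na(hits$rsid), "", hits$rsid),
                   alleles = paste0(hits$allele_a, "/", hits$allele_b),
                   risk_allele = hits$risk_allele,
                   p_value = hits$p_value, odds_ratio = hits$odds_ratio,
                   study_id = hits$study_id, stringsAsFactors = FALSE)
  oxi_write_tsv(df, path, build = build, seed = seed)
}

# -- molecular QTL catalogue --------------------------------------------------

.qtl_types <- c("eQTL", "pQTL", "sQTL", "polyQTL", "mQTL")

#' Read a molecular-QTL catalogue
#'
#' One row per (variant, gene, tissue, QTL type) regulation record. The
#' `effect_sign` column gives the direction of the effect-allele's effect on
#' the molecular trait (`+1`/`-1`); it may be empty when the direction is not
#' available from the source, in which case the record still supports target
#' mapping and scoring but never a direction-of-effect call.
#'
#' Required columns: `chrom`, `pos`, `alleles`, `effect_allele`, `gene`,
#' `qtl_type` (one of eQTL, pQTL, sQTL, polyQTL, mQTL), `tissue`,
#' `effect_sign`; optional `rsid`.
#'
#' @param path TSV file path.
#' @return data.frame with attribute `build`.
#' @export
read_qtl_table <- function(path) {
  raw <- oxi_read_tsv(path)
  df <- raw$df
  require_columns(df, c("chrom", "pos", "alleles", "effect_allele", "gene",
                        "qtl_type", "tissue", "effect_sign"), path)
  fl <- raw$first_data_line
  pos <- parse_num(df$pos, "pos", fl)
  al <- split_alleles(df$alleles, fl)
  eff <- toupper(trimws(df$effect_allele))
  bad <- eff != al$a & eff != al$b
  if (any(bad)) {
    stop(sprintf("effect_allele not among the variant alleles at line %d",
                 fl + which(bad)[1] - 1L), call. = FALSE)
  }
  qt <- trimws(df$qtl_type)
  badq <- !(qt %in% .qtl_types)
  if (any(badq)) {
    stop(sprintf("unknown qtl_type '%s' at line %d (expected one of %s)",
                 qt[which(badq)[1]], fl + which(badq)[1] - 1L,
                 paste(.qtl_types, collapse = ", ")), call. = FALSE)
  }
  sgn <- parse_num(df$effect_sign, "effect_sign", fl, allow_na = TRUE)
  bads <- !is.na(sgn) & !(sgn %in% c(-1, 1))
  if (any(bads)) {
    stop(sprintf("effect_sign must be +1, -1 or empty at line %d",
                 fl + which(bads)[1] - 1L), call. = FALSE)
  }
  rsid <- if ("rsid" %in% names(df)) df$rsid else NA_character_
  out <- data.frame(
    id = variant_id(df$chrom, pos, rsid),
    chrom = norm_chrom(df$chrom), pos = as.integer(pos),
    rsid = ifelse(is.na(rsid) | rsid == "", NA_character_, rsid),
    allele_a = al$a, allele_b = al$b,
    effect_allele = eff,
    gene = toupper(trimws(df$gene)),
    qtl_type = qt,
    tissue = trimws(df$tissue),
    effect_sign = as.integer(sgn),
    stringsAsFactors = FALSE
  )
  attr(out, "build") <- unname(raw$meta["build"])
  out
}

#' @rdname read_qtl_table
#' @param qtls data.frame as returned by `read_qtl_table()`.
#' @inheritParams write_gwas_hits
#' @export
write_qtl_table <- function(qtls, path, build = "GRCh37", seed = NULL) {
  df <- data.frame(chrom = qtls$chrom, pos = qtls$pos,
                   rsid = ifelse(is.na(qtls$rsid), "", qtls$rsid),
                   alleles = paste0(qtls$allele_a, "/", qtls$allele_b),
                   effect_allele = qtls$effect_allele, gene = qtls$gene,
                   qtl_type = qtls$qtl_type, tissue = qtls$tissue,
                   effect_sign = ifelse(is.na(qtls$effect_sign), "",
                                        sprintf("%+d", qtls$effect_sign)),
                   stringsAsFactors = FALSE)
  oxi_write_tsv(df, path, build = build, seed = seed)
}

# -- consequence annotations --------------------------------------------------

#' Read variant consequence annotations
#'
#' One row per (variant, gene) functional annotation with a consequence class
#' from the embedded ontology (see [consequence_classes()]) and a CADD-Phred
#' deleteriousness score.
#'
#' Required columns: `chrom`, `pos`, `gene`, `consequence`, `cadd_phred`;
#' optional `rsid`.
#'
#' @param path TSV file path.
#' @return data.frame with attribute `build`.
#' @export
read_consequences <- function(path) {
  raw <- oxi_read_tsv(path)
  df <- raw$df
  require_columns(df, c("chrom", "pos", "gene", "consequence", "cadd_phred"),
                  path)
  fl <- raw$first_data_line
  pos <- parse_num(df$pos, "pos", fl)
  cadd <- parse_num(df$cadd_phred, "cadd_phred", fl)
  if (any(cadd < 0)) {
    stop("cadd_phred must be >= 0 (line ",
         fl + which(cadd < 0)[1] - 1L, ")", call. = FALSE)
  }
  consequence_rank(trimws(df$consequence))  # validates the vocabulary
  rsid <- if ("rsid" %in% names(df)) df$rsid else NA_character_
  out <- data.frame(
    id = variant_id(df$chrom, pos, rsid),
    chrom = norm_chrom(df$chrom), pos = as.integer(pos),
    rsid = ifelse(is.na(rsid) | rsid == "", NA_character_, rsid),
    gene = toupper(trimws(df$gene)),
    consequence = trimws(df$consequence),
    cadd_phred = cadd,
    stringsAsFactors = FALSE
  )
  attr(out, "build") <- unname(raw$meta["build"])
  out
}

#' @rdname read_consequences
#' @param records data.frame as returned by `read_consequences()`.
#' @inheritParams write_gwas_hits
#' @export
write_consequences <- function(records, path, build = "GRCh37", seed = NULL) {
  df <- data.frame(chrom = records$chrom, pos = records$pos,
                   rsid = ifelse(is.na(records$rsid), "", records$rsid),
                   gene = records$gene, consequence = records$consequence,
                   cadd_phred = records$cadd_phred, stringsAsFactors = FALSE)
  oxi_write_tsv(df, path, build = build, seed = seed)
}

# -- pathways (GMT) -----------------------------------------------------------

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols. Member symbols are uppercased and de-duplicated.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `"pathway_sets"`), one per
#'   pathway.
#' @seealso [pathway_union()]
#' @export
read_pathways_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[trimws(lines) != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(toupper(trimws(f[-(1:2)]))))
  names(sets) <- vapply(fields, `[`, "", 1L)
  structure(sets, class = "pathway_sets")
}

#' Union of pathway members
#'
#' @param pathways a `"pathway_sets"` list from [read_pathways_gmt()].
#' @return character vector of unique member symbols.
#' @export
pathway_union <- function(pathways) {
  unique(unlist(pathways, use.names = FALSE))
}

#' @export
print.pathway_sets <- function(x, ...) {
  cat(length(x), "pathway set(s),", length(pathway_union(x)),
      "unique members\n")
  invisible(x)
}

#' @rdname read_pathways_gmt
#' @param pathways named list of member vectors.
#' @export
write_pathways_gmt <- function(pathways, path) {
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], "na", pathways[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# -- drug-target interactions -------------------------------------------------

.drug_statuses <- c("approved", "phase1", "phase2", "phase3", "experimental")

#' Read a drug-target interaction table
#'
#' Required columns: `drug`, `target_gene`, `mechanism` (inhibit / activate /
#' other), `status` (approved, phase1..3, experimental), `interaction_score`
#' (may be empty), `direct_action`, `validated_modulator` (logicals),
#' `source_db`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_drug_table <- function(path) {
  raw <- oxi_read_tsv(path)
  df <- raw$df
  require_columns(df, c("drug", "target_gene", "mechanism", "status",
                        "interaction_score", "direct_action",
                        "validated_modulator", "source_db"), path)
  fl <- raw$first_data_line
  mech <- trimws(df$mechanism)
  badm <- !(mech %in% c("inhibit", "activate", "other"))
  if (any(badm)) {
    stop(sprintf("mechanism must be inhibit/activate/other at line %d: '%s'",
                 fl + which(badm)[1] - 1L, mech[which(badm)[1]]),
         call. = FALSE)
  }
  st <- trimws(df$status)
  bads <- !(st %in% .drug_statuses)
  if (any(bads)) {
    stop(sprintf("unknown status '%s' at line %d", st[which(bads)[1]],
                 fl + which(bads)[1] - 1L), call. = FALSE)
  }
  score <- parse_num(df$interaction_score, "interaction_score", fl,
                     allow_na = TRUE)
  if (any(!is.na(score) & score < 0)) {
    stop("interaction_score must be >= 0", call. = FALSE)
  }
  data.frame(
    drug = trimws(df$drug),
    target_gene = toupper(trimws(df$target_gene)),
    mechanism = mech, status = st,
    interaction_score = score,
    direct_action = parse_logical(df$direct_action, "direct_action", fl),
    validated_modulator = parse_logical(df$validated_modulator,
                                        "validated_modulator", fl),
    source_db = trimws(df$source_db),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_drug_table
#' @param drugs data.frame as returned by `read_drug_table()`.
#' @export
write_drug_table <- function(drugs, path) {
  df <- drugs
  df$interaction_score <- ifelse(is.na(df$interaction_score), "",
                                 formatC(df$interaction_score, digits = 17,
                                         format = "g"))
  oxi_write_tsv(df, path, build = "GRCh37")
}

# -- ADME descriptor profiles -------------------------------------------------

#' Read ADME-Tox descriptor profiles
#'
#' Required columns: `compound`, `cns_activity` (integer in \[-2, 2\]),
#' `log_bb`, `mdck_perm` (nm/sec), `caco2_perm` (nm/sec),
#' `human_oral_absorption` (ordinal class 1-3), `pct_human_absorption`
#' (percent, 0-100). Empty cells become `NA` (a missing descriptor fails the
#' corresponding ADME rule).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_adme_table <- function(path) {
  raw <- oxi_read_tsv(path)
  df <- raw$df
  cols <- c("compound", "cns_activity", "log_bb", "mdck_perm", "caco2_perm",
            "human_oral_absorption", "pct_human_absorption")
  require_columns(df, cols, path)
  fl <- raw$first_data_line
  num <- lapply(cols[-1], function(cl) parse_num(df[[cl]], cl, fl,
                                                 allow_na = TRUE))
  names(num) <- cols[-1]
  if (any(!is.na(num$cns_activity) & abs(num$cns_activity) > 2)) {
    stop("cns_activity must lie in [-2, 2]", call. = FALSE)
  }
  if (any(!is.na(num$pct_human_absorption) &
          (num$pct_human_absorption < 0 | num$pct_human_absorption > 100))) {
    stop("pct_human_absorption must lie in [0, 100]", call. = FALSE)
  }
  if (any(!is.na(num$human_oral_absorption) &
          !(num$human_oral_absorption %in% 1:3))) {
    stop("human_oral_absorption must be an ordinal class 1, 2 or 3",
         call. = FALSE)
  }
  data.frame(compound = trimws(df$compound),
             cns_activity = as.integer(num$cns_activity),
             log_bb = num$log_bb,
             mdck_perm = num$mdck_perm,
             caco2_perm = num$caco2_perm,
             human_oral_absorption = as.integer(num$human_oral_absorption),
             pct_human_absorption = num$pct_human_absorption,
             stringsAsFactors = FALSE)
}

#' @rdname read_adme_table
#' @param profiles data.frame as returned by `read_adme_table()`.
#' @export
write_adme_table <- function(profiles, path) {
  oxi_write_tsv(profiles, path, build = "GRCh37")
}
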