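#' Filter consequence annotations to functionally relevant variants
#'
#' Keeps records whose consequence class is missense or more severe (rank at
#' or above missense in the embedded ontology) and whose CADD-Phred score
#' strictly exceeds `cadd_min`. A record at exactly `cadd_min` is dropped.
#'
#' @param records data.frame from [read_consequences()].
#' @param cadd_min CADD-Phred cutoff (strict).
#' @return the retained rows, with attribute `n_dropped`.
#' @export
consequence_filter <- function(records, cadd_min = 15) {
  stopifnot(cadd_min >= 0)
  if (nrow(records) == 0L) {
    attr(records, "n_dropped") <- 0L
    return(records)
  }
  rank <- consequence_rank(records$consequence)
  keep <- rank <= .missense_rank & records$cadd_phred > cadd_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "build") <- attr(records, "build", exact = TRUE)
  out
}

#' Map GWAS hits to gene targets through proxies, QTLs and consequences
#'
#' A gene becomes a target when a hit variant, or a proxy in strong LD with a
#' hit, (a) is a molecular QTL for the gene, or (b) carries a functionally
#' relevant consequence annotation for the gene (pass `consequences` through
#' [consequence_filter()] first). Each supporting record becomes one evidence
#' row carrying the proxy LD to the hit (`ld_to_hit`, 1 for the hit itself)
#' and the proxy allele coupled to the risk allele.
#'
#' Genes listed in `mhc_genes` are always excluded. When
#' `exclude_all_mhc_evidence` is `TRUE` (default), genes all of whose
#' evidence variants lie inside the MHC interval are also excluded; variants
#' inside the interval remain usable evidence for genes that have at least
#' one evidence variant outside it (such hits are down-weighted at the
#' scoring stage instead).
#'
#' @param hits GWAS hits from [read_gwas_hits()].
#' @param proxy_map proxy table from [expand_proxies()]; must cover every hit.
#' @param qtls QTL catalogue from [read_qtl_table()].
#' @param consequences filtered consequence records (may be `NULL`).
#' @param mhc_genes character vector of gene symbols to exclude.
#' @param mhc_interval closed MHC interval in bp on chromosome 6.
#' @param exclude_all_mhc_evidence drop genes with no evidence outside MHC.
#' @return object of class `"target_set"`: list with `evidence` (one row per
#'   evidence), `summary` (one row per retained gene), `excluded`
#'   (data.frame of excluded genes and reasons).
#' @export
map_targets <- function(hits, proxy_map, qtls, consequences = NULL,
                        mhc_genes = character(0),
                        mhc_interval = c(27e6, 33e6),
                        exclude_all_mhc_evidence = TRUE) {
  if (!all(hits$id %in% proxy_map$hit_id)) {
    missing <- setdiff(hits$id, proxy_map$hit_id)
    stop("proxy_map does not cover hit(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pm <- merge(proxy_map,
              hits[, c("id", "p_value", "odds_ratio", "chrom", "pos",
                       "risk_allele")],
              by.x = "hit_id", by.y = "id", suffixes = c("", "_hit"))
  names(pm)[names(pm) == "p_value"] <- "hit_p"
  names(pm)[names(pm) == "odds_ratio"] <- "hit_or"
  names(pm)[names(pm) == "chrom_hit"] <- "hit_chrom"
  names(pm)[names(pm) == "pos_hit"] <- "hit_pos"

  ev_list <- list()
  if (nrow(qtls) > 0L) {
    q <- merge(pm, qtls[, c("id", "gene", "qtl_type", "tissue",
                            "effect_allele", "effect_sign")],
               by.x = "proxy_id", by.y = "id")
    if (nrow(q) > 0L) {
      ev_list$qtl <- data.frame(
        gene = q$gene, hit_id = q$hit_id, hit_p = q$hit_p, hit_or = q$hit_or,
        hit_chrom = q$hit_chrom, hit_pos = q$hit_pos,
        via_id = q$proxy_id, via_chrom = q$chrom, via_pos = q$pos,
        kind = "qtl", qtl_type = q$qtl_type, tissue = q$tissue,
        effect_allele = q$effect_allele, effect_sign = q$effect_sign,
        ld_to_hit = q$r2, risk_coupled = q$risk_coupled,
        degenerate = q$degenerate,
        consequence = NA_character_, cadd_phred = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(consequences) && nrow(consequences) > 0L) {
    cq <- merge(pm, consequences[, c("id", "gene", "consequence",
                                     "cadd_phred")],
                by.x = "proxy_id", by.y = "id")
    if (nrow(cq) > 0L) {
      ev_list$consequence <- data.frame(
        gene = cq$gene, hit_id = cq$hit_id, hit_p = cq$hit_p,
        hit_or = cq$hit_or, hit_chrom = cq$hit_chrom, hit_pos = cq$hit_pos,
        via_id = cq$proxy_id, via_chrom = cq$chrom, via_pos = cq$pos,
        kind = "consequence", qtl_type = NA_character_,
        tissue = NA_character_, effect_allele = NA_character_,
        effect_sign = NA_integer_,
        ld_to_hit = cq$r2, risk_coupled = cq$risk_coupled,
        degenerate = cq$degenerate,
        consequence = cq$consequence, cadd_phred = cq$cadd_phred,
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ev_list)
  if (is.null(ev) || nrow(ev) == 0L) {
    ev <- data.frame(gene = character(0))
    return(structure(list(evidence = ev,
                          summary = data.frame(gene = character(0)),
                          excluded = data.frame(gene = character(0),
                                                reason = character(0))),
                     class = "target_set"))
  }
  # deterministic order regardless of input row order
  ev <- ev[order(ev$gene, ev$hit_id, ev$via_id, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL

  in_mhc_ev <- in_mhc(ev$via_chrom, ev$via_pos, mhc_interval)
  genes <- unique(ev$gene)
  excluded <- data.frame(gene = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  drop_listed <- genes[genes %in% toupper(mhc_genes)]
  if (length(drop_listed)) {
    excluded <- rbind(excluded,
                      data.frame(gene = drop_listed, reason = "mhc_gene_list",
                                 stringsAsFactors = FALSE))
  }
  if (exclude_all_mhc_evidence) {
    all_in <- vapply(genes, function(g) all(in_mhc_ev[ev$gene == g]), TRUE)
    drop_mhc <- setdiff(genes[all_in], drop_listed)
    if (length(drop_mhc)) {
      excluded <- rbind(excluded,
                        data.frame(gene = drop_mhc,
                                   reason = "all_evidence_in_mhc",
                                   stringsAsFactors = FALSE))
    }
  }
  keep <- !(ev$gene %in% excluded$gene)
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL

  if (nrow(ev) == 0L) {
    empty <- data.frame(gene = character(0), n_evidence = integer(0),
                        best_ld = numeric(0), evidence_kinds = character(0),
                        mhc_flag = logical(0), stringsAsFactors = FALSE)
    return(structure(list(evidence = ev, summary = empty,
                          excluded = excluded), class = "target_set"))
  }
  summary <- do.call(rbind, lapply(split(ev, ev$gene), function(g) {
    kinds <- ifelse(g$kind == "qtl",
                    paste0("qtl:", g$qtl_type, ":", g$tissue), g$kind)
    data.frame(gene = g$gene[1], n_evidence = nrow(g),
               best_ld = max(g$ld_to_hit),
               evidence_kinds = paste(sort(unique(kinds)), collapse = ";"),
               mhc_flag = all(in_mhc(g$via_chrom, g$via_pos, mhc_interval)),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(evidence = ev, summary = summary, excluded = excluded),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("target_set:", nrow(x$summary), "gene target(s),",
      nrow(x$evidence), "evidence row(s)\n")
  if (nrow(x$excluded)) {
    cat("  excluded:", nrow(x$excluded), "gene(s) (",
        paste(sprintf("%s: %d", names(table(x$excluded$reason)),
                      table(x$excluded$reason)), collapse = ", "), ")\n")
  }
  invisible(x)
}

#' @rdname map_targets
#' @param targets a `"target_set"`.
#' @param path output TSV path.
#' @export
write_targets <- function(targets, path) {
  oxi_write_tsv(targets$summary, path, build = "GRCh37")
}

#' Restrict a target set to given genes
#'
#' Internal helper shared by the pathway-overlap stage.
#' @noRd
subset_target_set <- function(targets, genes) {
  ev <- targets$evidence[targets$evidence$gene %in% genes, , drop = FALSE]
  sm <- targets$summary[targets$summary$gene %in% genes, , drop = FALSE]
  rownames(ev) <- NULL
  rownames(sm) <- NULL
  structure(list(evidence = ev, summary = sm, excluded = targets$excluded),
            class = "target_set")
}
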