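#' Scoring configuration for target prioritization
#'
#' Holds the constants of the five-criterion genetic prioritization score:
#'
#' * **c1** — top hit genome-wide significant (p < `gw_sig_p`): 5 points, or
#'   2 if every such hit lies in the MHC region;
#' * **c2** — top hit with a high disease effect (OR > `or_threshold`), with
#'   a decreasing score by LD to a gene-level molecular QTL proxy
#'   (`c2_bins`: >= 0.99 -> 4, \[0.95, 0.99) -> 3, \[0.90, 0.95) -> 2,
#'   \[0.80, 0.90) -> 1);
#' * **c3** — eQTL available: 10 points, plus 5 if an eQTL acts in
#'   `brain_tissue`;
#' * **c4** — LD between the top hit and an eQTL (`c4_bins`: >= 0.99 -> 5,
#'   then 3/2/1 over the same bins as c2);
#' * **c5** — a non-eQTL molecular QTL in LD >= `c5_ld_min` with a top hit:
#'   3 points.
#'
#' The maximum attainable total is 5 + 4 + 15 + 5 + 3 = 32. LD bins are
#' half-open `[lo, hi)` with the top bin closed at 0.99.
#'
#' @param gw_sig_p genome-wide significance threshold for c1.
#' @param or_threshold odds-ratio cutoff for c2 (strict).
#' @param c5_ld_min LD floor for c5.
#' @param top_fraction quantile retained by [select_top()].
#' @param score_threshold reference score cut reported alongside the
#'   quantile selection.
#' @param brain_tissue tissue label earning the c3 bonus.
#' @param mhc_interval closed MHC interval (bp, chromosome 6) for c1.
#' @return list of class `"score_config"`.
#' @export
score_config <- function(gw_sig_p = 5e-8, or_threshold = 1.2,
                         c5_ld_min = 0.99, top_fraction = 0.25,
                         score_threshold = 20, brain_tissue = "brain",
                         mhc_interval = c(27e6, 33e6)) {
  structure(list(gw_sig_p = gw_sig_p, or_threshold = or_threshold,
                 c2_bins = c(`0.99` = 4L, `0.95` = 3L, `0.9` = 2L,
                             `0.8` = 1L),
                 c4_bins = c(`0.99` = 5L, `0.95` = 3L, `0.9` = 2L,
                             `0.8` = 1L),
                 c5_ld_min = c5_ld_min, top_fraction = top_fraction,
                 score_threshold = score_threshold,
                 brain_tissue = brain_tissue, mhc_interval = mhc_interval),
            class = "score_config")
}

# LD bin lookup: bins are [lo, hi) except the top bin which is [0.99, 1].
# `bins` is a named vector, names = lower bounds in decreasing order.
ld_bin_score <- function(ld, bins) {
  lo <- as.numeric(names(bins))
  out <- integer(length(ld))
  for (i in seq_along(lo)) {
    out[ld >= lo[i] & out == 0L] <- bins[[i]]
  }
  out[is.na(ld)] <- 0L
  out
}

#' Intersect gene targets with pathway membership
#'
#' Retains the targets whose gene symbol belongs to the union of the pathway
#' member sets (symbols are compared uppercased). Order-independent.
#'
#' @param targets a `"target_set"` from [map_targets()].
#' @param pathways a `"pathway_sets"` list from [read_pathways_gmt()].
#' @return the restricted `"target_set"`, with attribute `n_before`.
#' @export
overlap_targets <- function(targets, pathways) {
  universe <- toupper(pathway_union(pathways))
  out <- subset_target_set(targets, universe)
  attr(out, "n_before") <- nrow(targets$summary)
  out
}

#' Score gene targets with the five-criterion prioritization scheme
#'
#' For each criterion the maximum applicable value over the target's
#' collected variants is awarded ("met by at least one collected variant").
#' See [score_config()] for the criteria.
#'
#' @param targets a `"target_set"` (normally after [overlap_targets()]).
#' @param cfg a [score_config()].
#' @return data.frame with one row per gene: `gene`, `c1`..`c5`, `total`,
#'   sorted by decreasing total then gene symbol.
#' @export
score_targets <- function(targets, cfg = score_config()) {
  stopifnot(inherits(cfg, "score_config"))
  ev <- targets$evidence
  if (nrow(ev) == 0L) {
    return(data.frame(gene = character(0), c1 = integer(0), c2 = integer(0),
                      c3 = integer(0), c4 = integer(0), c5 = integer(0),
                      total = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(split(ev, ev$gene), function(g) {
    score_one_target(g, cfg)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Score a single gene's evidence block. Exposed through score_targets();
# kept separate so tests can drive hand-built evidence directly.
score_one_target <- function(g, cfg) {
  stopifnot(nrow(g) >= 1L)
  qtl <- g[g$kind == "qtl", , drop = FALSE]
  eqtl <- qtl[qtl$qtl_type == "eQTL", , drop = FALSE]

  # c1: any genome-wide significant top hit; 5 outside MHC, 2 inside
  sig <- g[g$hit_p < cfg$gw_sig_p, , drop = FALSE]
  c1 <- 0L
  if (nrow(sig) > 0L) {
    hit_in_mhc <- in_mhc(sig$hit_chrom, sig$hit_pos, cfg$mhc_interval)
    c1 <- if (any(!hit_in_mhc)) 5L else 2L
  }

  # c2: high-effect hit (OR strictly above threshold), binned by LD to any
  # gene-level molecular QTL proxy of that hit
  c2 <- 0L
  high <- qtl[qtl$hit_or > cfg$or_threshold, , drop = FALSE]
  if (nrow(high) > 0L) {
    c2 <- max(ld_bin_score(high$ld_to_hit, cfg$c2_bins))
  }

  # c3: eQTL available, brain bonus
  c3 <- 0L
  if (nrow(eqtl) > 0L) {
    c3 <- 10L
    if (any(eqtl$tissue == cfg$brain_tissue)) c3 <- 15L
  }

  # c4: LD between top hit and eQTL
  c4 <- if (nrow(eqtl) > 0L) max(ld_bin_score(eqtl$ld_to_hit, cfg$c4_bins))
        else 0L

  # c5: non-eQTL QTL in near-perfect LD with a top hit
  other <- qtl[qtl$qtl_type != "eQTL", , drop = FALSE]
  c5 <- if (nrow(other) > 0L &&
            any(other$ld_to_hit >= cfg$c5_ld_min)) 3L else 0L

  data.frame(gene = g$gene[1], c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
             total = c1 + c2 + c3 + c4 + c5, stringsAsFactors = FALSE)
}

#' Select the top-scoring quantile of targets
#'
#' Retains the top `floor(top_fraction * N)` targets by total score, then
#' extends the selection to include every target tied with the boundary
#' score. The realized threshold (the lowest selected total) is attached as
#' the `"threshold"` attribute and echoed in the pipeline report.
#'
#' @param scores data.frame from [score_targets()].
#' @param cfg a [score_config()] (only `top_fraction` is used).
#' @return `scores` with a logical `selected` column, sorted by decreasing
#'   total; attribute `threshold`.
#' @export
select_top <- function(scores, cfg = score_config()) {
  stopifnot(nrow(scores) > 0L)
  out <- scores[order(-scores$total, scores$gene), , drop = FALSE]
  n_keep <- floor(cfg$top_fraction * nrow(out))
  if (n_keep < 1L) {
    out$selected <- FALSE
    attr(out, "threshold") <- NA_integer_
    rownames(out) <- NULL
    return(out)
  }
  boundary <- out$total[n_keep]
  out$selected <- out$total >= boundary
  attr(out, "threshold") <- boundary
  rownames(out) <- NULL
  out
}

#' @rdname select_top
#' @param path output TSV path.
#' @export
write_scores <- function(scores, path) {
  df <- scores
  if (is.null(df$selected)) df$selected <- NA
  oxi_write_tsv(df, path, build = "GRCh37")
}
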