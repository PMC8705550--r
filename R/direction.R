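#' Couple a risk allele to a QTL effect allele through LD phase
#'
#' The allele of the QTL variant that rides on the same haplotypes as the
#' disease risk allele is the risk allele's coupled allele. When hit and QTL
#' are the same variant the coupling is the identity. A degenerate LD pair
#' (D exactly 0) cannot resolve the phase and returns `NA`.
#'
#' @param hit one row of a hits data.frame (needs `id`, `risk_allele`).
#' @param qtl one row of a QTL data.frame (needs `id`).
#' @param ld an [ld_pair()] relating the two variants (ignored when the
#'   variants are identical).
#' @return the coupled allele (character), or `NA_character_` if unresolved.
#' @export
couple_risk_allele <- function(hit, qtl, ld = NULL) {
  if (hit$id == qtl$id) return(hit$risk_allele)
  if (is.null(ld)) stop("ld pair required when hit and QTL differ",
                        call. = FALSE)
  stopifnot(inherits(ld, "ld_pair"))
  ids <- c(ld$var_a$id, ld$var_b$id)
  if (!setequal(ids, c(hit$id, qtl$id))) {
    stop("ld pair does not relate ", hit$id, " and ", qtl$id, call. = FALSE)
  }
  if (ld$undefined || ld$degenerate) return(NA_character_)
  if (ld$var_a$id == hit$id) {
    unname(ld$coupled[hit$risk_allele])
  } else {
    # invert the bijection
    inv <- stats::setNames(names(ld$coupled), ld$coupled)
    unname(inv[hit$risk_allele])
  }
}

#' Call the direction of the risk-allele effect per gene and tissue
#'
#' For each target gene with QTL evidence in the requested tissue and a known
#' effect sign, the risk allele's coupled allele at the QTL variant
#' determines the direction: if the coupled allele is the QTL effect allele
#' the direction is the effect sign, otherwise its negation. A direction of
#' +1 (risk allele raises the molecular trait) implies therapeutic
#' inhibition; -1 implies activation.
#'
#' One call is emitted per gene, using the evidence with the highest
#' `ld_to_hit`; ties prefer eQTL over other QTL types, then the
#' lexicographically smallest variant id. If equally-ranked top evidences
#' disagree on the direction the call is flagged `conflict` and should be
#' excluded from drug matching. Evidence with a degenerate (phase-unresolved)
#' coupling or an unknown effect sign never contributes.
#'
#' @param targets a `"target_set"` from [map_targets()].
#' @param tissue tissue label the calls are restricted to.
#' @return data.frame with one row per callable gene: `gene`, `tissue`,
#'   `direction` (+1/-1), `modulation` (`"inhibit"`/`"activate"`),
#'   `coupled_allele`, `via_id`, `hit_id`, `qtl_type`, `ld_to_hit`,
#'   `conflict`.
#' @export
call_directions <- function(targets, tissue = "brain") {
  ev <- targets$evidence
  ev <- ev[ev$kind == "qtl" & ev$tissue == tissue &
             !is.na(ev$effect_sign) & !ev$degenerate &
             !is.na(ev$risk_coupled), , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(gene = character(0), tissue = character(0),
                      direction = integer(0), modulation = character(0),
                      coupled_allele = character(0), via_id = character(0),
                      hit_id = character(0), qtl_type = character(0),
                      ld_to_hit = numeric(0), conflict = logical(0),
                      stringsAsFactors = FALSE))
  }
  ev$direction <- ifelse(ev$risk_coupled == ev$effect_allele,
                         ev$effect_sign, -ev$effect_sign)
  calls <- lapply(split(ev, ev$gene), function(g) {
    # rank: highest LD, then eQTL before other QTL types
    best_ld <- max(g$ld_to_hit)
    top <- g[g$ld_to_hit == best_ld, , drop = FALSE]
    if (any(top$qtl_type == "eQTL")) {
      top <- top[top$qtl_type == "eQTL", , drop = FALSE]
    }
    conflict <- length(unique(top$direction)) > 1L
    top <- top[order(top$via_id), , drop = FALSE]
    b <- top[1, ]
    data.frame(gene = b$gene, tissue = tissue,
               direction = as.integer(b$direction),
               modulation = if (b$direction > 0) "inhibit" else "activate",
               coupled_allele = b$risk_coupled,
               via_id = b$via_id, hit_id = b$hit_id, qtl_type = b$qtl_type,
               ld_to_hit = b$ld_to_hit, conflict = conflict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' @rdname call_directions
#' @param directions data.frame from `call_directions()`.
#' @param path output TSV path.
#' @export
write_directions <- function(directions, path) {
  oxi_write_tsv(directions, path, build = "GRCh37")
}
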