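#' ADME-Tox gating thresholds
#'
#' Numeric realizations of the qualitative selection bands for CNS
#' penetration and oral bioavailability: predicted CNS activity at least 0,
#' medium-good blood-brain partition (logBB) and MDCK apparent permeability,
#' high human oral absorption (class and percent) and medium-good Caco2
#' apparent permeability. Defaults follow the descriptor tool's published
#' poor/medium/great conventions: logBB in \[-1.0, 1.2\] (medium cut of the
#' -3..1.2 scale), cell permeabilities at least 100 nm/sec (< 25 poor,
#' > 500 great), oral absorption class 3 of 3 and at least 80 percent.
#'
#' @param cns_min minimum predicted CNS activity (-2..2 scale).
#' @param logbb_range closed interval for logBB.
#' @param mdck_min minimum apparent MDCK permeability, nm/sec.
#' @param caco2_min minimum apparent Caco2 permeability, nm/sec.
#' @param hoa_min_class minimum human-oral-absorption ordinal class (1-3).
#' @param pct_hoa_min minimum percent human absorption.
#' @return list of class `"adme_thresholds"`.
#' @export
adme_thresholds <- function(cns_min = 0, logbb_range = c(-1.0, 1.2),
                            mdck_min = 100, caco2_min = 100,
                            hoa_min_class = 3, pct_hoa_min = 80) {
  stopifnot(length(logbb_range) == 2L, logbb_range[1] <= logbb_range[2])
  structure(list(cns_min = cns_min, logbb_range = logbb_range,
                 mdck_min = mdck_min, caco2_min = caco2_min,
                 hoa_min_class = hoa_min_class, pct_hoa_min = pct_hoa_min),
            class = "adme_thresholds")
}

#' Apply the ADME-Tox descriptor gate
#'
#' Evaluates every rule for every compound and reports per-rule verdicts; a
#' compound passes only if all rules pass. A missing descriptor fails its
#' rule (reason "missing"), hence the compound.
#'
#' @param profiles data.frame from [read_adme_table()].
#' @param th an [adme_thresholds()].
#' @return `profiles` with logical columns `cns_ok`, `logbb_ok`, `mdck_ok`,
#'   `caco2_ok`, `hoa_ok`, `pct_ok`, `adme_pass`, and `fail_reasons`
#'   (semicolon-joined names of failed rules, "" when passing).
#' @export
adme_pass <- function(profiles, th = adme_thresholds()) {
  stopifnot(inherits(th, "adme_thresholds"))
  ok <- function(x, test) !is.na(x) & test
  out <- profiles
  out$cns_ok <- ok(profiles$cns_activity, profiles$cns_activity >= th$cns_min)
  out$logbb_ok <- ok(profiles$log_bb,
                     profiles$log_bb >= th$logbb_range[1] &
                       profiles$log_bb <= th$logbb_range[2])
  out$mdck_ok <- ok(profiles$mdck_perm, profiles$mdck_perm >= th$mdck_min)
  out$caco2_ok <- ok(profiles$caco2_perm, profiles$caco2_perm >= th$caco2_min)
  out$hoa_ok <- ok(profiles$human_oral_absorption,
                   profiles$human_oral_absorption >= th$hoa_min_class)
  out$pct_ok <- ok(profiles$pct_human_absorption,
                   profiles$pct_human_absorption >= th$pct_hoa_min)
  rules <- c("cns_ok", "logbb_ok", "mdck_ok", "caco2_ok", "hoa_ok", "pct_ok")
  verdicts <- as.matrix(out[, rules])
  out$adme_pass <- rowSums(verdicts) == length(rules)
  missing_mat <- is.na(as.matrix(
    profiles[, c("cns_activity", "log_bb", "mdck_perm", "caco2_perm",
                 "human_oral_absorption", "pct_human_absorption")]))
  out$fail_reasons <- vapply(seq_len(nrow(out)), function(i) {
    failed <- rules[!verdicts[i, ]]
    if (!length(failed)) return("")
    tags <- sub("_ok$", "", failed)
    miss_flags <- missing_mat[i, match(failed, rules)]
    tags[miss_flags] <- paste0(tags[miss_flags], "(missing)")
    paste(tags, collapse = ";")
  }, "")
  out
}

#' Filter candidate drugs by status, evidence strength and direction
#'
#' A drug record is retained when all of the following hold:
#'
#' 1. its target gene is in the prioritized set;
#' 2. its development status is among `statuses` (approved / clinical-trial
#'    phases by default; `"experimental"` is a separate track);
#' 3. the interaction is supported: `direct_action`, or an interaction score
#'    strictly above 0.50, or published experimental validation
#'    (`validated_modulator`);
#' 4. its mechanism matches the therapeutic modulation required by the
#'    direction-of-effect call for the gene, when a non-conflicted call
#'    exists (no call for the gene means no direction constraint).
#'
#' The filter is idempotent and independent of input row order.
#'
#' @param drugs data.frame from [read_drug_table()].
#' @param prioritized_genes character vector of prioritized gene symbols.
#' @param directions data.frame from [call_directions()]; conflicted calls
#'   are ignored (they impose no constraint).
#' @param statuses development statuses allowed through.
#' @param score_min interaction-score cutoff (strict).
#' @param known_genes optional gene universe; a drug whose target is outside
#'   it triggers a warning and is dropped regardless of other rules.
#' @return the retained rows; attribute `"verdicts"` holds the full input
#'   with per-rule logical columns `gene_ok`, `status_ok`, `evidence_ok`,
#'   `direction_ok`, `retained`.
#' @export
filter_drugs <- function(drugs, prioritized_genes, directions = NULL,
                         statuses = c("approved", "phase1", "phase2",
                                      "phase3"),
                         score_min = 0.50, known_genes = NULL) {
  v <- drugs
  prioritized_genes <- toupper(prioritized_genes)
  if (!is.null(known_genes)) {
    unknown <- !(v$target_gene %in% toupper(known_genes))
    if (any(unknown)) {
      warning("dropping drug(s) with unknown target gene(s): ",
              paste(unique(paste0(v$drug[unknown], " (",
                                  v$target_gene[unknown], ")")),
                    collapse = ", "), call. = FALSE)
    }
  } else {
    unknown <- rep(FALSE, nrow(v))
  }
  v$gene_ok <- v$target_gene %in% prioritized_genes & !unknown
  v$status_ok <- v$status %in% statuses
  v$evidence_ok <- v$direct_action |
    (!is.na(v$interaction_score) & v$interaction_score > score_min) |
    v$validated_modulator
  mod <- character(0)
  if (!is.null(directions) && nrow(directions) > 0L) {
    usable <- directions[!directions$conflict, , drop = FALSE]
    mod <- stats::setNames(usable$modulation, usable$gene)
  }
  required <- unname(mod[v$target_gene])
  v$direction_ok <- is.na(required) | v$mechanism == required
  v$retained <- v$gene_ok & v$status_ok & v$evidence_ok & v$direction_ok
  out <- drugs[v$retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "verdicts") <- v
  out
}

#' @rdname filter_drugs
#' @param verdicts data.frame of per-rule verdicts (the `"verdicts"`
#'   attribute of a `filter_drugs()` result, or an [adme_pass()] result).
#' @param path output TSV path.
#' @export
write_drug_verdicts <- function(verdicts, path) {
  oxi_write_tsv(verdicts, path, build = "GRCh37")
}
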