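#' @title Synthetic-data generation with planted ground truth
#' @description
#' Every pipeline input (GWAS hits, QTL catalogue, consequence annotations,
#' genotype panel, pathway GMT, drug table, ADME table) can be generated
#' from a declarative plan with known ground truth, so each stage is
#' testable end to end without external downloads. Planted hit-proxy LD is
#' realized *exactly*: the haplotype pool is laid out with rational
#' frequencies on the symmetric 0.5/0.5 allele-frequency grid (where
#' r = 4f - 1 for pool fraction f of each coupled haplotype) and paired into
#' homozygotes, so the EM estimate has a closed form equal to the pool value.
#' The general-purpose [simulate_panel()] uses random haplotype pairing
#' instead and carries a +/-0.1 tolerance contract on realized r2.
#' @name synthetic-data
NULL

# run `expr` under a private RNG stream without disturbing the caller's seed
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Exact two-column genotype block at target r2 (allele freq 0.5 both loci).
# Returns a 2 x n_samples integer matrix (rows: locus 1, locus 2) whose
# realized EM r2 equals attr "realized_r2" exactly. Individuals are
# homozygous at both loci (identical haplotypes paired), which removes
# phase ambiguity; `perm` shuffles sample assignment so blocks of different
# genes are uncorrelated.
exact_ld_columns <- function(n_samples, target_r2, perm) {
  stopifnot(n_samples %% 2 == 0, target_r2 >= 0, target_r2 <= 1)
  r <- sqrt(target_r2)
  # m/2 individuals (2,2), m/2 (0,0), (n/2 - m/2) each of (2,0), (0,2)
  # where haplotype-pool fraction of each coupled haplotype is f = m/n_hap;
  # m must be even for homozygous pairing
  m <- round((1 + r) / 4 * 2 * n_samples / 2) * 2
  m <- min(max(m, n_samples %/% 2), n_samples)  # keep D >= 0
  half <- n_samples %/% 2
  n22 <- m %/% 2
  n00 <- m - n22
  rest <- n_samples - m
  n20 <- rest %/% 2
  n02 <- rest - n20
  g1 <- c(rep(2L, n22), rep(0L, n00), rep(2L, n20), rep(0L, n02))
  g2 <- c(rep(2L, n22), rep(0L, n00), rep(0L, n20), rep(2L, n02))
  realized_r <- 4 * (m / (2 * n_samples)) - 1
  out <- rbind(g1[perm], g2[perm])
  attr(out, "realized_r2") <- realized_r^2
  out
}

#' Simulate a block-structured genotype panel
#'
#' Draws haplotypes from block-structured pools: within a block, every
#' variant has a target r2 with the block's first variant (allele
#' frequencies 0.5). Haplotypes are paired at random into diploids, so the
#' realized pairwise r2 matches the target to within about +/-0.1 at
#' `n_samples >= 500`. Blocks land on separate 5-Mb regions so they do not
#' interact through the proxy window.
#'
#' @param n_samples number of diploid samples (>= 20).
#' @param blocks list of numeric vectors; element `b` gives the target r2 of
#'   variants 2..k of block `b` with the block's first variant (so a vector
#'   of length 2 makes a 3-variant block).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return a [genotype_panel()].
#' @export
simulate_panel <- function(n_samples, blocks, seed) {
  stopifnot(n_samples >= 20)
  r2s <- unlist(blocks)
  if (length(r2s) && any(r2s > 1 | r2s < 0)) {
    stop("target r2 must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_hap <- 2L * n_samples
    var_rows <- list()
    geno <- list()
    for (b in seq_along(blocks)) {
      h1 <- stats::rbinom(n_hap, 1L, 0.5)
      haps <- list(h1)
      for (r2 in blocks[[b]]) {
        r <- sqrt(r2)
        keep <- stats::runif(n_hap) < (1 + r) / 2
        haps[[length(haps) + 1L]] <- ifelse(keep, h1, 1L - h1)
      }
      ord <- sample.int(n_hap)  # random pairing
      chrom <- as.character((b - 1L) %% 22L + 1L)
      base <- 10e6 + 5e6 * ((b - 1L) %/% 22L)
      for (j in seq_along(haps)) {
        h <- haps[[j]][ord]
        g <- h[seq(1L, n_hap, by = 2L)] + h[seq(2L, n_hap, by = 2L)]
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          chrom = chrom, pos = as.integer(base + (j - 1L) * 1e4),
          rsid = sprintf("rs%d%03d", b, j),
          allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
        geno[[length(geno) + 1L]] <- as.integer(g)
      }
    }
    genotype_panel(do.call(rbind, var_rows),
                   do.call(rbind, geno),
                   sprintf("S%04d", seq_len(n_samples)))
  })
}

# allele pairs cycled over planted variants, for cosmetic variety
.allele_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T",
                          "A", "T", "C", "G"), ncol = 2, byrow = TRUE)

#' Generator configuration
#'
#' Declares a synthetic study: one GWAS hit per planted target gene, an
#' optional molecular QTL on the hit itself (`proxy_r2 = 1`) or on a proxy
#' variant at an exactly realized LD, optional consequence annotations,
#' pathway membership, and a drug plan with intended ADME outcomes.
#'
#' `planted_targets` columns (one row per gene): `gene`; `p_value`
#' (< 1e-5); `odds_ratio`; `qtl_type` (eQTL/pQTL/sQTL/polyQTL/mQTL or `NA`
#' for a consequence-only target); `tissue` (`NA` iff no QTL);
#' `effect_sign` (+1/-1 effect of the QTL effect allele, `NA` = unknown);
#' `proxy_r2` ((0, 1], LD between hit and QTL variant); optional
#' `in_pathway` (default `TRUE`; overridden by `pathway_fraction` when that
#' is not `NULL`), `mhc_hit` (hit placed inside the MHC interval; such genes
#' always get a proxy QTL variant just outside it), `consequence` +
#' `cadd_phred` (adds an annotation record on the hit variant).
#'
#' `drug_plan` columns: `drug`, `gene`, `mechanism`, `status`,
#' `interaction_score` (`NA` allowed), `direct_action`,
#' `validated_modulator`, `adme_pass` (intended ADME verdict).
#'
#' @param seed integer seed for the bundle's single pseudo-random stream.
#' @param n_samples diploid panel size (>= 20, even).
#' @param planted_targets data.frame as described above.
#' @param drug_plan data.frame as described above, or `NULL`.
#' @param pathway_fraction if not `NULL`, overrides `in_pathway`: the first
#'   `round(fraction * n)` genes are pathway members.
#' @param n_pathways number of pathway sets the members are spread over.
#' @param n_decoy_members pathway-only protein symbols with no genetic
#'   evidence.
#' @return validated list of class `"generator_config"`.
#' @export
generator_config <- function(seed, n_samples = 500L, planted_targets,
                             drug_plan = NULL, pathway_fraction = NULL,
                             n_pathways = 22L, n_decoy_members = 40L) {
  pt <- as.data.frame(planted_targets, stringsAsFactors = FALSE)
  req <- c("gene", "p_value", "odds_ratio", "qtl_type", "tissue",
           "effect_sign", "proxy_r2")
  missing <- setdiff(req, names(pt))
  if (length(missing)) {
    stop("planted_targets lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (n_samples < 20L || n_samples %% 2L != 0L) {
    stop("n_samples must be an even integer >= 20", call. = FALSE)
  }
  if (anyDuplicated(pt$gene)) {
    stop("planted_targets genes must be unique", call. = FALSE)
  }
  if (any(pt$p_value >= 1e-5 | pt$p_value <= 0)) {
    stop("planted p-values must lie in (0, 1e-5)", call. = FALSE)
  }
  if (any(pt$proxy_r2 <= 0 | pt$proxy_r2 > 1)) {
    stop("proxy_r2 must lie in (0, 1]", call. = FALSE)
  }
  if (!"in_pathway" %in% names(pt)) pt$in_pathway <- TRUE
  if (!is.null(pathway_fraction)) {
    pt$in_pathway <- seq_len(nrow(pt)) <= round(pathway_fraction * nrow(pt))
  }
  if (!"mhc_hit" %in% names(pt)) pt$mhc_hit <- FALSE
  if (!"consequence" %in% names(pt)) pt$consequence <- NA_character_
  if (!"cadd_phred" %in% names(pt)) pt$cadd_phred <- NA_real_
  no_qtl <- is.na(pt$qtl_type)
  if (any(no_qtl & !is.na(pt$tissue)) || any(!no_qtl & is.na(pt$tissue))) {
    stop("tissue must be given exactly for rows with a qtl_type",
         call. = FALSE)
  }
  if (any(no_qtl & !is.na(pt$effect_sign))) {
    stop("effect_sign without a QTL is infeasible", call. = FALSE)
  }
  if (any(no_qtl & is.na(pt$consequence))) {
    stop("a planted target needs a QTL or a consequence record",
         call. = FALSE)
  }
  if (any(no_qtl & pt$mhc_hit)) {
    stop("a consequence-only target with an MHC hit would be excluded ",
         "(all evidence inside the MHC interval)", call. = FALSE)
  }
  if (any(!no_qtl & !(pt$qtl_type %in% .qtl_types))) {
    stop("unknown qtl_type in plan", call. = FALSE)
  }
  pt$gene <- toupper(pt$gene)
  if (!is.null(drug_plan)) {
    dp <- as.data.frame(drug_plan, stringsAsFactors = FALSE)
    reqd <- c("drug", "gene", "mechanism", "status", "interaction_score",
              "direct_action", "validated_modulator", "adme_pass")
    missing <- setdiff(reqd, names(dp))
    if (length(missing)) {
      stop("drug_plan lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    dp$gene <- toupper(dp$gene)
    drug_plan <- dp
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 planted_targets = pt, drug_plan = drug_plan,
                 n_pathways = as.integer(n_pathways),
                 n_decoy_members = as.integer(n_decoy_members)),
            class = "generator_config")
}

# Straight-line restatement of the five scoring criteria, applied directly
# to a plan row (one hit, at most one QTL per gene). Used only to compute
# ground truth; kept deliberately independent of score_targets().
oracle_score_row <- function(row) {
  has_qtl <- !is.na(row$qtl_type)
  is_eqtl <- has_qtl && row$qtl_type == "eQTL"
  c1 <- 0L
  if (row$p_value < 5e-8) c1 <- if (row$mhc_hit) 2L else 5L
  bin <- function(ld, top) {
    if (ld >= 0.99) top
    else if (ld >= 0.95) 3L
    else if (ld >= 0.90) 2L
    else if (ld >= 0.80) 1L
    else 0L
  }
  c2 <- if (has_qtl && row$odds_ratio > 1.2) bin(row$proxy_r2, 4L) else 0L
  c3 <- 0L
  if (is_eqtl) {
    c3 <- 10L
    if (row$tissue == "brain") c3 <- 15L
  }
  c4 <- if (is_eqtl) bin(row$proxy_r2, 5L) else 0L
  c5 <- if (has_qtl && !is_eqtl && row$proxy_r2 >= 0.99) 3L else 0L
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
    total = c1 + c2 + c3 + c4 + c5)
}

# selection arithmetic restated for ground truth: top floor(fraction * n)
# totals, extended across boundary ties
oracle_select <- function(totals, fraction = 0.25) {
  ord <- order(-totals)
  n_keep <- floor(fraction * length(totals))
  if (n_keep < 1L) return(character(0))
  boundary <- totals[ord][n_keep]
  names(totals)[totals >= boundary]
}

#' Generate a full synthetic input bundle with ground truth
#'
#' Lays out one GWAS hit per planted gene (plus an exactly realized LD proxy
#' when `proxy_r2 < 1` or the hit is in the MHC), the corresponding QTL and
#' consequence records, a genotype panel, pathway sets, and the planned drug
#' and ADME tables. Ground truth (targets, directions, scores, prioritized
#' set, surviving candidates) is computed by a straight-line restatement of
#' the pipeline's rules, independent of the pipeline implementation.
#'
#' @param cfg a [generator_config()].
#' @param dir optional directory; when given, all seven input files plus
#'   `ground_truth.json` are written there (the seed is recorded in each
#'   file's comment header).
#' @return list with the in-memory inputs (`hits`, `qtls`, `consequences`,
#'   `panel`, `pathways`, `drugs`, `adme`), `ground_truth`, and `paths`
#'   (when `dir` was given).
#' @export
generate_bundle <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  pt <- cfg$planted_targets
  n <- nrow(pt)
  ns <- cfg$n_samples

  with_seed(cfg$seed, {
    # -- locus layout ---------------------------------------------------------
    non_mhc_chroms <- as.character(setdiff(1:22, 6))
    idx_non_mhc <- which(!pt$mhc_hit)
    idx_mhc <- which(pt$mhc_hit)
    chrom <- character(n); hit_pos <- integer(n)
    for (k in seq_along(idx_non_mhc)) {
      i <- idx_non_mhc[k]
      chrom[i] <- non_mhc_chroms[(k - 1L) %% 21L + 1L]
      hit_pos[i] <- as.integer(10e6 + 5e6 * ((k - 1L) %/% 21L))
    }
    for (k in seq_along(idx_mhc)) {
      i <- idx_mhc[k]
      chrom[i] <- "6"
      hit_pos[i] <- as.integer(32.55e6 + 0.11e6 * (k - 1L))
      if (hit_pos[i] > 33e6) stop("too many MHC hits for the layout",
                                  call. = FALSE)
    }
    # MHC genes always get a distinct QTL variant just outside the interval
    needs_proxy <- (!is.na(pt$qtl_type) & pt$proxy_r2 < 1) |
      (pt$mhc_hit & !is.na(pt$qtl_type))
    proxy_pos <- ifelse(pt$mhc_hit,
                        as.integer(33.05e6 + 0.11e6 *
                                     (cumsum(pt$mhc_hit) - 1L)),
                        hit_pos + 50000L)

    # -- panel ----------------------------------------------------------------
    var_rows <- list(); geno_rows <- list()
    realized <- rep(NA_real_, n)
    hit_id <- character(n); qtl_id <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      pair <- .allele_pairs[(i - 1L) %% nrow(.allele_pairs) + 1L, ]
      perm <- sample.int(ns)
      rs_hit <- sprintf("rs%06d", 2L * i - 1L)
      hit_id[i] <- rs_hit
      if (needs_proxy[i]) {
        cols <- exact_ld_columns(ns, pt$proxy_r2[i], perm)
        realized[i] <- attr(cols, "realized_r2")
        rs_qtl <- sprintf("rs%06d", 2L * i)
        qtl_id[i] <- rs_qtl
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          chrom = chrom[i], pos = hit_pos[i], rsid = rs_hit,
          allele_a = pair[1], allele_b = pair[2], stringsAsFactors = FALSE)
        geno_rows[[length(geno_rows) + 1L]] <- cols[1, ]
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          chrom = chrom[i], pos = proxy_pos[i], rsid = rs_qtl,
          allele_a = pair[1], allele_b = pair[2], stringsAsFactors = FALSE)
        geno_rows[[length(geno_rows) + 1L]] <- cols[2, ]
      } else {
        cols <- exact_ld_columns(ns, 1, perm)
        realized[i] <- if (is.na(pt$qtl_type[i])) NA_real_ else 1
        if (!is.na(pt$qtl_type[i])) qtl_id[i] <- rs_hit  # self-QTL
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          chrom = chrom[i], pos = hit_pos[i], rsid = rs_hit,
          allele_a = pair[1], allele_b = pair[2], stringsAsFactors = FALSE)
        geno_rows[[length(geno_rows) + 1L]] <- cols[1, ]
      }
    }
    panel <- genotype_panel(do.call(rbind, var_rows),
                            do.call(rbind, geno_rows),
                            sprintf("S%04d", seq_len(ns)))

    # -- GWAS hits (risk allele = allele_b of the hit variant) ----------------
    hits <- data.frame(
      id = hit_id, chrom = chrom, pos = hit_pos, rsid = hit_id,
      allele_a = .allele_pairs[(seq_len(n) - 1L) %% nrow(.allele_pairs) + 1L,
                               1L],
      allele_b = .allele_pairs[(seq_len(n) - 1L) %% nrow(.allele_pairs) + 1L,
                               2L],
      risk_allele = .allele_pairs[(seq_len(n) - 1L) %% nrow(.allele_pairs) +
                                    1L, 2L],
      p_value = pt$p_value, odds_ratio = pt$odds_ratio,
      study_id = "SYNTH1", stringsAsFactors = FALSE)

    # -- QTL catalogue: the effect allele is the coupled partner of the risk
    # allele (allele_b of the QTL variant, since the exact layout has D > 0),
    # so the planted direction equals effect_sign ---------------------------
    has_qtl <- !is.na(pt$qtl_type)
    qtls <- data.frame(
      id = qtl_id[has_qtl],
      chrom = chrom[has_qtl],
      pos = ifelse(needs_proxy[has_qtl], proxy_pos[has_qtl],
                   hit_pos[has_qtl]),
      rsid = qtl_id[has_qtl],
      allele_a = hits$allele_a[has_qtl], allele_b = hits$allele_b[has_qtl],
      effect_allele = hits$allele_b[has_qtl],
      gene = pt$gene[has_qtl], qtl_type = pt$qtl_type[has_qtl],
      tissue = pt$tissue[has_qtl],
      effect_sign = as.integer(pt$effect_sign[has_qtl]),
      stringsAsFactors = FALSE)

    # -- consequence annotations on the hit variant ---------------------------
    has_cons <- !is.na(pt$consequence)
    consequences <- data.frame(
      id = hit_id[has_cons], chrom = chrom[has_cons],
      pos = hit_pos[has_cons], rsid = hit_id[has_cons],
      gene = pt$gene[has_cons], consequence = pt$consequence[has_cons],
      cadd_phred = pt$cadd_phred[has_cons], stringsAsFactors = FALSE)

    # -- pathways -------------------------------------------------------------
    members <- pt$gene[pt$in_pathway]
    decoys <- sprintf("DECOY%03d", seq_len(cfg$n_decoy_members))
    all_members <- c(members, decoys)
    pathways <- stats::setNames(
      lapply(seq_len(cfg$n_pathways), function(p) {
        m <- all_members[(seq_along(all_members) - 1L) %%
                           cfg$n_pathways + 1L == p]
        if (!length(m)) m <- decoys[1]  # GMT lines need >= 1 member
        m
      }),
      sprintf("OS_PATHWAY_%02d", seq_len(cfg$n_pathways)))
    class(pathways) <- "pathway_sets"

    # -- drugs and ADME -------------------------------------------------------
    dp <- cfg$drug_plan
    drugs <- NULL; adme <- NULL
    if (!is.null(dp) && nrow(dp) > 0L) {
      drugs <- data.frame(
        drug = dp$drug, target_gene = dp$gene, mechanism = dp$mechanism,
        status = dp$status, interaction_score = dp$interaction_score,
        direct_action = dp$direct_action,
        validated_modulator = dp$validated_modulator,
        source_db = if ("source_db" %in% names(dp)) dp$source_db else
          "SYNTHDB",
        stringsAsFactors = FALSE)
      fail_kind <- c("cns", "logbb", "mdck", "pct")
      adme <- do.call(rbind, lapply(seq_len(nrow(dp)), function(i) {
        if (dp$adme_pass[i]) {
          data.frame(compound = dp$drug[i], cns_activity = 1L,
                     log_bb = round(0.1 + 0.05 * (i %% 5), 3),
                     mdck_perm = 500 + 10 * (i %% 7),
                     caco2_perm = 420 + 10 * (i %% 5),
                     human_oral_absorption = 3L,
                     pct_human_absorption = 88 + (i %% 10),
                     stringsAsFactors = FALSE)
        } else {
          k <- fail_kind[(i - 1L) %% 4L + 1L]
          data.frame(compound = dp$drug[i],
                     cns_activity = if (k == "cns") -1L else 1L,
                     log_bb = if (k == "logbb") -2.1 else 0.2,
                     mdck_perm = if (k == "mdck") 30 else 520,
                     caco2_perm = 430,
                     human_oral_absorption = 3L,
                     pct_human_absorption = if (k == "pct") 55 else 90,
                     stringsAsFactors = FALSE)
        }
      }))
    }

    # -- ground truth (independent restatement of the rules) ------------------
    score_mat <- t(vapply(seq_len(n), function(i) {
      row <- pt[i, ]
      row$proxy_r2 <- if (is.na(realized[i])) row$proxy_r2 else realized[i]
      oracle_score_row(row)
    }, c(c1 = 0L, c2 = 0L, c3 = 0L, c4 = 0L, c5 = 0L, total = 0L)))
    true_scores <- data.frame(gene = pt$gene, score_mat,
                              stringsAsFactors = FALSE)
    shared <- pt$gene[pt$in_pathway]
    shared_scores <- true_scores[true_scores$gene %in% shared, ]
    totals <- stats::setNames(shared_scores$total, shared_scores$gene)
    true_prioritized <- if (length(totals)) oracle_select(totals) else
      character(0)
    dir_rows <- pt$in_pathway & has_qtl & !is.na(pt$effect_sign) &
      !is.na(pt$tissue) & pt$tissue == "brain"
    true_directions <- data.frame(
      gene = pt$gene[dir_rows],
      direction = as.integer(pt$effect_sign[dir_rows]),
      modulation = ifelse(pt$effect_sign[dir_rows] > 0, "inhibit",
                          "activate"),
      stringsAsFactors = FALSE)
    true_candidates <- list(repurposable = character(0),
                            experimental = character(0))
    if (!is.null(dp) && nrow(dp) > 0L) {
      mod <- stats::setNames(true_directions$modulation,
                             true_directions$gene)
      ok <- dp$gene %in% true_prioritized &
        (dp$direct_action |
           (!is.na(dp$interaction_score) & dp$interaction_score > 0.5) |
           dp$validated_modulator) &
        (is.na(mod[dp$gene]) | dp$mechanism == unname(mod[dp$gene])) &
        dp$adme_pass
      true_candidates$repurposable <-
        dp$drug[ok & dp$status %in% c("approved", "phase1", "phase2",
                                      "phase3")]
      true_candidates$experimental <- dp$drug[ok & dp$status ==
                                                "experimental"]
    }
    ground_truth <- list(
      seed = cfg$seed,
      true_targets = pt$gene,
      true_shared = shared,
      true_directions = true_directions,
      true_scores = true_scores,
      true_prioritized = sort(true_prioritized),
      realized_r2 = stats::setNames(realized, pt$gene),
      true_candidates = true_candidates)

    out <- list(hits = hits, qtls = qtls, consequences = consequences,
                panel = panel, pathways = pathways, drugs = drugs,
                adme = adme, ground_truth = ground_truth)

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(
        gwas = file.path(dir, "gwas_hits.tsv"),
        qtl = file.path(dir, "qtls.tsv"),
        consequences = file.path(dir, "consequences.tsv"),
        panel = file.path(dir, "panel.tsv"),
        pathways = file.path(dir, "pathways.gmt"),
        drugs = file.path(dir, "drugs.tsv"),
        adme = file.path(dir, "adme.tsv"),
        ground_truth = file.path(dir, "ground_truth.json"))
      write_gwas_hits(hits, paths$gwas, seed = cfg$seed)
      write_qtl_table(qtls, paths$qtl, seed = cfg$seed)
      write_consequences(consequences, paths$consequences, seed = cfg$seed)
      write_panel(panel, paths$panel, seed = cfg$seed)
      write_pathways_gmt(pathways, paths$pathways)
      if (!is.null(drugs)) {
        write_drug_table(drugs, paths$drugs)
        write_adme_table(adme, paths$adme)
      }
      jsonlite::write_json(ground_truth, paths$ground_truth,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out$paths <- paths
    }
    out
  })
}
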