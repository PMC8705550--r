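#' @title Multiple-sclerosis / oxidative-stress case-study fixture
#' @description
#' A fixed synthetic bundle for the package's worked example: drug
#' repositioning against oxidative-stress pathway genes regulated by
#' multiple-sclerosis risk variants. The gene-level lists are real (the 18
#' brain-QTL targets, the 7 up- / 3 down-regulated direction calls, the 10
#' repurposable drugs over 5 targets, the 7 experimental survivors, and the
#' two MAPK1 inhibitors removed for direction inconsistency); the underlying
#' variants, genotype panel, p-values and the remaining 58 of the 85
#' pathway-overlap genes (named `SYNT..`) are synthetic stand-ins
#' constructed so that the funnel reproduces those lists: 85 overlap
#' targets, top-25% selection of 21 at a realized threshold of 20.
#' @name ms-fixture
NULL

# the 18 genes supported by molecular QTLs in brain
.ms_brain_genes <- c("ASF1A", "ATP6V1G2", "BBC3", "BCL2L11", "CAPN1",
                     "CARM1", "CHAC1", "CRTC3", "CSNK2B", "DNM2", "FOXO3",
                     "HSPA1L", "KEAP1", "MAPK1", "NUP85", "POM121C",
                     "PSMB9", "TRMT112")
# direction of the risk-allele effect on the molecular trait in brain
.ms_up_genes <- c("ASF1A", "CAPN1", "CARM1", "CHAC1", "NUP85", "POM121C",
                  "TRMT112")
.ms_down_genes <- c("BBC3", "MAPK1", "PSMB9")

.ms_table1_drugs <- data.frame(
  drug = c("BIIB021", "PEITC", "ABEMACICLIB", "ALVOCIDIB", "MILCICLIB",
           "PHA-793887", "ATIPRIMOD", "ENMD1198", "ERLOTINIB",
           "PILOCARPINE"),
  gene = c("CARM1", "MAPK1", "CDK4", "CDK4", "CDK4", "CDK4", "STAT3",
           "STAT3", "STAT3", "FOS"),
  mechanism = c("inhibit", "activate", "inhibit", "inhibit", "inhibit",
                "inhibit", "inhibit", "inhibit", "activate", "activate"),
  status = c("phase2", "phase2", "approved", "phase2", "phase2", "phase1",
             "phase2", "phase1", "approved", "approved"),
  interaction_score = c(0.72, NA, 0.90, 0.85, 0.60, 0.55, 0.52, NA, 0.60,
                        0.55),
  source_db = c("DGIdb", "SuperTarget", "DGIdb;DrugBank;OpenTarget",
                "DGIdb;DrugBank;OpenTarget", "DGIdb;OpenTarget", "DGIdb",
                "DGIdb", "DrugBank", "SuperTarget;DGIdb", "DGIdb"),
  stringsAsFactors = FALSE)

.ms_experimental_drugs <- data.frame(
  drug = c("MS049", "MS023", "TP064", "GSK4112", "SR9009", "SR9011",
           "SR8278"),
  gene = c("CARM1", "CARM1", "CARM1", "NR1D1", "NR1D1", "NR1D1", "NR1D1"),
  mechanism = c("inhibit", "inhibit", "inhibit", "activate", "activate",
                "activate", "inhibit"),
  stringsAsFactors = FALSE)

# build the 88-row planted-target plan (85 pathway genes + 3 extras that
# drop out at the pathway-overlap stage)
ms_fixture_plan <- function() {
  row <- function(gene, p, or, qtl, tissue, sign, r2, in_pathway = TRUE,
                  mhc = FALSE, cons = NA_character_, cadd = NA_real_) {
    data.frame(gene = gene, p_value = p, odds_ratio = or, qtl_type = qtl,
               tissue = tissue, effect_sign = sign, proxy_r2 = r2,
               in_pathway = in_pathway, mhc_hit = mhc, consequence = cons,
               cadd_phred = cadd, stringsAsFactors = FALSE)
  }
  top <- rbind(
    row("TRMT112", 1e-9, 1.3, "eQTL", "brain", +1, 1),        # 29
    row("CAPN1",   1e-9, 1.3, "eQTL", "brain", +1, 1),        # 29
    row("ASF1A",   1e-9, 1.3, "eQTL", "brain", +1, 1),        # 29
    row("BBC3",    1e-9, 1.3, "eQTL", "brain", -1, 1),        # 29
    row("NUP85",   1e-9, 1.3, "eQTL", "brain", +1, 0.9604),   # 26
    row("CARM1",   1e-9, 1.3, "eQTL", "brain", +1, 0.9604,
        cons = "missense_variant", cadd = 22),                # 26
    row("MAPK1",   1e-9, 1.3, "eQTL", "brain", -1, 0.9604),   # 26
    row("KEAP1",  1e-12, 1.4, "eQTL", "brain", NA, 1),        # 29
    do.call(rbind, lapply(c("MAPK3", "CDK4", "STAT3", "FOS", "NR1D1",
                            "HVCN1", "YWHAQ", "HDAC1", "NCF4"),
                          function(g) row(g, 1e-9, 1.3, "eQTL", "blood",
                                          NA, 1))),           # 24 each
    row("SYNT01",  1e-9, 1.25, "eQTL", "blood", NA, 1),       # 24
    row("SYNT02",  1e-9, 1.25, "eQTL", "blood", NA, 1),       # 24
    row("SYNT03",  1e-9, 1.25, "eQTL", "blood", NA, 1),       # 24
    row("SYNT04",  1e-9, 1.10, "eQTL", "blood", NA, 1)        # 20
  )
  low_named <- rbind(
    row("CHAC1",   1e-9, 1.3, "pQTL", "brain", +1, 1),        # 12
    row("POM121C", 1e-9, 1.3, "pQTL", "brain", +1, 1),        # 12
    row("PSMB9",  1e-10, 1.3, "pQTL", "brain", -1, 0.9604,
        mhc = TRUE),                                          # 5
    row("ATP6V1G2", 1e-10, 1.1, "sQTL", "brain", NA, 0.9604,
        mhc = TRUE),                                          # 2
    row("CSNK2B", 1e-10, 1.1, "mQTL", "brain", NA, 0.9604,
        mhc = TRUE),                                          # 2
    row("HSPA1L", 1e-10, 1.1, "pQTL", "brain", NA, 0.9604,
        mhc = TRUE),                                          # 2
    row("BCL2L11", 5e-6, 1.15, "eQTL", "brain", NA, 0.9604),  # 18
    row("FOXO3",   5e-6, 1.15, "eQTL", "brain", NA, 0.9604),  # 18
    row("CRTC3",   1e-9, 1.3, "sQTL", "brain", NA, 1),        # 12
    row("DNM2",    1e-9, 1.15, "mQTL", "brain", NA, 1),       # 8
    row("SYNT05",  1e-9, 1.3, NA, NA, NA, 1,
        cons = "missense_variant", cadd = 18)                 # 5
  )
  # 53 synthetic low-scoring pathway genes over three archetypes (15/7/7)
  arch <- lapply(6:58, function(i) {
    g <- sprintf("SYNT%02d", i)
    switch((i %% 3) + 1,
           row(g, 5e-6, 1.10, "eQTL", "blood", NA, 1),
           row(g, 1e-9, 1.30, "pQTL", "blood", NA, 0.9216),
           row(g, 5e-6, 1.25, "mQTL", "blood", NA, 1))
  })
  # consequence records that must NOT survive the severity/CADD filter
  arch[[1]]$consequence <- "synonymous_variant"
  arch[[1]]$cadd_phred <- 30
  arch[[2]]$consequence <- "missense_variant"
  arch[[2]]$cadd_phred <- 12
  extras <- do.call(rbind, lapply(sprintf("NONOS%02d", 1:3), function(g) {
    row(g, 1e-9, 1.3, "eQTL", "blood", NA, 1, in_pathway = FALSE)
  }))
  rbind(top, low_named, do.call(rbind, arch), extras)
}

ms_fixture_drug_plan <- function() {
  t1 <- .ms_table1_drugs
  rep_track <- data.frame(
    drug = t1$drug, gene = t1$gene, mechanism = t1$mechanism,
    status = t1$status, interaction_score = t1$interaction_score,
    direct_action = TRUE, validated_modulator = TRUE,
    adme_pass = TRUE, source_db = t1$source_db, stringsAsFactors = FALSE)
  # MAPK1-directed inhibitors: mechanism inconsistent with the required
  # activation, removed at the drug-selection stage
  removed <- data.frame(
    drug = c("MK8353", "LY3214996"), gene = "MAPK1", mechanism = "inhibit",
    status = "phase1", interaction_score = 0.80, direct_action = TRUE,
    validated_modulator = TRUE, adme_pass = FALSE, source_db = "DGIdb",
    stringsAsFactors = FALSE)
  ex <- .ms_experimental_drugs
  exp_track <- data.frame(
    drug = ex$drug, gene = ex$gene, mechanism = ex$mechanism,
    status = "experimental", interaction_score = NA_real_,
    direct_action = TRUE, validated_modulator = TRUE, adme_pass = TRUE,
    source_db = "Pharos", stringsAsFactors = FALSE)
  rbind(rep_track, removed, exp_track)
}

#' Build the case-study fixture bundle
#'
#' Constructs the fixed synthetic bundle described in [ms-fixture] (the
#' internal seed is fixed, so the bundle is always identical) and returns
#' it together with the expected result lists the funnel must reproduce.
#'
#' @param dir optional directory to write the seven input files plus the
#'   ground-truth JSON into.
#' @return the [generate_bundle()] result plus an `expected` element:
#'   `brain_qtl_genes` (18), `up_genes` (7), `down_genes` (3),
#'   `table1_drugs` (10 drugs over 5 targets), `experimental_survivors`
#'   (7), `removed_drugs` (MK8353, LY3214996), `n_overlap` (85), `n_top`
#'   (21) and `score_threshold` (20).
#' @examples
#' fx <- ms_fixture()
#' nrow(fx$hits)
#' fx$expected$n_overlap
#' @export
ms_fixture <- function(dir = NULL) {
  cfg <- generator_config(seed = 42L, n_samples = 200L,
                          planted_targets = ms_fixture_plan(),
                          drug_plan = ms_fixture_drug_plan(),
                          n_pathways = 22L, n_decoy_members = 40L)
  bundle <- generate_bundle(cfg, dir = dir)
  bundle$expected <- list(
    brain_qtl_genes = sort(.ms_brain_genes),
    up_genes = sort(.ms_up_genes),
    down_genes = sort(.ms_down_genes),
    table1_drugs = .ms_table1_drugs$drug,
    table1_targets = sort(unique(.ms_table1_drugs$gene)),
    experimental_survivors = .ms_experimental_drugs$drug,
    removed_drugs = c("MK8353", "LY3214996"),
    n_overlap = 85L, n_top = 21L, score_threshold = 20L)
  bundle
}
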