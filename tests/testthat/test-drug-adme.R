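drug_row <- function(drug, gene = "CARM1", mechanism = "inhibit",
                     status = "phase2", score = NA_real_, direct = TRUE,
                     validated = FALSE) {
  data.frame(drug = drug, target_gene = gene, mechanism = mechanism,
             status = status, interaction_score = score,
             direct_action = direct, validated_modulator = validated,
             source_db = "DB", stringsAsFactors = FALSE)
}

dir_call <- function(gene, direction) {
  data.frame(gene = gene, tissue = "brain", direction = direction,
             modulation = if (direction > 0) "inhibit" else "activate",
             coupled_allele = "G", via_id = "rsQ", hit_id = "rsH",
             qtl_type = "eQTL", ld_to_hit = 1, conflict = FALSE,
             stringsAsFactors = FALSE)
}

good_profile <- function(compound) {
  data.frame(compound = compound, cns_activity = 1L, log_bb = 0.2,
             mdck_perm = 600, caco2_perm = 500,
             human_oral_absorption = 3L, pct_human_absorption = 92,
             stringsAsFactors = FALSE)
}

test_that("direction-inconsistent modulators are removed", {
  # MAPK1 requires activation; its inhibitors must go, its activator stays
  drugs <- rbind(drug_row("MK8353", "MAPK1", "inhibit", "phase1", 0.8),
                 drug_row("LY3214996", "MAPK1", "inhibit", "phase1", 0.8),
                 drug_row("PEITC", "MAPK1", "activate", "phase2"))
  out <- filter_drugs(drugs, "MAPK1", dir_call("MAPK1", -1L))
  expect_identical(out$drug, "PEITC")
  v <- attr(out, "verdicts")
  expect_false(any(v$direction_ok[v$drug %in% c("MK8353", "LY3214996")]))
  # without a direction call the same inhibitors pass
  free <- filter_drugs(drugs, "MAPK1", NULL)
  expect_equal(nrow(free), 3L)
  # a conflicted call imposes no constraint
  conf <- dir_call("MAPK1", -1L); conf$conflict <- TRUE
  expect_equal(nrow(filter_drugs(drugs, "MAPK1", conf)), 3L)
})

test_that("interaction evidence needs direct action, score > 0.50 or validation", {
  drugs <- rbind(
    drug_row("A", score = 0.50, direct = FALSE),            # boundary: out
    drug_row("B", score = 0.51, direct = FALSE),            # in by score
    drug_row("C", score = NA, direct = FALSE, validated = TRUE),  # in
    drug_row("D", score = NA, direct = FALSE))              # out
  out <- filter_drugs(drugs, "CARM1", NULL)
  expect_setequal(out$drug, c("B", "C"))
})

test_that("status gating separates repurposable and experimental tracks", {
  drugs <- rbind(drug_row("APP", status = "approved"),
                 drug_row("PH3", status = "phase3"),
                 drug_row("EXP", status = "experimental"))
  rep_track <- filter_drugs(drugs, "CARM1", NULL)
  expect_setequal(rep_track$drug, c("APP", "PH3"))
  exp_track <- filter_drugs(drugs, "CARM1", NULL, statuses = "experimental")
  expect_identical(exp_track$drug, "EXP")
})

test_that("drug filtering is idempotent and order-independent", {
  drugs <- rbind(drug_row("A", "MAPK1", "activate"),
                 drug_row("B", "MAPK1", "inhibit"),
                 drug_row("C", "OTHERGENE"))
  dirs <- dir_call("MAPK1", -1L)
  once <- filter_drugs(drugs, "MAPK1", dirs)
  twice <- filter_drugs(once, "MAPK1", dirs)
  expect_identical(once$drug, twice$drug)
  shuffled <- filter_drugs(drugs[c(3, 1, 2), ], "MAPK1", dirs)
  expect_setequal(shuffled$drug, once$drug)
})

test_that("unknown target genes warn and are dropped", {
  drugs <- drug_row("A", "NOSUCHGENE")
  expect_warning(out <- filter_drugs(drugs, "CARM1", NULL,
                                     known_genes = c("CARM1", "MAPK1")),
                 "NOSUCHGENE")
  expect_equal(nrow(out), 0L)
})

test_that("ADME gate evaluates all six rules with per-rule verdicts", {
  profiles <- rbind(good_profile("PASS"),
                    transform(good_profile("CNSFAIL"), cns_activity = -1L),
                    transform(good_profile("BBFAIL"), log_bb = -1.5),
                    transform(good_profile("PCTFAIL"),
                              pct_human_absorption = 60))
  out <- adme_pass(profiles)
  expect_equal(out$adme_pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(out$cns_ok[out$compound == "CNSFAIL"])
  expect_equal(out$fail_reasons[out$compound == "CNSFAIL"], "cns")
  expect_equal(out$fail_reasons[out$compound == "BBFAIL"], "logbb")
})

test_that("a missing descriptor fails its rule with reason 'missing'", {
  p <- good_profile("NOMDCK")
  p$mdck_perm <- NA_real_
  out <- adme_pass(p)
  expect_false(out$adme_pass)
  expect_equal(out$fail_reasons, "mdck(missing)")
})

test_that("tightening any ADME threshold never grows the pass set", {
  set.seed(5)
  profiles <- data.frame(
    compound = sprintf("C%02d", 1:40),
    cns_activity = sample(-2:2, 40, replace = TRUE),
    log_bb = runif(40, -3, 1.5),
    mdck_perm = runif(40, 0, 800),
    caco2_perm = runif(40, 0, 800),
    human_oral_absorption = sample(1:3, 40, replace = TRUE),
    pct_human_absorption = runif(40, 0, 100),
    stringsAsFactors = FALSE)
  base <- adme_pass(profiles)$adme_pass
  tighter <- list(
    adme_thresholds(cns_min = 1),
    adme_thresholds(logbb_range = c(-0.5, 1.0)),
    adme_thresholds(mdck_min = 300),
    adme_thresholds(caco2_min = 300),
    adme_thresholds(pct_hoa_min = 95))
  for (th in tighter) {
    tight <- adme_pass(profiles, th)$adme_pass
    expect_true(all(base | !tight))  # tight pass set is a subset
  }
})
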