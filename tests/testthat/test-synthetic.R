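test_that("simulated panels realize their target r2 within tolerance", {
  panel <- simulate_panel(600, blocks = list(c(1, 0.9, 0.5)), seed = 13)
  ids <- panel$variants$id
  r2 <- vapply(2:4, function(j) ld_pair(panel, ids[1], ids[j])$r2, 0)
  expect_equal(r2[1], 1, tolerance = 1e-9)   # duplicated haplotypes
  expect_lt(abs(r2[2] - 0.9), 0.1)
  expect_lt(abs(r2[3] - 0.5), 0.1)
  # independent pair at large n
  null_panel <- simulate_panel(2000, blocks = list(c(0)), seed = 7)
  expect_lt(ld_pair(null_panel, null_panel$variants$id[1],
                    null_panel$variants$id[2])$r2, 0.02)
  expect_error(simulate_panel(600, blocks = list(c(1.2)), seed = 1),
               "r2")
})

test_that("panel simulation is reproducible and seed-sensitive", {
  a <- simulate_panel(100, blocks = list(c(0.9)), seed = 3)
  b <- simulate_panel(100, blocks = list(c(0.9)), seed = 3)
  c <- simulate_panel(100, blocks = list(c(0.9)), seed = 4)
  expect_identical(a$geno, b$geno)
  expect_false(identical(a$geno, c$geno))
})

plan_row <- function(gene, p = 1e-9, or = 1.3, qtl = "eQTL",
                     tissue = "brain", sign = 1L, r2 = 1, ...) {
  data.frame(gene = gene, p_value = p, odds_ratio = or, qtl_type = qtl,
             tissue = tissue, effect_sign = sign, proxy_r2 = r2, ...,
             stringsAsFactors = FALSE)
}

test_that("a perfect plan row earns the maximum ground-truth score of 32", {
  # gw-significant non-MHC hit, OR > 1.2, self brain eQTL... plus a pQTL
  # sibling gene showing c5 (single-QTL rows cannot combine c3 and c5)
  cfg <- generator_config(seed = 1, n_samples = 100,
                          planted_targets = plan_row("GMAX"))
  gt <- generate_bundle(cfg)$ground_truth
  expect_equal(gt$true_scores$total, 29L)  # 5 + 4 + 15 + 5, no pQTL
  expect_equal(unlist(gt$true_scores[1, c("c1", "c2", "c3", "c4", "c5")]),
               c(c1 = 5L, c2 = 4L, c3 = 15L, c4 = 5L, c5 = 0L),
               ignore_attr = TRUE)
})

test_that("plan validation rejects infeasible score requests", {
  expect_error(generator_config(seed = 1, planted_targets = plan_row(
    "G1", p = 2e-5)), "p-values")
  expect_error(generator_config(seed = 1, planted_targets = plan_row(
    "G1", qtl = NA, tissue = NA, sign = 1L)), "effect_sign")
  expect_error(generator_config(seed = 1, planted_targets = plan_row(
    "G1", qtl = NA, tissue = "brain", sign = NA)), "tissue")
  expect_error(generator_config(seed = 1, planted_targets = plan_row(
    "G1", qtl = NA, tissue = NA, sign = NA)), "consequence")
  expect_error(generator_config(seed = 1, planted_targets = plan_row(
    "G1", r2 = 0)), "proxy_r2")
})

test_that("pathway_fraction = 0 empties the overlap stage", {
  cfg <- generator_config(seed = 2, n_samples = 100,
                          planted_targets = rbind(plan_row("G1"),
                                                  plan_row("G2")),
                          pathway_fraction = 0)
  b <- generate_bundle(cfg)
  expect_length(b$ground_truth$true_shared, 0L)
  proxies <- expand_proxies(b$panel, b$hits)
  targets <- map_targets(b$hits, proxies, b$qtls)
  shared <- overlap_targets(targets, b$pathways)
  expect_equal(nrow(shared$summary), 0L)
})

test_that("bundles are byte-identical under one seed, different across seeds", {
  plan <- rbind(plan_row("G1"), plan_row("G2", r2 = 0.95, sign = -1L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  generate_bundle(generator_config(seed = 5, n_samples = 100,
                                   planted_targets = plan), dir = d1)
  generate_bundle(generator_config(seed = 5, n_samples = 100,
                                   planted_targets = plan), dir = d2)
  generate_bundle(generator_config(seed = 6, n_samples = 100,
                                   planted_targets = plan), dir = d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_false(identical(readLines(file.path(d1, "panel.tsv")),
                         readLines(file.path(d3, "panel.tsv"))))
})

test_that("planted proxy LD is realized exactly in the emitted panel", {
  plan <- rbind(plan_row("G1", r2 = 0.9604),
                plan_row("G2", r2 = 0.9216, qtl = "pQTL"))
  b <- generate_bundle(generator_config(seed = 8, n_samples = 200,
                                        planted_targets = plan))
  expect_equal(unname(b$ground_truth$realized_r2),
               c(0.9604, 0.9216), tolerance = 1e-12)
  ids <- b$panel$variants$id
  ld1 <- ld_pair(b$panel, ids[1], ids[2])
  expect_equal(ld1$r2, 0.9604, tolerance = 1e-12)
})

test_that("generator RNG use does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(generate_bundle(generator_config(
    seed = 9, n_samples = 100, planted_targets = plan_row("G1"))))
  expect_identical(runif(1), before)
})
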