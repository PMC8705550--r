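test_that("pathway overlap keeps exactly the genes in the member union", {
  ev <- do.call(rbind, lapply(sprintf("G%d", 1:7), ev_row))
  ts <- make_target_set(ev)
  sets <- structure(list(P1 = c("G1", "G2"), P2 = c("G2", "G5"),
                         P3 = c("OTHER")), class = "pathway_sets")
  out <- overlap_targets(ts, sets)
  expect_setequal(out$summary$gene, c("G1", "G2", "G5"))
  expect_equal(attr(out, "n_before"), 7L)
  none <- overlap_targets(ts, structure(list(P1 = "X1"),
                                        class = "pathway_sets"))
  expect_equal(nrow(none$summary), 0L)
})

test_that("the five criteria reproduce hand-summed scores", {
  # best case: gw-sig non-MHC hit, OR 1.3, self brain eQTL + self pQTL
  best <- rbind(
    ev_row("G1", qtl_type = "eQTL", tissue = "brain", ld = 1),
    ev_row("G1", qtl_type = "pQTL", tissue = "blood", ld = 1))
  s <- score_targets(make_target_set(best))
  expect_equal(unlist(s[1, c("c1", "c2", "c3", "c4", "c5")]),
               c(c1 = 5L, c2 = 4L, c3 = 15L, c4 = 5L, c5 = 3L))
  expect_equal(s$total, 32L)

  # MHC-only gw-sig hit with consequence evidence only
  mhc <- ev_row("G2", kind = "consequence", hit_p = 1e-10,
                hit_chrom = "6", hit_pos = 30e6, consequence =
                  "missense_variant", cadd = 22)
  s2 <- score_targets(make_target_set(mhc))
  expect_equal(unlist(s2[1, c("c1", "c2", "c3", "c4", "c5")]),
               c(c1 = 2L, c2 = 0L, c3 = 0L, c4 = 0L, c5 = 0L))

  # non-brain eQTL at LD 0.96 to a low-OR hit
  mid <- ev_row("G3", qtl_type = "eQTL", tissue = "blood", ld = 0.96,
                hit_or = 1.1)
  s3 <- score_targets(make_target_set(mid))
  expect_equal(unlist(s3[1, c("c1", "c2", "c3", "c4", "c5")]),
               c(c1 = 5L, c2 = 0L, c3 = 10L, c4 = 3L, c5 = 0L))
})

test_that("LD bins are half-open with the top bin closed at 0.99", {
  for (case in list(list(ld = 1.00, c2 = 4L, c4 = 5L),
                    list(ld = 0.99, c2 = 4L, c4 = 5L),
                    list(ld = 0.9899, c2 = 3L, c4 = 3L),
                    list(ld = 0.95, c2 = 3L, c4 = 3L),
                    list(ld = 0.9499, c2 = 2L, c4 = 2L),
                    list(ld = 0.90, c2 = 2L, c4 = 2L),
                    list(ld = 0.80, c2 = 1L, c4 = 1L),
                    list(ld = 0.7999, c2 = 0L, c4 = 0L))) {
    s <- score_targets(make_target_set(ev_row("G", ld = case$ld,
                                              tissue = "blood")))
    expect_equal(s$c2, case$c2, info = paste("c2 at ld", case$ld))
    expect_equal(s$c4, case$c4, info = paste("c4 at ld", case$ld))
  }
})

test_that("OR and c5 thresholds behave as specified", {
  # OR exactly 1.2 does not qualify for c2 (strictly greater required)
  s <- score_targets(make_target_set(ev_row("G", hit_or = 1.2)))
  expect_equal(s$c2, 0L)
  # non-eQTL at LD exactly 0.99 earns c5; below it does not
  s99 <- score_targets(make_target_set(
    ev_row("G", qtl_type = "pQTL", ld = 0.99)))
  expect_equal(s99$c5, 3L)
  s98 <- score_targets(make_target_set(
    ev_row("G", qtl_type = "pQTL", ld = 0.989)))
  expect_equal(s98$c5, 0L)
})

test_that("score is monotone under added evidence and raised LD", {
  set.seed(42)
  qtl_types <- c("eQTL", "pQTL", "sQTL", "mQTL")
  tissues <- c("brain", "blood")
  rand_ev <- function(gene) {
    ev_row(gene, qtl_type = sample(qtl_types, 1),
           tissue = sample(tissues, 1),
           ld = round(runif(1, 0.5, 1), 3),
           hit_p = 10^-runif(1, 5.1, 12),
           hit_or = runif(1, 1.0, 1.6))
  }
  for (i in 1:30) {
    ev <- do.call(rbind, lapply(seq_len(sample(1:4, 1)),
                                function(j) rand_ev("G")))
    total <- score_targets(make_target_set(ev))$total
    expect_gte(total, 0L); expect_lte(total, 32L)
    # adding evidence never lowers the total
    more <- rbind(ev, rand_ev("G"))
    expect_gte(score_targets(make_target_set(more))$total, total)
    # raising one evidence's LD never lowers the total
    up <- ev
    up$ld_to_hit[1] <- min(1, up$ld_to_hit[1] + runif(1, 0, 0.3))
    expect_gte(score_targets(make_target_set(up))$total, total)
  }
})

test_that("partial scores always come from their declared value sets", {
  set.seed(9)
  for (i in 1:40) {
    ev <- ev_row("G", qtl_type = sample(c("eQTL", "pQTL"), 1),
                 tissue = sample(c("brain", "liver"), 1),
                 ld = runif(1), hit_p = 10^-runif(1, 5.1, 10),
                 hit_or = runif(1, 0.9, 1.5),
                 hit_chrom = sample(c("6", "2"), 1),
                 hit_pos = round(runif(1, 25e6, 35e6)))
    s <- score_targets(make_target_set(ev))
    expect_true(s$c1 %in% c(0L, 2L, 5L))
    expect_true(s$c2 %in% 0:4)
    expect_true(s$c3 %in% c(0L, 10L, 15L))
    expect_true(s$c4 %in% c(0L, 1L, 2L, 3L, 5L))
    expect_true(s$c5 %in% c(0L, 3L))
    expect_equal(s$total, s$c1 + s$c2 + s$c3 + s$c4 + s$c5)
  }
})

test_that("top-quantile selection takes floor(f*N) and extends ties", {
  sc <- function(genes, totals) data.frame(gene = genes, total = totals,
                                           stringsAsFactors = FALSE)
  # 8 distinct totals, fraction 0.25 -> exactly 2
  s8 <- select_top(sc(sprintf("G%d", 1:8), c(30, 28, 25, 22, 20, 15, 10, 5)))
  expect_equal(sum(s8$selected), 2L)
  expect_equal(attr(s8, "threshold"), 28)
  # all-equal totals: the boundary tie extends to everyone
  s4 <- select_top(sc(sprintf("G%d", 1:4), rep(17, 4)))
  expect_equal(sum(s4$selected), 4L)
  # 85 scored targets at fraction 0.25 -> 21 before tie-extension
  s85 <- select_top(sc(sprintf("G%02d", 1:85), seq(100, by = -1,
                                                   length.out = 85)))
  expect_equal(sum(s85$selected), 21L)
})
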