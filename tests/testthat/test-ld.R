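test_that("EM equals closed-form gamete counting when phase is known", {
  # no double heterozygotes: every cell is phase-unambiguous
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 4  # (0,0): 2x AC
  tab[3, 3] <- 3  # (2,2): 2x BD
  tab[2, 1] <- 2  # (1,0): AC + BC
  tab[1, 2] <- 1  # (0,1): AC + AD
  em <- em_haplotype_freqs(tab)
  n_hap <- 2 * sum(tab)
  expect_equal(unname(em$freq),
               c(4 * 2 + 2 + 1, 1, 2, 3 * 2) / n_hap)
  expect_equal(sum(em$freq), 1, tolerance = 1e-12)
  expect_false(em$undefined)
})

test_that("all-double-heterozygote tables sit at the symmetric fixed point", {
  tab <- matrix(0, 3, 3)
  tab[2, 2] <- 12
  em <- em_haplotype_freqs(tab)
  expect_equal(unname(em$freq), rep(0.25, 4), tolerance = 1e-9)
  panel <- make_panel(rep(1L, 12), rep(1L, 12))
  ld <- ld_pair(panel, "rs001", "rs002")
  expect_true(ld$degenerate)
  expect_null(ld$coupled)
})

test_that("EM matches the exhaustive-likelihood oracle on random tables", {
  set.seed(11)
  for (i in 1:25) {
    tab <- random_tab(20)
    em <- em_haplotype_freqs(tab)
    if (em$undefined) next
    f <- em$freq
    d_em <- unname(f["BD"] - (f["BC"] + f["BD"]) * (f["AD"] + f["BD"]))
    if (abs(d_em) < 1e-8) next  # symmetric fixed point: phase undecidable
    oracle <- oracle_hap_grid(tab, step = 1e-5)
    expect_equal(unname(em$freq["BD"]), oracle$f_bd, tolerance = 1e-4)
  }
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(7)
  for (i in 1:40) {
    em <- em_haplotype_freqs(random_tab(sample(5:60, 1)))
    expect_true(all(diff(em$loglik) >= -1e-9))
    expect_equal(sum(em$freq), 1, tolerance = 1e-12)
  }
})

test_that("monomorphic loci give an undefined-LD condition, not an error", {
  panel <- make_panel(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 1L))
  ld <- ld_pair(panel, "rs001", "rs002")
  expect_true(ld$undefined)
  expect_true(is.na(ld$r2))
})

test_that("identical genotype columns are in perfect positive LD", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 2L)
  panel <- make_panel(g, g)
  ld <- ld_pair(panel, "rs001", "rs002")
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_gt(ld$d, 0)
  expect_identical(unname(ld$coupled["G"]), "G")
  expect_identical(unname(ld$coupled["A"]), "A")
})

test_that("independent loci in a large simulated panel show r2 near zero", {
  panel <- simulate_panel(2000, blocks = list(c(0)), seed = 7)
  ld <- ld_pair(panel, panel$variants$id[1], panel$variants$id[2])
  expect_lt(ld$r2, 0.01)
})

test_that("a hand-built 6-sample panel matches the grid-search oracle", {
  g1 <- c(2L, 2L, 1L, 1L, 0L, 0L)
  g2 <- c(2L, 1L, 1L, 0L, 0L, 0L)
  panel <- make_panel(g1, g2)
  ld <- ld_pair(panel, "rs001", "rs002")
  oracle <- oracle_hap_grid(oxiscore:::genotype_crosstab(g1, g2))
  expect_equal(ld$r2, oracle$r2, tolerance = 1e-4)
  expect_equal(ld$n_eff, 6L)
})

test_that("r2 is symmetric and invariant under allele-label swaps", {
  set.seed(3)
  g1 <- as.integer(sample(0:2, 40, replace = TRUE))
  g2 <- as.integer(pmin(2, pmax(0, g1 + sample(-1:1, 40, replace = TRUE))))
  panel <- make_panel(g1, g2)
  ab <- ld_pair(panel, "rs001", "rs002")
  ba <- ld_pair(panel, "rs002", "rs001")
  expect_equal(ab$r2, ba$r2, tolerance = 1e-12)
  # relabel locus 2 (swap allele_a/allele_b, flip genotype counts)
  swapped <- make_panel(g1, 2L - g2)
  sw <- ld_pair(swapped, "rs001", "rs002")
  expect_equal(sw$r2, ab$r2, tolerance = 1e-9)
  expect_equal(sw$d, -ab$d, tolerance = 1e-9)
  # the coupling must follow the relabelling: same physical allele pairing.
  # In `swapped`, allele labels A/G at locus 2 denote the opposite counts,
  # so coupled[G] flips between the two encodings.
  expect_false(unname(sw$coupled["G"]) == unname(ab$coupled["G"]))
})

test_that("missing genotypes are deleted pairwise and recorded in n_eff", {
  g1 <- c(2L, NA, 1L, 0L, 2L, 1L)
  g2 <- c(2L, 1L, NA, 0L, 2L, 1L)
  panel <- make_panel(g1, g2)
  ld <- ld_pair(panel, "rs001", "rs002")
  expect_equal(ld$n_eff, 4L)
})

test_that("proxy expansion keeps strict r2 exceedance, sorted by r2", {
  # exact pair at r = 0.9 -> r2 = 0.81 (m = 190 coupled of n = 200)
  panel <- exact_pair_panel(200, 190)
  hit <- make_hit()
  at_threshold <- expand_proxies(panel, hit, r2_min = 0.81)
  expect_equal(at_threshold$proxy_id, "rs001")  # self only: strict
  above <- expand_proxies(panel, hit, r2_min = 0.80)
  expect_equal(above$proxy_id, c("rs001", "rs002"))
  expect_equal(above$r2, c(1, 0.81), tolerance = 1e-9)
  expect_equal(above$risk_coupled, c("G", "G"))
})

test_that("proxy expansion returns planted block members above threshold", {
  panel <- simulate_panel(2000, blocks = list(c(0.95, 0.8, 0.5)), seed = 21)
  v <- panel$variants
  hit <- make_hit(id = v$id[1], chrom = v$chrom[1], pos = v$pos[1])
  px <- expand_proxies(panel, hit, r2_min = 0.7)
  expect_setequal(px$proxy_id, v$id[1:3])  # r2 ~ {1, 0.95, 0.8} kept
  expect_false(v$id[4] %in% px$proxy_id)   # r2 ~ 0.5 excluded
  expect_true(all(diff(px$r2) <= 0))
})

test_that("hits absent from the panel keep a self-proxy with a warning", {
  panel <- make_panel(c(0L, 1L, 2L, 1L))
  hit <- make_hit(id = "rs999", pos = 5e6)
  expect_warning(px <- expand_proxies(panel, hit), "absent from panel")
  expect_equal(nrow(px), 1L)
  expect_equal(px$r2, 1)
  expect_equal(px$proxy_id, "rs999")
})
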