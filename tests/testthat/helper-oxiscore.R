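# Shared builders and independent oracles for the test suite.

# -- panel builders ----------------------------------------------------------

# panel from explicit genotype vectors (one per variant)
make_panel <- function(..., chrom = NULL, pos = NULL) {
  geno <- rbind(...)
  n_var <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("1", n_var)
  if (is.null(pos)) pos <- seq(1e6, by = 1e4, length.out = n_var)
  variants <- data.frame(chrom = chrom, pos = pos,
                         rsid = sprintf("rs%03d", seq_len(n_var)),
                         allele_a = "A", allele_b = "G",
                         stringsAsFactors = FALSE)
  genotype_panel(variants, geno, sprintf("S%03d", seq_len(ncol(geno))))
}

# one-row hits data.frame matching make_panel()'s variant naming
make_hit <- function(id = "rs001", chrom = "1", pos = 1e6,
                     risk_allele = "G", p_value = 1e-9, odds_ratio = 1.3) {
  data.frame(id = id, chrom = chrom, pos = pos, rsid = id,
             allele_a = "A", allele_b = "G", risk_allele = risk_allele,
             p_value = p_value, odds_ratio = odds_ratio, study_id = "T1",
             stringsAsFactors = FALSE)
}

# -- evidence / target-set builders ------------------------------------------

ev_row <- function(gene, kind = "qtl", qtl_type = "eQTL", tissue = "brain",
                   ld = 1, hit_p = 1e-9, hit_or = 1.3, hit_chrom = "1",
                   hit_pos = 1e6, effect_allele = "G", effect_sign = 1L,
                   risk_coupled = "G", via_id = "rsX", hit_id = "rsH",
                   degenerate = FALSE, consequence = NA_character_,
                   cadd = NA_real_, via_chrom = hit_chrom,
                   via_pos = hit_pos) {
  data.frame(gene = gene, hit_id = hit_id, hit_p = hit_p, hit_or = hit_or,
             hit_chrom = hit_chrom, hit_pos = hit_pos, via_id = via_id,
             via_chrom = via_chrom, via_pos = via_pos, kind = kind,
             qtl_type = if (kind == "qtl") qtl_type else NA_character_,
             tissue = if (kind == "qtl") tissue else NA_character_,
             effect_allele = if (kind == "qtl") effect_allele else
               NA_character_,
             effect_sign = if (kind == "qtl") effect_sign else NA_integer_,
             ld_to_hit = ld, risk_coupled = risk_coupled,
             degenerate = degenerate, consequence = consequence,
             cadd_phred = cadd, stringsAsFactors = FALSE)
}

make_target_set <- function(evidence) {
  structure(list(evidence = evidence,
                 summary = data.frame(gene = unique(evidence$gene),
                                      stringsAsFactors = FALSE),
                 excluded = data.frame(gene = character(0),
                                       reason = character(0))),
            class = "target_set")
}

# -- independent LD oracle ----------------------------------------------------

# Exhaustive grid search of the two-locus multinomial likelihood over the
# one free haplotype frequency (margins are fixed by the allele counts).
# Written independently of the package's EM: its own cell probabilities,
# its own maximisation, vectorized over the grid.
oracle_hap_grid <- function(tab, step = 1e-5) {
  n <- sum(tab)
  p_b1 <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p_b2 <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, p_b1 + p_b2 - 1)
  hi <- min(p_b1, p_b2)
  f_bd <- seq(lo, hi, by = step)
  if (length(f_bd) == 0L) f_bd <- lo
  f_bc <- pmax(p_b1 - f_bd, 0)
  f_ad <- pmax(p_b2 - f_bd, 0)
  f_ac <- pmax(1 - f_bd - f_bc - f_ad, 0)
  cellp <- list(f_ac^2, 2 * f_ac * f_ad, f_ad^2,
                2 * f_ac * f_bc, 2 * f_ac * f_bd + 2 * f_ad * f_bc,
                2 * f_ad * f_bd,
                f_bc^2, 2 * f_bc * f_bd, f_bd^2)
  obs <- c(tab[1, 1], tab[1, 2], tab[1, 3],
           tab[2, 1], tab[2, 2], tab[2, 3],
           tab[3, 1], tab[3, 2], tab[3, 3])
  ll <- 0
  for (k in seq_len(9)) {
    if (obs[k] > 0) ll <- ll + obs[k] * log(pmax(cellp[[k]], 1e-300))
  }
  best <- f_bd[which.max(ll)]
  d <- best - p_b1 * p_b2
  denom <- p_b1 * (1 - p_b1) * p_b2 * (1 - p_b2)
  list(f_bd = best, d = d,
       r2 = if (denom > 0) d^2 / denom else NA_real_,
       loglik = max(ll))
}

# random 3x3 genotype count table with given total
random_tab <- function(total) {
  cells <- as.vector(stats::rmultinom(1, total, rep(1 / 9, 9)))
  matrix(cells, 3, 3)
}

# exact-LD two-variant panel (homozygous layout), r = 4f - 1 on the
# symmetric 0.5-frequency grid; n must be a multiple of 4
exact_pair_panel <- function(n, m_coupled, chrom = c("1", "1"),
                             pos = c(1e6, 1.05e6)) {
  m <- m_coupled
  stopifnot(m %% 2 == 0, m >= n / 2, m <= n)
  g1 <- c(rep(2L, m / 2), rep(0L, m / 2),
          rep(2L, (n - m) / 2), rep(0L, (n - m) / 2))
  g2 <- c(rep(2L, m / 2), rep(0L, m / 2),
          rep(0L, (n - m) / 2), rep(2L, (n - m) / 2))
  make_panel(g1, g2, chrom = chrom, pos = pos)
}

# write a small TSV fixture with a build header
write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
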