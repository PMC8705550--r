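#' @title Two-locus linkage disequilibrium
#' @description
#' Haplotype frequencies for a pair of biallelic loci are estimated from
#' unphased diploid genotypes by expectation-maximisation over the phase of
#' double heterozygotes (the same phase-resolution step population-genetics
#' tools perform before reporting D, D' and r2). The haplotypes are labelled
#' `AC`, `AD`, `BC`, `BD` where `A`/`B` are `allele_a`/`allele_b` of the
#' first locus and `C`/`D` of the second.
#' @name ld-engine
NULL

# 3x3 joint genotype cross-tabulation; rows = copies of allele_b at locus 1
# (0,1,2), cols = copies at locus 2. Pairwise deletion of missing genotypes.
genotype_crosstab <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  if (any(ok)) {
    t0 <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
    tab <- tab + unclass(t0)
  }
  tab
}

# Multinomial log-likelihood of a 3x3 genotype table under haplotype
# frequencies f = (AC, AD, BC, BD), up to the data-only constant.
hap_loglik <- function(tab, f) {
  p <- matrix(0, 3, 3)
  p[1, 1] <- f[1]^2
  p[1, 2] <- 2 * f[1] * f[2]
  p[1, 3] <- f[2]^2
  p[2, 1] <- 2 * f[1] * f[3]
  p[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  p[2, 3] <- 2 * f[2] * f[4]
  p[3, 1] <- f[3]^2
  p[3, 2] <- 2 * f[3] * f[4]
  p[3, 3] <- f[4]^2
  use <- tab > 0
  sum(tab[use] * log(pmax(p[use], .Machine$double.xmin)))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Estimates the four haplotype frequencies (`AC`, `AD`, `BC`, `BD`) from a
#' 3x3 table of joint unphased genotype counts. All cells except the double
#' heterozygote are phase-unambiguous; the double-heterozygote count is split
#' between the `AC/BD` and `AD/BC` configurations at each E-step in the ratio
#' of their current frequency products. Initialisation is the
#' linkage-equilibrium product of the (data-determined) allele frequencies,
#' so the result is deterministic. The log-likelihood is non-decreasing
#' across iterations.
#'
#' @param tab 3x3 numeric matrix of genotype counts; `tab[i, j]` is the
#'   number of samples carrying `i - 1` copies of `allele_b` at the first
#'   locus and `j - 1` at the second.
#' @param tol convergence tolerance on the max absolute frequency change.
#' @param max_iter iteration cap.
#' @return list with elements `freq` (named numeric of length 4 summing to
#'   1), `loglik` (per-iteration log-likelihood trace), `iterations`,
#'   `converged`, and `undefined` (`TRUE` when either locus is monomorphic,
#'   in which case LD is undefined and `freq` is the equilibrium product).
#' @examples
#' # no double heterozygotes: gamete counting is exact
#' tab <- matrix(0, 3, 3); tab[1, 1] <- 5; tab[3, 3] <- 5
#' em_haplotype_freqs(tab)$freq
#' @export
em_haplotype_freqs <- function(tab, tol = 1e-10, max_iter = 1000L) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(3L, 3L)))
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("genotype counts must be finite and non-negative", call. = FALSE)
  }
  n <- sum(tab)
  if (n < 1) stop("empty genotype table", call. = FALSE)
  # allele_b frequencies at each locus are fixed by the data (phase cannot
  # change allele counts)
  p_b1 <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p_b2 <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  f <- c(AC = (1 - p_b1) * (1 - p_b2), AD = (1 - p_b1) * p_b2,
         BC = p_b1 * (1 - p_b2), BD = p_b1 * p_b2)
  if (p_b1 %in% c(0, 1) || p_b2 %in% c(0, 1)) {
    return(list(freq = f, loglik = hap_loglik(tab, f), iterations = 0L,
                converged = TRUE, undefined = TRUE))
  }
  # phase-known haplotype counts contributed by the eight unambiguous cells
  base <- c(
    AC = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    AD = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    BC = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    BD = 2 * tab[3, 3] + tab[2, 3] + tab[3, 2]
  )
  dh <- tab[2, 2]
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ll <- c(ll, hap_loglik(tab, f))
    # E-step: split double heterozygotes between the two phasings
    denom <- f["AC"] * f["BD"] + f["AD"] * f["BC"]
    w <- if (denom > 0) unname(f["AC"] * f["BD"] / denom) else 0.5
    counts <- base + dh * c(w, 1 - w, 1 - w, w)
    # M-step
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  ll <- c(ll, hap_loglik(tab, f))
  list(freq = f, loglik = ll, iterations = iter, converged = converged,
       undefined = FALSE)
}

#' Pairwise LD between two panel variants
#'
#' Cross-tabulates the unphased genotypes of the two variants (samples
#' missing at either locus are dropped pairwise), estimates haplotype
#' frequencies by [em_haplotype_freqs()], and derives D, D', r2 and the
#' coupled-allele phase: `coupled` maps each allele of the first variant to
#' the allele of the second that preferentially co-occurs with it on
#' haplotypes (the sign of D). When D is exactly zero the phase is
#' undecidable and the pair is flagged `degenerate`.
#'
#' @param panel a [genotype_panel()].
#' @param id_a,id_b variant identifiers (rsID or `chrom:pos`) present in the
#'   panel.
#' @return object of class `"ld_pair"`: list with `var_a`, `var_b` (variant
#'   rows), `r2`, `d`, `d_prime`, `coupled` (named character, alleles of A ->
#'   alleles of B), `n_eff`, `degenerate`, `undefined`, `freq`.
#' @export
ld_pair <- function(panel, id_a, id_b) {
  stopifnot(inherits(panel, "genotype_panel"))
  ia <- match(id_a, panel$variants$id)
  ib <- match(id_b, panel$variants$id)
  if (is.na(ia)) stop("variant not in panel: ", id_a, call. = FALSE)
  if (is.na(ib)) stop("variant not in panel: ", id_b, call. = FALSE)
  g1 <- panel$geno[ia, ]
  g2 <- panel$geno[ib, ]
  n_eff <- sum(!is.na(g1) & !is.na(g2))
  if (n_eff < 1) stop("no samples with genotypes at both loci", call. = FALSE)
  tab <- genotype_crosstab(g1, g2)
  em <- em_haplotype_freqs(tab)
  va <- panel$variants[ia, ]
  vb <- panel$variants[ib, ]
  f <- em$freq
  p_b1 <- unname(f["BC"] + f["BD"])
  p_b2 <- unname(f["AD"] + f["BD"])
  d <- unname(f["BD"]) - p_b1 * p_b2
  denom <- p_b1 * (1 - p_b1) * p_b2 * (1 - p_b2)
  if (em$undefined || denom <= 0) {
    out <- list(var_a = va, var_b = vb, r2 = NA_real_, d = NA_real_,
                d_prime = NA_real_, coupled = NULL, n_eff = n_eff,
                degenerate = FALSE, undefined = TRUE, freq = f)
    class(out) <- "ld_pair"
    return(out)
  }
  r2 <- d^2 / denom
  d_max <- if (d >= 0) {
    min(p_b1 * (1 - p_b2), (1 - p_b1) * p_b2)
  } else {
    min(p_b1 * p_b2, (1 - p_b1) * (1 - p_b2))
  }
  d_prime <- if (d_max > 0) d / d_max else 0
  degenerate <- abs(d) < 1e-12
  coupled <- if (degenerate) {
    NULL
  } else if (d > 0) {
    stats::setNames(c(vb$allele_a, vb$allele_b), c(va$allele_a, va$allele_b))
  } else {
    stats::setNames(c(vb$allele_b, vb$allele_a), c(va$allele_a, va$allele_b))
  }
  out <- list(var_a = va, var_b = vb, r2 = r2, d = d, d_prime = d_prime,
              coupled = coupled, n_eff = n_eff, degenerate = degenerate,
              undefined = FALSE, freq = f)
  class(out) <- "ld_pair"
  out
}

#' @export
print.ld_pair <- function(x, ...) {
  cat("ld_pair:", x$var_a$id, "--", x$var_b$id, "\n")
  if (x$undefined) {
    cat("  LD undefined (monomorphic locus)\n")
  } else {
    cat(sprintf("  r2 = %.4f  D = %.4f  D' = %.4f  (n_eff = %d)\n",
                x$r2, x$d, x$d_prime, x$n_eff))
    if (x$degenerate) {
      cat("  degenerate: D = 0, coupled phase undecidable\n")
    } else {
      cat("  coupled:", paste(names(x$coupled), x$coupled, sep = ">",
                              collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Expand GWAS hits to LD proxies
#'
#' For every hit, finds the panel variants on the same chromosome within
#' `window_bp` whose r2 with the hit exceeds `r2_min` (strict inequality, so
#' a variant at exactly the threshold is excluded). Each hit always maps to
#' itself with r2 = 1. For every (hit, proxy) pair the coupled allele of the
#' proxy corresponding to the hit's risk allele is recorded; it drives the
#' direction-of-effect call downstream. Hits absent from the panel are
#' retained with their self-proxy only, with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param hits GWAS hits from [read_gwas_hits()].
#' @param r2_min LD threshold; proxies must exceed it strictly.
#' @param window_bp proxy search window around the hit position.
#' @return data.frame with one row per (hit, proxy): `hit_id`, `proxy_id`,
#'   `chrom`, `pos`, `allele_a`, `allele_b`, `r2`, `risk_coupled` (proxy
#'   allele coupled to the risk allele; `NA` when the phase is degenerate),
#'   `degenerate`. Rows are sorted per hit by descending r2, ties by
#'   position.
#' @export
expand_proxies <- function(panel, hits, r2_min = 0.7, window_bp = 1e6) {
  stopifnot(inherits(panel, "genotype_panel"), r2_min > 0, r2_min <= 1)
  pv <- panel$variants
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    self <- data.frame(hit_id = hit$id, proxy_id = hit$id,
                       chrom = hit$chrom, pos = hit$pos,
                       allele_a = hit$allele_a, allele_b = hit$allele_b,
                       r2 = 1, risk_coupled = hit$risk_allele,
                       degenerate = FALSE, stringsAsFactors = FALSE)
    if (!(hit$id %in% pv$id)) {
      warning("hit ", hit$id, " absent from panel; keeping self-proxy only",
              call. = FALSE)
      out[[i]] <- self
      next
    }
    cand <- which(pv$chrom == hit$chrom &
                    abs(pv$pos - hit$pos) <= window_bp &
                    pv$id != hit$id)
    rows <- list(self)
    for (k in cand) {
      ld <- ld_pair(panel, hit$id, pv$id[k])
      if (ld$undefined || is.na(ld$r2) || ld$r2 <= r2_min) next
      # align the coupling to the hit's allele labels as given in the hit
      # table (the panel row for the hit carries the same alleles)
      rc <- if (ld$degenerate) NA_character_ else
        unname(ld$coupled[hit$risk_allele])
      rows[[length(rows) + 1L]] <- data.frame(
        hit_id = hit$id, proxy_id = pv$id[k], chrom = pv$chrom[k],
        pos = pv$pos[k], allele_a = pv$allele_a[k],
        allele_b = pv$allele_b[k], r2 = ld$r2, risk_coupled = rc,
        degenerate = ld$degenerate, stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, rows)
    block <- block[order(-block$r2, block$pos), , drop = FALSE]
    out[[i]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname expand_proxies
#' @param proxy_map data.frame from `expand_proxies()`.
#' @param path output TSV path.
#' @export
write_proxy_map <- function(proxy_map, path) {
  oxi_write_tsv(proxy_map, path, build = "GRCh37")
}
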