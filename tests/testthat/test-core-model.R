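gwas_lines <- function(rows) {
  c("# build=GRCh37",
    "chrom\tpos\talleles\trisk_allele\tp_value\todds_ratio\tstudy_id",
    rows)
}

test_that("GWAS intake applies the p < 1e-5 gate and counts drops", {
  path <- write_fixture(gwas_lines(c(
    "1\t1000000\tA/G\tG\t1e-9\t1.30\tS1",     # retained
    "2\t2000000\tC/T\tT\t2e-5\t1.10\tS1",     # dropped (>= 1e-5)
    "3\t3000000\tA/C\tA\t9.9e-6\t1.20\tS1",   # retained (just under)
    "4\t4000000\tG/T\tG\t1e-5\t1.05\tS1",     # dropped (boundary)
    "5\t5000000\tA/T\tT\t5e-8\t1.40\tS1")))   # retained
  hits <- read_gwas_hits(path)
  expect_equal(nrow(hits), 3L)
  expect_equal(attr(hits, "n_dropped"), 2L)
  expect_equal(nrow(hits) + attr(hits, "n_dropped"), 5L)
  expect_setequal(hits$chrom, c("1", "3", "5"))
  expect_equal(get_build(hits), "GRCh37")
  # variants without rsid fall back to chrom:pos ids
  expect_equal(hits$id, c("1:1000000", "3:3000000", "5:5000000"))
})

test_that("GWAS reader rejects schema and row-level problems precisely", {
  no_col <- write_fixture(c("# build=GRCh37",
                            "chrom\tpos\talleles\trisk_allele\tp_value\tstudy_id",
                            "1\t100\tA/G\tG\t1e-9\tS1"))
  expect_error(read_gwas_hits(no_col), "odds_ratio")
  bad_num <- write_fixture(gwas_lines(c(
    "1\t1000000\tA/G\tG\t1e-9\t1.3\tS1",
    "2\t2000000\tA/G\tG\tnot_a_p\t1.3\tS1")))
  expect_error(read_gwas_hits(bad_num), "line 4")
  bad_risk <- write_fixture(gwas_lines("1\t100\tA/G\tT\t1e-9\t1.3\tS1"))
  expect_error(read_gwas_hits(bad_risk), "risk_allele")
  bad_alleles <- write_fixture(gwas_lines("1\t100\tA/A\tA\t1e-9\t1.3\tS1"))
  expect_error(read_gwas_hits(bad_alleles), "identical alleles")
})

test_that("tables round-trip through write/read losslessly", {
  fx <- ms_fixture()
  d <- withr::local_tempdir()

  write_gwas_hits(fx$hits, file.path(d, "h.tsv"))
  h2 <- read_gwas_hits(file.path(d, "h.tsv"))
  expect_equal(h2[names(h2)], fx$hits[names(h2)], tolerance = 1e-12)

  write_qtl_table(fx$qtls, file.path(d, "q.tsv"))
  q2 <- read_qtl_table(file.path(d, "q.tsv"))
  expect_equal(q2, fx$qtls, tolerance = 1e-12, ignore_attr = TRUE)

  write_panel(fx$panel, file.path(d, "p.tsv"))
  p2 <- read_panel(file.path(d, "p.tsv"))
  expect_identical(unname(p2$geno), unname(fx$panel$geno))
  expect_equal(p2$variants, fx$panel$variants)

  write_drug_table(fx$drugs, file.path(d, "dr.tsv"))
  d2 <- read_drug_table(file.path(d, "dr.tsv"))
  expect_equal(d2, fx$drugs, tolerance = 1e-12, ignore_attr = TRUE)

  write_adme_table(fx$adme, file.path(d, "a.tsv"))
  a2 <- read_adme_table(file.path(d, "a.tsv"))
  expect_equal(a2, fx$adme, tolerance = 1e-12, ignore_attr = TRUE)

  write_pathways_gmt(fx$pathways, file.path(d, "pw.gmt"))
  pw2 <- read_pathways_gmt(file.path(d, "pw.gmt"))
  expect_identical(unclass(pw2), unclass(fx$pathways))
})

test_that("GMT parsing uppercases, de-duplicates and unions members", {
  path <- write_fixture(c("OS1\tdesc\tKeap1\tMAPK1",
                          "OS2\tdesc\tmapk1\tMAPK1\tHDAC1"), ext = ".gmt")
  sets <- read_pathways_gmt(path)
  expect_identical(sets$OS1, c("KEAP1", "MAPK1"))
  expect_identical(sets$OS2, c("MAPK1", "HDAC1"))
  expect_setequal(pathway_union(sets), c("KEAP1", "MAPK1", "HDAC1"))

  # 22 one-gene pathways sharing a symbol collapse to a union of one
  shared <- write_fixture(sprintf("P%02d\tdesc\tNFE2L2", 1:22), ext = ".gmt")
  expect_length(pathway_union(read_pathways_gmt(shared)), 1L)

  short <- write_fixture(c("OS1\tdesc\tKEAP1", "OS2\tonly_two_fields"),
                         ext = ".gmt")
  expect_error(read_pathways_gmt(short), "line 2")
})

test_that("MHC membership uses the closed chr6 27-33 Mb interval", {
  expect_true(in_mhc("6", 30e6))
  expect_true(in_mhc("chr6", 27e6))    # closed lower boundary
  expect_true(in_mhc("6", 33e6))       # closed upper boundary
  expect_false(in_mhc("6", 26999999))
  expect_false(in_mhc("6", 33000001))
  expect_false(in_mhc("7", 30e6))
})

test_that("consequence vocabulary is ordered and closed", {
  expect_lt(consequence_rank("stop_gained"),
            consequence_rank("missense_variant"))
  expect_lt(consequence_rank("missense_variant"),
            consequence_rank("synonymous_variant"))
  expect_error(consequence_rank("made_up_class"), "made_up_class")
})

test_that("a minimal GT-only VCF loads as a genotype panel", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- write_fixture(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t1000000\trs001\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t1010000\trs002\tC\tT\t.\t.\t.\tGT\t0|1\t./.\t1|1"), ext = ".vcf")
  panel <- read_panel(vcf)
  expect_s3_class(panel, "genotype_panel")
  expect_equal(panel$variants$id, c("rs001", "rs002"))
  expect_equal(unname(panel$geno[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(panel$geno[2, ]), c(1L, NA, 2L))
  expect_equal(panel$variants$allele_b, c("G", "T"))
})

test_that("mixing genome builds across inputs is a hard error", {
  fx <- ms_fixture()
  d <- withr::local_tempdir()
  fx2 <- ms_fixture(dir = d)
  write_gwas_hits(fx$hits, file.path(d, "hits38.tsv"), build = "GRCh38")
  cfg <- pipeline_config(gwas = file.path(d, "hits38.tsv"),
                         qtl = fx2$paths$qtl, panel = fx2$paths$panel,
                         pathways = fx2$paths$pathways,
                         out_dir = file.path(d, "out"))
  expect_error(run_pipeline(cfg), "build mismatch")
})
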