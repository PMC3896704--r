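test_that("pedigree templates honor affected counts and determinism", {
  p1 <- generate_pedigree("cousin_pair", 2, seed = 1)
  expect_equal(nrow(p1$members), 8)
  expect_equal(length(affected_ids(p1)), 2)
  # affected cousins: shared grandparents, different nuclear families
  aff <- p1$members[p1$members$affection == "affected", ]
  expect_equal(length(unique(aff$mother_id)), 2)

  expect_error(generate_pedigree("cousin_pair", 5), "2..2")
  p5 <- generate_pedigree("avuncular_plus_cousin", 5, seed = 2)
  expect_equal(length(affected_ids(p5)), 5)

  expect_identical(generate_pedigree("second_cousin", 3, seed = 9),
                   generate_pedigree("second_cousin", 3, seed = 9))
})

test_that("gene drop reproduces Haldane recombination fractions", {
  # two markers 10 cM apart: recombinant fraction ~ (1 - exp(-0.2))/2
  map <- flat_map(2, af = c(0.5, 0.5), spacing_cM = 10)
  ped <- nuclear_pedigree(1)
  n <- 5000  # 2 meioses per drop -> 10,000 observed transmissions
  rec <- 0L; tot <- 0L
  set.seed(31)
  for (i in seq_len(n)) {
    gd <- gene_drop(ped, map, seed = NULL)
    d <- gd$descent
    for (h in c("pat", "mat")) {
      tot <- tot + 1L
      gp1 <- d[[h]][1, "c1"]; gp2 <- d[[h]][2, "c1"]
      if (gp1 != gp2) rec <- rec + 1L
    }
  }
  th <- (1 - exp(-0.2)) / 2
  se <- sqrt(th * (1 - th) / tot)
  expect_lt(abs(rec / tot - th), 3 * se)
})

test_that("zero map distance means complete cosegregation", {
  # strictly increasing cM required; epsilon spacing makes theta ~ 0
  map <- marker_map(data.frame(
    marker_id = c("m1", "m2", "m3"), chrom = "1",
    position_bp = c(1e4, 2e4, 3e4), position_cM = c(0, 1e-12, 2e-12),
    ref_allele = "A", alt_allele = "G", panel_af = 0.5,
    stringsAsFactors = FALSE))
  ped <- nuclear_pedigree(1)
  for (s in 1:20) {
    gd <- gene_drop(ped, map, seed = s)
    expect_equal(length(unique(gd$descent$pat[, "c1"])), 1)
    expect_equal(length(unique(gd$descent$mat[, "c1"])), 1)
  }
})

test_that("founder heterozygosity matches 2p(1-p)", {
  map <- flat_map(4000, af = rep(0.5, 4000), spacing_cM = 0.1)
  ped <- nuclear_pedigree(1)
  gd <- gene_drop(ped, map, seed = 11)
  het <- mean(gd$calls[, "p1"] == 1)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("array noise model hits configured rates", {
  map <- flat_map(2000, seed = 3, spacing_cM = 0.05)
  ped <- generate_pedigree("cousin_pair", 2, seed = 1)
  gd <- gene_drop(ped, map, seed = 2)

  clean <- simulate_array_genotypes(gd, 0, 0, seed = 5)
  expect_equal(clean$calls, gd$calls)
  expect_null(clean$phase)

  noisy <- simulate_array_genotypes(gd, error_rate = 0.02, missing_rate = 0,
                                    seed = 6)
  disc <- mean(noisy$calls != gd$calls)
  expect_lt(abs(disc - 0.02), 3 * sqrt(0.02 * 0.98 / length(gd$calls)))

  gappy <- simulate_array_genotypes(gd, 0, missing_rate = 0.05, seed = 7)
  cr <- mean(!is.na(gappy$calls))
  expect_lt(abs(cr - 0.95), 3 * sqrt(0.05 * 0.95 / length(gd$calls)))
})

test_that("control counts are binomial over 2n chromosomes", {
  expect_equal(unname(simulate_control_counts(0, 308, seed = 1)),
               c(0L, 616L))
  cc <- simulate_control_counts(0.5, 50000, seed = 2)
  expect_equal(unname(cc[2]), 100000L)
  expect_lt(abs(cc[1] / cc[2] - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("injected het causal variants sit on an all-affected shared haplotype", {
  map <- flat_map(60, seed = 21, spacing_cM = 1)
  for (s in 1:25) {
    ped <- generate_pedigree("cousin_pair", 2, seed = s)
    gd <- gene_drop(ped, map, seed = s + 500)
    inj <- inject_causal_variant(gd, ped, map, causal_spec(), seed = s)
    aff <- affected_ids(ped)
    expect_true(all(inj$genotypes[aff] == 1L))
    # brute-force descent trace: the flanking markers around the causal
    # position must carry the carrier slot in every affected
    gt <- inj$gt
    i <- findInterval(inj$variant$pos, map$position_bp)
    carried <- vapply(aff, function(id)
      gt$descent$pat[i, id] %in% inj$carrier_slots ||
        gt$descent$mat[i, id] %in% inj$carrier_slots, logical(1))
    carried_r <- vapply(aff, function(id)
      gt$descent$pat[i + 1, id] %in% inj$carrier_slots ||
        gt$descent$mat[i + 1, id] %in% inj$carrier_slots, logical(1))
    # no recombination can hit both flanks in all affected simultaneously
    expect_true(all(carried | carried_r))
  }
})

test_that("impossible causal models are rejected", {
  fs <- pedigree("F", make_members(
    list("dad", NA, NA, "male", "affected"),
    list("mom", NA, NA, "female", "unaffected"),
    list("son", "dad", "mom", "male", "affected")))
  map <- flat_map(10, seed = 1, chrom = "X")
  gd <- gene_drop(fs, map, seed = 1)
  expect_error(inject_causal_variant(gd, fs, map,
                                     causal_spec(model = "xlinked", chrom = "X"),
                                     seed = 1),
               "not compatible")
})

test_that("hom and xlinked injections realize their genotype patterns", {
  map <- flat_map(40, seed = 33, spacing_cM = 1)
  ped <- generate_pedigree("cousin_pair", 2, seed = 3)
  gd <- gene_drop(ped, map, seed = 4)
  hom <- inject_causal_variant(gd, ped, map, causal_spec(model = "hom"),
                               seed = 5)
  expect_true(all(hom$genotypes[affected_ids(ped)] == 2L))

  xmap <- flat_map(40, seed = 34, spacing_cM = 1, chrom = "X")
  xped <- generate_pedigree("cousin_pair", 2, seed = 6, x_compatible = TRUE)
  xgd <- gene_drop(xped, xmap, seed = 7)
  xin <- inject_causal_variant(xgd, xped, xmap,
                               causal_spec(model = "xlinked", chrom = "X"),
                               seed = 8)
  sex <- setNames(xped$members$sex, xped$members$person_id)
  aff <- affected_ids(xped)
  expect_true(all(xin$genotypes[aff][sex[aff] == "male"] == 2L))
  expect_true(all(xin$genotypes[aff][sex[aff] == "female"] == 1L))
})

test_that("exome tables carry the configured structure", {
  ped <- generate_pedigree("cousin_pair", 2, seed = 1)
  map <- flat_map(50, seed = 2)
  exo <- simulate_exome_table(ped, map, n_variants = 4000, seed = 3,
                              vqslod_fail_rate = 0.1)
  v <- exo$variants$variants
  expect_equal(nrow(v), 4000)
  frac_fail <- mean(v$vqslod <= 0)
  expect_lt(abs(frac_fail - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  expect_true(all(v$control_ac <= v$control_an))
  expect_true(all(v$effect %in% c("missense", "nonsense", "splice_site",
                                  "synonymous", "intronic")))

  # genotypes are Mendelian-consistent single-locus drops
  seq_ids <- colnames(exo$variants$gt)
  gt2 <- genotype_table(sprintf("v%d", seq_len(nrow(v))), seq_ids,
                        exo$variants$gt)
  expect_equal(nrow(mendelian_check(ped, gt2)), 0)

  # causal bookkeeping
  gd <- gene_drop(ped, map, seed = 5)
  inj <- inject_causal_variant(gd, ped, map, causal_spec(), seed = 6)
  exo2 <- simulate_exome_table(ped, map, 100, causal = inj, seed = 7)
  expect_equal(nrow(exo2$truth), 1)
  key <- paste(exo2$variants$variants$chrom, exo2$variants$variants$pos)
  expect_true(paste(exo2$truth$chrom, exo2$truth$pos) %in% key)
})

test_that("same seed gives bit-identical simulations", {
  cfg <- sim_config(n_families = 2, markers_per_autosome = 60, x_markers = 20,
                    n_autosomes = 2, n_exome_variants = 300, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$map, s2$map)
  expect_identical(s1$families$FAM01$array_gt$calls,
                   s2$families$FAM01$array_gt$calls)
  expect_identical(s1$families$FAM02$exome$variants,
                   s2$families$FAM02$exome$variants)
})

test_that("VCF round trip preserves records and genotypes", {
  ped <- generate_pedigree("cousin_pair", 2, seed = 1)
  map <- flat_map(30, seed = 2)
  exo <- simulate_exome_table(ped, map, 200, seed = 3)
  f <- tempfile(fileext = ".vcf")
  write_vcf(exo$variants, f)
  back <- read_vcf(f)
  expect_equal(back$variants$pos, exo$variants$variants$pos)
  expect_equal(back$variants$gene, exo$variants$variants$gene)
  expect_equal(back$variants$control_ac, exo$variants$variants$control_ac)
  expect_equal(back$variants$dbsnp_known, exo$variants$variants$dbsnp_known)
  expect_equal(back$gt, exo$variants$gt, ignore_attr = TRUE)
  expect_equal(back$dp, exo$variants$dp, ignore_attr = TRUE)
  expect_equal(round(back$variants$vqslod, 5),
               round(exo$variants$variants$vqslod, 5))

  # independent reader cross-check
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(as.integer(vcfR::getPOS(v)), exo$variants$variants$pos)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dec <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  expect_equal(unname(matrix(dec[gt_chr], nrow(gt_chr))),
               unname(exo$variants$gt))
})
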