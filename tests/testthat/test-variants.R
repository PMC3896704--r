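fixture_vcf <- function() {
  read_vcf(system.file("extdata", "filter_fixture.vcf",
                       package = "kindredscan"))
}

fixture_ped <- function() generate_pedigree("cousin_pair", 2, seed = 401)

fixture_segments <- function() {
  data.frame(family_id = "FAM1", chrom = "1",
             start_bp = 1000000L, end_bp = 2000000L,
             stringsAsFactors = FALSE)
}

test_that("quality filter applies strict VQSLOD and depth masking", {
  vs <- fixture_vcf()
  out <- quality_filter(vs)
  # VQSLOD exactly 0 and below are dropped
  expect_false(any(out$variants$vqslod <= 0))
  expect_equal(nrow(out$variants), 18)
  # depth 3 genotype becomes missing, depth 4 survives
  low <- which(out$variants$pos == 1200000)
  expect_true(is.na(out$gt[low, "07"]))
  expect_false(is.na(out$gt[low, "08"]))
  four <- which(out$variants$pos == 1250000)
  expect_false(any(is.na(out$gt[four, ])))
})

test_that("damaging filter keeps protein/splice-altering classes only", {
  vs <- fixture_vcf()
  out <- damaging_filter(vs)
  expect_true(all(out$variants$effect %in% c("missense", "nonsense",
                                             "splice_site")))
  expect_false(any(out$variants$effect %in% c("synonymous", "intronic")))
  # missing effect annotation drops with a warning
  vs2 <- vs
  vs2$variants$effect[1] <- NA
  expect_warning(damaging_filter(vs2), "effect annotation")
})

test_that("rarity filter applies the MAF threshold and novelty tiers", {
  vs <- fixture_vcf()
  out <- rarity_filter(vs)
  v <- out$variants
  expect_false(any(v$pos == 1300000))  # panel MAF 0.051 dropped
  expect_true(any(v$pos == 1350000))   # 0.049 kept
  expect_false(any(v$pos == 1650000))  # EVS 0.06 dropped
  expect_false(any(v$pos == 1700000))  # control 40/616 dropped
  # dbSNP-known variant with low frequencies is rare, catalog-free is novel
  expect_equal(v$rarity[v$pos == 1050000], "rare")
  expect_equal(v$rarity[v$pos == 1000000], "novel")
  # control counts of 15/612 (~2.5%) stay, tier rare
  expect_true(any(v$pos == 1050000))

  # control_an = 0 keeps the record and flags unknown control frequency
  vs3 <- vs
  vs3$variants$control_an[] <- 0L
  vs3$variants$control_ac[] <- 0L
  out3 <- rarity_filter(vs3)
  expect_true(all(out3$variants$control_freq_unknown))
})

test_that("segregation filter enforces per-model genotype patterns", {
  vs <- fixture_vcf()
  ped <- fixture_ped()
  het <- segregation_filter(vs, ped, "het")
  expect_true(all(het$gt[, "07"] == 1L & het$gt[, "08"] == 1L))
  expect_false(any(het$variants$pos %in% c(1550000, 1600000, 1400000)))

  hom <- segregation_filter(vs, ped, "hom")
  expect_equal(sort(hom$variants$pos), c(500000, 2200000))

  # X-linked on an incompatible family yields nothing, with a note
  expect_message(xl <- segregation_filter(vs, ped, "xlinked"),
                 "not compatible")
  expect_equal(nrow(xl$variants), 0)

  # X-linked on a compatible family: males hemizygous, females het
  xped <- generate_pedigree("cousin_pair", 2, seed = 7, x_compatible = TRUE)
  xped$members$sex[xped$members$person_id == "08"] <- "female"
  v <- fixture_vcf()$variants[1:2, ]
  v$chrom <- "X"; v$pos <- c(100L, 200L)
  gt <- matrix(c(2L, 1L, 2L, 2L), 2, byrow = TRUE,
               dimnames = list(NULL, c("07", "08")))
  dp <- matrix(30L, 2, 2, dimnames = list(NULL, c("07", "08")))
  xvs <- variant_set(v, gt, dp)
  keep <- segregation_filter(xvs, xped, "xlinked")
  expect_equal(keep$variants$pos, 100L)
})

test_that("IBD restriction uses 1-based inclusive segment boundaries", {
  vs <- fixture_vcf()
  segs <- fixture_segments()
  out <- ibd_restrict(vs, segs)
  expect_true(any(out$variants$pos == 1000000))   # at start_bp
  expect_false(any(out$variants$pos == 2000001))  # 1 bp past end_bp
  expect_false(any(out$variants$pos == 2500000))
  expect_true(all(out$variants$in_ibd))

  # random fixture against a naive interval scan
  set.seed(14)
  v <- fixture_vcf()$variants[rep(1, 200), ]
  v$pos <- sample.int(4000000, 200)
  gt <- matrix(1L, 200, 2, dimnames = list(NULL, c("07", "08")))
  vs2 <- variant_set(v, gt, gt + 29L)
  segs2 <- data.frame(family_id = "F", chrom = "1",
                      start_bp = c(500000L, 2500000L),
                      end_bp = c(900000L, 3100000L))
  got <- ibd_restrict(vs2, segs2)$variants$pos
  want <- v$pos[vapply(v$pos, function(p)
    any(p >= segs2$start_bp & p <= segs2$end_bp), logical(1))]
  expect_setequal(got, want)
})

test_that("the packaged 20-record fixture yields exactly its 4 survivors", {
  out <- suppressMessages(
    run_family_cascade(fixture_vcf(), fixture_ped(), fixture_segments()))
  expect_equal(out$pos, c(1000000, 1050000, 1250000, 1350000))
  expect_equal(out$rarity, c("novel", "rare", "novel", "rare"))
  expect_equal(out$model, rep("het", 4))
  expect_equal(out$control_counts[2], "15/612")
  counts <- attr(out, "stage_counts")
  expect_equal(unname(counts["input"]), 20)
  expect_equal(unname(counts["quality"]), 18)
  expect_equal(unname(counts["ibd_het"]), 4)
})

test_that("damaging and rarity filters commute", {
  vs <- fixture_vcf()
  a <- rarity_filter(damaging_filter(vs))
  b <- damaging_filter(rarity_filter(vs))
  expect_equal(a$variants, b$variants)
  expect_equal(a$gt, b$gt)
})

test_that("cascade output satisfies every stage predicate when re-checked", {
  ped <- generate_pedigree("cousin_pair", 2, seed = 5)
  map <- flat_map(60, seed = 6)
  exo <- simulate_exome_table(ped, map, 2000, seed = 7)
  segs <- data.frame(family_id = ped$family_id, chrom = "1",
                     start_bp = 100000L, end_bp = 400000L)
  out <- suppressMessages(run_family_cascade(exo$variants, ped, segs))
  if (nrow(out)) {
    key <- paste(out$chrom, out$pos)
    v <- exo$variants$variants
    idx <- match(key, paste(v$chrom, v$pos))
    expect_true(all(v$vqslod[idx] > 0))
    expect_true(all(v$effect[idx] %in% c("missense", "nonsense", "splice_site")))
    expect_true(all(pmin(v$af_panel1, 1 - v$af_panel1)[idx] < 0.05))
    expect_true(all(out$pos >= 100000 & out$pos <= 400000))
  }
  # empty input -> empty output
  vs0 <- exo$variants
  keep0 <- rep(FALSE, nrow(vs0$variants))
  vs0 <- kindredscan:::subset_variant_set(vs0, keep0)
  out0 <- suppressMessages(run_family_cascade(vs0, ped, segs))
  expect_equal(nrow(out0), 0)
})

test_that("gene summaries flag multi-family and cis-pair patterns", {
  cand <- data.frame(
    family_id = c("17342", "18074", "37232", "37232", "37117"),
    chrom = c("5", "5", "12", "12", "8"),
    pos = c(168180047L, 168180047L, 42862463L, 42864125L, 2965294L),
    ref_allele = "C", alt_allele = "T",
    gene = c("SLIT3", "SLIT3", "PRICKLE1", "PRICKLE1", "CSMD1"),
    effect = "missense", model = "het", rarity = "rare",
    control_counts = "1/616", in_ibd = TRUE, stringsAsFactors = FALSE)
  gs <- summarize_genes(cand)
  slit3 <- gs[gs$gene == "SLIT3", ]
  expect_true(slit3$multi_family)   # same variant in two families
  expect_equal(slit3$n_variants, 1)
  prickle1 <- gs[gs$gene == "PRICKLE1", ]
  expect_false(prickle1$multi_family)
  expect_equal(prickle1$cis_pair_families, "37232")  # two variants in cis
  csmd1 <- gs[gs$gene == "CSMD1", ]
  expect_false(csmd1$multi_family)
  expect_equal(csmd1$cis_pair_families, "")

  expect_equal(nrow(summarize_genes(cand[0, ])), 0)
})
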