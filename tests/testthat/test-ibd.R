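test_that("single-affected families share trivially", {
  ped <- nuclear_pedigree(2, affected = 1)
  map <- flat_map(15, seed = 1)
  gd <- gene_drop(ped, map, seed = 2)
  prof <- compute_sharing(ped, gd, map)
  expect_equal(prof$sharing, rep(1, 15))
})

test_that("single-marker sib-pair sharing matches exhaustive enumeration", {
  ped <- nuclear_pedigree(2)
  map <- flat_map(1, af = 0.5)

  # het father, hom-ref mother, both sibs het: the alt allele can only come
  # from the father's single alt haplotype, so the sibs provably share it
  gt1 <- genotype_table("m001", c("p1", "p2", "c1", "c2"),
                        matrix(c(1L, 0L, 1L, 1L), 1))
  p1 <- compute_sharing(ped, gt1, map)$sharing[1]
  expect_equal(p1, 1, tolerance = 1e-12)
  expect_equal(p1, oracle_sharing_single(ped, gt1, map), tolerance = 1e-12)

  # het x het parents with identical het sibs: biallelic genotypes cannot
  # distinguish the four founder alleles; enumeration gives exactly 1/2,
  # below the 3/4 prior
  gt2 <- genotype_table("m001", c("p1", "p2", "c1", "c2"),
                        matrix(c(1L, 1L, 1L, 1L), 1))
  p2 <- compute_sharing(ped, gt2, map)$sharing[1]
  expect_equal(p2, oracle_sharing_single(ped, gt2, map), tolerance = 1e-12)
  expect_equal(p2, 0.5, tolerance = 1e-12)

  # identical hom-alt sibs at a rare allele: sharing above prior
  gt3 <- genotype_table("m001", c("p1", "p2", "c1", "c2"),
                        matrix(c(1L, 1L, 2L, 2L), 1))
  map_rare <- flat_map(1, af = 0.1)
  p3 <- compute_sharing(ped, gt3, map_rare)$sharing[1]
  expect_equal(p3, oracle_sharing_single(ped, gt3, map_rare), tolerance = 1e-12)
  expect_equal(p3, 1, tolerance = 1e-12)
})

test_that("multipoint sharing equals exhaustive forward-backward", {
  set.seed(2024)
  for (i in 1:6) {
    ped <- random_small_pedigree(i)
    map <- flat_map(12, seed = 300 + i, spacing_cM = 3)
    gd <- gene_drop(ped, map, seed = 400 + i)
    agt <- simulate_array_genotypes(gd, 0, 0.05, seed = 500 + i)
    agt <- subset_genotypes(agt,
                            samples = ped$members$person_id[ped$members$genotyped])
    prof <- compute_sharing(ped, agt, map)
    oracle <- oracle_sharing(ped, agt, map)
    expect_lt(max(abs(prof$sharing - oracle)), 1e-8)
  }
})

test_that("founder-label symmetry and affected monotonicity hold", {
  ped <- generate_pedigree("cousin_pair", 2, seed = 4)
  map <- flat_map(25, seed = 5)
  gd <- gene_drop(ped, map, seed = 6)
  agt <- subset_genotypes(gd, samples = ped$members$person_id[ped$members$genotyped])
  base <- compute_sharing(ped, agt, map)$sharing

  # adding an affected member can never increase sharing
  ped_more <- ped
  ped_more$members$affection[ped_more$members$person_id == "03"] <- "affected"
  more <- compute_sharing(ped_more, agt, map)$sharing
  expect_true(all(more <= base + 1e-12))

  # all-missing markers fall back to the prior
  gt_na <- genotype_table(map$marker_id, agt$sample_ids,
                          matrix(NA_integer_, nrow(map), length(agt$sample_ids)))
  prior <- compute_sharing(ped, gt_na, map)$sharing
  expect_equal(prior, rep(0.25, nrow(map)), tolerance = 1e-12)
})

test_that("meiosis cap raises a capacity error", {
  ped <- generate_pedigree("avuncular_plus_cousin", 5, seed = 1)  # m = 14
  map <- flat_map(5, seed = 1)
  gd <- gene_drop(ped, map, seed = 2)
  expect_error(compute_sharing(ped, gd, map, max_meioses = 10L), "cap")
})

test_that("segment caller equals brute-force window evaluation", {
  params <- segment_params(10, 0.5)
  # engineered runs: 9 high markers never qualify, 12 do
  mk_prof <- function(sharing) {
    structure(data.frame(family_id = "F", chrom = "1",
                         marker_id = sprintf("m%03d", seq_along(sharing)),
                         position_bp = seq_along(sharing) * 1000L,
                         sharing = sharing),
              class = c("sharing_profile", "data.frame"))
  }
  run9 <- c(rep(0.1, 5), rep(0.9, 9), rep(0.1, 5))
  expect_equal(nrow(call_segments(mk_prof(run9), params)), 0)
  run12 <- c(rep(0.1, 5), rep(0.9, 12), rep(0.1, 5))
  seg <- call_segments(mk_prof(run12), params)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, 6000)
  expect_equal(seg$end_bp, 17000)
  expect_equal(seg$n_markers, 12)

  expect_equal(call_segments(mk_prof(rep(1, 30)), params)$n_markers, 30)
  expect_equal(nrow(call_segments(mk_prof(rep(0.4, 30)), params)), 0)
  # ties at the threshold do not qualify (strict >)
  expect_equal(nrow(call_segments(mk_prof(rep(0.5, 30)), params)), 0)

  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    w <- sample(1:12, 1)
    th <- runif(1, 0.2, 0.8)
    sharing <- runif(n)
    flags <- kindredscan:::flag_ibd_markers(sharing, w, th)
    expect_identical(flags, oracle_flags(sharing, w, th))
  }
})

test_that("segment calling is monotone in threshold and window", {
  set.seed(7)
  sharing <- runif(60)
  prof <- structure(data.frame(family_id = "F", chrom = "1",
                               marker_id = sprintf("m%03d", 1:60),
                               position_bp = (1:60) * 1000L,
                               sharing = sharing),
                    class = c("sharing_profile", "data.frame"))
  cover <- function(seg) sum(seg$n_markers)
  base <- cover(call_segments(prof, segment_params(5, 0.3)))
  expect_gte(base, cover(call_segments(prof, segment_params(5, 0.5))))
  expect_gte(base, cover(call_segments(prof, segment_params(8, 0.3))))
})

test_that("windowed LD pruning matches the brute-force oracle", {
  set.seed(123)
  for (i in 1:50) {
    n_mark <- sample(8:40, 1)
    n_samp <- sample(c(10, 30), 1)
    calls <- matrix(sample(0:2, n_mark * n_samp, replace = TRUE), n_mark)
    # plant a duplicate pair and a monomorphic marker
    if (n_mark >= 4) {
      calls[2, ] <- calls[1, ]
      calls[4, ] <- 1L
    }
    w <- sample(4:10, 1); st <- sample(1:4, 1); th <- runif(1, 0.3, 0.9)
    map <- flat_map(n_mark, af = rep(0.5, n_mark))
    gt <- genotype_table(map$marker_id, sprintf("s%d", 1:n_samp), calls)
    got <- ld_prune(gt, map, prune_params(w, st, th))
    want <- map$marker_id[oracle_prune(calls, w, st, th)]
    expect_identical(got, want)
  }
})

test_that("duplicate markers collapse and uncorrelated markers survive", {
  map <- flat_map(6, af = rep(0.5, 6))
  set.seed(5)
  calls <- matrix(sample(0:2, 6 * 40, replace = TRUE), 6)
  calls[3, ] <- calls[1, ]
  gt <- genotype_table(map$marker_id, sprintf("s%d", 1:40), calls)
  kept <- ld_prune(gt, map, prune_params(6, 2, 0.5))
  expect_true(xor("m001" %in% kept, "m003" %in% kept))

  ortho <- matrix(c(rep(0:2, length.out = 40),
                    rep(c(0L, 2L, 1L), length.out = 40)), 2, byrow = TRUE)
  map2 <- flat_map(2, af = rep(0.5, 2))
  gt2 <- genotype_table(map2$marker_id, sprintf("s%d", 1:40), ortho)
  r2 <- suppressWarnings(cor(ortho[1, ], ortho[2, ]))^2
  kept2 <- ld_prune(gt2, map2, prune_params(2, 1, max(r2 + 0.01, 0.5)))
  expect_equal(length(kept2), 2)
})

test_that("pruning is invariant to sample order", {
  map <- flat_map(20, seed = 8)
  ped <- generate_pedigree("cousin_pair", 2, seed = 1)
  gd <- gene_drop(ped, map, seed = 3)
  p <- prune_params(10, 3, 0.5)
  k1 <- ld_prune(gd, map, p)
  shuffled <- subset_genotypes(gd, samples = rev(gd$sample_ids))
  expect_identical(ld_prune(shuffled, map, p), k1)
})

test_that("genome-wide segments recover an injected variant's locus", {
  map <- simulate_marker_map(n_autosomes = 2, markers_per_autosome = 120,
                             x_markers = 0, seed = 10)
  panel <- simulate_panel_genotypes(map, seed = 11)
  hits <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    ped <- generate_pedigree("cousin_pair", 2, seed = s)
    gd <- gene_drop(ped, map, seed = 1000 + s)
    inj <- inject_causal_variant(gd, ped, map, causal_spec(), seed = 2000 + s)
    agt <- simulate_array_genotypes(
      subset_genotypes(inj$gt, samples = ped$members$person_id[ped$members$genotyped]),
      0.005, 0.01, map = map, ped = ped, seed = 3000 + s)
    res <- segments_genomewide(ped, agt, map, prune_gt = panel)
    seg <- res$segments
    inside <- any(seg$chrom == inj$variant$chrom &
                    seg$start_bp <= inj$variant$pos &
                    seg$end_bp >= inj$variant$pos)
    hits <- hits + inside
  }
  # smoke-level bound; the study-scale recall check (100 replicates, full
  # pipeline) lives in the acceptance suite
  expect_gte(hits / n_rep, 0.85)

  # empty genotype table -> empty output
  empty <- genotype_table(character(0), character(0),
                          matrix(integer(0), 0, 0))
  ped <- generate_pedigree("cousin_pair", 2, seed = 1)
  out <- segments_genomewide(ped, empty, map)
  expect_equal(nrow(out$segments), 0)
})

test_that("X-chromosome sharing respects hemizygous transmission", {
  xped <- generate_pedigree("cousin_pair", 2, seed = 2, x_compatible = TRUE)
  xmap <- flat_map(40, seed = 12, chrom = "X")
  xgd <- gene_drop(xped, xmap, seed = 13)
  agt <- subset_genotypes(xgd, samples = xped$members$person_id[xped$members$genotyped])
  prof <- compute_sharing(xped, agt, xmap)
  expect_true(all(prof$sharing >= 0 & prof$sharing <= 1))
  # descent truth: markers where both affected carry the same founder X slot
  aff <- affected_ids(xped)
  truth <- vapply(seq_len(nrow(xmap)), function(i) {
    s1 <- stats::na.omit(c(xgd$descent$pat[i, aff[1]], xgd$descent$mat[i, aff[1]]))
    s2 <- stats::na.omit(c(xgd$descent$pat[i, aff[2]], xgd$descent$mat[i, aff[2]]))
    length(intersect(s1, s2)) > 0
  }, logical(1))
  agree <- mean((prof$sharing > 0.5) == truth)
  expect_gte(agree, 0.8)
})
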