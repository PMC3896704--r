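#' Construct an annotated variant set
#'
#' One row per exome variant with annotation fields (gene, effect class,
#' external panel frequencies, control allele counts, VQSLOD) plus aligned
#' per-sample genotype and depth matrices.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `gene`, `effect`, `dbsnp_known`, `kg_present`,
#'   `af_panel1`, `af_panel2`, `af_panel3`, `evs_af`, `control_ac`,
#'   `control_an`, `vqslod` (and optionally `dbsnp_id`).
#' @param gt Integer matrix (variants x samples) of alt-allele counts, with
#'   column names as sample ids.
#' @param dp Integer matrix of per-sample read depths, same shape as `gt`.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, gt, dp) {
  req <- c("chrom", "pos", "ref_allele", "alt_allele", "gene", "effect",
           "dbsnp_known", "kg_present", "af_panel1", "af_panel2", "af_panel3",
           "evs_af", "control_ac", "control_an", "vqslod")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants missing columns: ", paste(miss, collapse = ", "))
  if (is.null(variants$dbsnp_id)) variants$dbsnp_id <- NA_character_
  gt <- as.matrix(gt); dp <- as.matrix(dp)
  if (nrow(gt) != nrow(variants) || nrow(dp) != nrow(variants))
    stop("gt/dp rows must match variants")
  if (is.null(colnames(gt))) stop("gt must have sample ids as column names")
  bad <- with(variants, control_ac < 0 | control_ac > control_an)
  if (any(bad, na.rm = TRUE)) stop("control_ac must lie in [0, control_an]")
  rownames(variants) <- NULL
  structure(list(variants = variants, gt = gt, dp = dp,
                 sample_ids = colnames(gt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d samples\n",
              nrow(x$variants), length(x$sample_ids)))
  invisible(x)
}

empty_variant_frame <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             dbsnp_id = character(0), ref_allele = character(0),
             alt_allele = character(0), gene = character(0),
             effect = character(0), dbsnp_known = logical(0),
             kg_present = logical(0), af_panel1 = numeric(0),
             af_panel2 = numeric(0), af_panel3 = numeric(0),
             evs_af = numeric(0), control_ac = integer(0),
             control_an = integer(0), vqslod = numeric(0),
             stringsAsFactors = FALSE)
}

subset_variant_set <- function(vs, keep) {
  variant_set(vs$variants[keep, , drop = FALSE],
              vs$gt[keep, , drop = FALSE],
              vs$dp[keep, , drop = FALSE])
}

#' Filter configuration
#'
#' Thresholds for the variant filter cascade. Inequalities follow the study
#' conventions: VQSLOD strictly greater than `min_vqslod`, depth at least
#' `min_depth` (4x includes 4), minor allele frequency strictly below
#' `maf_threshold` in every external panel and in the internal controls.
#'
#' @param maf_threshold Rarity threshold on the minor allele frequency.
#' @param min_depth Minimum per-sample read depth for a genotype call.
#' @param min_vqslod Call-quality threshold (exclusive).
#' @param damaging_effects Effect classes considered damaging.
#' @param models Inheritance models to evaluate.
#' @param xlinked_female_hom_ok Accept homozygous affected females under the
#'   X-linked model (default requires heterozygous).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.05, min_depth = 4L,
                          min_vqslod = 0,
                          damaging_effects = c("missense", "nonsense",
                                               "splice_site"),
                          models = c("het", "hom", "xlinked"),
                          xlinked_female_hom_ok = FALSE) {
  stopifnot(maf_threshold >= 0, min_depth >= 0)
  models <- match.arg(models, c("het", "hom", "xlinked"), several.ok = TRUE)
  structure(list(maf_threshold = maf_threshold, min_depth = as.integer(min_depth),
                 min_vqslod = min_vqslod, damaging_effects = damaging_effects,
                 models = models, xlinked_female_hom_ok = xlinked_female_hom_ok),
            class = "filter_config")
}

#' Call-quality filter
#'
#' Drops variants whose VQSLOD is not strictly greater than the threshold,
#' masks per-sample genotypes below the depth minimum, and drops variants
#' whose genotypes are then all missing.
#'
#' @param vs A [variant_set()].
#' @param config A [filter_config()].
#' @return A filtered [variant_set()].
#' @export
quality_filter <- function(vs, config = filter_config()) {
  keep <- !is.na(vs$variants$vqslod) & vs$variants$vqslod > config$min_vqslod
  vs <- subset_variant_set(vs, keep)
  if (nrow(vs$variants)) {
    low <- !is.na(vs$dp) & vs$dp < config$min_depth
    vs$gt[low] <- NA_integer_
    vs$gt[is.na(vs$dp)] <- NA_integer_
    any_called <- rowSums(!is.na(vs$gt)) > 0
    vs <- subset_variant_set(vs, any_called)
  }
  vs
}

#' Predicted-damaging filter
#'
#' Keeps variants whose effect class alters the protein or splicing:
#' missense, nonsense, or splice site (annotated within two nucleotides of an
#' exon boundary). Variants with missing effect annotation are dropped with a
#' warning.
#'
#' @inheritParams quality_filter
#' @return A filtered [variant_set()].
#' @export
damaging_filter <- function(vs, config = filter_config()) {
  eff <- vs$variants$effect
  if (anyNA(eff))
    warning(sum(is.na(eff)), " variants lack an effect annotation; dropped")
  keep <- !is.na(eff) & eff %in% config$damaging_effects
  subset_variant_set(vs, keep)
}

#' Rarity and novelty filter
#'
#' Drops variants whose minor allele frequency reaches the threshold in any
#' external panel, in the external exome cohort, or in the internal control
#' chromosomes (`control_ac / control_an`). Survivors are tiered `novel`
#' (absent from the external exome cohort, the population-reference flag and
#' dbSNP) or `rare`. Novelty is defined by the public catalogs only; internal
#' control absence is not required.
#'
#' @inheritParams quality_filter
#' @return A [variant_set()] whose `variants` gains `rarity` and
#'   `control_freq_unknown` columns.
#' @export
rarity_filter <- function(vs, config = filter_config()) {
  v <- vs$variants
  maf <- function(f) ifelse(is.na(f), 0, pmin(f, 1 - f))
  ctrl_f <- ifelse(v$control_an > 0, v$control_ac / v$control_an, NA_real_)
  common <- maf(v$af_panel1) >= config$maf_threshold |
    maf(v$af_panel2) >= config$maf_threshold |
    maf(v$af_panel3) >= config$maf_threshold |
    maf(v$evs_af) >= config$maf_threshold |
    (!is.na(ctrl_f) & maf(ctrl_f) >= config$maf_threshold)
  vs <- subset_variant_set(vs, !common)
  v <- vs$variants
  ctrl_f <- ifelse(v$control_an > 0, v$control_ac / v$control_an, NA_real_)
  evs_absent <- is.na(v$evs_af)
  v$rarity <- ifelse(evs_absent & !v$kg_present & !v$dbsnp_known,
                     "novel", "rare")
  v$control_freq_unknown <- is.na(ctrl_f)
  vs$variants <- v
  vs
}

#' Segregation filter
#'
#' Keeps variants carried by every affected, sequenced family member under
#' the requested inheritance model: `het` requires all affected heterozygous,
#' `hom` all affected homozygous alternate, `xlinked` (X chromosome only)
#' affected males hemizygous (coded 2) and affected females heterozygous.
#' A missing genotype in any affected member fails the variant. Unaffected
#' carriers are never penalized (incomplete-penetrance tolerance).
#'
#' @param vs A [variant_set()].
#' @param ped A [pedigree()].
#' @param model One of `"het"`, `"hom"`, `"xlinked"`.
#' @param config A [filter_config()].
#' @return A filtered [variant_set()].
#' @export
segregation_filter <- function(vs, ped, model = c("het", "hom", "xlinked"),
                               config = filter_config()) {
  model <- match.arg(model)
  m <- ped$members
  aff <- m$person_id[m$affection == "affected" & m$sequenced]
  aff <- intersect(aff, vs$sample_ids)
  if (!length(aff)) return(subset_variant_set(vs, logical(nrow(vs$variants))))

  if (model == "xlinked") {
    if (length(affected_ids(ped)) >= 2 && !xlinked_compatible(ped)) {
      message("family ", ped$family_id,
              " is not compatible with X-linked inheritance; no variants kept")
      return(subset_variant_set(vs, logical(nrow(vs$variants))))
    }
    on_x <- is_x_chrom(vs$variants$chrom)
    g <- vs$gt[, aff, drop = FALSE]
    sex <- stats::setNames(m$sex, m$person_id)[aff]
    ok <- rep(TRUE, nrow(vs$variants))
    for (j in seq_along(aff)) {
      want <- if (sex[j] == "male") g[, j] == 2L else
        if (config$xlinked_female_hom_ok) g[, j] %in% c(1L, 2L) else g[, j] == 1L
      ok <- ok & !is.na(g[, j]) & want
    }
    return(subset_variant_set(vs, on_x & ok))
  }

  target <- if (model == "het") 1L else 2L
  g <- vs$gt[, aff, drop = FALSE]
  ok <- rowSums(is.na(g)) == 0 & rowSums(g == target) == length(aff)
  ok[is.na(ok)] <- FALSE
  subset_variant_set(vs, ok)
}

#' Restrict variants to IBD segments
#'
#' Keeps variants whose position falls within any of the family's IBD
#' segments (1-based inclusive boundaries).
#'
#' @param vs A [variant_set()].
#' @param segments Data frame of IBD segments (`chrom`, `start_bp`, `end_bp`).
#' @return A [variant_set()] whose `variants` gains an `in_ibd` column; only
#'   in-segment variants are retained.
#' @export
ibd_restrict <- function(vs, segments) {
  v <- vs$variants
  in_ibd <- rep(FALSE, nrow(v))
  if (nrow(segments)) {
    for (i in seq_len(nrow(segments))) {
      s <- segments[i, ]
      in_ibd <- in_ibd | (v$chrom == s$chrom & v$pos >= s$start_bp &
                            v$pos <= s$end_bp)
    }
  }
  vs$variants$in_ibd <- in_ibd
  subset_variant_set(vs, in_ibd)
}

#' Run the per-family filter cascade
#'
#' Applies call quality, damaging effect, rarity, per-model segregation and
#' IBD restriction in order, then unions the surviving variants over the
#' configured inheritance models.
#'
#' @param vs A [variant_set()] for one family's sequenced members.
#' @param ped The family [pedigree()].
#' @param segments The family's IBD segments.
#' @param config A [filter_config()].
#' @return Data frame of candidate variants, ordered by chromosome, position
#'   and model, with columns `family_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `gene`, `effect`, `model`, `rarity`, `control_counts`,
#'   `in_ibd`.
#' @export
run_family_cascade <- function(vs, ped, segments, config = filter_config()) {
  counts <- c(input = nrow(vs$variants))
  vs <- quality_filter(vs, config)
  counts["quality"] <- nrow(vs$variants)
  vs <- damaging_filter(vs, config)
  counts["damaging"] <- nrow(vs$variants)
  vs <- rarity_filter(vs, config)
  counts["rarity"] <- nrow(vs$variants)
  out <- list()
  for (model in config$models) {
    seg_vs <- segregation_filter(vs, ped, model, config)
    counts[paste0("segregating_", model)] <- nrow(seg_vs$variants)
    seg_vs <- ibd_restrict(seg_vs, segments)
    counts[paste0("ibd_", model)] <- nrow(seg_vs$variants)
    v <- seg_vs$variants
    if (!nrow(v)) next
    out[[model]] <- data.frame(
      family_id = ped$family_id, chrom = v$chrom, pos = v$pos,
      ref_allele = v$ref_allele, alt_allele = v$alt_allele, gene = v$gene,
      effect = v$effect, model = model, rarity = v$rarity,
      control_counts = paste0(v$control_ac, "/", v$control_an),
      in_ibd = v$in_ibd, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    res <- data.frame(family_id = character(0), chrom = character(0),
                      pos = integer(0), ref_allele = character(0),
                      alt_allele = character(0), gene = character(0),
                      effect = character(0), model = character(0),
                      rarity = character(0), control_counts = character(0),
                      in_ibd = logical(0), stringsAsFactors = FALSE)
    attr(res, "stage_counts") <- counts
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(chrom_order(res$chrom), res$pos, res$model), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "stage_counts") <- counts
  res
}

chrom_order <- function(chrom) {
  x <- toupper(sub("^chr", "", chrom))
  n <- suppressWarnings(as.integer(x))
  n[x == "X"] <- 23L
  n[x == "Y"] <- 24L
  n[is.na(n)] <- 25L
  n
}

#' Summarize candidate variants by gene across families
#'
#' @param candidates Data frame of candidate variants from
#'   [run_family_cascade()] (rows tagged with `family_id`), possibly
#'   concatenated over families.
#' @return Data frame with one row per gene: `gene`, `n_families`,
#'   `families_hit` (comma-separated), `n_variants`, `multi_family`
#'   (variants in at least two families), `cis_pair_families` (families with
#'   at least two distinct candidate variants in the gene).
#' @export
summarize_genes <- function(candidates) {
  if (!nrow(candidates))
    return(data.frame(gene = character(0), n_families = integer(0),
                      families_hit = character(0), n_variants = integer(0),
                      multi_family = logical(0),
                      cis_pair_families = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(candidates$family_id, candidates$chrom, candidates$pos,
               candidates$alt_allele)
  uniq <- candidates[!duplicated(paste(key, candidates$gene)), , drop = FALSE]
  out <- lapply(split(uniq, uniq$gene), function(g) {
    fams <- sort(unique(g$family_id))
    per_fam <- vapply(split(g, g$family_id), function(d)
      length(unique(paste(d$chrom, d$pos, d$alt_allele))), integer(1))
    cis <- sort(names(per_fam)[per_fam >= 2])
    data.frame(gene = g$gene[1], n_families = length(fams),
               families_hit = paste(fams, collapse = ","),
               n_variants = length(unique(paste(g$chrom, g$pos, g$alt_allele))),
               multi_family = length(fams) >= 2,
               cis_pair_families = paste(cis, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
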