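# Study-shaped synthetic data: multiplex pedigrees with affected cousin
# pairs, a genetic marker map, gene-dropped array genotypes (Haldane map
# function, no interference), injected causal variants with a coherent
# descent history, and annotated exome variant tables with a simulated
# control cohort.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629)
}

template_capacity <- function(template) {
  c(cousin_pair = 2L, avuncular_plus_cousin = 5L, second_cousin = 3L)[template]
}

#' Generate a multiplex pedigree from a template
#'
#' Templates all contain at least one affected first- or second-cousin pair,
#' mirroring an extended-family ascertainment design. All members are
#' array-genotyped (studies of this design genotype substantially more
#' relatives than they sequence); only affected members are exome-sequenced.
#'
#' @param template One of `"cousin_pair"` (8 members, capacity 2 affected),
#'   `"avuncular_plus_cousin"` (capacity 5), `"second_cousin"` (capacity 3).
#' @param n_affected Number of affected members (within template capacity).
#' @param seed Integer seed (affected sexes are drawn).
#' @param family_id Family identifier.
#' @param p_male_affected Probability an affected member is male.
#' @param x_compatible Arrange linking parents so the pedigree is compatible
#'   with X-linked inheritance (maternal connecting line, affected males).
#' @return A valid [pedigree()].
#' @export
generate_pedigree <- function(template = c("cousin_pair",
                                           "avuncular_plus_cousin",
                                           "second_cousin"),
                              n_affected = 2L, seed = NULL,
                              family_id = "FAM1", p_male_affected = 0.9,
                              x_compatible = FALSE) {
  template <- match.arg(template)
  cap <- template_capacity(template)
  if (n_affected < 2 || n_affected > cap)
    stop("template '", template, "' supports 2..", cap, " affected members")
  with_seed(seed, {
    mk <- function(id, fa, mo, sex, aff, gtd, seqd)
      data.frame(person_id = id, father_id = fa, mother_id = mo, sex = sex,
                 affection = aff, genotyped = gtd, sequenced = seqd,
                 stringsAsFactors = FALSE)
    aff_sex <- function(n) ifelse(stats::runif(n) < p_male_affected,
                                  "male", "female")

    if (template == "cousin_pair") {
      sx <- if (x_compatible) c("male", "male") else aff_sex(2)
      link_sex <- if (x_compatible) c("female", "female") else
        c("male", "female")
      sp_sex <- ifelse(link_sex == "male", "female", "male")
      pid <- function(link, sp, l, s) if (link == "male") c(l, s) else c(s, l)
      par1 <- pid(link_sex[1], sp_sex[1], "03", "05")
      par2 <- pid(link_sex[2], sp_sex[2], "04", "06")
      members <- rbind(
        mk("01", NA, NA, "male", "unaffected", TRUE, FALSE),
        mk("02", NA, NA, "female", "unaffected", TRUE, FALSE),
        mk("03", "01", "02", link_sex[1], "unaffected", TRUE, FALSE),
        mk("04", "01", "02", link_sex[2], "unaffected", TRUE, FALSE),
        mk("05", NA, NA, sp_sex[1], "unaffected", TRUE, FALSE),
        mk("06", NA, NA, sp_sex[2], "unaffected", TRUE, FALSE),
        mk("07", par1[1], par1[2], sx[1], "affected", TRUE, TRUE),
        mk("08", par2[1], par2[2], sx[2], "affected", TRUE, TRUE))
    } else if (template == "avuncular_plus_cousin") {
      sx <- if (x_compatible) rep("male", 5) else aff_sex(5)
      link_sex <- if (x_compatible) c("female", "female") else
        c("male", "female")
      sp_sex <- ifelse(link_sex == "male", "female", "male")
      pid <- function(link, sp, l, s) if (link == "male") c(l, s) else c(s, l)
      par1 <- pid(link_sex[1], sp_sex[1], "03", "05")
      par2 <- pid(link_sex[2], sp_sex[2], "04", "06")
      members <- rbind(
        mk("01", NA, NA, "male", "unaffected", TRUE, FALSE),
        mk("02", NA, NA, "female", "unaffected", TRUE, FALSE),
        mk("03", "01", "02", link_sex[1], "unaffected", TRUE, FALSE),
        mk("04", "01", "02", link_sex[2], "unaffected", TRUE, FALSE),
        mk("05", NA, NA, sp_sex[1], "unaffected", TRUE, FALSE),
        mk("06", NA, NA, sp_sex[2], "unaffected", TRUE, FALSE),
        mk("07", par1[1], par1[2], sx[1], "affected", TRUE, TRUE),
        mk("08", par2[1], par2[2], sx[2], "affected", TRUE, TRUE))
      if (n_affected >= 3)
        members <- rbind(members,
                         mk("09", "01", "02", sx[3], "affected", TRUE, TRUE))
      if (n_affected >= 4)
        members <- rbind(members,
                         mk("10", par1[1], par1[2], sx[4], "affected", TRUE, TRUE))
      if (n_affected >= 5)
        members <- rbind(members,
                         mk("11", par2[1], par2[2], sx[5], "affected", TRUE, TRUE))
    } else {
      sx <- if (x_compatible) rep("male", 3) else aff_sex(3)
      link_sex <- if (x_compatible) c("female", "female", "female", "female") else
        c("male", "female", "male", "female")
      sp_sex <- ifelse(link_sex == "male", "female", "male")
      pid <- function(link, l, s) if (link == "male") c(l, s) else c(s, l)
      g1 <- pid(link_sex[1], "03", "05"); g2 <- pid(link_sex[2], "04", "06")
      g3 <- pid(link_sex[3], "07", "09"); g4 <- pid(link_sex[4], "08", "10")
      members <- rbind(
        mk("01", NA, NA, "male", "unaffected", TRUE, FALSE),
        mk("02", NA, NA, "female", "unaffected", TRUE, FALSE),
        mk("03", "01", "02", link_sex[1], "unaffected", TRUE, FALSE),
        mk("04", "01", "02", link_sex[2], "unaffected", TRUE, FALSE),
        mk("05", NA, NA, sp_sex[1], "unaffected", TRUE, FALSE),
        mk("06", NA, NA, sp_sex[2], "unaffected", TRUE, FALSE),
        mk("07", g1[1], g1[2], link_sex[3], "unaffected", TRUE, FALSE),
        mk("08", g2[1], g2[2], link_sex[4], "unaffected", TRUE, FALSE),
        mk("09", NA, NA, sp_sex[3], "unaffected", TRUE, FALSE),
        mk("10", NA, NA, sp_sex[4], "unaffected", TRUE, FALSE),
        mk("11", g3[1], g3[2], sx[1], "affected", TRUE, TRUE),
        mk("12", g4[1], g4[2], sx[2], "affected", TRUE, TRUE))
      if (n_affected >= 3)
        members <- rbind(members,
                         mk("13", g3[1], g3[2], sx[3], "affected", TRUE, TRUE))
    }
    ped <- pedigree(family_id, members)
    stopifnot(is_valid_pedigree(ped))
    ped
  })
}

#' Simulate a genetic marker map
#'
#' Evenly spaced pre-pruned array markers with panel allele frequencies drawn
#' uniformly from `af_range` (informative markers by default).
#'
#' @param n_autosomes Number of autosomes.
#' @param markers_per_autosome Markers per autosome.
#' @param x_markers Markers on the X chromosome (0 to omit it).
#' @param spacing_cM Inter-marker genetic distance in centimorgans.
#' @param af_range Range of alternate-allele panel frequencies.
#' @param seed Integer seed.
#' @return A [marker_map()].
#' @export
simulate_marker_map <- function(n_autosomes = 4L, markers_per_autosome = 450L,
                                x_markers = 200L, spacing_cM = 1,
                                af_range = c(0.2, 0.8), seed = NULL) {
  with_seed(seed, {
    chroms <- c(as.character(seq_len(n_autosomes)),
                if (x_markers > 0) "X")
    counts <- c(rep(markers_per_autosome, n_autosomes),
                if (x_markers > 0) x_markers)
    bases <- c("A", "C", "G", "T")
    rows <- lapply(seq_along(chroms), function(i) {
      k <- counts[i]
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
      data.frame(marker_id = sprintf("chr%s_m%04d", chroms[i], seq_len(k)),
                 chrom = chroms[i],
                 position_bp = as.integer(seq_len(k)) * 100000L,
                 position_cM = (seq_len(k) - 1) * spacing_cM,
                 ref_allele = ref, alt_allele = unname(alt),
                 panel_af = stats::runif(k, af_range[1], af_range[2]),
                 stringsAsFactors = FALSE)
    })
    marker_map(do.call(rbind, rows))
  })
}

# One meiosis along one chromosome: inheritance bits per marker under the
# Haldane model (first bit uniform, then independent crossovers).
meiosis_bits <- function(theta) {
  k <- length(theta) + 1L
  b <- integer(k)
  b[1] <- stats::rbinom(1, 1, 0.5)
  if (k > 1) {
    flips <- stats::rbinom(k - 1L, 1, theta)
    b <- cumsum(c(b[1], flips)) %% 2L
  }
  b
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn allele-wise from the map's panel
#' frequencies; each meiosis transmits a recombinant haplotype with
#' inter-marker recombination fraction given by the Haldane map function
#' (no interference). On the X chromosome fathers transmit their single X
#' to daughters intact and nothing to sons; male calls are coded 0/2.
#'
#' @param ped A valid [pedigree()].
#' @param map A [marker_map()] (sorted within chromosome).
#' @param seed Integer seed.
#' @return A phased [genotype_table()] over all pedigree members, with
#'   `phase` (allele matrices) and `descent` (founder allele slot labels;
#'   slots are numbered per chromosome type as in the IBD model).
#' @export
gene_drop <- function(ped, map, seed = NULL) {
  if (!is_valid_pedigree(ped)) stop("pedigree is not structurally valid")
  with_seed(seed, {
    m <- ped$members
    ord <- topo_order(ped)
    sex <- stats::setNames(m$sex, m$person_id)
    n_all <- length(ord)
    M <- nrow(map)
    pat_a <- mat_a <- matrix(NA_integer_, M, n_all, dimnames = list(map$marker_id, ord))
    pat_d <- mat_d <- matrix(NA_integer_, M, n_all, dimnames = list(map$marker_id, ord))

    for (ch in unique(map$chrom)) {
      sel <- which(map$chrom == ch)
      xchr <- is_x_chrom(ch)
      theta <- haldane_theta(diff(map$position_cM[sel]) / 100)
      af <- map$panel_af[sel]
      k <- length(sel)

      # founder slots (numbering matches build_descent)
      n_slots <- 0L
      slot1 <- slot2 <- stats::setNames(integer(n_all), ord)
      for (id in founder_ids(ped)) {
        if (xchr && sex[id] == "male") {
          n_slots <- n_slots + 1L
          slot1[id] <- slot2[id] <- n_slots
        } else {
          slot1[id] <- n_slots + 1L; slot2[id] <- n_slots + 2L
          n_slots <- n_slots + 2L
        }
      }
      hap <- matrix(stats::rbinom(k * n_slots, 1, af), k, n_slots)

      for (id in ord) {
        r <- m[m$person_id == id, ]
        if (is.na(r$father_id)) {
          if (xchr && sex[id] == "male") {
            mat_a[sel, id] <- hap[, slot1[id]]
            mat_d[sel, id] <- slot1[id]
          } else {
            pat_a[sel, id] <- hap[, slot1[id]]; pat_d[sel, id] <- slot1[id]
            mat_a[sel, id] <- hap[, slot2[id]]; mat_d[sel, id] <- slot2[id]
          }
          next
        }
        # maternal transmission (always a meiosis)
        bm <- meiosis_bits(theta)
        mo <- r$mother_id
        mo_a <- cbind(pat_a[sel, mo], mat_a[sel, mo])
        mo_d <- cbind(pat_d[sel, mo], mat_d[sel, mo])
        if (xchr && is.na(mo_a[1, 1])) {  # mother untracked? cannot happen
          stop("internal: mother lacks X alleles")
        }
        pick <- cbind(seq_len(k), bm + 1L)
        from_mo_a <- mo_a[pick]; from_mo_d <- mo_d[pick]
        if (xchr) {
          if (sex[id] == "male") {
            mat_a[sel, id] <- from_mo_a; mat_d[sel, id] <- from_mo_d
          } else {
            pat_a[sel, id] <- mat_a[sel, r$father_id]   # father's single X
            pat_d[sel, id] <- mat_d[sel, r$father_id]
            mat_a[sel, id] <- from_mo_a; mat_d[sel, id] <- from_mo_d
          }
        } else {
          bp <- meiosis_bits(theta)
          fa_a <- cbind(pat_a[sel, r$father_id], mat_a[sel, r$father_id])
          fa_d <- cbind(pat_d[sel, r$father_id], mat_d[sel, r$father_id])
          pickp <- cbind(seq_len(k), bp + 1L)
          pat_a[sel, id] <- fa_a[pickp]; pat_d[sel, id] <- fa_d[pickp]
          mat_a[sel, id] <- from_mo_a; mat_d[sel, id] <- from_mo_d
        }
      }
    }
    calls <- pat_a + mat_a
    xsel <- is_x_chrom(map$chrom)
    if (any(xsel)) {
      males <- ord[sex[ord] == "male"]
      calls[xsel, males] <- 2L * mat_a[xsel, males, drop = FALSE]
    }
    genotype_table(map$marker_id, ord, calls,
                   phase = list(pat = pat_a, mat = mat_a),
                   descent = list(pat = pat_d, mat = mat_d))
  })
}

#' Causal-variant specification
#'
#' @param gene Gene symbol assigned to the injected variant.
#' @param model Inheritance model: `"het"`, `"hom"`, or `"xlinked"`.
#' @param chrom Chromosome (defaults to the first autosome, or X for the
#'   X-linked model).
#' @param pos_bp Physical position (defaults to mid-chromosome).
#' @param effect Damaging effect class for the injected record.
#' @return A list of class `causal_spec`.
#' @export
causal_spec <- function(gene = "CAUSAL1", model = c("het", "hom", "xlinked"),
                        chrom = NULL, pos_bp = NULL, effect = "missense") {
  model <- match.arg(model)
  structure(list(gene = gene, model = model, chrom = chrom, pos_bp = pos_bp,
                 effect = effect), class = "causal_spec")
}

#' Inject a causal variant with a coherent descent history
#'
#' Assigns the variant to founder haplotype(s) and re-draws the causal
#' chromosome's gene drop until the configured inheritance pattern holds in
#' every affected member (rejection sampling), so the marker data and the
#' causal variant share one descent history. Under the heterozygous model a
#' single founder haplotype of a common ancestor carries the variant and all
#' affected end up heterozygous; under the homozygous model one haplotype of
#' every founder carries it and all affected end up homozygous; under the
#' X-linked model a founder X in the maternal connecting line carries it,
#' affected males are hemizygous and affected females heterozygous.
#'
#' @param gt A phased [genotype_table()] from [gene_drop()] (other
#'   chromosomes are kept as-is).
#' @param ped The [pedigree()] used for the drop.
#' @param map The [marker_map()] used for the drop.
#' @param spec A [causal_spec()].
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap.
#' @return List with `gt` (updated phased table), `variant` (one-row data
#'   frame of annotation fields), `genotypes` (named vector over all
#'   members), and `carrier_slots`.
#' @export
inject_causal_variant <- function(gt, ped, map, spec, seed = NULL,
                                  max_tries = 10000L) {
  stopifnot(inherits(spec, "causal_spec"))
  m <- ped$members
  aff <- affected_ids(ped)
  if (length(aff) < 1) stop("pedigree has no affected members")
  chrom <- spec$chrom
  if (is.null(chrom))
    chrom <- if (spec$model == "xlinked") "X" else
      unique(map$chrom[!is_x_chrom(map$chrom)])[1]
  if (spec$model == "xlinked") {
    if (!is_x_chrom(chrom)) stop("X-linked causal variants must be on X")
    if (length(aff) >= 2 && !xlinked_compatible(ped))
      stop("pedigree is not compatible with X-linked inheritance")
  }
  sel <- map$chrom == chrom
  if (!any(sel)) stop("chromosome ", chrom, " not in map")
  sub <- map[sel, , drop = FALSE]
  pos <- spec$pos_bp
  if (is.null(pos)) {
    mid <- ceiling(nrow(sub) / 2)
    pos <- if (mid < nrow(sub))
      (sub$position_bp[mid] + sub$position_bp[mid + 1]) %/% 2 else
        sub$position_bp[mid] + 1L
  }
  if (pos %in% sub$position_bp) pos <- pos + 1L
  # interpolate genetic position
  cm <- stats::approx(sub$position_bp, sub$position_cM, xout = pos,
                      rule = 2)$y
  causal_id <- ".__causal__"
  aug_row <- data.frame(marker_id = causal_id, chrom = chrom,
                        position_bp = as.integer(pos), position_cM = cm,
                        ref_allele = "C", alt_allele = "T", panel_af = 0,
                        stringsAsFactors = FALSE)
  aug <- rbind(sub, aug_row)
  aug <- aug[order(aug$position_bp), , drop = FALSE]
  if (any(duplicated(aug$position_bp)))
    stop("causal position collides with a map marker")
  aug <- marker_map(aug)

  xchr <- is_x_chrom(chrom)
  carrier_slots <- causal_carrier_slots(ped, aff, spec$model, xchr)

  ok <- FALSE
  for (try in seq_len(max_tries)) {
    drop <- gene_drop(ped, aug, seed = child_seed(seed, try))
    i <- match(causal_id, drop$marker_ids)
    dp <- drop$descent$pat[i, ]; dm <- drop$descent$mat[i, ]
    carry_p <- !is.na(dp) & dp %in% carrier_slots
    carry_m <- !is.na(dm) & dm %in% carrier_slots
    n_copies <- carry_p + carry_m
    sexv <- stats::setNames(m$sex, m$person_id)
    cond <- switch(spec$model,
      het = all(n_copies[aff] == 1L),
      hom = all(n_copies[aff] == 2L),
      xlinked = all(ifelse(sexv[aff] == "male",
                           carry_m[aff], n_copies[aff] == 1L)))
    if (cond) { ok <- TRUE; break }
  }
  if (!ok)
    stop("could not realize the ", spec$model,
         " causal pattern in ", max_tries, " tries (model impossible?)")

  genos <- carry_p + carry_m
  if (xchr) {
    males <- names(genos)[sexv[names(genos)] == "male"]
    genos[males] <- 2L * carry_m[males]
  }

  # splice re-dropped chromosome back into gt (causal row excluded)
  keep <- drop$marker_ids != causal_id
  rows_gt <- match(drop$marker_ids[keep], gt$marker_ids)
  for (fld in c("pat", "mat")) {
    gt$phase[[fld]][rows_gt, drop$sample_ids] <-
      drop$phase[[fld]][keep, , drop = FALSE]
    gt$descent[[fld]][rows_gt, drop$sample_ids] <-
      drop$descent[[fld]][keep, , drop = FALSE]
  }
  gt$calls[rows_gt, drop$sample_ids] <- drop$calls[keep, , drop = FALSE]

  variant <- data.frame(
    chrom = chrom, pos = as.integer(pos), dbsnp_id = NA_character_,
    ref_allele = "C", alt_allele = "T", gene = spec$gene,
    effect = spec$effect, dbsnp_known = FALSE, kg_present = FALSE,
    af_panel1 = 0, af_panel2 = 0, af_panel3 = 0, evs_af = NA_real_,
    control_ac = 0L, control_an = 2L * 308L, vqslod = 12.0,
    stringsAsFactors = FALSE)
  list(gt = gt, variant = variant, genotypes = genos,
       carrier_slots = carrier_slots)
}

# Founder allele slots designated to carry the causal variant.
causal_carrier_slots <- function(ped, aff, model, xchr) {
  m <- ped$members
  ord <- topo_order(ped)
  sex <- stats::setNames(m$sex, m$person_id)
  # slot numbering must match gene_drop / build_descent
  n_slots <- 0L
  slot1 <- slot2 <- stats::setNames(integer(length(ord)), ord)
  for (id in founder_ids(ped)) {
    if (xchr && sex[id] == "male") {
      n_slots <- n_slots + 1L; slot1[id] <- slot2[id] <- n_slots
    } else {
      slot1[id] <- n_slots + 1L; slot2[id] <- n_slots + 2L
      n_slots <- n_slots + 2L
    }
  }
  if (model == "hom") {
    # one carrier haplotype per founder lineage
    return(unname(slot1[founder_ids(ped)]))
  }
  anc <- Reduce(intersect, lapply(aff, function(id)
    ancestor_ids(ped, id, include_self = TRUE)))
  anc <- intersect(anc, founder_ids(ped))
  if (!length(anc))
    stop("affected members share no founder ancestor; cannot inject variant")
  if (model == "xlinked") {
    fem <- anc[sex[anc] == "female"]
    if (!length(fem)) stop("no female founder ancestor for X-linked variant")
    return(slot1[fem[1]])
  }
  slot1[sort(anc)[1]]
}

#' Add array-genotyping noise
#'
#' Each call is independently set missing with `missing_rate`, otherwise
#' perturbed by a single-allele flip with `error_rate`. Returns an unphased
#' table.
#'
#' @param gt A phased or unphased [genotype_table()].
#' @param error_rate,missing_rate Probabilities.
#' @param map Optional [marker_map()]; needed to apply the hemizygous (0/2)
#'   error convention on the X for male samples.
#' @param ped Optional [pedigree()] giving member sexes for X handling.
#' @param seed Integer seed.
#' @return An unphased [genotype_table()].
#' @export
simulate_array_genotypes <- function(gt, error_rate = 0, missing_rate = 0,
                                     map = NULL, ped = NULL, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    calls <- gt$calls
    n <- length(calls)
    xrow <- if (!is.null(map)) {
      is_x_chrom(map$chrom[match(gt$marker_ids, map$marker_id)])
    } else rep(FALSE, nrow(calls))
    male <- if (!is.null(ped)) {
      sex <- stats::setNames(ped$members$sex, ped$members$person_id)
      sex[gt$sample_ids] == "male"
    } else rep(FALSE, ncol(calls))
    hemi <- outer(xrow, male, `&`)

    err <- matrix(stats::runif(n) < error_rate, nrow(calls))
    flip_up <- matrix(stats::runif(n) < 0.5, nrow(calls))
    old <- calls
    do_err <- err & !is.na(old)
    # single-allele flip: 0 -> 1, 2 -> 1, 1 -> 0 or 2
    calls[do_err & old == 0L] <- 1L
    calls[do_err & old == 2L] <- 1L
    calls[do_err & old == 1L & flip_up] <- 2L
    calls[do_err & old == 1L & !flip_up] <- 0L
    # hemizygous convention: flips move between 0 and 2
    calls[do_err & hemi & old == 0L] <- 2L
    calls[do_err & hemi & old == 2L] <- 0L
    miss <- matrix(stats::runif(n) < missing_rate, nrow(calls))
    calls[miss] <- NA_integer_
    genotype_table(gt$marker_ids, gt$sample_ids, calls)
  })
}

#' Simulate control-cohort allele counts
#'
#' @param af Alternate-allele frequency.
#' @param n_samples Control samples successfully genotyped at the site.
#' @param seed Integer seed.
#' @return Integer vector `c(alt_count, total_chromosomes)` with
#'   `total = 2 * n_samples`.
#' @export
simulate_control_counts <- function(af, n_samples, seed = NULL) {
  stopifnot(af >= 0, af <= 1, n_samples >= 0)
  with_seed(seed, {
    an <- 2L * as.integer(n_samples)
    c(alt_count = stats::rbinom(1, an, af), total_chromosomes = an)
  })
}

#' Simulate an annotated exome variant table
#'
#' Background variants carry realistic annotation fields (effect class mix,
#' panel-frequency mixture of common and rare sites, catalog membership
#' flags, binomial control counts over a cohort with per-variant genotyping
#' missingness, per-sample depths, and a configurable fraction of records
#' failing the VQSLOD gate). Genotypes are produced by independent
#' single-locus gene drops, so they are Mendelian-consistent. An injected
#' causal fragment is appended and recorded in the truth manifest.
#'
#' @param ped A valid [pedigree()].
#' @param map A [marker_map()] (defines the chromosome spans).
#' @param n_variants Number of background variants.
#' @param causal Optional result of [inject_causal_variant()].
#' @param seed Integer seed.
#' @param control_n Control cohort size (samples).
#' @param vqslod_fail_rate Fraction of records drawn with VQSLOD <= 0.
#' @param low_depth_rate Fraction of genotype cells with shallow coverage.
#' @return List with `variants` (a [variant_set()] over sequenced members)
#'   and `truth` (data frame of injected causal records; zero rows if none).
#' @export
simulate_exome_table <- function(ped, map, n_variants = 5000L, causal = NULL,
                                 seed = NULL, control_n = 308L,
                                 vqslod_fail_rate = 0.08,
                                 low_depth_rate = 0.02) {
  with_seed(seed, {
    m <- ped$members
    ord <- topo_order(ped)
    seq_ids <- m$person_id[m$sequenced]
    chroms <- unique(map$chrom)
    spans <- lapply(chroms, function(ch) range(map$position_bp[map$chrom == ch]))
    names(spans) <- chroms

    ch <- sample(chroms, n_variants, replace = TRUE,
                 prob = vapply(chroms, function(c0)
                   sum(map$chrom == c0), numeric(1)))
    pos <- vapply(ch, function(c0)
      as.integer(round(stats::runif(1, spans[[c0]][1], spans[[c0]][2]))),
      integer(1))
    o <- order(chrom_order(ch), pos)
    ch <- ch[o]; pos <- pos[o]
    gene <- sprintf("G%s_%04d", ch, pos %/% 200000L)

    effect <- sample(c("missense", "nonsense", "splice_site", "synonymous",
                       "intronic"), n_variants, replace = TRUE,
                     prob = c(0.40, 0.02, 0.03, 0.25, 0.30))
    cls <- sample(c("novel", "rare", "common"), n_variants, replace = TRUE,
                  prob = c(0.10, 0.45, 0.45))
    af <- numeric(n_variants)
    af[cls == "rare"] <- stats::runif(sum(cls == "rare"), 5e-4, 0.04)
    af[cls == "common"] <- stats::runif(sum(cls == "common"), 0.05, 0.5)
    jit <- function(a) pmin(1, pmax(0, a * exp(stats::rnorm(length(a), 0, 0.15))))
    af1 <- jit(af); af2 <- jit(af); af3 <- jit(af)
    known <- af > 0
    evs_af <- ifelse(known & stats::runif(n_variants) < 0.97, jit(af), NA_real_)
    kg <- known & stats::runif(n_variants) < 0.90
    dbsnp <- known & stats::runif(n_variants) < 0.95
    dbsnp_id <- ifelse(dbsnp, sprintf("rs%07d", sample.int(9999999, n_variants,
                                                           replace = TRUE)),
                       NA_character_)
    n_eff <- control_n - stats::rbinom(n_variants, control_n,
                                       stats::runif(n_variants, 0, 0.02))
    an <- 2L * n_eff
    ac <- stats::rbinom(n_variants, an, af)

    fail <- stats::runif(n_variants) < vqslod_fail_rate
    vqslod <- ifelse(fail, -abs(stats::rnorm(n_variants, 2, 1.5)),
                     abs(stats::rnorm(n_variants, 6, 2.5)) + 1e-3)

    # per-variant single-locus gene drops (vectorized over variants)
    sexv <- stats::setNames(m$sex, m$person_id)
    xv <- is_x_chrom(ch)
    pat <- mat <- matrix(NA_integer_, n_variants, length(ord),
                         dimnames = list(NULL, ord))
    for (id in ord) {
      r <- m[m$person_id == id, ]
      if (is.na(r$father_id)) {
        a1 <- stats::rbinom(n_variants, 1, af)
        a2 <- stats::rbinom(n_variants, 1, af)
        if (sexv[id] == "male") {
          pat[, id] <- ifelse(xv, NA_integer_, a1)
          mat[, id] <- a2
        } else {
          pat[, id] <- a1; mat[, id] <- a2
        }
        next
      }
      bm <- stats::rbinom(n_variants, 1, 0.5)
      from_mo <- ifelse(bm == 1L, mat[, r$mother_id], pat[, r$mother_id])
      if (sexv[id] == "male") {
        bp <- stats::rbinom(n_variants, 1, 0.5)
        from_fa <- ifelse(bp == 1L, mat[, r$father_id], pat[, r$father_id])
        pat[, id] <- ifelse(xv, NA_integer_, from_fa)
        mat[, id] <- from_mo
      } else {
        bp <- stats::rbinom(n_variants, 1, 0.5)
        from_fa <- ifelse(bp == 1L, mat[, r$father_id], pat[, r$father_id])
        pat[, id] <- ifelse(xv, mat[, r$father_id], from_fa)
        mat[, id] <- from_mo
      }
    }
    gt_all <- pat + mat
    for (id in ord[sexv[ord] == "male"])
      gt_all[xv, id] <- 2L * mat[xv, id]

    gt <- gt_all[, seq_ids, drop = FALSE]
    dp <- matrix(stats::rpois(n_variants * length(seq_ids), 55),
                 n_variants, length(seq_ids), dimnames = list(NULL, seq_ids))
    shallow <- matrix(stats::runif(length(dp)) < low_depth_rate, n_variants)
    dp[shallow] <- stats::rpois(sum(shallow), 2)

    variants <- data.frame(
      chrom = ch, pos = pos, dbsnp_id = dbsnp_id,
      ref_allele = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      alt_allele = NA_character_, gene = gene, effect = effect,
      dbsnp_known = dbsnp, kg_present = kg,
      af_panel1 = af1, af_panel2 = af2, af_panel3 = af3, evs_af = evs_af,
      control_ac = ac, control_an = an, vqslod = vqslod,
      stringsAsFactors = FALSE)
    variants$alt_allele <- vapply(variants$ref_allele, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))

    truth <- data.frame(chrom = character(0), pos = integer(0),
                        gene = character(0), model = character(0),
                        stringsAsFactors = FALSE)
    if (!is.null(causal)) {
      cv <- causal$variant
      cg <- causal$genotypes[seq_ids]
      cdp <- pmax(stats::rpois(length(seq_ids), 60), 10L)
      variants <- rbind(variants, cv[, names(variants)])
      gt <- rbind(gt, matrix(as.integer(cg), 1,
                             dimnames = list(NULL, seq_ids)))
      dp <- rbind(dp, matrix(as.integer(cdp), 1,
                             dimnames = list(NULL, seq_ids)))
      truth <- data.frame(chrom = cv$chrom, pos = cv$pos, gene = cv$gene,
                          model = attr(causal, "model") %||% "het",
                          stringsAsFactors = FALSE)
    }
    o2 <- order(chrom_order(variants$chrom), variants$pos)
    variants <- variants[o2, , drop = FALSE]
    gt <- gt[o2, , drop = FALSE]
    dp <- dp[o2, , drop = FALSE]
    list(variants = variant_set(variants, gt, dp), truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate reference-panel genotypes
#'
#' Unrelated samples in Hardy-Weinberg proportions at the map's panel allele
#' frequencies, playing the role of the reference cohort against which LD
#' pruning is performed.
#'
#' @param map A [marker_map()].
#' @param n_samples Panel size.
#' @param seed Integer seed.
#' @return An unphased [genotype_table()].
#' @export
simulate_panel_genotypes <- function(map, n_samples = 120L, seed = NULL) {
  with_seed(seed, {
    calls <- matrix(stats::rbinom(nrow(map) * n_samples, 2, map$panel_af),
                    nrow(map), n_samples)
    genotype_table(map$marker_id, sprintf("REF%04d", seq_len(n_samples)),
                   calls)
  })
}

#' Simulation configuration
#'
#' Defaults are desk scale: 6 families, 4 autosomes x 450 markers plus 200 X
#' markers at 1 cM spacing, 5,000 exome variants per family, and a
#' 308-sample control cohort. The study-scale design (40 families, ~90,000
#' variant positions) is reachable by configuration.
#'
#' @param n_families Number of families.
#' @param templates Pedigree templates to draw from.
#' @param n_affected_range Inclusive range of affected members per family.
#' @param n_autosomes,markers_per_autosome,x_markers,spacing_cM,af_range
#'   Marker-map parameters (see [simulate_marker_map()]).
#' @param genotype_error_rate,missing_rate Array noise rates.
#' @param n_exome_variants Background exome variants per family.
#' @param control_cohort_size Control samples.
#' @param causal Default [causal_spec()] injected per family (`NULL` for
#'   none).
#' @param seed Root seed; all per-family seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 6L,
                       templates = c("cousin_pair", "avuncular_plus_cousin",
                                     "second_cousin"),
                       n_affected_range = c(2L, 5L),
                       n_autosomes = 4L, markers_per_autosome = 450L,
                       x_markers = 200L, spacing_cM = 1,
                       af_range = c(0.2, 0.8),
                       genotype_error_rate = 0.005, missing_rate = 0.01,
                       n_exome_variants = 5000L, control_cohort_size = 308L,
                       causal = causal_spec(), seed = 1L) {
  stopifnot(genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_families = n_families, templates = templates,
                 n_affected_range = n_affected_range,
                 n_autosomes = n_autosomes,
                 markers_per_autosome = markers_per_autosome,
                 x_markers = x_markers, spacing_cM = spacing_cM,
                 af_range = af_range,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 n_exome_variants = n_exome_variants,
                 control_cohort_size = control_cohort_size,
                 causal = causal, seed = seed),
            class = "sim_config")
}

#' Simulate a full multi-family study
#'
#' Generates a shared marker map and, per family, a pedigree, gene-dropped
#' phased genotypes with an injected causal variant, noisy unphased array
#' genotypes, and an annotated exome variant table with truth bookkeeping.
#'
#' @param config A [sim_config()].
#' @return List with `map`, `panel_gt` (reference-panel genotypes used for
#'   LD pruning), `families` (named list with elements `ped`, `array_gt`,
#'   `exome`, `truth`, `phased_gt`), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  map <- simulate_marker_map(config$n_autosomes, config$markers_per_autosome,
                             config$x_markers, config$spacing_cM,
                             config$af_range, seed = child_seed(config$seed, 1))
  panel_gt <- simulate_panel_genotypes(map, seed = child_seed(config$seed, 2))
  fams <- list()
  for (i in seq_len(config$n_families)) {
    fseed <- child_seed(config$seed, 100 + i)
    fam_id <- sprintf("FAM%02d", i)
    tpl <- with_seed(child_seed(fseed, 1),
                     sample(config$templates, 1))
    cap <- template_capacity(tpl)
    rng <- pmin(config$n_affected_range, cap)
    n_aff <- with_seed(child_seed(fseed, 2), {
      choices <- seq(rng[1], rng[2])
      choices[sample.int(length(choices), 1)]
    })
    x_needed <- !is.null(config$causal) && config$causal$model == "xlinked"
    ped <- generate_pedigree(tpl, n_aff, seed = child_seed(fseed, 3),
                             family_id = fam_id, x_compatible = x_needed)
    phased <- gene_drop(ped, map, seed = child_seed(fseed, 4))
    causal <- NULL
    if (!is.null(config$causal)) {
      spec <- config$causal
      spec$gene <- paste0(spec$gene, "_", fam_id)
      causal <- inject_causal_variant(phased, ped, map, spec,
                                      seed = child_seed(fseed, 5))
      attr(causal, "model") <- spec$model
      phased <- causal$gt
    }
    genotyped <- ped$members$person_id[ped$members$genotyped]
    array_gt <- simulate_array_genotypes(
      subset_genotypes(phased, samples = genotyped),
      error_rate = config$genotype_error_rate,
      missing_rate = config$missing_rate,
      map = map, ped = ped, seed = child_seed(fseed, 6))
    exo <- simulate_exome_table(ped, map, config$n_exome_variants,
                                causal = causal,
                                seed = child_seed(fseed, 7),
                                control_n = config$control_cohort_size)
    fams[[fam_id]] <- list(ped = ped, array_gt = array_gt,
                           exome = exo$variants, truth = exo$truth,
                           phased_gt = phased)
  }
  list(map = map, panel_gt = panel_gt, families = fams, config = config)
}
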