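# Readers and writers for the plain-text interchange formats used by the
# pipeline: PLINK-style PED/MAP for pedigree + array genotypes, a VCF v4.2
# subset for annotated exome variants, and BED/TSV exports for IBD segments.

sex_to_ped <- function(sex) ifelse(sex == "male", 1L, 2L)
aff_to_ped <- function(aff) c(affected = 2L, unaffected = 1L, unknown = 0L)[aff]

#' Write a PLINK-style PED file
#'
#' Six pedigree columns (family, person, father, mother, sex, phenotype;
#' 0 = missing) optionally followed by two allele columns per marker, using
#' the map's ref/alt bases and `0 0` for missing calls.
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @param gt Optional [genotype_table()]; samples restricted to pedigree
#'   members present in the table.
#' @param map [marker_map()] (required with `gt`) giving marker order and
#'   allele codes.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, gt = NULL, map = NULL) {
  m <- ped$members
  base <- data.frame(
    family = ped$family_id, person = m$person_id,
    father = ifelse(is.na(m$father_id), "0", m$father_id),
    mother = ifelse(is.na(m$mother_id), "0", m$mother_id),
    sex = sex_to_ped(m$sex), phenotype = aff_to_ped(m$affection),
    stringsAsFactors = FALSE)
  if (!is.null(gt)) {
    if (is.null(map)) stop("map is required to write genotype columns")
    idx <- match(map$marker_id, gt$marker_ids)
    if (anyNA(idx)) stop("map markers missing from genotype table")
    cols <- lapply(seq_len(nrow(m)), function(i) {
      id <- m$person_id[i]
      if (!id %in% gt$sample_ids) return(rep("0 0", nrow(map)))
      g <- gt$calls[idx, id]
      a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, map$alt_allele, map$ref_allele))
      a2 <- ifelse(is.na(g), "0", ifelse(g == 2, map$alt_allele, map$ref_allele))
      paste(a1, a2)
    })
    base$genotypes <- vapply(cols, paste, character(1), collapse = " ")
  }
  lines <- do.call(paste, c(unname(base), list(sep = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PLINK-style PED file
#'
#' @param path PED file path.
#' @param map Optional [marker_map()]; when supplied and genotype columns are
#'   present, genotypes are decoded against its ref/alt alleles.
#' @param family_id Family to extract when the file holds several; default is
#'   the first.
#' @return A list with elements `pedigree` and (when genotype columns exist
#'   and `map` is given) `genotypes`.
#' @export
read_ped <- function(path, map = NULL, family_id = NULL) {
  toks <- strsplit(readLines(path), "[ \t]+")
  fam <- vapply(toks, `[`, character(1), 1)
  if (is.null(family_id)) family_id <- fam[1]
  toks <- toks[fam == family_id]
  if (!length(toks)) stop("family '", family_id, "' not found in ", path)
  six <- t(vapply(toks, `[`, character(6), 1:6))
  members <- data.frame(
    person_id = six[, 2],
    father_id = ifelse(six[, 3] == "0", NA_character_, six[, 3]),
    mother_id = ifelse(six[, 4] == "0", NA_character_, six[, 4]),
    sex = ifelse(six[, 5] == "1", "male", "female"),
    affection = c("unknown", "unaffected", "affected")[as.integer(six[, 6]) + 1L],
    stringsAsFactors = FALSE)
  ped <- pedigree(family_id, members)
  out <- list(pedigree = ped)
  ncols <- length(toks[[1]])
  if (ncols > 6 && !is.null(map)) {
    n_mark <- (ncols - 6L) / 2L
    if (n_mark != nrow(map)) stop("genotype columns do not match map length")
    calls <- matrix(NA_integer_, n_mark, length(toks))
    for (j in seq_along(toks)) {
      al <- toks[[j]][-(1:6)]
      a1 <- al[seq(1, length(al), 2)]
      a2 <- al[seq(2, length(al), 2)]
      g <- ifelse(a1 == "0" | a2 == "0", NA_integer_,
                  (a1 == map$alt_allele) + (a2 == map$alt_allele))
      calls[, j] <- as.integer(g)
    }
    out$genotypes <- genotype_table(map$marker_id, members$person_id, calls)
  }
  out
}

#' Write / read a PLINK-style MAP file
#'
#' Four columns: chromosome, marker id, genetic position (cM), physical
#' position (bp). Allele codes and panel frequencies travel in a sidecar
#' marker-info TSV written by [write_marker_info()].
#'
#' @param map A [marker_map()].
#' @param path Output path.
#' @return `path` (writers) or a data frame (readers), invisibly for writers.
#' @export
write_map <- function(map, path) {
  utils::write.table(map[, c("chrom", "marker_id", "position_cM", "position_bp")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
write_marker_info <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_marker_info <- function(path) {
  marker_map(utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = list(chrom = "character")))
}

#' Write IBD segments as BED and TSV
#'
#' BED uses the 0-based half-open convention (`start_bp - 1`, `end_bp`);
#' the TSV keeps 1-based inclusive coordinates with marker counts and mean
#' sharing.
#'
#' @param segments Data frame of IBD segments (`family_id`, `chrom`,
#'   `start_bp`, `end_bp`, `n_markers`, `mean_sharing`).
#' @param path Output path (BED) or TSV path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments)) {
    bed <- data.frame(chrom = segments$chrom,
                      start = segments$start_bp - 1L,
                      end = segments$end_bp,
                      name = segments$family_id)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

vcf_info_field <- function(info, key) {
  m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
  out <- rep(NA_character_, length(info))
  hit <- m != -1L
  out[hit] <- sub(paste0("^;?", key, "="), "",
                  substring(info[hit], m[hit], m[hit] + attr(m, "match.length")[hit] - 1L))
  out
}

#' Write an annotated variant set as VCF
#'
#' VCF v4.2 subset with INFO keys GENE, EFF, AF_PANEL1/2/3, EVS_AF, KG,
#' DBSNP, AC_CTRL, AN_CTRL, VQSLOD and per-sample GT:DP.
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param source_label Fixed header source string (kept constant so repeated
#'   runs are byte-identical).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, source_label = "kindredscan") {
  v <- vs$variants
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_label),
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
           "##INFO=<ID=AF_PANEL1,Number=1,Type=Float,Description=\"Panel 1 allele frequency\">",
           "##INFO=<ID=AF_PANEL2,Number=1,Type=Float,Description=\"Panel 2 allele frequency\">",
           "##INFO=<ID=AF_PANEL3,Number=1,Type=Float,Description=\"Panel 3 allele frequency\">",
           "##INFO=<ID=EVS_AF,Number=1,Type=Float,Description=\"External exome cohort allele frequency\">",
           "##INFO=<ID=KG,Number=0,Type=Flag,Description=\"Present in 1000 Genomes\">",
           "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"Known dbSNP site\">",
           "##INFO=<ID=AC_CTRL,Number=1,Type=Integer,Description=\"Control alternate allele count\">",
           "##INFO=<ID=AN_CTRL,Number=1,Type=Integer,Description=\"Control called chromosomes\">",
           "##INFO=<ID=VQSLOD,Number=1,Type=Float,Description=\"Variant quality log-odds\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$sample_ids), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE, digits = 8,
                                                     scientific = FALSE))
  info <- paste0("GENE=", v$gene, ";EFF=", v$effect,
                 ";AF_PANEL1=", fmt_num(v$af_panel1),
                 ";AF_PANEL2=", fmt_num(v$af_panel2),
                 ";AF_PANEL3=", fmt_num(v$af_panel3))
  has_evs <- !is.na(v$evs_af)
  info[has_evs] <- paste0(info[has_evs], ";EVS_AF=", fmt_num(v$evs_af[has_evs]))
  info[v$kg_present] <- paste0(info[v$kg_present], ";KG")
  info <- paste0(info, ";AC_CTRL=", v$control_ac, ";AN_CTRL=", v$control_an,
                 ";VQSLOD=", fmt_num(v$vqslod))
  info[v$dbsnp_known] <- sub(";AC_CTRL", ";DBSNP;AC_CTRL", info[v$dbsnp_known],
                             fixed = TRUE)
  gtf <- matrix("./.:.", nrow(v), length(vs$sample_ids))
  gcode <- c("0/0", "0/1", "1/1")
  for (j in seq_along(vs$sample_ids)) {
    g <- vs$gt[, j]
    d <- vs$dp[, j]
    gtf[, j] <- paste0(ifelse(is.na(g), "./.", gcode[g + 1L]), ":",
                       ifelse(is.na(d), ".", d))
  }
  body <- paste(v$chrom, v$pos, ifelse(is.na(v$dbsnp_id), ".", v$dbsnp_id),
                v$ref_allele, v$alt_allele, ".", "PASS", info, "GT:DP",
                apply(gtf, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read the VCF subset written by [write_vcf()]
#'
#' @param path VCF path (plain text).
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t")[[1]]
  samples <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  if (!length(rows)) {
    v <- empty_variant_frame()
    return(variant_set(v, matrix(NA_integer_, 0, length(samples),
                                 dimnames = list(NULL, samples)),
                       matrix(NA_integer_, 0, length(samples),
                              dimnames = list(NULL, samples))))
  }
  tab <- t(vapply(rows, `[`, character(length(header)), seq_along(header)))
  info <- tab[, 8]
  num <- function(key) suppressWarnings(as.numeric(vcf_info_field(info, key)))
  v <- data.frame(
    chrom = tab[, 1], pos = as.integer(tab[, 2]),
    dbsnp_id = ifelse(tab[, 3] == ".", NA_character_, tab[, 3]),
    ref_allele = tab[, 4], alt_allele = tab[, 5],
    gene = vcf_info_field(info, "GENE"),
    effect = vcf_info_field(info, "EFF"),
    dbsnp_known = grepl("(^|;)DBSNP(;|$)", info),
    kg_present = grepl("(^|;)KG(;|$)", info),
    af_panel1 = num("AF_PANEL1"), af_panel2 = num("AF_PANEL2"),
    af_panel3 = num("AF_PANEL3"), evs_af = num("EVS_AF"),
    control_ac = as.integer(num("AC_CTRL")),
    control_an = as.integer(num("AN_CTRL")),
    vqslod = num("VQSLOD"),
    stringsAsFactors = FALSE)
  gt <- matrix(NA_integer_, nrow(v), length(samples),
               dimnames = list(NULL, samples))
  dp <- gt
  gmapn <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  for (j in seq_along(samples)) {
    cell <- strsplit(tab[, 9 + j], ":", fixed = TRUE)
    gs <- vapply(cell, `[`, character(1), 1)
    ds <- vapply(cell, `[`, character(1), 2)
    gt[, j] <- unname(gmapn[gs])
    dp[, j] <- suppressWarnings(as.integer(ds))
  }
  variant_set(v, gt, dp)
}

#' Read a candidate gene list
#'
#' One symbol per line; symbols are uppercased and whitespace-stripped.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Text file path.
#' @return Character vector of normalized gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalize_symbols(x))
}

normalize_symbols <- function(x) toupper(gsub("\\s+", "", x))
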