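#' Construct a pedigree
#'
#' A pedigree is the unit of analysis: a directed family graph with sex,
#' affection status, and flags for which members were array-genotyped and
#' exome-sequenced. Founders have both parents absent; every non-founder has
#' both parents present (half-founders are rejected at validation).
#'
#' @param family_id Family identifier (scalar).
#' @param members Data frame with columns `person_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex` (`"male"`/`"female"`),
#'   `affection` (`"affected"`/`"unaffected"`/`"unknown"`), and logical
#'   `genotyped` and `sequenced`.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(family_id, members) {
  stopifnot(is.data.frame(members), nrow(members) > 0)
  req <- c("person_id", "father_id", "mother_id", "sex", "affection")
  miss <- setdiff(req, names(members))
  if (length(miss))
    stop("members is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(members$genotyped)) members$genotyped <- TRUE
  if (is.null(members$sequenced)) members$sequenced <- members$genotyped
  members$person_id <- as.character(members$person_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  rownames(members) <- NULL
  structure(list(family_id = as.character(family_id), members = members),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf("Pedigree %s: %d members (%d affected, %d founders)\n",
              x$family_id, nrow(m), sum(m$affection == "affected"),
              sum(is.na(m$father_id) & is.na(m$mother_id))))
  invisible(x)
}

founder_ids <- function(ped) {
  m <- ped$members
  m$person_id[is.na(m$father_id) & is.na(m$mother_id)]
}

nonfounder_ids <- function(ped) {
  m <- ped$members
  m$person_id[!(is.na(m$father_id) & is.na(m$mother_id))]
}

#' Affected member ids
#'
#' Members with `affection == "affected"`. Individuals of unknown affection
#' are excluded from every affected-sharing computation.
#' @param ped A [pedigree()].
#' @return Character vector of person ids.
#' @export
affected_ids <- function(ped) {
  m <- ped$members
  m$person_id[m$affection == "affected"]
}

# Topological order (parents before children); NULL if a cycle exists.
topo_order <- function(ped) {
  m <- ped$members
  placed <- character(0)
  remaining <- m$person_id
  while (length(remaining)) {
    ready <- vapply(remaining, function(id) {
      r <- m[m$person_id == id, ]
      (is.na(r$father_id) || r$father_id %in% placed) &&
        (is.na(r$mother_id) || r$mother_id %in% placed)
    }, logical(1))
    # parents referenced but absent from the pedigree never resolve; treat
    # them as placed so the order is still computable for validation
    if (!any(ready)) {
      ext <- vapply(remaining, function(id) {
        r <- m[m$person_id == id, ]
        fo <- is.na(r$father_id) || !(r$father_id %in% m$person_id) ||
          r$father_id %in% placed
        mo <- is.na(r$mother_id) || !(r$mother_id %in% m$person_id) ||
          r$mother_id %in% placed
        fo && mo
      }, logical(1))
      if (!any(ext)) return(NULL)
      ready <- ext
    }
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

ancestor_ids <- function(ped, id, include_self = FALSE) {
  m <- ped$members
  out <- if (include_self) id else character(0)
  frontier <- id
  repeat {
    rows <- m[m$person_id %in% frontier, , drop = FALSE]
    up <- unique(c(rows$father_id, rows$mother_id))
    up <- up[!is.na(up) & up %in% m$person_id & !(up %in% out)]
    if (!length(up)) break
    out <- c(out, up)
    frontier <- up
  }
  out
}

#' Validate pedigree structure
#'
#' Checks the structural invariants required by downstream IBD and
#' segregation analysis: parent references resolve to same-family members of
#' the correct sex, individuals are founders (both parents absent) or have
#' both parents present, the parent graph is acyclic, and no member's parents
#' share a common ancestor (consanguinity loops are rejected).
#'
#' @param ped A [pedigree()].
#' @return Data frame of violations with columns `code`, `person_id`,
#'   `message`; zero rows iff the pedigree is structurally valid.
#' @export
validate_pedigree <- function(ped) {
  m <- ped$members
  v <- list()
  add <- function(code, id, msg)
    v[[length(v) + 1]] <<- data.frame(code = code, person_id = id,
                                      message = msg, stringsAsFactors = FALSE)

  dup <- m$person_id[duplicated(m$person_id)]
  for (id in unique(dup)) add("duplicate_id", id, "duplicated person id")
  bad_sex <- m$person_id[!m$sex %in% c("male", "female")]
  for (id in bad_sex) add("bad_sex", id, "sex must be 'male' or 'female'")
  bad_aff <- m$person_id[!m$affection %in% c("affected", "unaffected", "unknown")]
  for (id in bad_aff) add("bad_affection", id, "unrecognized affection status")

  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    half <- xor(is.na(r$father_id), is.na(r$mother_id))
    if (half) add("half_founder", r$person_id,
                  "exactly one parent present; founders must have both absent")
    for (role in c("father", "mother")) {
      pid <- r[[paste0(role, "_id")]]
      if (is.na(pid)) next
      if (!pid %in% m$person_id) {
        add("missing_parent", r$person_id,
            sprintf("%s '%s' not in pedigree", role, pid))
      } else {
        psex <- m$sex[m$person_id == pid][1]
        want <- if (role == "father") "male" else "female"
        if (!identical(psex, want))
          add("parent_sex", r$person_id,
              sprintf("%s '%s' is not %s", role, pid, want))
      }
      if (identical(pid, r$person_id))
        add("cycle", r$person_id, "individual is its own parent")
    }
  }

  if (is.null(topo_order(ped))) {
    add("cycle", NA_character_, "parent references contain a cycle")
  } else {
    # consanguinity loop: parents of some member share an ancestor
    for (i in seq_len(nrow(m))) {
      r <- m[i, ]
      if (is.na(r$father_id) || is.na(r$mother_id)) next
      if (!(r$father_id %in% m$person_id) || !(r$mother_id %in% m$person_id)) next
      fa <- ancestor_ids(ped, r$father_id, include_self = TRUE)
      mo <- ancestor_ids(ped, r$mother_id, include_self = TRUE)
      if (length(intersect(fa, mo)))
        add("consanguinity_loop", r$person_id,
            "parents share a common ancestor; looped pedigrees are not supported")
    }
  }

  if (!length(v))
    return(data.frame(code = character(0), person_id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' @rdname validate_pedigree
#' @export
is_valid_pedigree <- function(ped) nrow(validate_pedigree(ped)) == 0L

#' Enumerate meioses
#'
#' Lists the meioses of a pedigree in the canonical order used to index
#' inheritance-vector bits: sorted by child id, paternal before maternal.
#' Every non-founder contributes exactly two meioses.
#'
#' @param ped A valid [pedigree()].
#' @return Data frame with columns `child_id`, `parent_role`
#'   (`"paternal"`/`"maternal"`), `parent_id`.
#' @export
enumerate_meioses <- function(ped) {
  if (!is_valid_pedigree(ped))
    stop("pedigree is not structurally valid; see validate_pedigree()")
  m <- ped$members
  nf <- m[!(is.na(m$father_id) & is.na(m$mother_id)), , drop = FALSE]
  if (!nrow(nf))
    return(data.frame(child_id = character(0), parent_role = character(0),
                      parent_id = character(0), stringsAsFactors = FALSE))
  nf <- nf[order(nf$person_id), , drop = FALSE]
  out <- data.frame(
    child_id = rep(nf$person_id, each = 2L),
    parent_role = rep(c("paternal", "maternal"), times = nrow(nf)),
    parent_id = as.vector(rbind(nf$father_id, nf$mother_id)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mendelian consistency check
#'
#' Flags child/parent genotype pairs that are incompatible under biallelic
#' autosomal inheritance (one homozygous for the reference allele, the other
#' homozygous for the alternate). Missing calls never violate.
#'
#' @param ped A [pedigree()].
#' @param gt A [genotype_table()] whose samples are pedigree members.
#' @return Data frame of violations with columns `marker_id`, `child_id`,
#'   `parent_id`.
#' @export
mendelian_check <- function(ped, gt) {
  m <- ped$members
  unknown <- setdiff(gt$sample_ids, m$person_id)
  if (length(unknown))
    stop("samples not in pedigree: ", paste(unknown, collapse = ", "))
  duos <- m[!(is.na(m$father_id) & is.na(m$mother_id)), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(duos))) {
    child <- duos$person_id[i]
    if (!child %in% gt$sample_ids) next
    gc <- gt$calls[, child]
    for (pid in c(duos$father_id[i], duos$mother_id[i])) {
      if (is.na(pid) || !pid %in% gt$sample_ids) next
      gp <- gt$calls[, pid]
      bad <- which(!is.na(gc) & !is.na(gp) &
                     ((gc == 2L & gp == 0L) | (gc == 0L & gp == 2L)))
      if (length(bad))
        out[[length(out) + 1]] <- data.frame(
          marker_id = gt$marker_ids[bad], child_id = child, parent_id = pid,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(marker_id = character(0), child_id = character(0),
                      parent_id = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$marker_id, res$child_id, res$parent_id), , drop = FALSE]
}

# Possible founder-X-allele origins for each member's X chromosome(s).
# Returns a list person_id -> character vector of founder allele labels.
x_possible_origins <- function(ped) {
  m <- ped$members
  ord <- topo_order(ped)
  poss <- list()
  for (id in ord) {
    r <- m[m$person_id == id, ]
    if (is.na(r$father_id)) {
      poss[[id]] <- if (r$sex == "male") paste0(id, ".X") else
        paste0(id, c(".X1", ".X2"))
    } else {
      from_mother <- poss[[r$mother_id]]
      if (r$sex == "male") {
        poss[[id]] <- from_mother
      } else {
        poss[[id]] <- unique(c(from_mother, poss[[r$father_id]]))
      }
    }
  }
  poss
}

#' X-linked compatibility of a pedigree
#'
#' TRUE iff a single founder X allele could be carried (hemizygously by
#' males, on at least one X by females) by every affected member — i.e. the
#' affected members are connected without any male-to-male transmission of
#' the putative risk allele.
#'
#' @param ped A valid [pedigree()] with at least two affected members.
#' @return Logical scalar.
#' @export
xlinked_compatible <- function(ped) {
  aff <- affected_ids(ped)
  if (length(aff) < 2)
    stop("xlinked_compatible requires at least two affected members")
  poss <- x_possible_origins(ped)
  common <- Reduce(intersect, poss[aff])
  length(common) > 0
}

#' Obligate carriers of a segregating variant
#'
#' Given the affected members that carry a variant under a heterozygous
#' model, identifies unsequenced individuals who must also carry it: those
#' lying on every transmission path from the carriers' most recent common
#' transmitting ancestor(s) down to the carriers. When the most recent
#' common ancestors are a couple whose individual transmitter cannot be
#' resolved (e.g. the parents of an affected sib pair), both are returned
#' with status `"candidate"`.
#'
#' @param ped A valid [pedigree()].
#' @param carriers Character vector of affected carrier person ids.
#' @return Data frame with columns `person_id`, `status`
#'   (`"obligate"` or `"candidate"`).
#' @export
obligate_carriers <- function(ped, carriers) {
  m <- ped$members
  if (!all(carriers %in% m$person_id))
    stop("carriers must be members of the pedigree")
  empty <- data.frame(person_id = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  if (length(carriers) < 2) return(empty)

  anc_sets <- lapply(carriers, function(id) ancestor_ids(ped, id, include_self = TRUE))
  common <- Reduce(intersect, anc_sets)
  common <- setdiff(common, carriers)
  if (!length(common)) return(empty)
  # most recent = those with no child also in the common set
  is_mrca <- vapply(common, function(id) {
    kids <- m$person_id[(!is.na(m$father_id) & m$father_id == id) |
                          (!is.na(m$mother_id) & m$mother_id == id)]
    !any(kids %in% common)
  }, logical(1))
  mrca <- common[is_mrca]

  # chain from each carrier up to (exclusive) the MRCA set
  chain <- character(0)
  for (id in carriers) {
    cur <- id
    repeat {
      r <- m[m$person_id == cur, ]
      if (is.na(r$father_id)) break
      par <- c(r$father_id, r$mother_id)
      nxt <- par[vapply(par, function(p)
        any(mrca %in% ancestor_ids(ped, p, include_self = TRUE)), logical(1))]
      if (!length(nxt)) break
      # outbred pedigree: exactly one parent leads toward the MRCA unless
      # the parents ARE the MRCA couple
      if (all(par %in% mrca)) break
      cur <- nxt[1]
      if (cur %in% mrca) break
      chain <- c(chain, cur)
    }
  }
  chain <- unique(chain)

  seq_flag <- stats::setNames(m$sequenced, m$person_id)
  obligate <- chain[!seq_flag[chain]]
  out <- if (length(obligate))
    data.frame(person_id = sort(obligate), status = "obligate",
               stringsAsFactors = FALSE) else empty

  # ambiguous couple case: MRCAs are a mated pair directly above all carriers
  if (length(mrca) == 2) {
    sexes <- stats::setNames(m$sex, m$person_id)[mrca]
    mated <- any(m$father_id %in% mrca & m$mother_id %in% mrca, na.rm = TRUE)
    if (mated && length(unique(sexes)) == 2 && !length(chain)) {
      cand <- mrca[!seq_flag[mrca]]
      if (length(cand))
        out <- rbind(out, data.frame(person_id = sort(cand),
                                     status = "candidate",
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
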