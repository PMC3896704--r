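# Inheritance-vector bookkeeping shared by the Lander-Green HMM and the
# gene-dropping simulator: for every inheritance vector v, which founder
# allele slot each individual's paternal/maternal allele descends from.

#' Build founder-allele descent arrays
#'
#' For a pedigree and chromosome type, enumerates all inheritance vectors
#' (one bit per meiosis; on the X chromosome only maternal meioses carry a
#' bit, since father-to-daughter X transmission is deterministic and fathers
#' transmit no X to sons) and returns, for each member, the founder allele
#' slot of each of their alleles under every vector.
#'
#' @param ped A valid [pedigree()].
#' @param chrom_type `"autosome"` or `"x"`.
#' @param max_meioses Capacity cap on the number of inheritance-vector bits.
#' @return List with elements `n_meioses`, `n_slots`, `slot_owner`,
#'   `A1`/`A2` (V x member integer matrices of slot indices; on the X,
#'   males have a single allele and `A1 == A2`), `members` (column order),
#'   and `meiosis_info`.
#' @keywords internal
build_descent <- function(ped, chrom_type = c("autosome", "x"),
                          max_meioses = 16L) {
  chrom_type <- match.arg(chrom_type)
  m <- ped$members
  ord <- topo_order(ped)
  if (is.null(ord)) stop("pedigree contains a cycle")
  founders <- founder_ids(ped)
  nonf <- setdiff(ord, founders)

  if (chrom_type == "autosome") {
    mei <- enumerate_meioses(ped)
    n_mei <- nrow(mei)
  } else {
    kids <- sort(nonf)
    mei <- data.frame(child_id = kids, parent_role = "maternal",
                      parent_id = m$mother_id[match(kids, m$person_id)],
                      stringsAsFactors = FALSE)
    n_mei <- nrow(mei)
  }
  if (n_mei > max_meioses)
    stop("pedigree has ", n_mei, " meioses; cap is ", max_meioses,
         " (raise max_meioses if memory allows)")
  V <- 2L^n_mei
  vbits <- function(j) bitwAnd(bitwShiftR(0:(V - 1L), j - 1L), 1L) == 1L

  # founder slots
  slot_owner <- character(0)
  slot1 <- slot2 <- stats::setNames(integer(length(ord)), ord)
  n_slots <- 0L
  for (id in founders) {
    sex <- m$sex[m$person_id == id]
    if (chrom_type == "x" && sex == "male") {
      n_slots <- n_slots + 1L
      slot1[id] <- slot2[id] <- n_slots
      slot_owner <- c(slot_owner, id)
    } else {
      slot1[id] <- n_slots + 1L
      slot2[id] <- n_slots + 2L
      n_slots <- n_slots + 2L
      slot_owner <- c(slot_owner, id, id)
    }
  }
  if (n_slots > 30L)
    stop("more than 30 founder allele slots; sharing masks need <= 30")

  A1 <- matrix(0L, V, length(ord), dimnames = list(NULL, ord))
  A2 <- matrix(0L, V, length(ord), dimnames = list(NULL, ord))
  for (id in founders) {
    A1[, id] <- slot1[id]
    A2[, id] <- slot2[id]
  }
  for (id in nonf) {
    r <- m[m$person_id == id, ]
    if (chrom_type == "autosome") {
      jp <- which(mei$child_id == id & mei$parent_role == "paternal")
      jm <- which(mei$child_id == id & mei$parent_role == "maternal")
      bp <- vbits(jp)
      bm <- vbits(jm)
      A1[, id] <- ifelse(bp, A2[, r$father_id], A1[, r$father_id])
      A2[, id] <- ifelse(bm, A2[, r$mother_id], A1[, r$mother_id])
    } else {
      jm <- which(mei$child_id == id)
      bm <- vbits(jm)
      from_mother <- ifelse(bm, A2[, r$mother_id], A1[, r$mother_id])
      if (r$sex == "male") {
        A1[, id] <- from_mother
        A2[, id] <- from_mother
      } else {
        A1[, id] <- A1[, r$father_id]  # father's single X
        A2[, id] <- from_mother
      }
    }
  }
  # founder-symmetry masks: swapping a founder's two haplotype labels is
  # equivalent to toggling the meiosis bits of all their transmitting
  # meioses; emissions are invariant under these XOR masks (used by the HMM
  # to compute emissions once per orbit)
  masks <- integer(0)
  for (id in founders) {
    if (chrom_type == "x" && m$sex[m$person_id == id] == "male") next
    if (chrom_type == "autosome") {
      role <- if (m$sex[m$person_id == id] == "male") "paternal" else "maternal"
      js <- which(mei$parent_id == id & mei$parent_role == role)
    } else {
      js <- which(mei$parent_id == id)
    }
    if (length(js))
      masks <- c(masks, Reduce(bitwXor, bitwShiftL(1L, js - 1L)))
  }

  list(n_meioses = n_mei, n_slots = n_slots, slot_owner = slot_owner,
       A1 = A1, A2 = A2, members = ord, meiosis_info = mei,
       founder_masks = masks)
}

# Indicator over inheritance vectors of the all-affected sharing event:
# some founder allele slot is carried by every affected member.
sharing_indicator <- function(desc, affected) {
  V <- nrow(desc$A1)
  if (!length(affected)) return(rep(TRUE, V))
  mask <- rep(bitwShiftL(1L, desc$n_slots) - 1L, V)
  if (desc$n_slots >= 31L) stop("slot mask overflow")
  for (id in affected) {
    mi <- bitwOr(bitwShiftL(1L, desc$A1[, id] - 1L),
                 bitwShiftL(1L, desc$A2[, id] - 1L))
    mask <- bitwAnd(mask, mi)
  }
  mask != 0L
}
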