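# Independent reference implementations used as oracles. These deliberately
# avoid the package's internal code paths: exhaustive enumeration instead of
# component factorization, dense transition matrices instead of butterfly
# updates, and direct window scans instead of run-length logic.

# ---- exhaustive Lander-Green forward-backward (autosomes) -----------------

oracle_topo <- function(members) {
  placed <- character(0)
  left <- members$person_id
  while (length(left)) {
    ok <- vapply(left, function(id) {
      r <- members[members$person_id == id, ]
      (is.na(r$father_id) || r$father_id %in% placed) &&
        (is.na(r$mother_id) || r$mother_id %in% placed)
    }, logical(1))
    placed <- c(placed, left[ok])
    left <- left[!ok]
  }
  placed
}

# slot pair (paternal, maternal) of every member under one inheritance
# vector; bits ordered as (child sorted, paternal then maternal)
oracle_slots_for_vector <- function(members, bits) {
  ord <- oracle_topo(members)
  foun <- ord[vapply(ord, function(id)
    is.na(members$father_id[members$person_id == id]), logical(1))]
  nonf <- sort(setdiff(ord, foun))
  slot <- list()
  k <- 0
  for (id in foun) { slot[[id]] <- c(k + 1, k + 2); k <- k + 2 }
  for (id in ord) {
    if (id %in% foun) next
    r <- members[members$person_id == id, ]
    j <- 2 * (match(id, nonf) - 1)
    bp <- bits[j + 1]; bm <- bits[j + 2]
    fa <- slot[[r$father_id]]; mo <- slot[[r$mother_id]]
    slot[[id]] <- c(fa[bp + 1], mo[bm + 1])
  }
  list(slots = slot, n_slots = k)
}

oracle_sharing <- function(ped, gt, map) {
  members <- ped$members
  aff <- members$person_id[members$affection == "affected"]
  typed <- intersect(gt$sample_ids,
                     members$person_id[members$genotyped])
  nonf <- sort(members$person_id[!is.na(members$father_id)])
  m_bits <- 2 * length(nonf)
  V <- 2^m_bits
  bitmat <- sapply(seq_len(m_bits), function(j) (0:(V - 1)) %/% 2^(j - 1) %% 2)
  bitmat <- matrix(bitmat, nrow = V)

  per_v <- lapply(seq_len(V), function(v)
    oracle_slots_for_vector(members, bitmat[v, ]))
  n_slots <- per_v[[1]]$n_slots
  B <- 2^n_slots
  patt <- sapply(seq_len(n_slots), function(s) (0:(B - 1)) %/% 2^(s - 1) %% 2)
  patt <- matrix(patt, nrow = B)

  share <- vapply(seq_len(V), function(v) {
    sl <- per_v[[v]]$slots
    common <- Reduce(intersect, lapply(aff, function(id) sl[[id]]))
    length(common) > 0
  }, logical(1))

  idx <- match(gt$marker_ids, map$marker_id)
  mp <- map[idx, , drop = FALSE]
  M <- nrow(mp)
  emis <- matrix(0, V, M)
  for (t in seq_len(M)) {
    p <- mp$panel_af[t]
    prior_b <- apply(patt, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
    for (v in seq_len(V)) {
      sl <- per_v[[v]]$slots
      ok <- rep(TRUE, B)
      for (id in typed) {
        g <- gt$calls[t, id]
        if (is.na(g)) next
        cnt <- patt[, sl[[id]][1]] + patt[, sl[[id]][2]]
        ok <- ok & (cnt == g)
      }
      emis[v, t] <- sum(prior_b[ok])
    }
  }

  if (M == 1) {
    post <- emis[, 1] / sum(emis[, 1])
    return(sum(post[share]))
  }

  theta <- (1 - exp(-2 * diff(mp$position_cM) / 100)) / 2
  ham <- matrix(0L, V, V)
  for (j in seq_len(m_bits))
    ham <- ham + abs(outer(bitmat[, j], bitmat[, j], `-`))
  uth <- unique(theta)
  tr_cache <- lapply(uth, function(th) th^ham * (1 - th)^(m_bits - ham))
  trans_at <- function(t) tr_cache[[match(theta[t], uth)]]

  alpha <- matrix(0, V, M)
  alpha[, 1] <- emis[, 1] / V
  alpha[, 1] <- alpha[, 1] / sum(alpha[, 1])
  for (t in 2:M) {
    a <- as.vector(t(trans_at(t - 1)) %*% alpha[, t - 1]) * emis[, t]
    alpha[, t] <- a / sum(a)
  }
  beta <- matrix(0, V, M)
  beta[, M] <- 1
  for (t in (M - 1):1) {
    b <- as.vector(trans_at(t) %*% (beta[, t + 1] * emis[, t + 1]))
    beta[, t] <- b / sum(b)
  }
  post <- alpha * beta
  post <- sweep(post, 2, colSums(post), "/")
  colSums(post[share, , drop = FALSE])
}

oracle_sharing_single <- oracle_sharing

# ---- brute-force sliding-window segment flags -----------------------------

oracle_flags <- function(sharing, window, threshold) {
  n <- length(sharing)
  if (n < window) return(rep(all(sharing > threshold), n))
  flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (s in max(1, i - window + 1):min(i, n - window + 1)) {
      if (all(sharing[s:(s + window - 1)] > threshold)) { flag[i] <- TRUE; break }
    }
  }
  flag
}

# ---- brute-force windowed LD pruning --------------------------------------

oracle_prune <- function(calls, window_size, step, r2_threshold) {
  n <- nrow(calls)
  keep <- rep(TRUE, n)
  maf <- apply(calls, 1, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    if (is.nan(f)) 0 else min(f, 1 - f)
  })
  s <- 1
  repeat {
    e <- min(s + window_size - 1, n)
    repeat {
      live <- (s:e)[keep[s:e]]
      removed <- FALSE
      if (length(live) >= 2) {
        for (a in live) {
          for (b in live[live > a]) {
            r <- suppressWarnings(cor(calls[a, ], calls[b, ],
                                      use = "pairwise.complete.obs"))
            if (!is.na(r) && r^2 > r2_threshold) {
              drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else b
              keep[drop] <- FALSE
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
      if (!removed) break
    }
    if (e == n) break
    s <- s + step
  }
  keep
}

# ---- exact combinatorial hypergeometric tail ------------------------------

# Pascal triangle: integer-exact binomial coefficients (values <= C(60,30)
# ~ 1.2e17; additions beyond 2^53 are correctly rounded doubles, keeping the
# oracle's relative error ~1e-14)
oracle_choose_table <- function(N) {
  CT <- matrix(0, N + 1, N + 1)
  CT[, 1] <- 1
  for (i in 2:(N + 1))
    for (j in 2:i)
      CT[i, j] <- CT[i - 1, j - 1] + CT[i - 1, j]
  CT
}

oracle_hyper_tail <- function(k, K, n, N, CT) {
  hi <- min(K, n)
  j <- k:hi
  terms <- CT[K + 1, j + 1] * CT[N - K + 1, n - j + 1]
  sum(terms) / CT[N + 1, n + 1]
}

# ---- small pedigree builders ----------------------------------------------

make_members <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(person_id = r[[1]], father_id = r[[2]], mother_id = r[[3]],
               sex = r[[4]], affection = r[[5]],
               genotyped = if (length(r) >= 6) r[[6]] else TRUE,
               sequenced = if (length(r) >= 7) r[[7]] else TRUE,
               stringsAsFactors = FALSE)))
}

nuclear_pedigree <- function(n_children = 2, affected = seq_len(min(2, n_children)),
                             family_id = "NUC") {
  rows <- list(list("p1", NA, NA, "male", "unaffected"),
               list("p2", NA, NA, "female", "unaffected"))
  for (i in seq_len(n_children))
    rows <- c(rows, list(list(sprintf("c%d", i), "p1", "p2",
                              if (i %% 2) "male" else "female",
                              if (i %in% affected) "affected" else "unaffected")))
  pedigree(family_id, do.call(make_members, rows))
}

# random small pedigree with <= 10 meioses for oracle comparisons
random_small_pedigree <- function(i) {
  kind <- i %% 5
  if (kind == 0) nuclear_pedigree(2)
  else if (kind == 1) nuclear_pedigree(3, affected = c(1, 3))
  else if (kind == 2) generate_pedigree("cousin_pair", 2, seed = 100 + i)
  else if (kind == 3) nuclear_pedigree(4, affected = c(2, 4))
  else generate_pedigree("avuncular_plus_cousin", 3, seed = 100 + i)  # m = 10
}

flat_map <- function(n, af = NULL, spacing_cM = 2, chrom = "1", seed = NULL) {
  if (is.null(af)) af <- withr_seed_runif(n, seed)
  marker_map(data.frame(
    marker_id = sprintf("m%03d", seq_len(n)), chrom = chrom,
    position_bp = seq_len(n) * 10000L,
    position_cM = (seq_len(n) - 1) * spacing_cM,
    ref_allele = "A", alt_allele = "G", panel_af = af,
    stringsAsFactors = FALSE))
}

withr_seed_runif <- function(n, seed) {
  if (is.null(seed)) return(runif(n, 0.2, 0.8))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  runif(n, 0.2, 0.8)
}
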