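#' Build a dominance matrix from agonistic interaction records
#'
#' Entry `(i, j)` counts the interactions animal `i` won against animal `j`
#' (i.e. records where `i` was the aggressor and `j` the aggrieved). Animals
#' named in `ids` but absent from the records are kept as zero rows/columns
#' so they can still be placed in the rank order.
#'
#' @param records data frame with columns `aggressor_id` and `aggrieved_id`.
#' @param ids character vector of all animal ids in the group.
#' @return an integer matrix of class `dominance_matrix` with `ids` as
#'   dimnames.
#' @export
build_dominance_matrix <- function(records, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("`ids` must be unique")
  if (length(ids) < 2L) stop("a dominance matrix needs at least 2 animals")
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(records) > 0L) {
    ag <- as.character(records$aggressor_id)
    av <- as.character(records$aggrieved_id)
    if (any(ag == av)) stop("self-interaction records are not allowed")
    unknown <- setdiff(c(ag, av), ids)
    if (length(unknown)) {
      stop("records refer to unknown ids: ", paste(unknown, collapse = ", "))
    }
    tab <- table(factor(ag, ids), factor(av, ids))
    m <- m + unclass(tab)
    storage.mode(m) <- "integer"
  }
  structure(m, class = c("dominance_matrix", "matrix"))
}

#' Combi1 dominance index
#'
#' Per-animal score \eqn{D_i/(D_i+S_i) + D_i - S_i}, where \eqn{D_i} and
#' \eqn{S_i} are the numbers of domination (wins) and subdomination (losses)
#' of animal `i` over the rest of the group. An animal with no interactions
#' (`D + S = 0`) scores 0 by convention, leaving it mid-ranked.
#'
#' @param matrix a `dominance_matrix` (or plain square count matrix with
#'   dimnames).
#' @return data frame with columns `id`, `D`, `S`, `combi1`, ordered as the
#'   matrix rows.
#' @export
combi1 <- function(matrix) {
  m <- unclass(matrix)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m < 0)) stop("dominance counts must be non-negative")
  D <- rowSums(m)
  S <- colSums(m)
  tot <- D + S
  ratio <- ifelse(tot > 0, D / pmax(tot, 1), 0)
  data.frame(
    id = rownames(m) %||% as.character(seq_len(nrow(m))),
    D = as.numeric(D), S = as.numeric(S),
    combi1 = ratio + D - S,
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count inconsistencies of a rank order against a dominance matrix
#'
#' A pair of animals placed at positions `p < q` is inconsistent when the
#' lower-placed animal beat the higher-placed one more often than the
#' reverse (`counts[j, i] > counts[i, j]`). Ties — including equal non-zero
#' counts — are never inconsistencies. `I` is the number of inconsistent
#' pairs and `SI` the sum of their rank distances `q - p`.
#'
#' @param matrix dominance count matrix.
#' @param order integer or character permutation of the matrix ids, most
#'   dominant first.
#' @return list with elements `I` and `SI`.
#' @export
count_inconsistencies <- function(matrix, order) {
  m <- unclass(matrix)
  idx <- order_to_index(m, order)
  n <- nrow(m)
  perm <- m[idx, idx, drop = FALSE]
  bad <- t(perm) > perm            # entry (p, q): lower-placed beats higher
  up <- upper.tri(bad)
  I <- sum(bad & up)
  dist <- abs(row(bad) - col(bad))
  SI <- sum(dist[bad & up])
  list(I = as.integer(I), SI = as.integer(SI))
}

order_to_index <- function(m, order) {
  n <- nrow(m)
  if (is.character(order)) {
    idx <- match(order, rownames(m))
    if (anyNA(idx)) stop("order contains unknown ids")
  } else {
    idx <- as.integer(order)
  }
  if (length(idx) != n || !setequal(idx, seq_len(n))) {
    stop("`order` must be a permutation of the matrix ids")
  }
  idx
}

combi1_initial_order <- function(m) {
  sc <- combi1(m)
  order(-sc$combi1, -sc$D, sc$id)
}

#' I&SI linear rank order
#'
#' Finds a linear order of the animals that minimises, lexicographically,
#' first the number of inconsistencies `I` and then their total strength
#' `SI`. The search starts from the Combi1 order (ties broken by larger `D`,
#' then id), then sweeps over all pairwise swaps, accepting any swap that
#' improves `(I, SI)`, until a sweep makes no change. If sweeps stall before
#' `max_sweeps` is exhausted, seeded random restarts from shuffled orders try
#' to escape local optima; the best order found is returned. The result is
#' never worse than the initial Combi1 order.
#'
#' @param matrix dominance count matrix.
#' @param seed integer seed for the restart shuffles (deterministic output).
#' @param max_sweeps maximum improvement sweeps across all restarts.
#' @return data frame (one row per animal, most dominant first) with columns
#'   `id`, `D`, `S`, `combi1`, `order_position`, plus attributes `I`, `SI`
#'   and `converged`.
#' @export
isi_order <- function(matrix, seed = 1L, max_sweeps = 100L) {
  m <- unclass(matrix)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2L)
  n <- nrow(m)
  sc <- combi1(m)

  # (I, SI) contribution of all pairs involving position p (vectorized)
  pos_contrib <- function(idx, p) {
    k <- seq_len(n)[-p]
    wins_p <- m[idx[p], idx[k]]
    wins_k <- m[idx[k], idx[p]]
    bad <- ifelse(k < p, wins_p > wins_k, wins_k > wins_p)
    c(I = sum(bad), SI = sum(abs(k - p)[bad]))
  }
  pair_contrib <- function(idx, p, q) { # p < q
    bad <- m[idx[q], idx[p]] > m[idx[p], idx[q]]
    c(I = as.integer(bad), SI = if (bad) q - p else 0L)
  }

  swap_descent <- function(idx, budget) {
    sweeps <- 0L
    cur <- count_inconsistencies(m, idx)
    cur <- c(I = cur$I, SI = cur$SI)
    repeat {
      if (sweeps >= budget) return(list(idx = idx, I = cur[["I"]],
                                        SI = cur[["SI"]],
                                        converged = FALSE, used = sweeps))
      sweeps <- sweeps + 1L
      improved <- FALSE
      for (p in seq_len(n - 1L)) {
        for (q in seq(p + 1L, n)) {
          before <- pos_contrib(idx, p) + pos_contrib(idx, q) -
            pair_contrib(idx, p, q)
          cand <- idx
          cand[c(p, q)] <- cand[c(q, p)]
          after <- pos_contrib(cand, p) + pos_contrib(cand, q) -
            pair_contrib(cand, p, q)
          alt <- cur - before + after
          if (alt[["I"]] < cur[["I"]] ||
              (alt[["I"]] == cur[["I"]] && alt[["SI"]] < cur[["SI"]])) {
            idx <- cand
            cur <- alt
            improved <- TRUE
          }
        }
      }
      if (!improved) return(list(idx = idx, I = cur[["I"]],
                                 SI = cur[["SI"]],
                                 converged = TRUE, used = sweeps))
    }
  }

  insertion_descent <- function(state, budget) {
    idx <- state$idx
    cur <- c(I = state$I, SI = state$SI)
    sweeps <- 0L
    repeat {
      if (sweeps >= budget) break
      sweeps <- sweeps + 1L
      improved <- FALSE
      for (p in seq_len(n)) {
        for (q in seq_len(n)) {
          if (p == q) next
          cand <- append(idx[-p], idx[p], after = q - 1L)
          alt <- count_inconsistencies(m, cand)
          if (alt$I < cur[["I"]] ||
              (alt$I == cur[["I"]] && alt$SI < cur[["SI"]])) {
            idx <- cand
            cur <- c(I = alt$I, SI = alt$SI)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(idx = idx, I = cur[["I"]], SI = cur[["SI"]],
         converged = state$converged, used = sweeps)
  }

  polish <- function(state, budget) {
    # alternate swap and insertion descents until neither improves
    repeat {
      ins <- insertion_descent(state, budget)
      if (ins$I == state$I && ins$SI == state$SI) return(ins)
      state <- swap_descent(ins$idx, budget)
      if (state$I == ins$I && state$SI == ins$SI) return(state)
    }
  }

  budget <- as.integer(max_sweeps)
  best <- polish(swap_descent(combi1_initial_order(m), budget), budget)
  budget <- budget - best$used
  # a couple of seeded random restarts to escape local optima of the
  # pairwise-swap neighbourhood (noisy tournaments routinely keep I > 0)
  with_stream(seed, "isi_restarts", {
    for (r in 1:2) {
      if (budget <= 0L || best$I == 0L) break
      res <- polish(swap_descent(sample.int(n), budget), budget)
      budget <- budget - max(res$used, 1L)
      if (res$I < best$I || (res$I == best$I && res$SI < best$SI)) best <- res
    }
  })

  idx <- best$idx
  out <- sc[idx, , drop = FALSE]
  out$order_position <- seq_len(n)
  rownames(out) <- NULL
  structure(out, I = best$I, SI = best$SI, converged = best$converged)
}

#' Exhaustive I&SI oracle
#'
#' Enumerates every permutation of the animals (`n <= 8`) and returns the
#' global lexicographic minimum of `(I, SI)`. Among optimal orders, ties are
#' broken by the Combi1 initial order's positions, then id, so the result is
#' deterministic. Intended as an independent reference for [isi_order()].
#'
#' @param matrix dominance count matrix with at most 8 animals.
#' @return list with elements `order` (ids, most dominant first), `I`, `SI`.
#' @export
exhaustive_isi_oracle <- function(matrix) {
  m <- unclass(matrix)
  n <- nrow(m)
  if (n > 8L) stop("exhaustive search refuses n > 8")
  perms <- permutations(n)
  base <- combi1_initial_order(m) # preference used only to break ties
  pref <- order(base)             # position of each animal under combi1
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    idx <- perms[r, ]
    sc <- count_inconsistencies(m, idx)
    key <- c(sc$I, sc$SI, pref[idx])
    if (is.null(best) || lex_less(key, best$key)) {
      best <- list(key = key, idx = idx, I = sc$I, SI = sc$SI)
    }
  }
  ids <- rownames(m) %||% as.character(seq_len(n))
  list(order = ids[best$idx], I = best$I, SI = best$SI)
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Standardized hierarchical rank covariate
#'
#' Maps rank positions to a linear score with the most dominant animal at
#' +1 and the least dominant at -1, the "hierarchical rank" covariate used
#' in the pelt-biting models (higher value = higher dominance).
#'
#' @param order_position integer vector of 1-based rank positions
#'   (1 = most dominant) within one group.
#' @return numeric vector in `[-1, 1]`.
#' @export
standardize_rank <- function(order_position) {
  n <- length(order_position)
  if (n < 2L) stop("cannot standardize the rank of a single animal")
  if (!setequal(order_position, seq_len(n))) {
    stop("`order_position` must be a permutation of 1..n")
  }
  1 - 2 * (order_position - 1) / (n - 1)
}
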