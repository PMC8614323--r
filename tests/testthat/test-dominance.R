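test_that("dominance matrices count wins with zero rows for silent animals", {
  rec <- data.frame(aggressor_id = c("A", "A", "B"),
                    aggrieved_id = c("B", "B", "A"))
  m <- build_dominance_matrix(rec, c("A", "B", "C"))
  expect_equal(m["A", "B"], 2L)
  expect_equal(m["B", "A"], 1L)
  expect_true(all(m["C", ] == 0L) && all(m[, "C"] == 0L))
  expect_equal(diag(unclass(m)), c(A = 0L, B = 0L, C = 0L))

  empty <- build_dominance_matrix(rec[0, ], c("A", "B", "C"))
  expect_true(all(unclass(empty) == 0L))

  expect_error(build_dominance_matrix(
    data.frame(aggressor_id = "A", aggrieved_id = "Z"), c("A", "B")),
    "unknown ids")
  expect_error(build_dominance_matrix(
    data.frame(aggressor_id = "A", aggrieved_id = "A"), c("A", "B")),
    "self-interaction")
})

test_that("combi1 reproduces the index arithmetic and its conventions", {
  m <- matrix(c(0L, 5L, 0L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  sc <- combi1(m)
  expect_equal(sc$combi1[sc$id == "A"], 5 / 5 + 5 - 0)      # 6.0
  expect_equal(sc$combi1[sc$id == "B"], 0 / 5 + 0 - 5)      # -5.0

  m2 <- matrix(c(0L, 3L, 7L, 0L), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(combi1(m2)$combi1[1], 3 / 10 + 3 - 7)        # -3.7

  zero <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_equal(combi1(zero)$combi1, rep(0, 3))              # 0/0 convention
})

test_that("domination and subdomination totals balance the interaction count", {
  set.seed(11)
  for (r in 1:10) {
    m <- random_dominance_matrix(sample(3:8, 1))
    sc <- combi1(m)
    expect_equal(sum(sc$D), sum(sc$S))
    expect_equal(sum(sc$D), sum(m))
  }
})

test_that("combi1 strictly increases in D at fixed S", {
  base <- combi1(matrix(c(0L, 3L, 7L, 0L), 2, 2, byrow = TRUE,
                        dimnames = list(c("A", "B"), c("A", "B"))))
  more <- combi1(matrix(c(0L, 4L, 7L, 0L), 2, 2, byrow = TRUE,
                        dimnames = list(c("A", "B"), c("A", "B"))))
  expect_gt(more$combi1[1], base$combi1[1])
})

test_that("inconsistencies count reversed pairs weighted by rank distance", {
  m <- transitive_matrix(4)
  expect_equal(count_inconsistencies(m, 1:4), list(I = 0L, SI = 0L))

  # only C beats A, order A,B,C: one inconsistent pair at distance 2
  m2 <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  m2["C", "A"] <- 2L
  expect_equal(count_inconsistencies(m2, c("A", "B", "C")),
               list(I = 1L, SI = 2L))

  # equal non-zero counts are ties, not inconsistencies
  m3 <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m3["A", "B"] <- m3["B", "A"] <- 3L
  expect_equal(count_inconsistencies(m3, c("A", "B"))$I, 0L)
  expect_equal(count_inconsistencies(m3, c("B", "A"))$I, 0L)

  expect_error(count_inconsistencies(m2, c(1L, 2L)), "permutation")
})

test_that("reversing a strict transitive order flips every pair", {
  for (n in 4:6) {
    m <- transitive_matrix(n)
    rev_sc <- count_inconsistencies(m, n:1)
    expect_equal(rev_sc$I, n * (n - 1L) / 2L)
    # brute force over the pair set
    si <- sum(vapply(utils::combn(n, 2, simplify = FALSE),
                     function(p) abs(p[2] - p[1]), 0L))
    expect_equal(rev_sc$SI, as.integer(si))
  }
})

test_that("I&SI ordering solves transitive and empty tournaments exactly", {
  m <- transitive_matrix(6)
  rk <- isi_order(m, seed = 1)
  expect_equal(rk$id, LETTERS[1:6])
  expect_equal(attr(rk, "I"), 0L)
  expect_equal(attr(rk, "SI"), 0L)
  expect_true(attr(rk, "converged"))

  zero <- matrix(0L, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  rk0 <- isi_order(zero, seed = 1)
  expect_equal(attr(rk0, "I"), 0L)
  expect_equal(rk0$order_position, 1:4)
})

test_that("heuristic order is never worse than the initial combi1 order", {
  set.seed(21)
  for (r in 1:20) {
    m <- random_dominance_matrix(sample(4:7, 1))
    sc <- combi1(m)
    init <- order(-sc$combi1, -sc$D, sc$id)
    ini <- count_inconsistencies(m, init)
    rk <- isi_order(m, seed = r)
    expect_true(attr(rk, "I") < ini$I ||
                  (attr(rk, "I") == ini$I && attr(rk, "SI") <= ini$SI))
  }
})

test_that("exhaustive oracle handles the documented small cases", {
  m2 <- matrix(c(0L, 1L, 0L, 0L), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  o <- exhaustive_isi_oracle(m2)
  expect_equal(o$order, c("A", "B"))
  expect_equal(c(o$I, o$SI), c(0L, 0L))

  # 3-cycle: no order can be consistent; orders following the cycle
  # direction carry one inconsistency, the reversed ones two (enumeration
  # of all 6 permutations)
  cyc <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  cyc["A", "B"] <- cyc["B", "C"] <- cyc["C", "A"] <- 1L
  expect_equal(exhaustive_isi_oracle(cyc)$I, 1L)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), 3:1)
  is <- vapply(perms, function(p)
    count_inconsistencies(cyc, as.integer(p))$I, 0L)
  expect_true(all(is >= 1L))
  expect_equal(min(is), 1L)
  expect_setequal(unique(is), c(1L, 2L))

  expect_equal(exhaustive_isi_oracle(transitive_matrix(4))$I, 0L)
  expect_error(exhaustive_isi_oracle(random_dominance_matrix(9)), "n > 8")
})

test_that("heuristic I&SI attains the exhaustive optimum on random data", {
  set.seed(33)
  for (r in 1:50) {
    m <- random_dominance_matrix(sample(4:6, 1))
    rk <- isi_order(m, seed = r)
    oracle <- exhaustive_isi_oracle(m)
    expect_equal(attr(rk, "I"), oracle$I)
    expect_equal(attr(rk, "SI"), oracle$SI)
  }
})

test_that("standardized rank maps positions linearly onto [-1, 1]", {
  expect_equal(standardize_rank(1:3), c(1, 0, -1))
  expect_equal(standardize_rank(c(2L, 1L)), c(-1, 1))
  expect_setequal(standardize_rank(sample(1:5)), seq(-1, 1, by = 0.5))
  expect_error(standardize_rank(1L), "single animal")
  expect_error(standardize_rank(c(1L, 3L)), "permutation")
})
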