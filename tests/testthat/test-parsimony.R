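test_that("Fitch lengths match textbook cases", {
  tr <- parse_tree("((A,B),(C,D));")
  expect_equal(fitch_length(tr, list(A = 0, B = 0, C = 0, D = 0)), 0L)
  expect_equal(fitch_length(tr, list(A = 0, B = 0, C = 1, D = 1)), 1L)
  expect_equal(fitch_length(tr, list(A = 0, B = 1, C = 0, D = 1)), 2L)
  expect_equal(fitch_length(tr, list(A = 0, B = "?", C = 1, D = 1)), 1L)
  expect_equal(fitch_length(tr, list(A = c(0, 1), B = 1, C = 0, D = 0)), 1L)
  expect_error(fitch_length(tr, list(A = 0, B = 0, C = 1)), "tip without a cell")
})

test_that("Fitch equals exhaustive assignment minimization on random instances", {
  set.seed(405)
  for (i in 1:120) {
    n <- sample(3:7, 1)
    tr <- ape::rtree(n, br = NULL)
    n_states <- sample(2:4, 1)
    sets <- lapply(seq_len(n), function(i) {
      cl <- random_cell(n_states)
      if (identical(cl, "?") || identical(cl, "-")) integer(0) else cl
    })
    names_sets <- stats::setNames(sets, tr$tip.label)
    col <- lapply(names_sets, function(s) if (length(s) == 0) "?" else s)
    expect_equal(fitch_length(tr, col), brute_fitch(tr, sets))
  }
})

test_that("Fitch equals the Sankoff dynamic program, including polytomies", {
  set.seed(406)
  for (i in 1:80) {
    n <- sample(4:9, 1)
    tr <- ape::rtree(n, br = NULL)
    if (i %% 2 == 0) tr <- ape::di2multi(ape::rtree(n), tol = stats::runif(1, 0.2, 0.8))
    n <- length(tr$tip.label)
    sets <- lapply(seq_len(n), function(i) {
      cl <- random_cell(4)
      if (identical(cl, "?") || identical(cl, "-")) integer(0) else cl
    })
    col <- stats::setNames(lapply(sets, function(s) if (length(s) == 0) "?" else s),
                           tr$tip.label)
    expect_equal(fitch_length(tr, col), sankoff_steps(tr, sets))
  }
})

test_that("phangorn's parsimony agrees with the engine on clean binary data", {
  set.seed(407)
  for (i in 1:10) {
    tr <- simulate_tree(sample(5:12, 1))
    cfg <- sim_config(n_tips = length(tr$tip.label), n_chars = 30, rate = 0.5)
    m <- simulate_characters(tr, cfg)
    dat <- matrix(NA_character_, length(m$taxa), m$n_chars,
                  dimnames = list(m$taxa, NULL))
    for (tx in m$taxa) {
      for (j in seq_len(m$n_chars)) dat[tx, j] <- as.character(cell_states(m, tx, j))
    }
    pd <- phangorn::phyDat(dat, type = "USER", levels = c("0", "1"))
    expect_equal(tree_score(tr, m)$total_length,
                 phangorn::parsimony(tr, pd, method = "fitch"))
  }
})

test_that("minimum conceivable steps ignore polymorphism and missing cells", {
  expect_equal(min_steps(list("?", "?", "?")), 0L)
  expect_equal(min_steps(list(0, 1, 2)), 2L)
  expect_equal(min_steps(list(c(0, 1), 0, 1)), 1L)
  expect_equal(min_steps(list(c(0, 2), c(1, 2), 2)), 0L)
  expect_equal(min_steps(list(0, "-", 0, "?")), 0L)
})

test_that("min_steps equals the brute-force minimum of Fitch over all trees", {
  set.seed(408)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    sets <- lapply(seq_len(n), function(i) {
      cl <- random_cell(3, p_poly = 0.3)
      if (identical(cl, "?") || identical(cl, "-")) integer(0) else cl
    })
    trees <- phangorn::allTrees(n, rooted = FALSE)
    best <- min(vapply(trees, function(tr) brute_fitch(tr, sets), integer(1)))
    expect_equal(min_steps(sets), best)
  }
})

test_that("the concave fit is correct, monotone, and concave in extra steps", {
  expect_equal(implied_fit(0, 12), 0)
  expect_equal(implied_fit(1, 12), 1 / 13)
  expect_equal(implied_fit(13, 12), 0.52)
  f <- implied_fit(0:100, 12)
  expect_true(all(diff(f) > 0))          # strictly increasing
  expect_true(all(diff(diff(f)) < 0))    # concave by finite differences
  expect_true(all(f >= 0 & f < 1))
  expect_error(implied_fit(1, 0), "positive")
  expect_error(implied_fit(-1, 12), "non-negative")
})

test_that("tree_score totals compose per-character Fitch lengths and fits", {
  m <- parse_matrix("A 000\nB 010\nC 100\nD 110\n")
  tr <- parse_tree("((A,B),(C,D));")
  ts <- tree_score(tr, m, iw_config(k = 12))
  expect_equal(ts$per_character$s, c(1L, 2L, 0L))
  expect_equal(ts$per_character$m, c(1L, 1L, 0L))
  expect_equal(ts$per_character$e, c(0L, 1L, 0L))
  expect_equal(ts$total_length, 3L)
  expect_equal(ts$total_fit, implied_fit(1, 12))
  expect_equal(sum(ts$per_character$f), ts$total_fit)

  const <- parse_matrix("A 11\nB 11\nC 11\nD 11\n")
  ts0 <- tree_score(tr, const)
  expect_equal(ts0$total_fit, 0)
  expect_equal(ts0$total_length, 0L)
})

test_that("characters with fewer than two observed tips score zero", {
  m <- parse_matrix("A 0?\nB ??\nC ?1\nD ??\n")
  ts <- tree_score(parse_tree("((A,B),(C,D));"), m)
  expect_equal(ts$total_length, 0L)
  expect_equal(ts$total_fit, 0)
})

test_that("scores are invariant to rooting and to matrix row order", {
  set.seed(409)
  for (i in 1:10) {
    tr <- simulate_tree(sample(5:10, 1))
    m <- random_morpho_matrix(length(tr$tip.label), 12, n_states = 3)
    m$taxa <- tr$tip.label  # align names
    rownames(m$mask) <- rownames(m$kind) <- m$taxa
    base <- tree_score(tr, m)
    reroot <- ape::root(ape::unroot(tr), outgroup = sample(tr$tip.label, 1),
                        resolve.root = TRUE)
    expect_equal(tree_score(reroot, m)$total_fit, base$total_fit)
    expect_equal(tree_score(ape::unroot(tr), m)$total_length, base$total_length)
    perm <- sample(seq_along(m$taxa))
    mp <- m
    mp$taxa <- m$taxa[perm]
    mp$mask <- m$mask[perm, , drop = FALSE]
    mp$kind <- m$kind[perm, , drop = FALSE]
    expect_equal(tree_score(tr, mp)$total_fit, base$total_fit)
  }
})

test_that("raw-length scoring reproduces equal-weights parsimony totals", {
  set.seed(410)
  tr <- simulate_tree(8)
  m <- random_morpho_matrix(8, 20)
  m$taxa <- tr$tip.label
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  ts <- tree_score(tr, m, iw_config(k = 12, score_kind = "raw_length"))
  expect_equal(ts$score, ts$total_length)
  expect_equal(ts$total_length, sum(ts$per_character$s))
  expect_lt(tree_score(tr, m)$total_fit, m$n_chars)
})
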