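test_that("attachment enumeration covers each unrooted edge exactly once", {
  expect_length(enumerate_attachments(parse_tree("((A,B),(C,D));")), 5L)
  set.seed(420)
  bb <- simulate_tree(20)
  expect_length(enumerate_attachments(bb), 2L * 20L - 3L)
  expect_length(enumerate_attachments(parse_tree("(A,B,C,D);")), 4L)
})

test_that("an all-missing fossil ties across every edge", {
  set.seed(421)
  bb <- simulate_tree(6)
  m <- random_morpho_matrix(6, 10)
  m$taxa <- bb$tip.label
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  # append an all-missing fossil row
  m$taxa <- c(m$taxa, "GHOST")
  m$mask <- rbind(m$mask, 0L)
  m$kind <- rbind(m$kind, "missing")
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  res <- place_fossil(bb, m, "GHOST")
  expect_length(res$argmax_set, 9L)
  expect_true(all(res$table$rank == 1L))
  expect_true(all(res$table$tie))
})

test_that("a duplicated extant row without homoplasy lands on its twin's edge", {
  set.seed(422)
  bb <- simulate_tree(6)
  cfg <- sim_config(n_tips = 6, n_chars = 60, rate = 0.05)
  m <- simulate_characters(bb, cfg)
  twin <- bb$tip.label[3]
  m$taxa <- c(m$taxa, "DOPPEL")
  m$mask <- rbind(m$mask, m$mask[twin, ])
  m$kind <- rbind(m$kind, m$kind[twin, ])
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  res <- place_fossil(bb, m, "DOPPEL")
  twin_ref <- enumerate_attachments(bb)[
    vapply(attr(fossilplace:::edge_table(bb), "clades"),
           function(cl) identical(cl, twin), logical(1))]
  expect_true(twin_ref %in% res$argmax_set)
})

test_that("placement rankings equal an independent naive implementation", {
  set.seed(423)
  for (i in 1:12) {
    full <- simulate_tree(7)
    cfg <- sim_config(n_tips = 7, n_chars = 20, rate = 0.2,
                      missing_fraction = 0.3)
    m <- simulate_characters(full, cfg)
    fossil <- sample(full$tip.label, 1)
    m <- fossilize(m, fossil, cfg, seed = NULL)
    bb <- ape::drop.tip(full, fossil)
    mine <- place_fossil(bb, m, fossil)
    oracle <- naive_place(bb, m, fossil, k = 12)
    at <- match(oracle$refs, mine$table$edge_ref)
    expect_setequal(mine$table$edge_ref, oracle$refs)
    expect_equal(mine$table$total_fit[at], oracle$fits, tolerance = 1e-9)
    expect_equal(mine$table$rank[at], oracle$rank)
  }
})

test_that("adding the fossil raises each character's length by zero or one", {
  set.seed(424)
  bb <- simulate_tree(8)
  cfg <- sim_config(n_tips = 8, n_chars = 40, rate = 0.3)
  m <- simulate_characters(bb, cfg)
  m$taxa <- c(m$taxa, "F")
  newrow <- m$mask[2, ]
  m$mask <- rbind(m$mask, newrow)
  m$kind <- rbind(m$kind, "observed")
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  base <- tree_score(bb, m)$per_character$s
  for (rf in enumerate_attachments(bb)) {
    aug <- attach_fossil(bb, rf, "F")
    delta <- tree_score(aug, m)$per_character$s - base
    expect_true(all(delta %in% c(0L, 1L)))
  }
})

test_that("every augmented score is at least the backbone's own score", {
  set.seed(425)
  bb <- simulate_tree(7)
  cfg <- sim_config(n_tips = 7, n_chars = 30, rate = 0.4)
  m <- simulate_characters(bb, cfg)
  m$taxa <- c(m$taxa, "F")
  m$mask <- rbind(m$mask, sample(c(1L, 2L), 30, replace = TRUE))
  m$kind <- rbind(m$kind, "observed")
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  res <- place_fossil(bb, m, "F")
  expect_true(all(res$table$total_length >= res$backbone_score$total_length))
  expect_true(all(res$table$total_length - res$backbone_score$total_length
                  <= m$n_chars))
})

test_that("clade restriction filters the ranking to edges inside the clade", {
  bb <- parse_tree("((A,B),(C,D));")
  m <- parse_matrix("A 00\nB 01\nC 11\nD 11\nF 01\n")
  res <- place_fossil(bb, m, "F", restrict_to = list(c("A", "B")))
  # the clade's two terminal branches plus its stem branch qualify
  expect_setequal(res$table$clade, c("A", "B", "A,B"))
  expect_error(place_fossil(bb, m, "F", restrict_to = list("nope")),
               "excludes every edge")
})

test_that("placement validates its preconditions", {
  bb <- parse_tree("((A,B),(C,D));")
  m <- parse_matrix("A 00\nB 01\nC 11\nD 11\nF 01\n")
  expect_error(place_fossil(bb, m, "NOPE"), "not found in the matrix")
  expect_error(place_fossil(bb, m, "A"), "already a backbone tip")
})

test_that("reported TSV and annotated Newick agree to the printed precision", {
  set.seed(426)
  bb <- simulate_tree(6)
  cfg <- sim_config(n_tips = 6, n_chars = 25, rate = 0.3)
  m <- simulate_characters(bb, cfg)
  m$taxa <- c(m$taxa, "F")
  m$mask <- rbind(m$mask, sample(c(1L, 2L), 25, replace = TRUE))
  m$kind <- rbind(m$kind, "observed")
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  res <- place_fossil(bb, m, "F")
  rep <- report_placements(res, digits = 2)

  expect_equal(nrow(rep$table), length(enumerate_attachments(bb)))
  # harvest annotations back out of the Newick and compare to the table
  reparsed <- parse_tree(rep$newick)
  tip_ann <- regmatches(reparsed$tip.label,
                        regexpr("[0-9]+\\.[0-9]{2}$", reparsed$tip.label))
  node_ann <- if (is.null(reparsed$node.label)) character(0) else
    reparsed$node.label[nzchar(reparsed$node.label)]
  got <- sort(as.numeric(c(tip_ann, node_ann)))
  want <- sort(round(res$table$total_fit, 2))
  # every tabled score appears somewhere among the branch labels
  expect_true(all(round(got, 2) %in% want))
  expect_length(got, nrow(res$table))
})

test_that("placement output is byte-deterministic across reruns", {
  set.seed(427)
  bb <- simulate_tree(6)
  cfg <- sim_config(n_tips = 6, n_chars = 20, rate = 0.3, seed = 99)
  m <- simulate_characters(bb, cfg)
  m$taxa <- c(m$taxa, "F")
  m$mask <- rbind(m$mask, sample(c(1L, 2L), 20, replace = TRUE))
  m$kind <- rbind(m$kind, "observed")
  rownames(m$mask) <- rownames(m$kind) <- m$taxa
  f1 <- tempfile()
  f2 <- tempfile()
  report_placements(place_fossil(bb, m, "F"), prefix = f1)
  report_placements(place_fossil(bb, m, "F"), prefix = f2)
  expect_identical(readLines(paste0(f1, ".placements.tsv")),
                   readLines(paste0(f2, ".placements.tsv")))
  expect_identical(unname(tools::md5sum(paste0(f1, ".annotated.nwk"))),
                   unname(tools::md5sum(paste0(f2, ".annotated.nwk"))))
})
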