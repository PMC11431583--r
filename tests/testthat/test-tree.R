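worked_text <- "CADCADCCACAECCACACEDDCADCABCCACAECCACACEDD"

test_that("nested decomposition recovers the worked-example hierarchy", {
  tree <- decompose_nested(worked_text, rq = 2)
  root <- tree$root
  expect_equal(vapply(root$children, `[[`, "", "sequence"),
               c("CCACAECCACACEDD", "CADCA"))
  mer15 <- root$children[[1]]
  expect_equal(vapply(mer15$children, `[[`, "", "sequence"), "CCACA")
  expect_equal(vapply(mer15$children[[1]]$children, `[[`, "", "sequence"), "CA")
  expect_equal(vapply(root$children[[2]]$children, `[[`, "", "sequence"), "CA")
  expect_equal(tree$stats$max_depth, 3L)
  # "CA" is a leaf
  expect_length(mer15$children[[1]]$children[[1]]$children, 0L)
  # full structural match against the recursive brute-force oracle
  expect_tree_matches_oracle(root, oracle_tree(worked_text, 2))
})

test_that("texts without repeats give a childless root", {
  tree <- decompose_nested("abcdef", rq = 2)
  expect_length(tree$root$children, 0L)
  expect_equal(tree$stats$max_depth, 0L)
  expect_equal(length(tree$root$noise$pos), 6L)
})

test_that("effective counts multiply along the ancestor chain", {
  fit <- nrsdm(worked_text, rq = 2)
  nodes <- tree_nodes(fit)
  expect_equal(nodes$effective_count[nodes$depth == 0], 1)
  expect_equal(nodes$q[nodes$depth == 0], 1)
  ccaca <- nodes[nodes$sequence == "CCACA", ]
  expect_equal(ccaca$effective_count, 4)
  expect_equal(ccaca$q, 20 / 42)
  ca <- nodes[nodes$sequence == "CA", ]
  expect_equal(sort(ca$effective_count), c(4, 8))
  expect_equal(sort(ca$q), c(8 / 42, 16 / 42))
  # depth-1 symbols reduce to the plain coverage probability
  d1 <- nodes[nodes$depth == 1, ]
  expect_equal(d1$q, coverage_probability(d1$count_in_parent, d1$length, 42))
})

walk_conservation <- function(node) {
  covered <- sum(vapply(node$children, function(ch) {
    ch$count_in_parent * nchar(ch$sequence)
  }, 0))
  here <- covered + length(node$noise$pos) == nchar(node$sequence)
  c(list(here), lapply(node$children, walk_conservation))
}

test_that("the root decomposition equals the flat repeat search", {
  set.seed(5)
  for (i in 1:10) {
    txt <- random_text(sample(10:60, 1), sample(2:4, 1))
    tree <- decompose_nested(txt, rq = 2)
    flat <- find_repeats(txt, rq = 2)
    expect_equal(vapply(tree$root$children, `[[`, "", "sequence"),
                 flat$symbols$sequence)
    expect_equal(vapply(tree$root$children, `[[`, 0L, "count_in_parent"),
                 flat$symbols$count)
    expect_equal(tree$root$noise$pos, flat$noise_positions)
    # per-node conservation at every node
    ok <- unlist(walk_conservation(tree$root))
    expect_true(all(ok), info = txt)
  }
})

test_that("sha256 matches the published test vectors", {
  expect_equal(nrsdm:::sha256_hex(""),
               "e3b0c44298fc1c149afbf4c8996fb92427ae41e4649b934ca495991b7852b855")
  expect_equal(nrsdm:::sha256_hex("abc"),
               "ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad")
  expect_equal(nrsdm:::sha256_hex(
    "abcdbcdecdefdefgefghfghighijhijkijkljklmklmnlmnomnopnopq"),
    "248d6a61d20638b8e5c026930c3e6039a33ce45964ff2167f6ecedd419db06c1")
})

test_that("tree digests are deterministic and structure-sensitive", {
  t1 <- decompose_nested(worked_text, rq = 2)
  t2 <- decompose_nested(worked_text, rq = 2)
  expect_identical(tree_hash(t1), tree_hash(t2))
  # golden digest of the worked-example tree (frozen from the oracle-verified run)
  expect_identical(tree_hash(t1),
                   "d7f836704d1b67a854e4bf09ed8e9edc090ea60c9b0580c99188e9e4c066e311")
  # altering one noise character changes the digest
  t3 <- t1
  t3$root$noise$char[1] <- "Z"
  expect_false(identical(tree_hash(t3), tree_hash(t1)))
  # altering a child count changes the digest
  t4 <- t1
  t4$root$children[[1]]$count_in_parent <- 3L
  expect_false(identical(tree_hash(t4), tree_hash(t1)))
})

test_that("node table is consistent with tree stats", {
  fit <- nrsdm(worked_text, rq = 2)
  nodes <- tree_nodes(fit)
  st <- fit$tree$stats
  expect_equal(nrow(nodes), st$n_nodes)
  expect_equal(max(nodes$depth), st$max_depth)
  expect_equal(sum(nodes$is_leaf), st$n_leaves)
  # node count <= 1 + sum of branching over non-leaf nodes
  expect_lte(nrow(nodes), 1 + sum(!nodes$is_leaf) * st$max_branching)
})
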