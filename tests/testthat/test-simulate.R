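test_that("the logistic map recursion hits its fixed point and validates input", {
  x <- may_map(2.5, 500, x0 = 0.5)
  expect_length(x, 500L)
  expect_equal(tail(x, 1), 1 - 1 / 2.5, tolerance = 1e-9)
  # post-transient discretization collapses to a single character
  txt <- discretize(tail(x, 100), build_scale("L: 8/4/0.01", x))
  expect_equal(length(unique(strsplit(txt, "")[[1]])), 1L)
  # tiny x0 decays towards 0 in the subcritical regime
  expect_lt(may_map(0.9, 50, x0 = 1e-12)[50], 1e-12)
  expect_error(may_map(3.5, 10, x0 = 0), "x0")
  expect_error(may_map(5, 10), "rho")
  expect_identical(may_map(3.7, 100, 0.42), may_map(3.7, 100, 0.42))
})

test_that("period doubling ladder is recovered independently of x0", {
  set.seed(31)
  expected <- c("3.2" = 2L, "3.5" = 4L, "3.56" = 8L)
  for (rho_s in names(expected)) {
    rho <- as.numeric(rho_s)
    for (x0 in runif(10, 0.05, 0.95)) {
      txt <- may_text(rho, 1001, x0)
      expect_equal(detect_period(txt, burn_in = 500), expected[[rho_s]],
                   info = paste(rho, x0))
    }
  }
})

test_that("period detection returns the fundamental period or NA", {
  expect_equal(detect_period("abababab", burn_in = 0), 2L)
  expect_equal(detect_period("aaaa", burn_in = 0), 1L)
  expect_identical(detect_period("abcdefgh", burn_in = 0), NA_integer_)
  # burn-in defaults to the first half
  expect_equal(detect_period(paste0("xq", strrep("ab", 20))), 2L)
})

test_that("Lorenz integration is deterministic, bounded, and respects equilibria", {
  sol <- lorenz_system(2000, dt = 0.005)
  expect_equal(nrow(sol), 2000L)
  expect_true(all(is.finite(as.matrix(sol))))
  # bounded on the classic attractor over the tested horizon
  expect_true(all(abs(sol$x) < 100) && all(abs(sol$z) < 150))
  # deterministic replay is bit-identical
  expect_identical(sol, lorenz_system(2000, dt = 0.005))
  # the origin is an equilibrium
  sol0 <- lorenz_system(10, init = c(0, 0, 0))
  expect_true(all(as.matrix(sol0[c("x", "y", "z")]) == 0))
  # C+ = (sqrt(beta(rho-1)), sqrt(beta(rho-1)), rho-1) is an equilibrium
  b <- 8 / 3; r <- 28
  cp <- c(sqrt(b * (r - 1)), sqrt(b * (r - 1)), r - 1)
  solc <- lorenz_system(10, init = cp)
  expect_equal(as.numeric(solc[10, c("x", "y", "z")]), cp, tolerance = 1e-8)
  expect_error(lorenz_system(10, dt = -1), "dt")
})

test_that("planted nested-periodic texts carry their ground truth", {
  gen <- nested_periodic_text("at", 3, 4, spacer = "q")
  expect_equal(gen$text, strrep("atatatq", 4))
  expect_equal(gen$truth$block_len, 7L)
  # same seed, same corrupted text
  g1 <- nested_periodic_text("ab", 3, 5, "z", noise_rate = 0.1, seed = 99)
  g2 <- nested_periodic_text("ab", 3, 5, "z", noise_rate = 0.1, seed = 99)
  expect_identical(g1$text, g2$text)
  expect_equal(length(g1$truth$noise_positions), round(0.1 * nchar(g1$text)))
  # corrupted characters are outside the planted alphabet
  ch <- strsplit(g1$text, "")[[1]][g1$truth$noise_positions + 1L]
  expect_true(all(ch %in% as.character(0:9)))
})

test_that("noise-free planted hierarchies are recovered by the decomposition", {
  # even outer counts tile completely, so the root keeps zero noise
  specs <- list(list("at", 3L, 4L, "q"), list("cg", 4L, 6L, "xy"),
                list("abc", 2L, 6L, "z"))
  for (sp in specs) {
    gen <- nested_periodic_text(sp[[1]], sp[[2]], sp[[3]], sp[[4]])
    tree <- decompose_nested(gen$text, rq = 2)
    nodes <- tree_nodes(tree)
    # the motif appears as a node, below some whole-block multiple node
    motif_rows <- nodes[nodes$sequence == gen$truth$motif, ]
    expect_gte(nrow(motif_rows), 1L)
    block_rows <- nodes[nodes$length %% gen$truth$block_len == 0 &
                          !is.na(nodes$parent), ]
    expect_gte(nrow(block_rows), 1L)
    expect_gt(min(motif_rows$depth), min(block_rows$depth))
    expect_gte(tree$stats$max_depth, 2L)
    # noise-free: full coverage at the root
    expect_equal(length(tree$root$noise$pos), 0L)
  }
})
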