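worked_text <- "CADCADCCACAECCACACEDDCADCABCCACAECCACACEDD"

test_that("non-overlapping occurrence counting is greedy and mask-aware", {
  expect_equal(count_nonoverlapping("aaaa", "aa"),
               list(count = 2L, positions = c(0L, 2L)))
  # long pattern in the worked-example text
  hit <- count_nonoverlapping(worked_text, "CCACAECCACACEDD")
  expect_equal(hit$count, 2L)
  expect_equal(hit$positions, c(6L, 27L))
  # a mask blocking the only occurrence
  mask <- c(FALSE, TRUE, FALSE)
  expect_equal(count_nonoverlapping("aba", "ab", mask)$count, 0L)
  expect_error(count_nonoverlapping("abc", ""), "non-empty")
})

test_that("greedy longest-first extraction matches the worked example", {
  r <- find_repeats(worked_text, rq = 2)
  expect_equal(r$symbols$sequence, c("CCACAECCACACEDD", "CADCA"))
  expect_equal(r$symbols$count, c(2L, 2L))
  expect_equal(r$noise_positions, c(5L, 26L))
  expect_equal(r$noise_chars, c("D", "B"))
  expect_equal(r$noise_fraction, 2 / 42)
  # matches the brute-force oracle exactly
  o <- oracle_asrsm(worked_text, 2)
  expect_equal(r$symbols$sequence, vapply(o$symbols, `[[`, "", "sequence"))
  expect_equal(r$symbols$positions,
               lapply(o$symbols, function(s) as.integer(s$positions)))
})

test_that("longest-first is honored and edge cases are sane", {
  # length floor(8/2) = 4 is found before the length-2 tiling
  r <- find_repeats("xyxyxyxy", rq = 2)
  expect_equal(r$symbols$sequence, "xyxy")
  expect_equal(r$symbols$count, 2L)
  expect_equal(r$noise_fraction, 0)
  # no repeats at all
  r2 <- find_repeats("abcdefgh", rq = 2)
  expect_equal(nrow(r2$symbols), 0L)
  expect_equal(r2$noise_fraction, 1)
  # a period-p text repeated a multiple of rq times is fully covered
  r3 <- find_repeats(strrep("abc", 6), rq = 3)
  expect_equal(r3$coverage_fraction, 1)
  r4 <- find_repeats(strrep("uv", 8), rq = 2)
  expect_equal(r4$coverage_fraction, 1)
  expect_error(find_repeats("abcd", rq = 1), "rq")
})

test_that("coverage probability and spectrogram follow the band identity", {
  expect_equal(coverage_probability(2, 15, 42), 30 / 42)
  expect_equal(coverage_probability(2, 4, 8), 1)       # full tiling
  expect_equal(coverage_probability(2, 1, 10000), 2e-4)
  expect_error(coverage_probability(2, 3, 0), "positive")

  sp <- spectrogram(find_repeats(worked_text, rq = 2))
  expect_equal(sp$length, c(5L, 15L))
  expect_equal(sp$frequency, c(2L, 2L))
  expect_equal(sp$prob, c(10 / 42, 30 / 42))
  # every row satisfies prob = f * l / L exactly
  expect_equal(sp$prob, sp$frequency * sp$length / 42)
  # empty result gives an empty spectrogram
  expect_equal(nrow(spectrogram(find_repeats("abcdef"))), 0L)
  # two distinct same-length symbols merge into one row
  txt <- paste0(strrep("aab", 2), strrep("ccd", 2), "xyz")
  r <- find_repeats(txt, rq = 2)
  sp2 <- spectrogram(r)
  row3 <- sp2[sp2$length == 3, ]
  expect_equal(row3$frequency, 4L)
  expect_equal(row3$prob, 4 * 3 / nchar(txt))
})

test_that("extraction equals the brute-force oracle on random texts", {
  set.seed(101)
  n_cases <- 250
  for (i in seq_len(n_cases)) {
    txt <- random_text(sample(2:60, 1), sample(2:6, 1))
    rq <- sample(2:3, 1)
    r <- find_repeats(txt, rq = rq)
    o <- oracle_asrsm(txt, rq = rq)
    expect_equal(r$symbols$sequence, vapply(o$symbols, `[[`, "", "sequence"),
                 info = txt)
    expect_equal(r$symbols$count,
                 vapply(o$symbols, function(s) as.integer(s$count), 0L),
                 info = txt)
    expect_equal(r$noise_positions, as.integer(o$noise_positions), info = txt)
    # conservation: sum g*l + noise = L
    expect_equal(sum(r$symbols$count * r$symbols$length) + length(r$noise_positions),
                 nchar(txt), info = txt)
    # disjointness: locked intervals plus noise partition [0, L)
    covered <- unlist(lapply(seq_len(nrow(r$symbols)), function(k) {
      unlist(lapply(r$symbols$positions[[k]],
                    function(p) p + seq_len(r$symbols$length[k]) - 1L))
    }))
    expect_equal(sort(c(covered, r$noise_positions)), 0:(nchar(txt) - 1L),
                 info = txt)
  }
})
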