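test_that("source constructors validate and expose the design tables", {
  expect_equal(probTable(lvl0)[1, "B"], 0.72)
  expect_equal(markovOrder(lvl0), 0L)
  expect_equal(unname(probTable(rnd)[1, ]), rep(0.25, 4))
  expect_error(makeLevel0Source(c(0.18, 0.72, 0.05, 0.06)), "sum to 1")
  expect_error(makeLevel0Source(c(-0.1, 0.9, 0.1, 0.1)), "non-negative")

  expect_equal(probTable(lvl1)["A", "B"], 0.8)
  expect_equal(probTable(lvl1)["A", "C"], 0.2)
  expect_true(all(rowSums(probTable(lvl1) > 0) == 2))
  ## three allowed targets in one row violates strict mode
  bad <- canonicalLevel1Table()
  bad["A", ] <- c(0.1, 0.7, 0.2, 0)
  expect_error(makeLevel1Source(bad), "strict")
  ## deterministic chain admitted without strict mode, entropy rate 0
  expect_equal(entropyRateBits(summarizeSource(cyclicSource())), 0)
})

test_that("stationary distribution matches a linear-solve oracle and flags reducible chains", {
  expect_equal(unname(stationaryDistribution(lvl1)),
               stationaryOracle(probTable(lvl1)),
               tolerance = 1e-8)
  expect_equal(unname(stationaryDistribution(lvl1)), rep(0.25, 4),
               tolerance = 1e-8)
  ## two disjoint closed classes: {A,B} and {C,D}
  P <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  P["A", "B"] <- 1; P["B", "A"] <- 1; P["C", "D"] <- 1; P["D", "C"] <- 1
  red <- makeLevel1Source(P, strict = FALSE, label = "reducible")
  expect_error(stationaryDistribution(red), "A,B")
  expect_error(stationaryDistribution(red), "C,D")
})

test_that("entropy, entropy rate and complexity reproduce the design constants", {
  s1 <- summarizeSource(lvl1)
  expect_equal(marginalEntropyBits(s1), 2, tolerance = 1e-9)
  expect_equal(entropyRateBits(s1), -0.8 * log2(0.8) - 0.2 * log2(0.2),
               tolerance = 1e-9)
  expect_equal(round(complexityBits(s1), 2), 1.28)
  ## memory-less sources carry no predictive structure
  expect_identical(complexityBits(summarizeSource(lvl0)), 0)
  expect_identical(complexityBits(summarizeSource(rnd)), 0)
  ## entropy ordering holds for an arbitrary source
  set.seed(42)
  for (i in 1:5) {
    src <- makeLevel1Source(randomTable(minp = 0.01), strict = FALSE)
    s <- summarizeSource(src)
    expect_gte(entropyRateBits(s), 0)
    expect_lte(entropyRateBits(s), marginalEntropyBits(s) + 1e-9)
    expect_lte(marginalEntropyBits(s), 2 + 1e-9)
  }
})

test_that("sequence generation is reproducible and matches the source statistics", {
  s1 <- generateSequence(lvl0, 672, seed = 7)
  s2 <- generateSequence(lvl0, 672, seed = 7)
  expect_identical(symbols(s1), symbols(s2))
  expect_length(symbols(s1), 672)
  expect_equal(mean(symbols(s1) == "B"), 0.72, tolerance = 0.06)
  expect_false(identical(symbols(generateSequence(lvl0, 672, seed = 8)),
                         symbols(s1)))
  ## uniform source at n = 10000: binomial sampling-error bound
  su <- generateSequence(rnd, 10000, seed = 1)
  freqs <- table(factor(symbols(su), levels = alphabet(rnd))) / 10000
  expect_true(all(abs(freqs - 0.25) < 0.02))
  ## deterministic cycle continues uniquely from its initial context
  cyc <- generateSequence(cyclicSource(), 8, seed = 3, initialContext = "A")
  expect_identical(paste0(symbols(cyc), collapse = ""), "BCDABCDA")
  expect_error(generateSequence(lvl0, 0), "positive")
})

test_that("empirical conditional tables converge to the source table", {
  ## trivial direct counts
  expect_equal(empiricalTable("ABAB", 1)$probs["A", "B"], 1)
  expect_equal(empiricalTable("ABAB", 1)$probs["B", "A"], 1)
  e0 <- empiricalTable("AAAB", 0)
  expect_equal(unname(e0$probs[1, c("A", "B")]), c(0.75, 0.25))
  expect_equal(sum(e0$counts), 4L)
  ## a 672-symbol sample: each conditional within binomial tolerance
  s <- generateSequence(lvl1, 672, seed = 7)
  emp <- empiricalTable(s, 1)
  expect_true(all(abs(emp$probs - probTable(lvl1)[rownames(emp$probs), ]) < 0.05))
  ## 3-sd convergence at n = 10000 at the realized context counts
  big <- generateSequence(lvl1, 10000, seed = 2)
  emp <- empiricalTable(big, 1)
  n_c <- rowSums(emp$counts)
  Q <- probTable(lvl1)[rownames(emp$probs), ]
  tol <- 3 * sqrt(Q * (1 - Q) / n_c)
  expect_true(all(abs(emp$probs - Q) <= pmax(tol, 1e-12)))
  expect_error(empiricalTable("AB", 2), "exceed")
})

test_that("KL divergence to the source matches hand and enumeration oracles", {
  ## a sequence reproducing the source table exactly has zero divergence
  exact <- seqFromString(paste0(rep(c(rep("A", 18), rep("B", 72),
                                      rep("C", 5), rep("D", 5)), 1),
                                collapse = ""))
  expect_equal(klToSource(exact, lvl0), 0, tolerance = 1e-12)
  ## single-symbol sequence: -log2(source probability)
  expect_equal(klToSource("BBBB", lvl0), -log2(0.72), tolerance = 1e-12)
  ## term-by-term enumeration oracle on fixed frequencies (0.2, 0.7, 0.05, 0.05)
  s <- seqFromString(paste0(c(rep("A", 20), rep("B", 70), rep("C", 5),
                              rep("D", 5)), collapse = ""))
  manual <- 0.2 * log2(0.2 / 0.18) + 0.7 * log2(0.7 / 0.72) +
    0.05 * log2(0.05 / 0.05) + 0.05 * log2(0.05 / 0.05)
  expect_equal(klToSource(s, lvl0), manual, tolerance = 1e-12)
  ## empirical mass on a source-impossible target flags infinity
  expect_identical(klToSource("AD", cyclicSource()), Inf)
  expect_error(klToSource("ABXE", lvl0), "outside")
  ## non-negativity on sampled sequences
  for (seed in 1:5)
    expect_gte(klToSource(generateSequence(lvl1, 300, seed = seed), lvl1), 0)
})

test_that("sequence selection keeps the lowest-divergence candidates deterministically", {
  sel <- selectSequences(lvl0, 200, 672, 10, seed = 3)
  expect_length(sel, 10)
  kl <- attr(sel, "allKL")
  kept <- vapply(sel, function(s) s@kl, 1.0)
  expect_false(is.unsorted(kept))
  expect_lte(max(kept), min(sort(kl)[11:200]))
  expect_lt(mean(kept), mean(kl))
  ## recomputing a kept sequence's divergence reproduces its stored value
  expect_equal(klToSource(sel[[1]], lvl0), kept[[1]], tolerance = 1e-12)
  ## determinism and keep-all
  sel2 <- selectSequences(lvl0, 200, 672, 10, seed = 3)
  expect_identical(lapply(sel, symbols), lapply(sel2, symbols))
  all5 <- selectSequences(lvl1, 5, 100, 5, seed = 1)
  expect_length(all5, 5)
  expect_error(selectSequences(lvl0, 5, 100, 6, seed = 1), "nKeep")
})

test_that("per-sequence entropy rate uses within-sequence context weights", {
  expect_equal(sequenceEntropyRate("ABABABAB", 1), 0)
  expect_equal(sequenceEntropyRate("AABB", 0), 1)
  s <- generateSequence(lvl1, 672, seed = 7)
  expect_equal(sequenceEntropyRate(s, 1), -0.8 * log2(0.8) - 0.2 * log2(0.2),
               tolerance = 0.05)
})
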