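test_that("AbDist is the L1 distance between response and target distributions", {
  p <- c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)
  q <- c(A = 0.18, B = 0.72, C = 0.05, D = 0.05)
  expect_equal(abDist(p, p), 0)
  expect_equal(abDist(p, q), 0.07 + 0.47 + 0.20 + 0.20, tolerance = 1e-12)
  expect_equal(abDist(c(A = 1, B = 0), c(A = 0, B = 1)), 2)
  expect_error(abDist(c(A = 0.5, B = 0.5), c(X = 0.5, Y = 0.5)),
               "different alphabets")
  expect_error(abDist(c(A = 0.5, B = 0.6), c(A = 0.5, B = 0.5)), "sum to 1")
})

test_that("the random-guess baseline reproduces the printed values", {
  expect_equal(round(piRand(lvl0), 2), 0.53)
  expect_equal(round(piRand(lvl1), 2), 0.45)
  expect_equal(piRand(rnd), 1)
  ## closed form for any order-0 source: 1 - sum(|p - 0.25|)/2
  set.seed(3)
  for (i in 1:5) {
    p <- stats::runif(4); p <- p / sum(p)
    src <- makeLevel0Source(p)
    expect_equal(piRand(src), 1 - sum(abs(p - 0.25)) / 2, tolerance = 1e-12)
  }
})

test_that("the Performance Index scores constructed response sets exactly", {
  ## responses reproducing the source distribution exactly: PI = 1
  exact <- responsesFromCounts(setNames(list(c(A = 18, B = 72, C = 5, D = 5)), ""))
  repE <- performanceIndex(exact, lvl0)[[1]]
  expect_equal(repE@pi, 1)
  ## uniform responses against the frequency source: PI = 0.53
  unif <- responsesFromCounts(setNames(list(c(A = 25, B = 25, C = 25, D = 25)), ""))
  repU <- performanceIndex(unif, lvl0)[[1]]
  expect_equal(repU@pi, 0.53)
  expect_equal(repU@piNormalized, 0, tolerance = 1e-12)
  ## all-B responses (a perfect maximizer): PI = 0.72
  maxi <- responsesFromCounts(setNames(list(c(A = 0, B = 100, C = 0, D = 0)), ""))
  expect_equal(performanceIndex(maxi, lvl0)[[1]]@pi,
               1 - (0.18 + 0.28 + 0.05 + 0.05) / 2)
  ## per-context identity PI = 1 - AbDist/2 and the weighted mean
  r1 <- responsesFromCounts(list(A = c(A = 0, B = 8, C = 2, D = 0),
                                 B = c(A = 0, B = 0, C = 10, D = 0),
                                 C = c(A = 2, B = 0, C = 0, D = 8),
                                 D = c(A = 10, B = 0, C = 0, D = 0)))
  rep1 <- performanceIndex(r1, lvl1)[[1]]
  expect_equal(rep1@perContextPI, 1 - rep1@perContextAbDist / 2)
  expect_equal(rep1@pi, sum(0.25 * rep1@perContextPI), tolerance = 1e-12)
  expect_error(performanceIndex(new("ResponseSet",
                                    records = records(r1)[0, ],
                                    alphabet = alphabet(r1)), lvl1),
               "empty")
})

test_that("unobserved contexts contribute their random-guess overlap", {
  ## only context A answered; B, C, D rows fall back to uniform guessing
  partial <- responsesFromCounts(list(A = c(A = 0, B = 8, C = 2, D = 0)))
  rep <- performanceIndex(partial, lvl1)[[1]]
  unifPI <- 1 - abDist(rep(0.25, 4), c(0.8, 0.2, 0, 0)) / 2
  expect_equal(unname(rep@perContextPI["B"]), unifPI, tolerance = 1e-12)
  piA <- 1 - abDist(c(0, 0.8, 0.2, 0), probTable(lvl1)["A", ]) / 2
  expect_equal(rep@pi, 0.25 * piA + 0.75 * unifPI, tolerance = 1e-12)
})

test_that("the empirical reference scores a replay of the realized targets as perfect", {
  blk <- partitionBlock(generateSequence(lvl1, 672, seed = 2), seed = 2)
  tr <- trials(blk)
  replay <- new("ResponseSet",
                records = data.frame(responderId = "replay", blockIndex = 1L,
                                     trialIndex = tr$trial,
                                     context = substring(tr$context,
                                                         tr$length, tr$length),
                                     choice = tr$target, isNull = FALSE,
                                     stringsAsFactors = FALSE),
                alphabet = alphabet(lvl1))
  rep <- performanceIndex(replay, lvl1, reference = "empirical",
                          blocks = list(blk))[[1]]
  expect_equal(rep@pi, 1)
  expect_error(performanceIndex(replay, lvl1, reference = "empirical"),
               "blocks")
})

test_that("matcher responders beat the random-guess baseline on 56-trial blocks", {
  blocks <- makeTrainingDesign(lvl1, nSessions = 1L, seed = 21L,
                               nGenerate = 60L, poolSize = 10L)
  m <- responderModel("matcher", seed = 31)
  reports <- performanceIndex(simulateResponses(m, blocks, lvl1), lvl1)
  pis <- vapply(reports, function(r) r@pi, 1.0)
  expect_true(all(pis > piRand(lvl1)))
})

test_that("accuracy counts exact target predictions with nulls incorrect", {
  blk <- partitionBlock(generateSequence(lvl1, 672, seed = 5), seed = 5)
  tr <- trials(blk)
  mk <- function(choice, isNull = FALSE)
    new("ResponseSet",
        records = data.frame(responderId = "a", blockIndex = 1L,
                             trialIndex = tr$trial,
                             context = substring(tr$context, tr$length,
                                                 tr$length),
                             choice = choice, isNull = isNull,
                             stringsAsFactors = FALSE),
        alphabet = alphabet(lvl1))
  expect_equal(accuracy(mk(tr$target), list(blk)), 1)
  expect_equal(accuracy(mk(NA_character_, TRUE), list(blk)), 0)
  ## pure maximizer approaches the 0.8 modal-target rate on many trials
  nTrials <- 4000L
  s <- generateSequence(lvl1, nTrials * 9L, seed = 6)
  big <- partitionBlock(s, lengthsSpec = rep(8L, nTrials), seed = 6)
  r <- simulateResponses(responderModel("maximizer", seed = 9), list(big), lvl1)
  expect_equal(accuracy(r, list(big)), 0.8, tolerance = 0.03)
})
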