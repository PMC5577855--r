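test_that("baseline models floor and renormalize as specified", {
  ## matching model equals the source table when all entries exceed the floor
  expect_equal(baselineModel(lvl0, "matching", epsilon = 0.01),
               probTable(lvl0))
  ## maximization with floor 0.01: (0.01, 1, 0.01, 0.01) / 1.03
  mx <- baselineModel(lvl0, "maximization", epsilon = 0.01)
  expect_equal(unname(mx[1, ]), c(0.01, 1, 0.01, 0.01) / 1.03,
               tolerance = 1e-12)
  expect_equal(round(unname(mx[1, ]), 2), c(0.01, 0.97, 0.01, 0.01))
  ## epsilon 0 leaves the degenerate point mass; KL from any spread
  ## responder is then flagged infinite
  mx0 <- baselineModel(lvl1, "maximization", epsilon = 0)
  expect_true(all(rowSums(mx0 == 1) == 1))
  spread <- matrix(0.25, 4, 4, dimnames = dimnames(mx0))
  expect_identical(klRM(spread, mx0), Inf)
  ## ambiguous modal target under strict mode
  tie <- makeLevel0Source(c(0.4, 0.4, 0.1, 0.1))
  expect_error(baselineModel(tie, "maximization", strict = TRUE),
               "non-unique")
  ## rows stay stochastic after smoothing
  expect_equal(rowSums(baselineModel(lvl1, "maximization", 0.05)),
               c(A = 1, B = 1, C = 1, D = 1), tolerance = 1e-12)
})

test_that("response models are epsilon-floored empirical tables", {
  r <- responsesFromCounts(list(A = c(A = 0, B = 10, C = 0, D = 0)))
  R0 <- responseModel(r, 1, epsilon = 0)
  expect_equal(unname(R0["A", ]), c(0, 1, 0, 0))
  expect_equal(unname(R0["B", ]), rep(0.25, 4))  # unobserved -> uniform
  R <- responseModel(r, 1, epsilon = 0.01)
  expect_true(all(R >= 0.01 / (1 + 4 * 0.01) - 1e-12))
  expect_equal(rowSums(R), c(A = 1, B = 1, C = 1, D = 1), tolerance = 1e-12)
  empty <- new("ResponseSet",
               records = data.frame(responderId = "x", blockIndex = 1L,
                                    trialIndex = 1L, context = "A",
                                    choice = NA_character_, isNull = TRUE),
               alphabet = c("A", "B", "C", "D"))
  expect_error(responseModel(empty, 1), "non-null")
})

test_that("context-weighted KL matches a scalar enumeration oracle", {
  ## hand example: one context, R = (1,0), M = (0.5,0.5) -> 1 bit
  R <- matrix(c(1, 0), 1, dimnames = list("", c("A", "B")))
  M <- matrix(c(0.5, 0.5), 1, dimnames = list("", c("A", "B")))
  expect_equal(klRM(R, M), 1)
  expect_equal(klRM(R, R), 0)
  ## random tables against the brute-force oracle, 1e-12
  set.seed(17)
  for (i in 1:20) {
    R <- randomTable(); M <- randomTable(minp = 0.01)
    w <- stats::runif(4); w <- w / sum(w); names(w) <- rownames(R)
    expect_equal(klRM(R, M, w), klOracle(R, M, w), tolerance = 1e-12)
    expect_gte(klRM(R, M, w), 0)            # Gibbs inequality
    expect_equal(klRM(R, R, w), 0)          # identity of indiscernibles
  }
  expect_error(klRM(randomTable(), matrix(0.5, 2, 2)), "same contexts")
})

test_that("strategy choice separates matching from maximization and crosses zero", {
  nTrials <- 4000L
  s <- generateSequence(lvl1, nTrials * 9L, seed = 12)
  big <- partitionBlock(s, lengthsSpec = rep(8L, nTrials), seed = 12)
  rMatch <- simulateResponses(responderModel("matcher", seed = 1),
                              list(big), lvl1)
  rMax <- simulateResponses(responderModel("maximizer", seed = 1),
                            list(big), lvl1)
  expect_lt(strategyChoice(rMatch, lvl1), 0)
  expect_gt(strategyChoice(rMax, lvl1), 0)
  ## Delta-KL is linear in the response table (the R*log R terms cancel),
  ## so the exact zero crossing is solvable: R placed where the two
  ## log-ratio terms balance
  eps <- 0.05
  Mmatch <- baselineModel(lvl0, "matching", eps)
  Mmax <- baselineModel(lvl0, "maximization", eps)
  g <- log2(Mmax[1, ] / Mmatch[1, ])
  ## two-point response on B and C balancing g
  rB <- g["C"] / (g["C"] - g["B"])
  R <- matrix(c(0, rB, 1 - rB, 0), 1,
              dimnames = list("", c("A", "B", "C", "D")))
  expect_equal(klRM(R, Mmatch) - klRM(R, Mmax), 0, tolerance = 1e-12)
  ## mixtures interpolate monotonically between the two poles
  mixAt <- function(w) {
    Rw <- w * Mmax + (1 - w) * Mmatch
    klRM(Rw, Mmatch) - klRM(Rw, Mmax)
  }
  vals <- vapply(seq(0, 1, 0.25), mixAt, 1.0)
  expect_true(all(diff(vals) > 0))
  expect_lt(vals[1], 0); expect_gt(vals[5], 0)
})

test_that("strategy curves and the integrated index follow their closed forms", {
  ## constant curve at v over n blocks: index = (v - v_baseline) * (n - 1)
  v <- 0.3; n <- 6L
  curve <- new("StrategyCurve", values = rep(v, n),
               blockIndices = seq_len(n), responderId = "const",
               levelLabel = "level1")
  idx <- strategyIndex(curve, lvl1, epsilon = 0.05)
  eps <- 0.05
  w <- stationaryDistribution(lvl1, "context")
  v0 <- -klRM(baselineModel(lvl1, "matching", eps),
              baselineModel(lvl1, "maximization", eps), w)
  expect_equal(indexValue(idx), (v - v0) * (n - 1), tolerance = 1e-12)
  ## a participant replaying the baseline scores zero
  base <- new("StrategyCurve", values = rep(v0, n),
              blockIndices = seq_len(n), responderId = "base",
              levelLabel = "level1")
  expect_equal(indexValue(strategyIndex(base, lvl1, epsilon = eps)), 0,
               tolerance = 1e-12)
  ## the opposite convention flips the sign
  expect_equal(indexValue(strategyIndex(curve, lvl1, epsilon = eps,
                                        convention = "matching-minus-participant")),
               -indexValue(idx), tolerance = 1e-12)
  expect_error(strategyIndex(new("StrategyCurve", values = 1,
                                 blockIndices = 1L, responderId = "x",
                                 levelLabel = "y"), lvl1),
               "at least 2")
})

test_that("the strategy index is monotone in the mixture weight toward maximization", {
  blocks <- makeTrainingDesign(lvl1, nSessions = 1L, blocksPerSession = 5L,
                               seed = 41L, nGenerate = 60L, poolSize = 10L)
  idxAt <- function(ceiling) {
    m <- responderModel("mixture", schedule = rep(ceiling, 5),
                        asymptoticPolicy = "maximizer", seed = 13,
                        id = sprintf("w%g", ceiling))
    r <- simulateResponses(m, blocks, lvl1)
    indexValue(strategyIndex(strategyCurve(r, lvl1), lvl1))
  }
  vals <- vapply(c(0, 0.5, 1), idxAt, 1.0)
  expect_true(all(diff(vals) > 0))
})
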