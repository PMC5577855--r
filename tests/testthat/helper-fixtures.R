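## Shared fixtures: canonical sources, small designs and independent
## oracles used across test files.

lvl0 <- makeLevel0Source()
lvl1 <- makeLevel1Source()
rnd <- makeRandomSource()

## Deterministic 4-cycle: A -> B -> C -> D -> A with probability 1.
cyclicSource <- function() {
  P <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  P["A", "B"] <- 1; P["B", "C"] <- 1; P["C", "D"] <- 1; P["D", "A"] <- 1
  makeLevel1Source(P, strict = FALSE, label = "cycle")
}

## A SymbolSequence from a plain string.
seqFromString <- function(s, alphabet = c("A", "B", "C", "D")) {
  new("SymbolSequence", symbols = strsplit(s, "")[[1]],
      alphabet = alphabet, sourceLabel = "fixture", seed = NA_integer_,
      kl = NA_real_, id = "fix")
}

## Training design: nSessions x blocksPerSession blocks with global block
## indices, drawn from a freshly selected pool.
makeTrainingDesign <- function(source, nSessions = 4L, blocksPerSession = 5L,
                               seed = 11L, poolSize = 50L, nGenerate = 200L) {
  pool <- selectSequences(source, nGenerate, 672L, poolSize, seed = seed)
  blocks <- list()
  for (s in seq_len(nSessions)) {
    sess <- buildTrainingSession(source, pool, blocksPerSession,
                                 seed = seed + s)
    for (b in seq_along(sess))
      sess[[b]]@blockIndex <- (s - 1L) * blocksPerSession + b
    blocks <- c(blocks, sess)
  }
  blocks
}

## A ResponseSet built directly from per-context choice counts (order-0:
## single empty context). countsByContext: named list context -> named
## integer vector of choice counts.
responsesFromCounts <- function(countsByContext,
                                alphabet = c("A", "B", "C", "D"),
                                blockIndex = 1L) {
  rows <- do.call(rbind, lapply(seq_along(countsByContext), function(i) {
    cnt <- countsByContext[[i]]
    data.frame(context = names(countsByContext)[i],
               choice = rep(names(cnt), cnt), stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  new("ResponseSet",
      records = data.frame(responderId = "fixture",
                           blockIndex = as.integer(blockIndex),
                           trialIndex = seq_len(n), context = rows$context,
                           choice = rows$choice, isNull = FALSE,
                           stringsAsFactors = FALSE),
      alphabet = alphabet)
}

## Independent stationary-distribution oracle: linear solve of pi P = pi,
## sum(pi) = 1 (no power iteration).
stationaryOracle <- function(P) {
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  as.numeric(qr.solve(A, b))
}

## Independent KL oracle: scalar double loop, no vectorization shared with
## the implementation.
klOracle <- function(R, M, w) {
  total <- 0
  for (i in seq_len(nrow(R))) {
    for (j in seq_len(ncol(R))) {
      if (R[i, j] > 0) {
        if (M[i, j] == 0) return(Inf)
        total <- total + w[[i]] * R[i, j] * log2(R[i, j] / M[i, j])
      }
    }
  }
  as.numeric(total)
}

## Random row-stochastic 4x4 table.
randomTable <- function(minp = 0) {
  P <- matrix(stats::runif(16, min = minp), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  P / rowSums(P)
}
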