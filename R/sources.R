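## Markov sources: construction, sampling, information-theoretic summaries,
## KL divergence of sequences to their source, and KL-based sequence selection.

.DEFAULT_ALPHABET <- c("A", "B", "C", "D")

#' Zero-order (memory-less) Markov source
#'
#' Builds an order-0 source in which each symbol occurs independently with a
#' fixed probability. The frequency-statistics condition of the experiment
#' uses occurrence probabilities 0.18, 0.72, 0.05 and 0.05 for symbols A-D;
#' the familiarization/control condition uses the uniform 0.25 source
#' ([makeRandomSource()]).
#'
#' @param probs Numeric vector of occurrence probabilities, one per alphabet
#'   symbol, summing to 1 (tolerance 1e-9).
#' @param alphabet Symbol labels (default `A, B, C, D`).
#' @param label Source label.
#' @return A [MarkovSource-class] of order 0.
#' @examples
#' lvl0 <- makeLevel0Source()
#' probTable(lvl0)
#' @export
makeLevel0Source <- function(probs = c(0.18, 0.72, 0.05, 0.05),
                             alphabet = .DEFAULT_ALPHABET,
                             label = "level0") {
  probs <- as.numeric(probs)
  if (length(probs) != length(alphabet))
    stop("need exactly one probability per alphabet symbol")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop(sprintf("probabilities must be non-negative and sum to 1 (sum = %g)",
                 sum(probs)))
  P <- matrix(probs, nrow = 1L, dimnames = list("", alphabet))
  new("MarkovSource", alphabet = alphabet, order = 0L, probs = P,
      label = label)
}

#' Uniform random source
#'
#' Order-0 source presenting all four symbols with equal probability 25%,
#' used for familiarization and as the untrained control condition.
#'
#' @inheritParams makeLevel0Source
#' @return A [MarkovSource-class] of order 0.
#' @export
makeRandomSource <- function(alphabet = .DEFAULT_ALPHABET, label = "random") {
  makeLevel0Source(rep(1 / length(alphabet), length(alphabet)),
                   alphabet = alphabet, label = label)
}

#' Canonical first-order transition matrix
#'
#' The default context-by-target matrix for the context-statistics condition:
#' each context allows exactly two targets with probabilities 0.8 and 0.2
#' (A->B/C, B->C/D, C->D/A, D->A/B). Its stationary symbol distribution is
#' uniform, so the marginal entropy attains the 2-bit maximum while the
#' entropy rate is the binary entropy of (0.8, 0.2).
#'
#' @param alphabet Symbol labels (default `A, B, C, D`).
#' @return A 4x4 row-stochastic matrix with contexts as rownames.
#' @export
canonicalLevel1Table <- function(alphabet = .DEFAULT_ALPHABET) {
  n <- length(alphabet)
  P <- matrix(0, n, n, dimnames = list(alphabet, alphabet))
  for (i in seq_len(n)) {
    P[i, alphabet[(i %% n) + 1L]] <- 0.8
    P[i, alphabet[((i + 1L) %% n) + 1L]] <- 0.2
  }
  P
}

#' First-order Markov source
#'
#' Builds an order-1 source from a context-by-target transition matrix. By
#' default (`strict = TRUE`) every context row must place its mass on exactly
#' two targets, mirroring the experimental design in which only two symbols
#' may follow any context; set `strict = FALSE` to admit arbitrary
#' row-stochastic matrices (e.g. deterministic chains).
#'
#' @param rows Row-stochastic matrix with one row per context symbol and one
#'   column per target symbol. Defaults to [canonicalLevel1Table()].
#' @param alphabet Symbol labels.
#' @param label Source label.
#' @param strict Require exactly two non-zero targets per context row.
#' @return A [MarkovSource-class] of order 1.
#' @examples
#' lvl1 <- makeLevel1Source()
#' summarizeSource(lvl1)
#' @export
makeLevel1Source <- function(rows = canonicalLevel1Table(alphabet),
                             alphabet = .DEFAULT_ALPHABET,
                             label = "level1", strict = TRUE) {
  rows <- as.matrix(rows)
  if (is.null(rownames(rows))) rownames(rows) <- alphabet
  if (is.null(colnames(rows))) colnames(rows) <- alphabet
  rows <- rows[alphabet, alphabet, drop = FALSE]
  if (strict) {
    nz <- rowSums(rows > 1e-12)
    if (any(nz != 2L))
      stop(sprintf("strict mode: contexts with != 2 allowed targets: %s",
                   paste(rownames(rows)[nz != 2L], collapse = ", ")))
  }
  new("MarkovSource", alphabet = alphabet, order = 1L, probs = rows,
      label = label)
}

## ---- stationary distribution ------------------------------------------

## Context-level transition matrix: context c emits target t with P[c, t]
## and moves to the shifted context.
.contextTransition <- function(source) {
  k <- source@order
  ctxs <- rownames(source@probs)
  n <- length(ctxs)
  TM <- matrix(0, n, n, dimnames = list(ctxs, ctxs))
  for (i in seq_len(n)) {
    for (t in source@alphabet) {
      p <- source@probs[i, t]
      if (p > 0) {
        j <- match(.shiftContext(ctxs[i], t, k), ctxs)
        TM[i, j] <- TM[i, j] + p
      }
    }
  }
  TM
}

## Closed communicating classes of a non-negative transition matrix.
.closedClasses <- function(TM) {
  A <- TM > 0
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | outer(R[, k], R[k, ])
  comm <- R & t(R)
  key <- apply(comm, 1L, function(row) paste(which(row), collapse = ","))
  classes <- lapply(unique(key), function(k) which(key == k))
  Filter(function(cl) {
    out <- setdiff(which(apply(A[cl, , drop = FALSE], 2L, any)), cl)
    length(out) == 0L
  }, classes)
}

#' Stationary distribution of a Markov source
#'
#' Computed by power iteration on the lazy chain `(P + I)/2` (which shares
#' the stationary distribution and is aperiodic by construction) to a 1e-10
#' max-norm tolerance. A chain with more than one closed communicating class
#' has no unique stationary distribution and raises an error naming the
#' offending states.
#'
#' @param source A [MarkovSource-class].
#' @param what `"symbol"` for the stationary distribution over alphabet
#'   symbols (default), `"context"` for the distribution over length-k
#'   contexts (identical for order 1; a point mass on the empty context for
#'   order 0).
#' @param tol Max-norm convergence tolerance.
#' @return Named numeric distribution.
#' @export
stationaryDistribution <- function(source, what = c("symbol", "context"),
                                   tol = 1e-10) {
  what <- match.arg(what)
  stopifnot(is(source, "MarkovSource"))
  if (source@order == 0L) {
    ctx <- c(1); names(ctx) <- ""
    if (what == "context") return(ctx)
    return(source@probs[1L, ])
  }
  TM <- .contextTransition(source)
  closed <- .closedClasses(TM)
  if (length(closed) > 1L) {
    stop(sprintf(
      "no unique stationary distribution: disjoint closed state sets {%s}",
      paste(vapply(closed, function(cl)
        paste(rownames(TM)[cl], collapse = ","), ""), collapse = "} {")))
  }
  n <- nrow(TM)
  L <- (TM + diag(n)) / 2
  pi <- rep(1 / n, n)
  for (it in seq_len(100000L)) {
    newpi <- as.numeric(pi %*% L)
    if (max(abs(newpi - pi)) < tol) { pi <- newpi; break }
    pi <- newpi
  }
  pi <- pi / sum(pi)
  names(pi) <- rownames(TM)
  if (what == "context") return(pi)
  ## distribution of the next emitted symbol under stationarity
  m <- as.numeric(pi %*% source@probs)
  names(m) <- source@alphabet
  m
}

#' Entropy, entropy rate and complexity of a source
#'
#' The marginal entropy is the Shannon entropy (bits) of the stationary
#' symbol distribution; the entropy rate is the stationary-context-weighted
#' average of the conditional target entropies; their difference is the
#' predictive complexity (average past-future mutual information) of the
#' source. For an order-0 source the entropy rate equals the marginal
#' entropy and the complexity is exactly 0.
#'
#' @param source A [MarkovSource-class].
#' @return A [SourceSummary-class].
#' @examples
#' complexityBits(summarizeSource(makeLevel1Source()))  # ~1.28 bits
#' @export
summarizeSource <- function(source) {
  stopifnot(is(source, "MarkovSource"))
  piCtx <- stationaryDistribution(source, "context")
  m <- stationaryDistribution(source, "symbol")
  hMarg <- .entropyBits(m)
  rowH <- apply(source@probs, 1L, .entropyBits)
  hRate <- sum(piCtx * rowH[names(piCtx)])
  cx <- if (source@order == 0L) 0 else max(0, hMarg - hRate)
  if (source@order == 0L) hRate <- hMarg
  new("SourceSummary", stationary = m, marginalEntropyBits = hMarg,
      entropyRateBits = hRate, complexityBits = cx)
}

## ---- sequence generation ----------------------------------------------

#' Generate a symbol sequence from a Markov source
#'
#' Draws `length` symbols from the chain. The initial length-k context is
#' drawn from the stationary context distribution unless supplied, so the
#' output is marginally stationary from its first symbol; the context itself
#' (supplied or drawn) precedes the output and is not part of it.
#' Identical `(source, length, seed, initialContext)` inputs reproduce the
#' identical sequence bit-for-bit.
#'
#' @param source A [MarkovSource-class].
#' @param length Number of symbols to emit (>= 1).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @param initialContext Optional context string of exactly `markovOrder(source)`
#'   symbols.
#' @return A [SymbolSequence-class].
#' @examples
#' s <- generateSequence(makeLevel0Source(), 672, seed = 7)
#' mean(symbols(s) == "B")  # close to 0.72
#' @export
generateSequence <- function(source, length, seed = NULL,
                             initialContext = NULL) {
  stopifnot(is(source, "MarkovSource"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  if (!is.null(seed) && is.na(suppressWarnings(as.integer(seed))))
    stop("seed must be coercible to an integer")
  k <- source@order
  ctxs <- rownames(source@probs)
  if (!is.null(initialContext)) {
    if (nchar(initialContext) != k || !(initialContext %in% ctxs))
      stop(sprintf("initialContext must be a valid length-%d context", k))
  }
  out <- .withSeed(seed, {
    ctx <- if (is.null(initialContext)) {
      piCtx <- stationaryDistribution(source, "context")
      sample(names(piCtx), 1L, prob = piCtx)
    } else initialContext
    syms <- character(length)
    for (i in seq_len(length)) {
      row <- .ctxRow(source@probs, ctx)
      syms[i] <- sample(source@alphabet, 1L, prob = row)
      ctx <- .shiftContext(ctx, syms[i], k)
    }
    syms
  })
  new("SymbolSequence", symbols = out, alphabet = source@alphabet,
      sourceLabel = source@label,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      kl = NA_real_, id = "")
}

## Vectorized batch generator used by selectSequences: generates n sequences
## of length len simultaneously (one vectorized step per position). Must be
## called inside an established RNG state. Returns an integer matrix of
## symbol indices (n x len).
.generateMatrix <- function(source, n, len) {
  a <- source@alphabet
  nA <- length(a)
  if (source@order == 0L) {
    return(matrix(sample.int(nA, n * len, replace = TRUE,
                             prob = source@probs[1L, ]),
                  nrow = n, ncol = len))
  }
  ctxs <- rownames(source@probs)
  cum <- t(apply(source@probs, 1L, cumsum))
  nextCtx <- matrix(0L, length(ctxs), nA, dimnames = list(ctxs, a))
  for (i in seq_along(ctxs)) for (j in seq_len(nA))
    nextCtx[i, j] <- match(.shiftContext(ctxs[i], a[j], source@order), ctxs)
  piCtx <- stationaryDistribution(source, "context")
  ctxIdx <- sample.int(length(ctxs), n, replace = TRUE, prob = piCtx)
  M <- matrix(0L, n, len)
  for (pos in seq_len(len)) {
    u <- stats::runif(n)
    tIdx <- 1L + as.integer(rowSums(u > cum[ctxIdx, , drop = FALSE]))
    M[, pos] <- tIdx
    ctxIdx <- nextCtx[cbind(ctxIdx, tIdx)]
  }
  M
}

## ---- empirical tables and divergences ---------------------------------

.seqSymbols <- function(x) {
  if (is(x, "SymbolSequence")) x@symbols
  else if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    strsplit(x, "")[[1]]
  else as.character(x)
}

#' Empirical context-conditional table of a sequence
#'
#' Maximum-likelihood conditional target frequencies over all contexts
#' observed in the sequence (positions `order+1 ... n`). Contexts never
#' observed are absent from the table.
#'
#' @param x A [SymbolSequence-class], a character vector of symbols, or a
#'   single string.
#' @param order Memory order k (sequence must be longer than k).
#' @param alphabet Alphabet; taken from the sequence when available.
#' @return A list with matrices `probs` (rows sum to 1) and `counts`, one
#'   row per observed context.
#' @examples
#' empiricalTable("ABAB", 1)$probs
#' @export
empiricalTable <- function(x, order, alphabet = NULL) {
  syms <- .seqSymbols(x)
  if (is.null(alphabet))
    alphabet <- if (is(x, "SymbolSequence")) x@alphabet else sort(unique(syms))
  order <- as.integer(order)
  n <- length(syms)
  if (n <= order)
    stop(sprintf("sequence length (%d) must exceed the order (%d)", n, order))
  str <- paste0(syms, collapse = "")
  pos <- seq.int(order + 1L, n)
  ctx <- if (order == 0L) rep("", length(pos)) else
    substring(str, pos - order, pos - 1L)
  tgt <- syms[pos]
  counts <- table(factor(ctx, levels = sort(unique(ctx))),
                  factor(tgt, levels = alphabet))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  probs <- counts / rowSums(counts)
  list(probs = probs, counts = counts)
}

#' KL divergence of a sequence from its generating source
#'
#' Empirical-from-source divergence `sum P_emp * log2(P_emp / Q)` in bits,
#' with the `0*log 0 == 0` convention. For order >= 1 the per-context terms
#' are weighted by the empirical context frequencies of the sequence
#' (`weights = "empirical"`, the default) or by the source's stationary
#' context probabilities (`weights = "stationary"`, in which case contexts
#' unobserved in the sequence contribute 0). Empirical mass on a
#' source-impossible target yields `+Inf`, the flagged
#' support-violation state.
#'
#' @param x A [SymbolSequence-class] (or symbol vector/string).
#' @param source The generating [MarkovSource-class].
#' @param weights Context weighting scheme.
#' @return Non-negative numeric (possibly `Inf`), in bits.
#' @examples
#' klToSource("BBBB", makeLevel0Source())  # -log2(0.72)
#' @export
klToSource <- function(x, source, weights = c("empirical", "stationary")) {
  weights <- match.arg(weights)
  stopifnot(is(source, "MarkovSource"))
  syms <- .seqSymbols(x)
  if (!all(syms %in% source@alphabet))
    stop("sequence contains symbols outside the source alphabet")
  emp <- empiricalTable(syms, source@order, alphabet = source@alphabet)
  w <- if (weights == "empirical") {
    rowSums(emp$counts) / sum(emp$counts)
  } else {
    piCtx <- stationaryDistribution(source, "context")
    piCtx[match(rownames(emp$counts), names(piCtx))]
  }
  total <- 0
  for (i in seq_len(nrow(emp$probs))) {
    p <- emp$probs[i, ]
    q <- .ctxRow(source@probs, rownames(emp$probs)[i])
    if (any(p > 0 & q == 0)) return(Inf)
    sel <- p > 0
    total <- total + w[i] * sum(p[sel] * log2(p[sel] / q[sel]))
  }
  as.numeric(total)
}

## KL of one integer-coded row (batch path); k <= 1 fast paths.
.klRowIdx <- function(idx, source) {
  nA <- length(source@alphabet)
  if (source@order == 0L) {
    cnt <- tabulate(idx, nbins = nA)
    p <- cnt / sum(cnt)
    q <- source@probs[1L, ]
    if (any(p > 0 & q == 0)) return(Inf)
    sel <- p > 0
    return(sum(p[sel] * log2(p[sel] / q[sel])))
  }
  ## order 1: transitions within the emitted sequence only, matching
  ## klToSource on the same symbols
  len <- length(idx)
  code <- (idx[-len] - 1L) * nA + idx[-1L]
  cnt <- matrix(tabulate(code, nbins = nA * nA), nrow = nA, byrow = TRUE)
  rowTot <- rowSums(cnt)
  total <- 0
  nTrans <- len - 1L
  for (c in which(rowTot > 0)) {
    p <- cnt[c, ] / rowTot[c]
    q <- source@probs[source@alphabet[c], ]
    if (any(p > 0 & q == 0)) return(Inf)
    sel <- p > 0
    total <- total + (rowTot[c] / nTrans) * sum(p[sel] * log2(p[sel] / q[sel]))
  }
  total
}

#' Generate many sequences and keep those closest to the source
#'
#' Generates `nGenerate` sequences of `length` symbols, computes each one's
#' KL divergence to the source, and returns the `nKeep` sequences with the
#' lowest divergence (ascending; ties broken by generation index, lower
#' first). The defaults reproduce the sequence-pool construction of the
#' experiment: 10,000 candidates of 672 symbols, 50 kept.
#'
#' @param source A [MarkovSource-class].
#' @param nGenerate Number of candidate sequences.
#' @param length Symbols per sequence.
#' @param nKeep Number of sequences to keep (`<= nGenerate`).
#' @param seed Integer seed (required for a reproducible pool).
#' @return A list of `nKeep` [SymbolSequence-class] objects sorted by
#'   ascending KL (stored in their `kl` slot), with attribute `"allKL"`
#'   holding the divergences of every candidate in generation order.
#' @export
selectSequences <- function(source, nGenerate = 10000L, length = 672L,
                            nKeep = 50L, seed = 1L) {
  stopifnot(is(source, "MarkovSource"))
  nGenerate <- as.integer(nGenerate); nKeep <- as.integer(nKeep)
  length <- as.integer(length)
  if (nKeep > nGenerate) stop("nKeep must not exceed nGenerate")
  M <- .withSeed(seed, .generateMatrix(source, nGenerate, length))
  kl <- numeric(nGenerate)
  for (i in seq_len(nGenerate)) {
    kl[i] <- if (source@order <= 1L) .klRowIdx(M[i, ], source)
             else klToSource(source@alphabet[M[i, ]], source)
  }
  ord <- order(kl, seq_len(nGenerate))
  keep <- ord[seq_len(nKeep)]
  out <- lapply(keep, function(i) {
    new("SymbolSequence", symbols = source@alphabet[M[i, ]],
        alphabet = source@alphabet, sourceLabel = source@label,
        seed = as.integer(seed), kl = kl[i],
        id = sprintf("seq%05d", i))
  })
  names(out) <- vapply(out, function(s) s@id, "")
  attr(out, "allKL") <- kl
  out
}

#' Per-sequence empirical entropy rate
#'
#' Entropy rate of a single sequence in bits: the conditional entropies of
#' the empirical context-conditional distributions, weighted by the
#' within-sequence (empirical) context frequencies. For order 0 this is the
#' entropy of the empirical symbol distribution.
#'
#' @inheritParams empiricalTable
#' @return Non-negative numeric, in bits.
#' @examples
#' sequenceEntropyRate("ABABABAB", 1)  # 0: deterministic alternation
#' @export
sequenceEntropyRate <- function(x, order, alphabet = NULL) {
  emp <- empiricalTable(x, order, alphabet = alphabet)
  w <- rowSums(emp$counts) / sum(emp$counts)
  sum(w * apply(emp$probs, 1L, .entropyBits))
}
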