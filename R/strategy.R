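## Matching-versus-maximization strategy statistics: baseline models,
## epsilon-smoothed response models, context-weighted KL, per-block Delta-KL
## strategy choice, strategy curves and the integrated strategy index.

.DEFAULT_EPSILON <- 0.05

#' Baseline response models
#'
#' `matching` is the source's own context-conditional table: an ideal
#' probability matcher reproduces the presented statistics. `maximization`
#' places all mass on each context's modal target (ties broken by alphabet
#' order, or an error under `strict = TRUE`). Both tables are floored at
#' `epsilon` and renormalized; without smoothing the maximization model is
#' degenerate and its KL from any non-deterministic responder is infinite.
#' Flooring leaves a table unchanged whenever all its entries already
#' exceed `epsilon`.
#'
#' @param source A [MarkovSource-class].
#' @param kind `"matching"` or `"maximization"`.
#' @param epsilon Smoothing floor in `[0, 1/|alphabet|)`; `0` disables
#'   smoothing (downstream KLs may then be flagged infinite).
#' @param strict Error on contexts with a non-unique modal target.
#' @return Context-by-target probability matrix.
#' @examples
#' baselineModel(makeLevel0Source(), "maximization", epsilon = 0.01)
#' @export
baselineModel <- function(source, kind = c("matching", "maximization"),
                          epsilon = .DEFAULT_EPSILON, strict = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is(source, "MarkovSource"))
  P <- source@probs
  if (kind == "maximization") {
    if (strict) {
      mx <- apply(P, 1L, max)
      nmax <- rowSums(abs(P - mx) < 1e-12)
      if (any(nmax > 1L))
        stop(sprintf("non-unique modal target for context(s): %s",
                     paste(rownames(P)[nmax > 1L], collapse = ", ")))
    }
    M <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
    M[cbind(seq_len(nrow(P)), apply(P, 1L, which.max))] <- 1
    P <- M
  }
  if (epsilon > 0) P <- .floorRenorm(P, epsilon) else P
}

#' Empirical response model of a responder
#'
#' Conditional response frequencies of the non-null responses, grouped by
#' the trailing-k context recorded with each trial, over the full context
#' set of the given order; contexts with no non-null responses get the
#' uniform (random-guess) row. Epsilon-floored and renormalized for KL
#' stability; with floor `epsilon` no entry falls below
#' `epsilon / (1 + |alphabet| * epsilon)`.
#'
#' @param responses A [ResponseSet-class].
#' @param order Memory order k defining the conditioning contexts.
#' @param epsilon Smoothing floor (see [baselineModel()]).
#' @return Context-by-target probability matrix.
#' @export
responseModel <- function(responses, order, epsilon = .DEFAULT_EPSILON) {
  stopifnot(is(responses, "ResponseSet"))
  rec <- responses@records
  if (!any(!rec$isNull)) stop("no non-null responses to model")
  a <- responses@alphabet
  contexts <- .allContexts(a, as.integer(order))
  counts <- .responseCounts(rec, contexts, a)
  tot <- rowSums(counts)
  R <- counts
  R[tot > 0, ] <- counts[tot > 0, , drop = FALSE] / tot[tot > 0]
  R[tot == 0, ] <- 1 / length(a)
  if (epsilon > 0) .floorRenorm(R, epsilon) else R
}

#' Context-weighted KL divergence between two conditional tables
#'
#' `sum_c w(c) * sum_t R(t|c) * log2(R(t|c) / M(t|c))` in bits, with the
#' `0*log 0 == 0` convention; `R > 0` where `M = 0` yields the flagged
#' `+Inf` state. Rows are matched by context name.
#'
#' @param R,M Context-by-target probability matrices over the same contexts
#'   and alphabet.
#' @param weights Context weights summing to 1 (default uniform over the
#'   contexts; strategy functions pass the source's stationary context
#'   probabilities).
#' @return Non-negative numeric (possibly `Inf`), in bits.
#' @export
klRM <- function(R, M, weights = NULL) {
  if (!identical(dim(R), dim(M)))
    stop("R and M must be tables over the same contexts and alphabet")
  if (!is.null(rownames(R)) && !is.null(rownames(M)) &&
      !identical(rownames(R), rownames(M))) {
    i <- match(rownames(R), rownames(M))
    if (anyNA(i)) stop("R and M must be tables over the same contexts")
    M <- M[i, , drop = FALSE]
  }
  if (is.null(weights)) weights <- rep(1 / nrow(R), nrow(R))
  if (!is.null(names(weights)) && !is.null(rownames(R)) &&
      !identical(names(weights), rownames(R)))
    weights <- weights[match(rownames(R), names(weights))]
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  total <- 0
  for (i in seq_len(nrow(R))) {
    p <- R[i, ]; q <- M[i, ]
    if (any(p > 0 & q == 0)) return(Inf)
    sel <- p > 0
    total <- total + weights[i] * sum(p[sel] * log2(p[sel] / q[sel]))
  }
  as.numeric(total)
}

.strategyWeights <- function(responses, source, weights) {
  if (weights == "stationary") {
    stationaryDistribution(source, "context")
  } else {
    rec <- responses@records
    ok <- !rec$isNull
    contexts <- .allContexts(source@alphabet, source@order)
    cnt <- table(factor(rec$context[ok], levels = contexts))
    w <- as.numeric(cnt) / sum(cnt)
    names(w) <- contexts
    w
  }
}

#' Per-block strategy choice (Delta-KL)
#'
#' `KL(R || M_matching) - KL(R || M_maximization)` where `R` is the
#' responder's epsilon-smoothed response model. Negative values indicate a
#' strategy closer to probability matching, positive values a strategy
#' closer to maximization. Computed over all records passed in; use
#' [strategyCurve()] to get one value per training block.
#'
#' @param responses A [ResponseSet-class] (typically one block).
#' @param source The generating [MarkovSource-class].
#' @param epsilon Smoothing floor for both baseline and response models.
#' @param weights `"stationary"` (default) weights contexts by the source's
#'   stationary context probabilities; `"empirical"` by the responder's
#'   observed context frequencies.
#' @return Numeric Delta-KL in bits.
#' @export
strategyChoice <- function(responses, source, epsilon = .DEFAULT_EPSILON,
                           weights = c("stationary", "empirical")) {
  weights <- match.arg(weights)
  stopifnot(is(responses, "ResponseSet"), is(source, "MarkovSource"))
  R <- responseModel(responses, source@order, epsilon)
  Mmatch <- baselineModel(source, "matching", epsilon)
  Mmax <- baselineModel(source, "maximization", epsilon)
  w <- .strategyWeights(responses, source, weights)
  klRM(R, Mmatch, w) - klRM(R, Mmax, w)
}

## ResponseSet restricted to a set of blocks.
.subsetBlocks <- function(responses, blockIdx) {
  new("ResponseSet",
      records = responses@records[
        responses@records$blockIndex %in% blockIdx, , drop = FALSE],
      alphabet = responses@alphabet)
}

#' Strategy curve across training blocks
#'
#' One [strategyChoice()] value per block of the response set.
#'
#' @inheritParams strategyChoice
#' @param levelLabel Label stored on the curve.
#' @return A [StrategyCurve-class].
#' @export
strategyCurve <- function(responses, source, epsilon = .DEFAULT_EPSILON,
                          weights = c("stationary", "empirical"),
                          levelLabel = sourceLabel(source)) {
  weights <- match.arg(weights)
  rec <- responses@records
  blockIdx <- sort(unique(rec$blockIndex))
  vals <- vapply(blockIdx, function(b)
    strategyChoice(.subsetBlocks(responses, b), source, epsilon, weights),
    1.0)
  new("StrategyCurve", values = vals, blockIndices = as.integer(blockIdx),
      responderId = if (nrow(rec)) rec$responderId[1] else "",
      levelLabel = levelLabel)
}

## Strategy choice of the exact-matching baseline: its response model IS
## the (smoothed) matching model, so Delta-KL = -KL(M_matching || M_max).
.matchingBaselineChoice <- function(source, epsilon, w) {
  Mmatch <- baselineModel(source, "matching", epsilon)
  Mmax <- baselineModel(source, "maximization", epsilon)
  -klRM(Mmatch, Mmax, w)
}

#' Integrated strategy index
#'
#' Trapezoidal integral of the responder's strategy curve over block index,
#' compared with the integral of the exact-matching baseline curve (the
#' constant Delta-KL of a responder whose response model equals the
#' matching model). Under the default convention
#' `"participant-minus-matching"` the index is positive toward
#' maximization; `"matching-minus-participant"` flips the sign.
#'
#' @param curve A [StrategyCurve-class] with at least 2 blocks.
#' @param source The generating [MarkovSource-class].
#' @param epsilon Smoothing floor (must match the curve's).
#' @param convention Subtraction order.
#' @param weights Context weighting, as in [strategyChoice()].
#' @return A [StrategyIndex-class].
#' @export
strategyIndex <- function(curve, source, epsilon = .DEFAULT_EPSILON,
                          convention = c("participant-minus-matching",
                                         "matching-minus-participant"),
                          weights = c("stationary", "empirical")) {
  convention <- match.arg(convention)
  weights <- match.arg(weights)
  stopifnot(is(curve, "StrategyCurve"))
  if (length(curve@values) < 2L)
    stop("strategy index needs a curve with at least 2 blocks")
  x <- as.numeric(curve@blockIndices)
  pInt <- .trapz(x, curve@values)
  w <- if (weights == "stationary") stationaryDistribution(source, "context")
       else stop("empirical weights need a response set; use 'stationary'")
  v0 <- .matchingBaselineChoice(source, epsilon, w)
  bInt <- v0 * (max(x) - min(x))
  val <- if (convention == "participant-minus-matching") pInt - bInt
         else bInt - pInt
  new("StrategyIndex", value = val, responderId = curve@responderId,
      nBlocks = length(curve@values), baselineIntegral = bInt,
      participantIntegral = pInt, convention = convention)
}
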