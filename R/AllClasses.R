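#' @import methods
NULL

#' Markov stochastic source
#'
#' A k-th order Markov source over a small symbol alphabet. The next symbol
#' (the "target") is drawn from a distribution conditioned on the previous
#' `k` symbols (the "context"). Order 0 is a memory-less source with a single
#' empty context.
#'
#' @slot alphabet Ordered character vector of symbol labels (canonically
#'   `A, B, C, D`).
#' @slot order Non-negative integer memory order `k`.
#' @slot probs Row-stochastic matrix: one row per length-`k` context
#'   (rownames are context strings, oldest symbol first; `""` for order 0),
#'   one column per alphabet symbol.
#' @slot label Free-text label (e.g. `"level0"`, `"level1"`, `"random"`).
#'
#' @seealso [makeLevel0Source()], [makeLevel1Source()], [summarizeSource()]
#' @exportClass MarkovSource
setClass("MarkovSource",
         slots = c(alphabet = "character",
                   order    = "integer",
                   probs    = "matrix",
                   label    = "character"))

setValidity("MarkovSource", function(object) {
  msgs <- character()
  a <- object@alphabet
  k <- object@order
  P <- object@probs
  if (length(a) < 2L || anyDuplicated(a))
    msgs <- c(msgs, "alphabet must hold at least 2 distinct symbols")
  if (any(nchar(a) != 1L))
    msgs <- c(msgs, "alphabet symbols must be single characters")
  if (length(k) != 1L || is.na(k) || k < 0L)
    msgs <- c(msgs, "order must be a single non-negative integer")
  if (!is.numeric(P))
    msgs <- c(msgs, "probs must be a numeric matrix")
  if (length(msgs)) return(msgs)
  if (!identical(colnames(P), a))
    msgs <- c(msgs, "probs columns must match the alphabet")
  expected <- .allContexts(a, k)
  if (nrow(P) != length(expected) || !setequal(rownames(P), expected))
    msgs <- c(msgs, sprintf(
      "probs must have one row per length-%d context (%d expected, %d found)",
      k, length(expected), nrow(P)))
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  bad <- abs(rowSums(P) - 1) > 1e-9
  if (any(bad))
    msgs <- c(msgs, sprintf("context rows do not sum to 1: %s",
                            paste(rownames(P)[bad], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MarkovSource", function(object) {
  cat(sprintf("MarkovSource '%s': order %d over {%s}\n",
              object@label, object@order,
              paste(object@alphabet, collapse = ", ")))
  print(round(object@probs, 4))
})

#' Symbol sequence emitted by a Markov source
#'
#' @slot symbols Character vector of single-character symbols.
#' @slot alphabet The source alphabet the symbols belong to.
#' @slot sourceLabel Label of the generating source.
#' @slot seed Integer seed used at generation (`NA` if unknown).
#' @slot kl KL divergence to the generating source in bits
#'   (`NA` unless computed, e.g. by [selectSequences()]).
#' @slot id Free-text identifier.
#'
#' @exportClass SymbolSequence
setClass("SymbolSequence",
         slots = c(symbols = "character", alphabet = "character",
                   sourceLabel = "character", seed = "integer",
                   kl = "numeric", id = "character"))

setValidity("SymbolSequence", function(object) {
  msgs <- character()
  if (length(object@symbols) < 1L)
    msgs <- c(msgs, "sequence must contain at least one symbol")
  if (!all(object@symbols %in% object@alphabet))
    msgs <- c(msgs, "all symbols must be members of the alphabet")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SymbolSequence", function(object) {
  n <- length(object@symbols)
  headstr <- paste(utils::head(object@symbols, 40L), collapse = "")
  cat(sprintf("SymbolSequence [%s]: %d symbols from '%s'%s\n  %s%s\n",
              object@id, n, object@sourceLabel,
              if (is.na(object@kl)) "" else sprintf(" (KL %.4f bits)", object@kl),
              headstr, if (n > 40L) "..." else ""))
})

#' Information-theoretic summary of a Markov source
#'
#' @slot stationary Stationary distribution over the alphabet symbols.
#' @slot marginalEntropyBits Entropy of the stationary symbol distribution.
#' @slot entropyRateBits Stationary-context-weighted conditional entropy.
#' @slot complexityBits Predictive complexity: marginal entropy minus
#'   entropy rate (past-future mutual information), in bits.
#'
#' @exportClass SourceSummary
setClass("SourceSummary",
         slots = c(stationary = "numeric",
                   marginalEntropyBits = "numeric",
                   entropyRateBits = "numeric",
                   complexityBits = "numeric"))

setValidity("SourceSummary", function(object) {
  msgs <- character()
  if (abs(sum(object@stationary) - 1) > 1e-9)
    msgs <- c(msgs, "stationary distribution must sum to 1")
  if (object@entropyRateBits > object@marginalEntropyBits + 1e-9)
    msgs <- c(msgs, "entropy rate cannot exceed marginal entropy")
  if (abs(object@complexityBits -
          (object@marginalEntropyBits - object@entropyRateBits)) > 1e-9)
    msgs <- c(msgs, "complexity must equal marginal entropy minus entropy rate")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SourceSummary", function(object) {
  cat(sprintf(paste0("SourceSummary: H(marginal) = %.4f bits, ",
                     "entropy rate = %.4f bits, complexity = %.4f bits\n"),
              object@marginalEntropyBits, object@entropyRateBits,
              object@complexityBits))
  cat("stationary:", paste(sprintf("%s=%.4f", names(object@stationary),
                                   object@stationary), collapse = " "), "\n")
})

#' Block of prediction trials
#'
#' A block consumes one symbol stream left-to-right without gaps: each trial
#' shows a context of 8-14 symbols (10 during scanning) and hides the next
#' stream symbol as the to-be-predicted target.
#'
#' @slot trials `data.frame` with columns `trial`, `length`, `context`
#'   (the displayed symbols, as a string), `target`.
#' @slot blockIndex Position of the block within its session/run.
#' @slot levelLabel,sourceLabel Provenance labels.
#' @slot sequenceId Identifier of the sequence the block was cut from.
#'
#' @exportClass Block
setClass("Block",
         slots = c(trials = "data.frame", blockIndex = "integer",
                   levelLabel = "character", sourceLabel = "character",
                   sequenceId = "character"))

setValidity("Block", function(object) {
  tr <- object@trials
  need <- c("trial", "length", "context", "target")
  if (!all(need %in% names(tr)))
    return(sprintf("trials must have columns %s", paste(need, collapse = ", ")))
  if (nrow(tr) && !all(nchar(tr$context) == tr$length))
    return("context strings must match their recorded trial lengths")
  TRUE
})

setMethod("show", "Block", function(object) {
  cat(sprintf("Block %d ('%s'): %d trials, context lengths %s\n",
              object@blockIndex, object@levelLabel, nrow(object@trials),
              paste(range(object@trials$length), collapse = "-")))
})

#' Synthetic responder model
#'
#' Defines how a simulated participant chooses a symbol on each trial:
#' `uniform` guesses equiprobably, `matcher` samples the source's
#' context-conditional distribution (probability matching), `maximizer`
#' always picks the modal target, and `mixture` interpolates per block
#' between uniform guessing and an asymptotic policy according to a
#' learning schedule. Independently, each trial lapses to a uniform guess
#' with probability `lapse` and is omitted (null response) with probability
#' `nullRate`.
#'
#' @slot id Responder identifier.
#' @slot policy One of `"uniform"`, `"matcher"`, `"maximizer"`, `"mixture"`.
#' @slot lapse Probability in `[0,1]` of a uniform random response.
#' @slot nullRate Probability in `[0,1]` of a null (omitted) response.
#' @slot schedule Per-block mixture weights in `[0,1]` on the asymptotic
#'   policy (used when `policy == "mixture"`; the last weight is carried
#'   forward if there are more blocks than weights).
#' @slot asymptoticPolicy `"matcher"` or `"maximizer"` (mixture policy only).
#' @slot seed Integer RNG seed for the responder.
#'
#' @exportClass ResponderModel
setClass("ResponderModel",
         slots = c(id = "character", policy = "character", lapse = "numeric",
                   nullRate = "numeric", schedule = "numeric",
                   asymptoticPolicy = "character", seed = "integer"))

setValidity("ResponderModel", function(object) {
  msgs <- character()
  if (!object@policy %in% c("uniform", "matcher", "maximizer", "mixture"))
    msgs <- c(msgs, "unknown policy")
  if (object@lapse < 0 || object@lapse > 1)
    msgs <- c(msgs, "lapse must lie in [0, 1]")
  if (object@nullRate < 0 || object@nullRate > 1)
    msgs <- c(msgs, "nullRate must lie in [0, 1]")
  if (length(object@schedule) &&
      (any(object@schedule < 0) || any(object@schedule > 1)))
    msgs <- c(msgs, "mixture weights must lie in [0, 1]")
  if (object@policy == "mixture") {
    if (!length(object@schedule))
      msgs <- c(msgs, "mixture policy needs a non-empty schedule")
    if (!object@asymptoticPolicy %in% c("matcher", "maximizer"))
      msgs <- c(msgs, "asymptoticPolicy must be 'matcher' or 'maximizer'")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ResponderModel", function(object) {
  cat(sprintf("ResponderModel '%s': policy %s%s, lapse %.2f, nullRate %.2f\n",
              object@id, object@policy,
              if (object@policy == "mixture")
                sprintf(" -> %s over %d blocks", object@asymptoticPolicy,
                        length(object@schedule)) else "",
              object@lapse, object@nullRate))
})

#' Per-trial responses of one responder
#'
#' @slot records `data.frame` with columns `responderId`, `blockIndex`,
#'   `trialIndex`, `context` (the trailing-k conditioning context),
#'   `choice` (symbol, `NA` for a null response) and `isNull`.
#' @slot alphabet The response alphabet.
#'
#' @exportClass ResponseSet
setClass("ResponseSet",
         slots = c(records = "data.frame", alphabet = "character"))

setValidity("ResponseSet", function(object) {
  rec <- object@records
  need <- c("responderId", "blockIndex", "trialIndex", "context",
            "choice", "isNull")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  ok <- is.na(rec$choice) | rec$choice %in% object@alphabet
  if (!all(ok)) return("choices must be alphabet members or NA (null)")
  if (any(rec$isNull != is.na(rec$choice)))
    return("isNull must flag exactly the NA choices")
  TRUE
})

setMethod("show", "ResponseSet", function(object) {
  rec <- object@records
  cat(sprintf("ResponseSet '%s': %d trials in %d blocks (%d null)\n",
              if (nrow(rec)) rec$responderId[1] else "?", nrow(rec),
              length(unique(rec$blockIndex)), sum(rec$isNull)))
})

#' Performance Index report for one block
#'
#' @slot perContextAbDist Named L1 distances in `[0, 2]` per context.
#' @slot perContextPI Named overlaps `1 - AbDist/2` per context.
#' @slot pi Stationary-context-weighted mean of the per-context PIs.
#' @slot piRand Random-guess baseline for the source.
#' @slot piNormalized `pi - piRand`.
#' @slot nUsed Number of non-null responses scored.
#' @slot blockIndex Block the report refers to.
#'
#' @exportClass PIReport
setClass("PIReport",
         slots = c(perContextAbDist = "numeric", perContextPI = "numeric",
                   pi = "numeric", piRand = "numeric",
                   piNormalized = "numeric", nUsed = "integer",
                   blockIndex = "integer"))

setValidity("PIReport", function(object) {
  msgs <- character()
  if (any(object@perContextAbDist < -1e-9 | object@perContextAbDist > 2 + 1e-9))
    msgs <- c(msgs, "AbDist values must lie in [0, 2]")
  if (max(abs(object@perContextPI -
              (1 - object@perContextAbDist / 2))) > 1e-9)
    msgs <- c(msgs, "per-context PI must equal 1 - AbDist/2")
  if (abs(object@piNormalized - (object@pi - object@piRand)) > 1e-9)
    msgs <- c(msgs, "normalized PI must equal pi - piRand")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PIReport", function(object) {
  cat(sprintf("PIReport block %d: PI = %.3f (rand %.3f, normalized %+.3f), n = %d\n",
              object@blockIndex, object@pi, object@piRand,
              object@piNormalized, object@nUsed))
})

#' Strategy curve across training blocks
#'
#' Per-block Delta-KL strategy-choice values for one responder: negative
#' values lie toward probability matching, positive toward maximization.
#'
#' @slot values Per-block Delta-KL values (bits).
#' @slot blockIndices Integer block indices the values belong to.
#' @slot responderId,levelLabel Provenance.
#'
#' @exportClass StrategyCurve
setClass("StrategyCurve",
         slots = c(values = "numeric", blockIndices = "integer",
                   responderId = "character", levelLabel = "character"))

setValidity("StrategyCurve", function(object) {
  if (length(object@values) != length(object@blockIndices))
    return("one strategy-choice value per scored block is required")
  TRUE
})

setMethod("show", "StrategyCurve", function(object) {
  cat(sprintf("StrategyCurve '%s' (%s): %d blocks, final %+0.3f bits\n",
              object@responderId, object@levelLabel, length(object@values),
              utils::tail(object@values, 1L)))
})

#' Integrated strategy index
#'
#' Integral difference between a responder's strategy curve and the
#' exact-matching baseline curve across training blocks.
#'
#' @slot value The strategy index (positive toward maximization under the
#'   default convention).
#' @slot responderId Responder identifier.
#' @slot nBlocks Number of blocks integrated over.
#' @slot baselineIntegral,participantIntegral The two trapezoidal integrals.
#' @slot convention Subtraction order used (see [strategyIndex()]).
#'
#' @exportClass StrategyIndex
setClass("StrategyIndex",
         slots = c(value = "numeric", responderId = "character",
                   nBlocks = "integer", baselineIntegral = "numeric",
                   participantIntegral = "numeric", convention = "character"))

setMethod("show", "StrategyIndex", function(object) {
  cat(sprintf("StrategyIndex '%s': %+0.3f over %d blocks (%s)\n",
              object@responderId, object@value, object@nBlocks,
              object@convention))
})
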