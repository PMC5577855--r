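## Internal numeric and RNG helpers shared across modules.

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
## seed = NULL means "use the current stream" (no save/restore, no reseeding).
.withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(expr)
}

## Deterministic sub-seed derivation (counter scheme). Stays below 2^31 - 1.
.deriveSeed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 100003 + counter * 7919) %% 2147483629)
}

## Shannon entropy in bits with the 0*log(0) == 0 convention.
.entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## All length-k contexts over an alphabet, oldest symbol first, as strings.
## Ordering: newest symbol varies fastest, matching how a human reads
## "context AB then target" tables.
.allContexts <- function(alphabet, k) {
  if (k == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  ## expand.grid varies column 1 fastest; column 1 is the OLDEST symbol, so
  ## reorder rows so the newest (last column) varies fastest.
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  apply(grid, 1L, paste0, collapse = "")
}

## Shift a context string after emitting `target` (drop oldest, append newest).
.shiftContext <- function(context, target, k) {
  if (k == 0L) return("")
  substring(paste0(context, target), 2L, k + 1L)
}

## Floor every entry of a row-stochastic matrix at eps, then renormalize rows.
.floorRenorm <- function(P, eps) {
  stopifnot(eps >= 0, eps < 1 / ncol(P))
  Q <- pmax(P, eps)
  Q / rowSums(Q)
}

## Row(s) of a context-by-target table looked up by context string.
## Plain character indexing cannot be used: the order-0 empty context ""
## never matches dimnames under `[`.
.ctxRow <- function(P, ctx) {
  i <- match(ctx, rownames(P))
  if (anyNA(i)) stop(sprintf("unknown context(s): %s",
                             paste(ctx[is.na(i)], collapse = ", ")))
  out <- P[i, , drop = (length(ctx) == 1L)]
  if (length(ctx) > 1L) rownames(out) <- ctx
  out
}

## Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  if (length(x) < 2L) stop("trapezoidal integration needs at least 2 points")
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}
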