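#' Derive a stream seed from a base seed and integer codes
#'
#' Deterministically mixes a base seed with one or more integer codes
#' (case index, domain code, step counter, ...) so that every random draw
#' in the package has its own reproducible stream. The result is always in
#' `[0, 2^31 - 2]`, safe for [set.seed()].
#'
#' @param seed base integer seed
#' @param ... additional integer codes mixed in, in order
#' @return a single integer seed
#' @export
mix_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (v in c(...)) {
    h <- (h * 69069 + as.numeric(v) * 641 + 1013904223) %% m
    h <- (h * 48271) %% m   # Lehmer step to spread low bits
  }
  as.integer(h %% (m - 1))
}

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so data generation, augmentation and weight
#' initialization never interfere with each other's random streams.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Softmax over the channel (first) axis of a (C, ...) array.
channel_softmax <- function(x) {
  d <- dim(x)
  C <- d[1]
  m <- matrix(x, nrow = C)
  mx <- m[1, ]
  if (C > 1) for (cc in 2:C) mx <- pmax(mx, m[cc, ])
  e <- exp(m - rep(mx, each = C))
  p <- e / rep(colSums(e), each = C)
  dim(p) <- d
  p
}

# Concatenate two (C, ...) arrays along the channel axis.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == length(db), all(da[-1] == db[-1]))
  ma <- matrix(a, nrow = da[1]); mb <- matrix(b, nrow = db[1])
  y <- rbind(ma, mb)
  dim(y) <- c(da[1] + db[1], da[-1])
  y
}

# Split a (C, ...) array into two halves along the channel axis.
split_channels <- function(x) {
  d <- dim(x)
  C <- d[1]
  m <- matrix(x, nrow = C)
  a <- m[seq_len(C / 2), , drop = FALSE]
  b <- m[(C / 2 + 1):C, , drop = FALSE]
  dim(a) <- c(C / 2, d[-1]); dim(b) <- c(C / 2, d[-1])
  list(a, b)
}

# Global-norm gradient clipping over a named list of arrays.
clip_gradients <- function(g, max_norm) {
  total <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    s <- max_norm / total
    g <- lapply(g, function(x) x * s)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
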