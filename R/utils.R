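# Internal helpers: seeded RNG scoping and substream derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

# Deterministic substream seed: one master integer seed plus a stream name
# yields an independent seed. Streams are fixed per component (attributes,
# each feature, outcomes) so adding a feature or changing n never shuffles
# the draws of another component.
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h * 104729) %% 2147483629)
}

# Categorical draws by inverse-CDF on sequential uniforms: consumes exactly
# n variates, so the first m draws are identical for any larger n.
draw_categorical <- function(n, probs) {
  if (n == 0L) return(integer(0))
  findInterval(stats::runif(n), cumsum(probs), left.open = TRUE) + 1L
}

clip01 <- function(x) pmin(1, pmax(0, x))

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
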