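# Random-source abstraction.
#
# Every stochastic decision in the engine is an inverse-CDF transform of a
# uniform draw pulled through rng_unif(). The production source draws from
# R's global RNG (so set.seed() gives full reproducibility); the scripted
# source replays a fixed queue of uniforms, which makes single-worker
# scenario scripts fully deterministic while exercising the identical engine
# code path.

#' Create a random source
#'
#' @param values optional numeric vector of uniforms in `[0, 1]`. When given,
#'   the source is *scripted*: draws are consumed from `values` in order and
#'   exhaustion is an error. When `NULL`, draws come from R's global RNG.
#' @return An environment of class `worksim_rng`.
#' @examples
#' r <- rng_source(c(0.1, 0.9))
#' rng_unif(r, 2)
#' @export
rng_source <- function(values = NULL) {
  e <- new.env(parent = emptyenv())
  e$scripted <- !is.null(values)
  if (e$scripted) {
    stopifnot(is.numeric(values), all(values >= 0 & values <= 1))
    e$values <- as.numeric(values)
    e$pos <- 0L
  }
  class(e) <- "worksim_rng"
  e
}

#' Draw uniforms from a random source
#'
#' @param rng a `worksim_rng` source, or `NULL` for the global RNG.
#' @param n number of draws.
#' @return Numeric vector of `n` uniforms in `[0, 1]`.
#' @export
rng_unif <- function(rng, n) {
  if (n == 0L) return(numeric(0))
  if (is.null(rng) || !rng$scripted) return(stats::runif(n))
  if (rng$pos + n > length(rng$values)) {
    stop("scripted random source exhausted (needed ", n, " more draw(s) at ",
         "position ", rng$pos, " of ", length(rng$values), ")", call. = FALSE)
  }
  out <- rng$values[(rng$pos + 1L):(rng$pos + n)]
  rng$pos <- rng$pos + n
  out
}

# inverse-CDF helpers -------------------------------------------------------

# normal censored below at 0 (mass below zero is negligible for the cost
# distributions used: mean 100, sd 20)
q_cost <- function(u, mean, sd) pmax(stats::qnorm(u, mean, sd), 0)

# lognormal re-parameterized to a target arithmetic mean and sd
q_salary <- function(u, mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  stats::qlnorm(u, meanlog = mu, sdlog = sqrt(sigma2))
}

# normal truncated to [lo, hi] (used for treatment responsiveness)
q_truncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# symmetric uniform noise on [-half, +half]
q_noise <- function(u, half) (2 * u - 1) * half
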