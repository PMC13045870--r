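#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm pnorm rnorm runif rbinom median sd kmeans approx
#' @importFrom utils write.csv read.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named sub-stream seed from a session seed
#'
#' All randomness in a simulated session flows from one integer seed via
#' named sub-streams (schedule, agent, clocks, frames), so each component
#' is reproducible on its own. The derived seed is a deterministic hash of
#' the parent seed and the stream name, kept below 2^31.
#'
#' @param seed Integer parent seed.
#' @param name Character stream name.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "schedule")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- abs(as.numeric(seed)) %% m
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% m
  as.integer((h * 48271) %% m)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
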