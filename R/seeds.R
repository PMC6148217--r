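#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Independent random streams (location sampling, per-iteration classifier
#' initialisation, fold assignment, per-sample image synthesis) are keyed by
#' descriptive tags so that changing one stage never perturbs another.
#'
#' @param seed integer master seed.
#' @param ... character or numeric tags naming the stream.
#' @return an integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' sub_seed(1, "sampling")
#' sub_seed(1, "classifier", 3)
sub_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime below 2^31
  tag <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
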