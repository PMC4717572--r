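#' Derive a labelled child seed from a master seed
#'
#' Modules derive their own RNG seeds from the master seed by a fixed,
#' labelled scheme (component name plus index), so any component can be
#' regenerated independently of the others while staying deterministic.
#' The hash is a plain 31-bit multiplicative string fold; all arithmetic
#' stays below 2^53 so it is exact in doubles.
#'
#' @param master integer master seed.
#' @param label character component label, e.g. `"cohort"`.
#' @param index optional integer sub-index (e.g. iteration number).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' childSeed(42, "network")
#' childSeed(42, "netwas", 3)
#' @export
childSeed <- function(master, label, index = 0L) {
  stopifnot(length(master) == 1L, is.finite(master),
            length(label) == 1L, is.character(label),
            length(index) == 1L, is.finite(index))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  h <- (h * 48271 + (as.numeric(master) %% m)) %% m
  h <- (h * 69621 + (as.numeric(index) %% m)) %% m
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# 12-significant-digit decimal formatting for reproducible text diffs.
fmtNum <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- "NA"
  out
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
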