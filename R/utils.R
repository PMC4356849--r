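#' @keywords internal
"_PACKAGE"

# Row-wise log-sum-exp for an n x K matrix of log terms.
log_row_sum_exp <- function(lp) {
  m <- apply(lp, 1L, max)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m))[1L]
    stop("log-likelihood underflow: subject ", bad,
         " has zero density under every class", call. = FALSE)
  }
  m + log(rowSums(exp(lp - m)))
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a 31-bit integer
#' seed, so that adding a pipeline stage never perturbs the random streams of
#' earlier stages.
#'
#' @param master Integer master seed.
#' @param stage Character scalar naming the stage.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  s <- (abs(master) %% m) * 48271 %% m
  out <- (s + h) %% m
  as.integer(max(out, 1))
}

# Tiny FNV-1a style hash of a character vector, for config fingerprints.
config_hash <- function(x) {
  txt <- paste(x, collapse = "\n")
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Format doubles at full precision so that write -> read round-trips exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1L))
  out
}

stop_field <- function(field, msg) {
  stop("invalid `", field, "`: ", msg, call. = FALSE)
}
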