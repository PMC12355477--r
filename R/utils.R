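## Internal helpers: RNG substream keying, misc.

`%||%` <- function(a, b) if (is.null(a)) b else a

MODULUS_31 <- 2147483647  # 2^31 - 1; all derived seeds stay below this

#' Derive a reproducible substream seed
#'
#' Mixes the master seed with integer keys (patient index, replication index,
#' a purpose tag, ...) into a seed in `[1, 2^31 - 2]` usable with
#' `set.seed()`. The mixer is a Lehmer-style accumulation evaluated exactly
#' in double precision, so the same inputs always give the same seed on any
#' platform.
#'
#' @param ... integers (or strings, hashed by character codes) to mix.
#' @return a single integer seed.
#' @keywords internal
mix_seed <- function(...) {
  parts <- list(...)
  h <- 988041851
  for (x in parts) {
    if (is.character(x)) x <- utf8ToInt(paste(x, collapse = "|"))
    for (v in as.numeric(x)) {
      v <- abs(v) %% MODULUS_31
      h <- (h * 48271 + v + 11) %% MODULUS_31
      h <- (h * 69621) %% MODULUS_31
    }
  }
  as.integer(h %% (MODULUS_31 - 2) + 1)
}

## purpose tags for substreams (kept stable: they define the stream layout)
PURPOSE_COHORT <- 104729L
PURPOSE_DEATH  <- 224737L
PURPOSE_TRAJ   <- 350377L
PURPOSE_PSA    <- 479909L
PURPOSE_RUN    <- 611953L

# annual probability -> constant hazard rate
prob_to_rate <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  -log1p(-p)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_config <- function(...) {
  stop(structure(class = c("sz_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
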