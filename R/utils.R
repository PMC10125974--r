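# Internal helpers shared across modules.

# Deterministic seed for one generator call: a stable per-generator offset
# plus an optional per-item key keeps the streams of different generators
# independent, so adding a generator does not perturb the others.
gen_seed <- function(seed, offset, key = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  s <- (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
  if (!is.null(key)) {
    s <- s + sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key)))) %% 99991L
  }
  as.integer(s %% .Machine$integer.max)
}

with_gen_seed <- function(seed, offset, key = NULL, code) {
  withr::with_seed(gen_seed(seed, offset, key), code)
}

# robust sd via median absolute deviation (normal-consistent)
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

stop_input <- function(msg) rlang::abort(msg, class = "igem_input_error")
stop_config <- function(msg) rlang::abort(msg, class = "igem_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
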