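# internal helpers shared across modules

# deterministic child seed: each generator call owns its stream, so adding a
# call does not perturb earlier ones; result stays inside 32-bit integer range
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  code <- utf8ToInt(tag)
  h <- sum(code * seq_along(code))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

tme_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "gliomaTME_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

validation_error <- function(fmt, ...) {
  tme_stop("gliomaTME_validation_error", fmt, ...)
}

schema_error <- function(fmt, ...) {
  tme_stop("gliomaTME_schema_error", fmt, ...)
}

# rolling 32-bit hash of a deparsed R object, for provenance stamps
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 4294967296
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
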