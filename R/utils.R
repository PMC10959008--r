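# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG stream without disturbing the caller's
# RNG state. Generators advertise purity in (config, seed); this is how.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_rifseg <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rifseg_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_rifseg(sprintf("`%s` must be supplied", name), "rifseg_invalid_config")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop_rifseg(sprintf("`%s` must be a single finite number in [%s, %s]",
                        name, format(lower), format(upper)),
                "rifseg_invalid_config")
  }
  invisible(x)
}

# Polynomial rolling hash over the serialized object (mod the Mersenne
# prime 2^31 - 1); stable fingerprint for manifests and output headers,
# no cryptographic intent.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 17
  for (b in as.integer(raw)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
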