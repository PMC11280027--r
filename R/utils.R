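# Internal helpers: seeded evaluation, logging, unit constants.

# 1 uM expressed in mol/cm^3; 1 uL expressed in cm^3. All permeability
# arithmetic is done in mol, cm^3 and s so that Papp comes out in cm/s.
.UM_TO_MOL_PER_CM3 <- 1e-9
.UL_TO_CM3 <- 1e-3

# Evaluate `code` under a private RNG stream, restoring global state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

pf_log <- function(level, ..., log_level = getOption("permaflow.log_level", "warn")) {
  if (.log_levels[[level]] >= .log_levels[[log_level]]) {
    message(sprintf("[permaflow:%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

stop_pf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# lognormal multiplier with expectation 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}
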