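# Internal unit conversions: user-facing lengths are in micrometres, speeds in
# um/s, rotation rates in Hz, torques in pN um; all balances are evaluated in
# SI (m, s, Pa s, N) with angular velocities in rad/s.
.UM <- 1e-6        # m per um
.PN_UM <- 1e-18    # N m per pN um

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never disturb user code.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

.assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                           strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside its valid range", name, x), call. = FALSE)
  }
  invisible(x)
}

# Stable hash of a configuration object (md5 of its canonical JSON), used to
# stamp outputs with provenance.
.config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
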