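#' @importFrom stats rnbinom rpois rmultinom rnorm runif rbinom rgamma quantile
#'   pt p.adjust t.test median setNames rchisq
#' @importFrom utils write.table read.delim
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a deterministic 31-bit sub-seed from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  offsets <- c(cells = 1L, adt = 2L, hto = 3L, qc = 4L, doublet = 5L,
               batch = 6L, subsample = 7L, rank = 8L, decide = 9L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 7919 + off * 1000003) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_scalar <- function(x, field, min = -Inf, max = Inf,
                         integer = FALSE, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_min && x <= min)
    stop_field(field, sprintf("must be > %s", min))
  if (!strict_min && x < min)
    stop_field(field, sprintf("must be >= %s", min))
  if (x > max) stop_field(field, sprintf("must be <= %s", max))
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  invisible(x)
}

as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else as.matrix(m)
}
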