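#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor cor.test lm median pf pnorm pwilcox
#'   quantile rnorm sd shapiro.test var
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state so
# generator functions are pure in (params, seed) and do not perturb the
# session stream.
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
    })
    set.seed(seed)
  }
  force(expr)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) stop_param(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower) stop_param(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper) stop_param(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper) stop_param(field, sprintf("must be <= %g", upper))
  invisible(x)
}
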