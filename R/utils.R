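#' @importFrom stats dnorm pnorm qnorm runif rnorm median sd aggregate anova
#'   as.formula p.adjust pt quantile rgeom t.test complete.cases uniroot var
#'   prcomp predict setNames
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded package functions never disturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' One top-level seed deterministically spawns all stage- and
#' participant-level seeds, so a single integer reproduces an entire run.
#' The derived seed is always a valid 32-bit integer.
#'
#' @param master integer master seed.
#' @param label character label naming the consumer (stage, participant, ...).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 104729
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% m
  }
  s <- ((abs(as.numeric(master)) %% m) * 48271 + h) %% m
  as.integer(max(1, s))
}

stop_vrgaze <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "vrgaze_error")))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_vrgaze("`%s` must be a finite number in [%s, %s], got: %s",
                name, format(lower), format(upper),
                paste(format(x), collapse = ","),
                class = "vrgaze_validation_error")
  }
  invisible(x)
}
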