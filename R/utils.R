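#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every random stage draws its own seed from
# (master seed, stage label, trial index) so results do not depend on how many
# draws earlier stages consumed. Kept below 2^31 - 1.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)))
  s <- (abs(as.numeric(master)) %% 2147483647) * 48271 +
    h * 69621 + as.numeric(index) * 16807 + 1
  as.integer(s %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified half split: returns logical vector, TRUE = training half.
# With odd class counts the training half takes the ceiling for the majority
# class and the floor for the minority, alternating by trial parity so that
# both roundings are exercised.
stratified_half_split <- function(y, parity = 0L) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  maj <- if (n1 >= n0) 1L else 0L
  take <- function(n, is_maj) {
    if (n %% 2L == 0L) return(n %/% 2L)
    base <- n %/% 2L
    up <- if (is_maj) parity %% 2L == 0L else parity %% 2L == 1L
    base + as.integer(up)
  }
  k1 <- take(n1, maj == 1L); k0 <- take(n0, maj == 0L)
  train <- logical(length(y))
  train[sample(which(y == 1L), k1)] <- TRUE
  train[sample(which(y == 0L), k0)] <- TRUE
  train
}

#' @useDynLib plasmasig, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
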