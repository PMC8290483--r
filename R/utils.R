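# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded operations do not perturb the global random stream. A `NULL`
#' seed evaluates `code` against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  code
}

# whole-number check tolerant of double storage
is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# row-wise sample standard deviation (n-1 denominator); 0 for single columns
row_sd <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  sqrt(pmax(0, (rowSums(m^2) - n * mu^2) / (n - 1)))
}

# geometric mean with +1 pseudocount, row-wise: exp(mean(log(x+1))) - 1
row_gm <- function(m) {
  expm1(rowMeans(log1p(m)))
}

# Dirichlet draw via normalized gammas; returns a length(alpha) vector
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {
    # pathological all-zero draw (tiny alphas): fall back to the mean
    return(alpha / sum(alpha))
  }
  g / s
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
}
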