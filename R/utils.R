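#' Derive a reproducible child seed from a master seed
#'
#' Stable string hash so that per-region / per-stage / per-permutation seeds
#' are a deterministic function of the master seed and a label, independent
#' of execution order. The hash is a polynomial rolling hash over the UTF-8
#' bytes of the concatenated arguments, reduced modulo 2^31 - 1 so the result
#' is always a valid R integer seed.
#'
#' @param master_seed Integer master seed.
#' @param ... Further labels (character or numeric) mixed into the hash.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character,
                                                   character(1))),
               collapse = "/")
  bytes <- utf8ToInt(key)
  m <- 2147483647  # 2^31 - 1, prime
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic split-R-hat: each chain is split in half, and the ratio of pooled
#' to within-chain variance is computed over the resulting 2m sequences.
#'
#' @param draws Matrix of post-warmup draws, iterations x chains.
#' @return Scalar R-hat (NA if fewer than 4 iterations).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based estimate using the initial positive sequence of
#' pairwise autocorrelation sums, computed per chain and pooled.
#'
#' @param draws Matrix of post-warmup draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  total <- 0
  for (j in seq_len(ncol(draws))) {
    x <- draws[, j]
    if (stats::var(x) == 0) {
      total <- total + n
      next
    }
    ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
                     demean = TRUE)$acf[-1]
    # sum pairwise (Geyer initial positive sequence)
    s <- 0
    k <- 1
    while (k + 1 <= length(ac)) {
      pair <- ac[k] + ac[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
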