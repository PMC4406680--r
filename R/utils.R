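#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the previous RNG state, so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop() with sprintf-style formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# check that x is a single finite number, optionally positive
check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("`%s` must be a single finite number", name)
  if (positive && x <= 0) abort("`%s` must be > 0", name)
  invisible(x)
}

# fill NA cells of a matrix with the mean of their non-NA 4/8-neighbours,
# iterating until no NA remains (approximates nearest-neighbour filling;
# used for continuous surfaces such as terrain)
fill_na_neighbours <- function(m, max_iter = 1000L) {
  if (!anyNA(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
               c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (it in seq_len(max_iter)) {
    na_idx <- is.na(m)
    if (!any(na_idx)) break
    acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    for (o in offs) {
      s <- shift(m, o[1], o[2])
      ok <- !is.na(s)
      acc[ok] <- acc[ok] + s[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    fill <- na_idx & cnt > 0
    m[fill] <- acc[fill] / cnt[fill]
    if (!any(fill)) break   # isolated all-NA raster: give up
  }
  m
}

# smooth a matrix with a separable Gaussian kernel (reflected edges)
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x) {            # x: matrix, smooth down columns
    n <- nrow(x)
    idx <- c(rev(seq_len(rad)), seq_len(n), n + 1 - seq_len(rad))
    xp <- x[pmin(pmax(idx, 1L), n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}
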