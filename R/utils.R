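# Internal numerical helpers: seeded evaluation, small-kernel convolution,
# block pooling and grid resampling. All grids are base matrices indexed
# [row, col] with row = retinotopic/scene y and col = x.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded scene generation and
#' trials do not disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' 2-D convolution with a small kernel
#'
#' Correlation-style placement: the kernel element at (`oy`, `ox`) offsets
#' gathers from `x[i + oy, j + ox]`. Implemented as shift-and-add, which is
#' fast for the few-dozen-tap kernels used throughout.
#'
#' @param x numeric matrix.
#' @param k numeric kernel matrix.
#' @param oy,ox integer offsets of the kernel's reference cell (row/col index
#'   of the zero-offset tap, 1-based). Defaults centre the kernel.
#' @param pad "zero" or "replicate" treatment of out-of-grid samples.
#' @return matrix of `dim(x)`.
#' @keywords internal
conv2d <- function(x, k, oy = (nrow(k) + 1L) %/% 2L, ox = (ncol(k) + 1L) %/% 2L,
                   pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  m <- nrow(x); n <- ncol(x)
  out <- matrix(0, m, n)
  for (a in seq_len(nrow(k))) {
    dy <- a - oy
    for (b in seq_len(ncol(k))) {
      w <- k[a, b]
      if (w == 0) next
      dx <- b - ox
      src_r <- seq_len(m) + dy
      src_c <- seq_len(n) + dx
      if (pad == "replicate") {
        src_r <- pmin(pmax(src_r, 1L), m)
        src_c <- pmin(pmax(src_c, 1L), n)
        out <- out + w * x[src_r, src_c, drop = FALSE]
      } else {
        rr <- src_r >= 1L & src_r <= m
        cc <- src_c >= 1L & src_c <= n
        if (!any(rr) || !any(cc)) next
        out[rr, cc] <- out[rr, cc] + w * x[src_r[rr], src_c[cc], drop = FALSE]
      }
    }
  }
  out
}

#' Separable convolution (row profile then column profile)
#' @keywords internal
conv_sep <- function(x, krow, kcol, oy = (length(krow) + 1L) %/% 2L,
                     ox = (length(kcol) + 1L) %/% 2L, pad = "zero") {
  x <- conv2d(x, matrix(krow, ncol = 1), oy = oy, ox = 1L, pad = pad)
  conv2d(x, matrix(kcol, nrow = 1), oy = 1L, ox = ox, pad = pad)
}

#' Block-mean downsampling by an integer factor
#' @keywords internal
block_mean <- function(x, f) {
  m <- nrow(x); n <- ncol(x)
  stopifnot(m %% f == 0, n %% f == 0)
  mo <- m %/% f; no <- n %/% f
  # average rows within blocks, then columns
  dim(x) <- c(f, mo, n)
  x <- colMeans(x)                      # mo x n
  x <- t(x); dim(x) <- c(f, no, mo)
  t(colMeans(x))                        # mo x no
}

#' Linear-interpolation resampling matrix from an n-point to an m-point grid
#'
#' Grids are cell-centred over the same physical extent; returns an m x n
#' matrix `A` so that `A %*% v` resamples a length-n profile to length m.
#' @keywords internal
resample_matrix <- function(n_from, n_to) {
  A <- matrix(0, n_to, n_from)
  # cell centres in [0, 1]
  cf <- (seq_len(n_from) - 0.5) / n_from
  ct <- (seq_len(n_to) - 0.5) / n_to
  for (i in seq_len(n_to)) {
    pos <- ct[i]
    j <- findInterval(pos, cf)
    if (j <= 0) A[i, 1] <- 1
    else if (j >= n_from) A[i, n_from] <- 1
    else {
      w <- (pos - cf[j]) / (cf[j + 1] - cf[j])
      A[i, j] <- 1 - w
      A[i, j + 1] <- w
    }
  }
  A
}

#' Connected components of a logical matrix (4-connectivity)
#' @return integer matrix of labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  lab <- matrix(0L, m, n)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% m + 1L
      j <- (p - 1L) %/% m + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < m) p + 1L,
                  if (j > 1L) p - m, if (j < n) p + m)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Rectify (half-wave) a matrix
#' @keywords internal
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# 1-D Gaussian taps on integer offsets -r..r, peak 1 (unnormalised)
gauss_taps <- function(sigma, r = ceiling(3 * sigma)) {
  x <- -r:r
  exp(-x^2 / (2 * sigma^2))
}

# zero-sum centre-surround taps (each lobe unit-normalised, common radius)
dog_taps <- function(sigma_c, sigma_s) {
  r <- ceiling(3 * sigma_s)
  kc <- gauss_taps(sigma_c, r); kc <- kc / sum(kc)
  ks <- gauss_taps(sigma_s, r); ks <- ks / sum(ks)
  kc - ks
}
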