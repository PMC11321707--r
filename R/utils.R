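# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stream child seed from a master seed. Keeps results for one
# stream stable when another stream's draws change, and stays below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  streams <- c(
    block = 101L, aggregate = 211L, peaks = 307L, dosy = 401L,
    kinetics = 503L, reference = 601L, noise = 701L
  )
  off <- if (is.character(stream)) {
    if (!stream %in% names(streams)) stop("unknown seed stream: ", stream)
    streams[[stream]]
  } else {
    as.integer(stream)
  }
  (as.integer(seed) %% 1000000L) * 1009L + off
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a positive finite scalar", call. = FALSE)
  }
  invisible(x)
}
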