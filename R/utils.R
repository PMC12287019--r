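#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards so library calls never perturb user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed fan-out: one master seed, one stream per stage/index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  tag_num <- sum(utf8ToInt(as.character(tag)) * (seq_along(utf8ToInt(as.character(tag))) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + tag_num) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

# Coerce anything mask-like to an integer 0/1 matrix.
as_mask <- function(x) {
  if (!is.matrix(x)) stop("mask must be a matrix", call. = FALSE)
  m <- x
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

as_gray <- function(x, L = 256L) {
  if (!is.matrix(x)) stop("image must be a matrix", call. = FALSE)
  if (any(x < 0) || any(x > L - 1)) {
    stop(sprintf("pixel values must lie in [0, %d]", L - 1), call. = FALSE)
  }
  m <- round(x)
  storage.mode(m) <- "integer"
  m
}

# Shift a matrix by (dy, dx); vacated cells are filled with `fill`
# (out-of-image treated as background for morphology).
shift_mat <- function(m, dy, dx, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0 && ys[1] <= h && xs[1] <= w) {
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  }
  out
}

# round-half-up (the conventional round(.) of image processing texts,
# distinct from R's banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
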