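`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a private RNG stream; restores the caller's .Random.seed so
# generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit seed from a string key (polynomial rolling hash);
# used to derive per-eye / per-region seeds from ids.
derive_seed <- function(..., base = 0L) {
  key <- paste(c(base, ...), collapse = "|")
  h <- 7
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483587
  as.integer(h + 1)
}

stopifnot_binary <- function(m, what = "mask") {
  if (!is.matrix(m)) stop(what, " must be a matrix", call. = FALSE)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop(what, " must be strictly binary", call. = FALSE)
  invisible(TRUE)
}

as_binary <- function(m) {
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

#' Convert between pixel indices and physical millimeters
#'
#' Pixel `i` (1-based) has its center at `(i - 0.5) * scale / 1000` mm; the
#' same convention is used for rows and columns (origin at the image
#' top-left, row increasing downward).
#'
#' @param i pixel index (row or column).
#' @param x physical coordinate in mm.
#' @param scale_um_px micrometers per pixel.
#' @export
px_to_mm <- function(i, scale_um_px) (i - 0.5) * scale_um_px / 1000

#' @rdname px_to_mm
#' @export
mm_to_px <- function(x, scale_um_px) x / (scale_um_px / 1000) + 0.5

# moving median with odd window; endpoints handled by runmed's median rule
smooth_median <- function(x, half_window) {
  if (half_window <= 0 || length(x) < 3) return(x)
  k <- min(2L * as.integer(half_window) + 1L,
           if (length(x) %% 2 == 0) length(x) - 1L else length(x))
  if (k < 3) return(x)
  as.numeric(runmed(x, k, endrule = "median"))
}

# centred moving average that keeps endpoints fixed and shrinks the window
# near the ends (no phantom shortening of the path)
smooth_ma <- function(x, window) {
  n <- length(x)
  if (window <= 1 || n < 3) return(x)
  hw <- floor(window / 2)
  out <- x
  for (i in seq_len(n)) {
    h <- min(hw, i - 1L, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}
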