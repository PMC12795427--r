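# Internal validation helpers shared across modules.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_field(field, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    abort_field(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

# Running mean along the first dimension of a matrix, partial windows at the
# edges. Used for axial box filtering of whole volumes (columns = A-scans).
run_mean_cols <- function(m, width) {
  if (width <= 1L) return(m)
  n <- nrow(m)
  cs <- apply_cumsum_cols(m)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  # inclusive window sum = cs[hi] - cs[lo] + m[lo]
  out <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE] + m[lo, , drop = FALSE]
  out / (hi - lo + 1)
}

apply_cumsum_cols <- function(m) {
  # cumsum columnwise without an R-level loop over columns
  matrix(cumsum_by_col(m), nrow = nrow(m))
}

cumsum_by_col <- function(m) {
  n <- nrow(m)
  x <- as.vector(m)
  cs <- cumsum(x)
  if (ncol(m) > 1L) {
    offs <- cs[seq.int(n, length(x) - n, by = n)]
    cs <- cs - rep(c(0, offs), each = n)
  }
  cs
}

# 2-D box mean with edge-clipped (partial) windows, exact counts.
box_mean2 <- function(m, width) {
  if (width <= 1L) return(m)
  t(run_mean_cols(t(run_mean_cols(m, width)), width))
}

# 2-D running median via EBImage (odd window), used to smooth boundary maps.
# Borders are padded by odd (antisymmetric) reflection, which continues
# linear trends exactly and so avoids edge bias on sloped surfaces.
median2 <- function(m, width) {
  if (width <= 1L) return(m)
  w <- max(1L, width %/% 2L)
  w1 <- min(w, nrow(m) - 1L); w2 <- min(w, ncol(m) - 1L)
  p <- pad_odd_reflect(m, w)
  rng <- range(p, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(m)
  scaled <- (p - rng[1]) / diff(rng)
  out <- EBImage::medianFilter(scaled, size = w) * diff(rng) + rng[1]
  out[w1 + seq_len(nrow(m)), w2 + seq_len(ncol(m))]
}

pad_odd_reflect <- function(m, w) {
  n <- nrow(m); p <- ncol(m)
  w1 <- min(w, n - 1L); w2 <- min(w, p - 1L)
  top <- 2 * m[rep(1L, w1), , drop = FALSE] - m[1L + rev(seq_len(w1)), , drop = FALSE]
  bot <- 2 * m[rep(n, w1), , drop = FALSE] - m[n - seq_len(w1), , drop = FALSE]
  m2 <- rbind(top, m, bot)
  left <- 2 * m2[, rep(1L, w2), drop = FALSE] - m2[, 1L + rev(seq_len(w2)), drop = FALSE]
  right <- 2 * m2[, rep(p, w2), drop = FALSE] - m2[, p - seq_len(w2), drop = FALSE]
  cbind(left, m2, right)
}

# Physical pixel-centre coordinate grids (micrometres) for an en-face map.
enface_coords <- function(nx, ny, dx, dy) {
  list(
    x = (seq_len(nx) - 0.5) * dx,
    y = (seq_len(ny) - 0.5) * dy
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
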