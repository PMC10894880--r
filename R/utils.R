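# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All generator determinism rests on this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# the 32-bit signed integer range R requires.
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == as.integer(x)

# Coerce a tile to a numeric H x W x 3 array on the 8-bit (0..255) scale.
as_tile <- function(tile) {
  if (is.character(tile) && length(tile) == 1) {
    tile <- png::readPNG(tile) * 255
  }
  if (!is.array(tile) || length(dim(tile)) != 3 || dim(tile)[3] < 3) {
    stopf("expected an H x W x 3 RGB tile array")
  }
  tile[, , 1:3, drop = FALSE]
}

write_tile_png <- function(tile, path) {
  png::writePNG(pmin(pmax(tile / 255, 0), 1), target = path)
}

# Block-mean downsampling by an integer factor (area averaging).
downsample_block <- function(img, f) {
  stopifnot(f >= 1, f == as.integer(f))
  if (f == 1) return(img)
  d <- dim(img)
  h <- (d[1] %/% f) * f
  w <- (d[2] %/% f) * f
  img <- img[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, c(h %/% f, w %/% f, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    m <- rowsum(m, rep(seq_len(h %/% f), each = f))            # pool rows
    m <- t(rowsum(t(m), rep(seq_len(w %/% f), each = f)))      # pool cols
    out[, , ch] <- m / (f * f)
  }
  out
}

# Bilinear resize used when the resampling factor is not an integer.
resize_bilinear <- function(img, new_h, new_w) {
  d <- dim(img)
  ys <- (seq_len(new_h) - 0.5) * d[1] / new_h - 0.5
  xs <- (seq_len(new_w) - 0.5) * d[2] / new_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), d[1] - 1)
  x0 <- pmin(pmax(floor(xs), 0), d[2] - 1)
  y1 <- pmin(y0 + 1, d[1] - 1)
  x1 <- pmin(x0 + 1, d[2] - 1)
  wy <- ys - y0
  wx <- xs - x0
  out <- array(0, c(new_h, new_w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    a <- m[y0 + 1, x0 + 1, drop = FALSE]
    b <- m[y0 + 1, x1 + 1, drop = FALSE]
    cc <- m[y1 + 1, x0 + 1, drop = FALSE]
    dd <- m[y1 + 1, x1 + 1, drop = FALSE]
    top <- a + sweep(b - a, 2, wx, "*")
    bot <- cc + sweep(dd - cc, 2, wx, "*")
    out[, , ch] <- top + sweep(bot - top, 1, wy, "*")
  }
  out
}
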