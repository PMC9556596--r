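## Independent oracles and small builders used across the suite.

## Literal zero-normalised cross-correlation from its definition.
oracle_zncc <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  den <- sqrt(sum(am^2) * sum(bm^2))
  if (den == 0) return(NA_real_)
  sum(am * bm) / den
}

## Brute-force PIV at one grid centre: evaluate the ZNCC at every shift and
## take the argmax with the same deterministic tie-break (smallest
## magnitude, then (dy, dx)).
oracle_piv_point <- function(f1, f2, cx, cy, hs, margin) {
  src <- f1[(cy - hs):(cy + hs), (cx - hs):(cx + hs)]
  sh <- expand.grid(dx = -margin:margin, dy = -margin:margin)
  sh <- sh[order(sh$dx^2 + sh$dy^2, sh$dy, sh$dx), ]
  best <- -Inf; bdx <- 0; bdy <- 0
  for (k in seq_len(nrow(sh))) {
    dx <- sh$dx[k]; dy <- sh$dy[k]
    tgt <- f2[(cy + dy - hs):(cy + dy + hs), (cx + dx - hs):(cx + dx + hs)]
    cc <- oracle_zncc(src, tgt)
    if (!is.na(cc) && cc > best) { best <- cc; bdx <- dx; bdy <- dy }
  }
  list(dx = bdx, dy = bdy, corr = best)
}

## Full-frame speckle pair: frame2 equals frame1 shifted by (dx, dy) px
## (vacated pixels filled with zeros).
speckle_pair <- function(h = 64, w = 64, dx = 3, dy = 0, seed = 11) {
  set.seed(seed)
  f1 <- matrix(100 * exp(rnorm(h * w, 0, 0.3)), h, w)
  f2 <- matrix(0, h, w)
  xs <- seq_len(w); ys <- seq_len(h)
  okx <- xs - dx >= 1 & xs - dx <= w
  oky <- ys - dy >= 1 & ys - dy <= h
  f2[ys[oky], xs[okx]] <- f1[ys[oky] - dy, xs[okx] - dx]
  list(f1 = f1, f2 = f2)
}

## Brute-force grayscale opening (min over the structuring element, then
## max), out-of-bounds treated as background for the erosion.
oracle_opening <- function(mask, brush) {
  h <- nrow(mask); w <- ncol(mask)
  r <- (nrow(brush) - 1) / 2
  off <- which(brush == 1, arr.ind = TRUE) - (r + 1)
  ero <- matrix(FALSE, h, w); dil <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    ys <- y + off[, 1]; xs <- x + off[, 2]
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    vals <- rep(FALSE, nrow(off)); vals[ok] <- mask[cbind(ys[ok], xs[ok])]
    ero[y, x] <- all(vals)
  }
  for (y in seq_len(h)) for (x in seq_len(w)) {
    ys <- y + off[, 1]; xs <- x + off[, 2]
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    dil[y, x] <- any(ero[cbind(ys[ok], xs[ok])])
  }
  dil
}

## Rotate a matrix 90 degrees clockwise on screen; pixel (x, y) of an
## H x W image maps to (H + 1 - y, x) in the W x H result.
rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot90_cw_xy <- function(xy, h) cbind(h + 1 - xy[, 2], xy[, 1])

## Jaccard overlap of two masks.
mask_overlap <- function(a, b) sum(a & b) / sum(a | b)

## A fixed uniform flow field over an all-true mask.
uniform_field <- function(u0, v0, h = 20, w = 20, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  flow_field(u = matrix(u0, h, w), v = matrix(v0, h, w), valid = valid)
}
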