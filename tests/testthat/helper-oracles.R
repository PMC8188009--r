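# Shared helpers: brute-force oracles and small generators. Fixtures are
# built in code; nothing is read from disk.

# exhaustive nearest-background search (image border = background)
brute_edt <- function(bin) {
  d <- dim(bin)
  co <- as.matrix(expand.grid(z = 0:(d[1] - 1), y = 0:(d[2] - 1), x = 0:(d[3] - 1)))
  bg <- co[!bin[co + 1], , drop = FALSE]
  out <- apply(co, 1, function(p) {
    if (!bin[matrix(p + 1, 1)]) return(0)
    dborder <- min(p + 1, d - p)
    dmin <- if (nrow(bg)) sqrt(min(colSums((t(bg) - p)^2))) else Inf
    min(dborder, dmin)
  })
  array(out, d)
}

# brute-force ball median filter (out-of-grid samples omitted)
brute_median3 <- function(vol, radius) {
  d <- dim(vol)
  off <- as.matrix(expand.grid(dz = -radius:radius, dy = -radius:radius,
                               dx = -radius:radius))
  off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    nb <- sweep(off, 2, c(z, y, x), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    out[z, y, x] <- median(vol[nb[ok, , drop = FALSE]])
  }
  out
}

# random valid ellipsoid inside the given dims
random_ellipsoid <- function(dims) {
  ax <- qr.Q(qr(matrix(rnorm(9), 3)))
  r <- sort(runif(3, 1, max(3, min(dims) / 3)))
  ctr <- runif(3, min(dims) / 4, 3 * min(dims) / 4)
  ellipsoid(ctr, r, ax)
}

# number of 26-connected foreground components
count_components26 <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(bin)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  for (i in idx) {
    if (lab[i]) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(p), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1 + d[2] * (nb[, 3] - 1))
      new <- lin[bin[lin] & lab[lin] == 0L]
      lab[new] <- nxt
      queue <- c(queue, new)
    }
  }
  nxt
}

# a tiny TIFF with two pages of differing dimensions (malformed stack)
write_mixed_page_tiff <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L)
  # page 1: 2x2 at offset 8; page 2: 3x1 at offset 12
  w32(16L)  # first IFD offset
  writeBin(as.integer(c(1, 2, 3, 4)), con, size = 1)      # page 1 data
  writeBin(as.integer(c(5, 6, 7, 0)), con, size = 1)      # page 2 data (+pad)
  ifd <- function(w, h, off, nxt) {
    w16(6L)
    ent <- function(tag, type, count, val) {
      w16(tag); w16(type); w32(count)
      if (type == 3) { w16(val); w16(0L) } else w32(val)
    }
    ent(256L, 4L, 1L, w); ent(257L, 4L, 1L, h); ent(258L, 3L, 1L, 8L)
    ent(259L, 3L, 1L, 1L); ent(273L, 4L, 1L, off); ent(279L, 4L, 1L, w * h)
    w32(nxt)
  }
  ifd(2L, 2L, 8L, 16L + 2L + 6L * 12L + 4L)
  ifd(3L, 1L, 12L, 0L)
  invisible(path)
}
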