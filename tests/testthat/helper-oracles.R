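# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately re-derive results by the most direct
# method available (per-pixel loops, flood fill, exhaustive search) and
# share no code with the implementation.

# --- flood fill / connected components (plain R, queue-based) ----------

flood_from <- function(mask, i, j, conn = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  stack <- (j - 1L) * H + i
  seen[i, j] <- TRUE
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1); dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  keep <- if (conn == 8) 1:8 else c(1, 3, 5, 7)
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    pi <- (p - 1L) %% H + 1L; pj <- (p - 1L) %/% H + 1L
    for (d in keep) {
      ni <- pi + dr[d]; nj <- pj + dc[d]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
          mask[ni, nj] && !seen[ni, nj]) {
        seen[ni, nj] <- TRUE
        stack <- c(stack, (nj - 1L) * H + ni)
      }
    }
  }
  seen
}

oracle_label <- function(mask, conn = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) {
    for (i in seq_len(nrow(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        lab[flood_from(mask, i, j, conn)] <- nxt
      }
    }
  }
  lab
}

# hole-filled version of a single-component mask: background 4-connected
# to the padded frame stays outside, everything else is region
oracle_fill_holes <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(TRUE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- !comp
  outside <- flood_from(pad, 1L, 1L, conn = 4)[2:(H + 1L), 2:(W + 1L)]
  !outside
}

# --- naive per-pixel LBP oracle with explicit bilinear interpolation ----

oracle_lbp <- function(g, mask, scales) {
  H <- nrow(g); W <- ncol(g)
  out <- numeric(0)
  for (s in scales) {
    R <- s[1]; P <- s[2]; m <- ceiling(R)
    h <- numeric(P + 2)
    for (yy in 0:(H - 1)) for (xx in 0:(W - 1)) {
      if (!mask[yy + 1, xx + 1]) next
      if (xx < m || xx > W - 1 - m || yy < m || yy > H - 1 - m) next
      centre <- g[yy + 1, xx + 1]
      bits <- logical(P)
      for (k in 0:(P - 1)) {
        ang <- 2 * pi * k / P
        nx <- xx + R * cos(ang); ny <- yy - R * sin(ang)
        if (abs(nx - round(nx)) < 1e-8) nx <- round(nx)
        if (abs(ny - round(ny)) < 1e-8) ny <- round(ny)
        x0 <- floor(nx); y0 <- floor(ny); wx <- nx - x0; wy <- ny - y0
        x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
        val <- (1 - wx) * (1 - wy) * g[y0 + 1, x0 + 1] +
          wx * (1 - wy) * g[y0 + 1, x1 + 1] +
          (1 - wx) * wy * g[y1 + 1, x0 + 1] +
          wx * wy * g[y1 + 1, x1 + 1]
        bits[k + 1] <- val >= centre - 1e-6
      }
      tr <- sum(bits != bits[c(2:P, 1)])
      lab <- if (tr <= 2) sum(bits) else P + 1
      h[lab + 1] <- h[lab + 1] + 1
    }
    out <- c(out, h / sum(h))
  }
  out
}

# --- misc fixture builders ---------------------------------------------

square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side - 1, y0),
        c(x0 + side - 1, y0 + side - 1), c(x0, y0 + side - 1))
}

disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1), each = H), H)
  ys <- matrix(rep(0:(H - 1), times = W), H)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

cysts_equal <- function(a, b) {
  identical(lapply(unname(a$cysts), unclass), lapply(unname(b$cysts), unclass))
}

# constant-colour test image with given green channel
flat_rgb <- function(H, W, r = 100, g = 100, b = 100) {
  rgb_image(array(rep(c(r, g, b), each = H * W), c(H, W, 3)))
}

mask_region <- function(cy, H, W) {
  m <- matrix(FALSE, H, W)
  m[cy$region] <- TRUE
  m
}

# hole filling works per-mask (not per-component): background 4-connected
# to the frame survives, every enclosed pocket is filled
oracle_fill_holes_all <- oracle_fill_holes
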