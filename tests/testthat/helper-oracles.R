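# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Rcpp morphology, EBImage distmap, stats::wilcox).

# Grayscale opening with a ball-shaped SE by direct shift-and-extremum:
# erosion then dilation, out-of-image neighbours ignored.
oracle_ball_opening <- function(x, diameter) {
  r <- diameter / 2
  ri <- floor(r)
  offs <- list()
  for (dr in -ri:ri) for (dc in -ri:ri) {
    if (dr^2 + dc^2 <= r^2)
      offs[[length(offs) + 1]] <- c(dr, dc, sqrt(r^2 - dr^2 - dc^2))
  }
  nr <- nrow(x); nc <- ncol(x)
  shift_apply <- function(src, f, init, sign) {
    out <- matrix(init, nr, nc)
    for (o in offs) {
      dr <- o[1]; dc <- o[2]; h <- o[3]
      rs <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 - dc):min(nc, nc - dc)
      out[rs, cs] <- f(out[rs, cs], src[rs + dr, cs + dc] + sign * h)
    }
    out
  }
  er <- shift_apply(x, pmin, Inf, -1)
  # dilation uses the reflected SE; the ball is symmetric
  shift_apply(er, pmax, -Inf, +1)
}

# Exact per-pixel ring: pixels whose min Euclidean distance to any object
# pixel lies in (gap, gap + width].
oracle_ring <- function(obj, gap, width) {
  nr <- nrow(obj); nc <- ncol(obj)
  op <- which(obj, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  if (!nrow(op)) return(out)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (obj[r, c]) next
    d <- sqrt(min((op[, 1] - r)^2 + (op[, 2] - c)^2))
    out[r, c] <- d > gap & d <= gap + width
  }
  out
}

# Connected-component count by an independent stack-based flood fill.
oracle_count_components <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nb <- if (eight) expand.grid(dr = -1:1, dc = -1:1) else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  count <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] &&
            !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Two-sided exact Mann-Whitney p by enumeration of all C(n+m, n) rank
# assignments (tie-free inputs).
oracle_mann_whitney_p <- function(a, b) {
  n <- length(a); m <- length(b)
  u_stat <- function(xa, xb) sum(outer(xa, xb, ">")) # U for first sample
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p <- if (u_obs <= n * m / 2) mean(us <= u_obs) else mean(us >= u_obs)
  min(1, 2 * p)
}

# Kruskal-Wallis H from the rank-sum formula (no tie correction needed for
# tie-free inputs).
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  N <- length(x); rk <- rank(x)
  rs <- tapply(rk, g, sum)
  n <- lengths(groups)
  12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
}

make_tempdir <- function() {
  d <- tempfile("lequant_fx_")
  dir.create(d)
  d
}

# Noise-free, blur-free photophysics; callers may override any field.
clean_phys <- function(...) {
  args <- list(psf_sigma = 0, poisson_noise = FALSE,
               gaussian_read_noise_sd = 0, shading_amplitude = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(photophysics_params, args)
}
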