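# Independent brute-force oracles used to check the morphological kernels.
# Everything here is deliberately naive (shift-based filters, iterate-to-
# fixed-point geodesic operations, O(n^2) ordered flooding) and shares no
# code with the package internals.

elementary_se <- function(conn) {
  if (conn == 8) matrix(1, 3, 3)
  else matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
}

# flat min/max filter by explicit shifts with +/-Inf padding
oracle_filter <- function(x, se, op) {
  ctr <- (dim(se) + 1) / 2
  offs <- which(se == 1, arr.ind = TRUE)
  nr <- nrow(x); nc <- ncol(x)
  pad <- if (identical(op, pmax)) -Inf else Inf
  big <- matrix(pad, nr + 2 * nrow(se), nc + 2 * ncol(se))
  big[nrow(se) + (1:nr), ncol(se) + (1:nc)] <- x
  out <- matrix(pad, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1] - ctr[1]; dc <- offs[k, 2] - ctr[2]
    out <- op(out, big[nrow(se) + (1:nr) + dr, ncol(se) + (1:nc) + dc])
  }
  out
}

oracle_dilate <- function(x, se) oracle_filter(x, se, pmax)
oracle_erode <- function(x, se) oracle_filter(x, se, pmin)
oracle_opening <- function(x, se) oracle_dilate(oracle_erode(x, se), se)
oracle_closing <- function(x, se) oracle_erode(oracle_dilate(x, se), se)

# geodesic reconstruction by dilation: iterate elementary geodesic steps
oracle_reconstruct_dilate <- function(marker, mask, conn = 8) {
  se <- elementary_se(conn)
  j <- pmin(marker, mask)
  repeat {
    j2 <- pmin(oracle_dilate(j, se), mask)
    if (identical(j2, j)) return(j)
    j <- j2
  }
}

oracle_reconstruct_erode <- function(marker, mask, conn = 8) {
  se <- elementary_se(conn)
  j <- pmax(marker, mask)
  repeat {
    j2 <- pmax(oracle_erode(j, se), mask)
    if (identical(j2, j)) return(j)
    j <- j2
  }
}

oracle_open_reconstruction <- function(g, r, b, conn = 8) {
  oracle_reconstruct_dilate(oracle_opening(g, unclass(b)), r, conn)
}

oracle_close_reconstruction <- function(g, r, b, conn = 8) {
  hi <- max(g, r, 1)
  hi - oracle_open_reconstruction(hi - g, hi - r, b, conn)
}

neighbours_of <- function(i, j, nr, nc, conn) {
  d8 <- cbind(dr = c(-1, 0, 1, -1, 1, -1, 0, 1),
              dc = c(-1, -1, -1, 0, 0, 1, 1, 1))
  d4 <- cbind(dr = c(0, -1, 1, 0), dc = c(-1, 0, 0, 1))
  d <- if (conn == 8) d8 else d4
  out <- cbind(i + d[, 1], j + d[, 2])
  out[out[, 1] >= 1 & out[, 1] <= nr & out[, 2] >= 1 & out[, 2] <= nc, ,
      drop = FALSE]
}

# exhaustive regional-minima scan: flood each equal-value plateau and look
# for a strictly lower neighbour
oracle_regional_minima <- function(x, conn = 8) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  seen <- matrix(FALSE, nr, nc)
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (seen[i0, j0]) next
    v <- x[i0, j0]
    plateau <- matrix(c(i0, j0), 1, 2)
    seen[i0, j0] <- TRUE
    frontier <- plateau
    is_min <- TRUE
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (k in seq_len(nrow(frontier))) {
        nb <- neighbours_of(frontier[k, 1], frontier[k, 2], nr, nc, conn)
        for (q in seq_len(nrow(nb))) {
          vi <- x[nb[q, 1], nb[q, 2]]
          if (vi < v) is_min <- FALSE
          if (vi == v && !seen[nb[q, 1], nb[q, 2]]) {
            seen[nb[q, 1], nb[q, 2]] <- TRUE
            nxt <- rbind(nxt, nb[q, , drop = FALSE])
          }
        }
      }
      if (!is.null(nxt)) plateau <- rbind(plateau, nxt)
      frontier <- if (is.null(nxt)) matrix(0, 0, 2) else nxt
    }
    if (is_min) out[plateau] <- TRUE
  }
  out
}

# naive ordered flooding with the same documented semantics as the
# package watershed: candidates are processed in increasing surface value
# (FIFO on exact ties), a pixel takes the label of its settled neighbours
# when they agree and is a ridge otherwise.
oracle_watershed <- function(surface, markers, conn = 8, assign_ridge = TRUE) {
  nr <- nrow(surface); nc <- ncol(surface)
  lab <- markers
  settled <- markers > 0
  cand_idx <- integer(0)
  cand_ord <- integer(0)
  queued <- matrix(FALSE, nr, nc)
  tick <- 0L
  push_neighbours <- function(i, j) {
    nb <- neighbours_of(i, j, nr, nc, conn)
    for (q in seq_len(nrow(nb))) {
      ii <- nb[q, 1]; jj <- nb[q, 2]
      if (!settled[ii, jj] && !queued[ii, jj]) {
        queued[ii, jj] <<- TRUE
        tick <<- tick + 1L
        cand_idx <<- c(cand_idx, (jj - 1L) * nr + ii)
        cand_ord <<- c(cand_ord, tick)
      }
    }
  }
  for (j in seq_len(nc)) for (i in seq_len(nr))
    if (settled[i, j]) push_neighbours(i, j)
  while (length(cand_idx) > 0) {
    vals <- surface[cand_idx]
    best <- which(vals == min(vals))
    best <- best[which.min(cand_ord[best])]
    p <- cand_idx[best]
    cand_idx <- cand_idx[-best]; cand_ord <- cand_ord[-best]
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    nb <- neighbours_of(i, j, nr, nc, conn)
    sel <- settled[nb]
    ls <- unique(lab[nb[sel, , drop = FALSE]])
    ls <- ls[ls > 0]
    settled[i, j] <- TRUE
    if (length(ls) == 0L) next
    if (length(ls) == 1L) {
      lab[i, j] <- ls
      push_neighbours(i, j)
    } else {
      lab[i, j] <- if (assign_ridge) min(ls) else 0L
      if (assign_ridge) push_neighbours(i, j)
    }
  }
  lab
}

# mean Euclidean distance of mismatched pixels to the reference boundary,
# computed with explicit pairwise distances
oracle_mismatch_spacing <- function(candidate, reference) {
  nr <- nrow(reference); nc <- ncol(reference)
  is_boundary <- function(i, j) {
    if (!reference[i, j]) return(FALSE)
    nb4 <- neighbours_of(i, j, nr, nc, 4)
    nrow(nb4) < 4 || any(!reference[nb4])
  }
  bnd <- which(outer(seq_len(nr), seq_len(nc),
                     Vectorize(is_boundary)), arr.ind = TRUE)
  mism <- which(xor(candidate, reference), arr.ind = TRUE)
  if (nrow(mism) == 0) return(0)
  mean(vapply(seq_len(nrow(mism)), function(k) {
    min(sqrt((bnd[, 1] - mism[k, 1])^2 + (bnd[, 2] - mism[k, 2])^2))
  }, numeric(1)))
}

# between-class-variance maximizing threshold by exhaustive search over
# 256 histogram bins
oracle_otsu_threshold <- function(x, levels = 256) {
  h <- tabulate(pmin(floor(x * levels) + 1L, levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf; thr <- mids[1]
  for (t in seq_len(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; thr <- mids[t] + 0.5 / levels }
  }
  thr
}

# direct 3x3 Sobel convolution with replicated borders
oracle_sobel_magnitude <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- x[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    win <- pad[i:(i + 2), j:(j + 2)]
    gx[i, j] <- sum(win * kx)
    gy[i, j] <- sum(win * t(kx))
  }
  sqrt(gx^2 + gy^2)
}

random_test_raster <- function(nr, nc, levels = NULL) {
  x <- matrix(runif(nr * nc), nr, nc)
  if (!is.null(levels)) x <- (ceiling(x * levels) - 1) / (levels - 1)
  x
}

disk_mask <- function(r, center = NULL, nr = NULL, nc = NULL) {
  if (is.null(nr)) nr <- 2 * r + 7
  if (is.null(nc)) nc <- nr
  if (is.null(center)) center <- c(nr, nc) / 2
  outer((seq_len(nr) - 0.5 - center[1])^2,
        (seq_len(nc) - 0.5 - center[2])^2, "+") <= r^2
}
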