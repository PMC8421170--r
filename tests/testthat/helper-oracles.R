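# Independent oracles used to cross-check the implementation.

# Shift a matrix by (dr, dc), filling vacated cells with 0.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- intersect(seq_len(nr), seq_len(nr) - dr)
  cs <- intersect(seq_len(nc), seq_len(nc) - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

seOffsets <- function(se) {
  ctr <- (dim(se) + 1L) / 2L
  w <- which(se != 0, arr.ind = TRUE)
  cbind(dr = w[, 1L] - ctr[1L], dc = w[, 2L] - ctr[2L])
}

# Erosion/dilation as explicit shift compositions (independent of EBImage's
# filter-based implementation).
naiveErode <- function(mask, se) {
  off <- seOffsets(se)
  out <- matrix(1L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out & shiftMat(mask, -off[k, 1L], -off[k, 2L])
  out * 1L
}

naiveDilate <- function(mask, se) {
  off <- seOffsets(se)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out | shiftMat(mask, off[k, 1L], off[k, 2L])
  out * 1L
}

naiveOpenClose <- function(mask, se) {
  op <- naiveDilate(naiveErode(mask, se), se)
  naiveErode(naiveDilate(op, se), se)
}

# Random connected blob grown from a seed pixel (kept away from borders).
randomBlob <- function(nr, nc, npix, pad = 8L) {
  r <- sample((pad + 1):(nr - pad), 1L)
  c <- sample((pad + 1):(nc - pad), 1L)
  m <- matrix(0L, nr, nc)
  m[r, c] <- 1L
  cur <- matrix(c(r, c), 1L)
  while (sum(m) < npix) {
    i <- cur[sample(nrow(cur), 1L), ]
    step <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    r2 <- min(max(i[1L] + step[1L], pad + 1L), nr - pad)
    c2 <- min(max(i[2L] + step[2L], pad + 1L), nc - pad)
    if (!m[r2, c2]) {
      m[r2, c2] <- 1L
      cur <- rbind(cur, c(r2, c2))
    }
  }
  m
}

# Exhaustive one-to-one assignment: over all injective mappings of tracks to
# detections passing both gates, maximize matches then minimize total
# distance. Feasible for tiny instances only.
exhaustiveMatch <- function(trackXY, trackArea, detXY, detArea, tDis, tSize) {
  nt <- nrow(trackXY); nd <- nrow(detXY)
  ok <- matrix(FALSE, nt, nd)
  dm <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) for (j in seq_len(nd)) {
    d <- sqrt(sum((trackXY[i, ] - detXY[j, ])^2))
    ratio <- max(trackArea[i], detArea[j]) / min(trackArea[i], detArea[j])
    if (d <= tDis && ratio <= tSize) { ok[i, j] <- TRUE; dm[i, j] <- d }
  }
  best <- NULL; bestN <- -1L; bestCost <- Inf
  assign <- integer(nt)
  recur <- function(i, used, n, cost) {
    if (i > nt) {
      if (n > bestN || (n == bestN && cost < bestCost)) {
        bestN <<- n; bestCost <<- cost; best <<- assign
      }
      return(invisible())
    }
    for (j in seq_len(nd)) {
      if (ok[i, j] && !used[j]) {
        assign[i] <<- j
        used[j] <- TRUE
        recur(i + 1L, used, n + 1L, cost + dm[i, j])
        used[j] <- FALSE
      }
    }
    assign[i] <<- 0L
    recur(i + 1L, used, n, cost)
  }
  recur(1L, logical(nd), 0L, 0)
  best
}

# Small helper: a filled disk mask.
diskMask <- function(nr, nc, r0, c0, rad) {
  m <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if ((r - r0)^2 + (c - c0)^2 <= rad^2) m[r, c] <- 1L
  m
}
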