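# Independent brute-force oracles. These deliberately share no code
# with the package: plain double loops and direct formula evaluation.

# build a quantized_roi directly from a level matrix (NA = outside mask)
make_qroi <- function(levels, n_gray = max(levels, na.rm = TRUE) + 1L,
                      values = levels[!is.na(levels)], role = "tumor",
                      spacing_mm = 1) {
  structure(list(levels = levels, values = as.numeric(values),
                 n_gray = as.integer(n_gray), role = role,
                 constant = length(unique(values)) == 1L,
                 spacing_mm = spacing_mm),
            class = "quantized_roi")
}

# exhaustive pair enumeration GLCM (symmetric, normalized)
oracle_glcm <- function(L, ng, dy, dx) {
  h <- nrow(L); w <- ncol(L)
  cnt <- matrix(0, ng, ng)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
    a <- L[r, c]; b <- L[r2, c2]
    if (is.na(a) || is.na(b)) next
    cnt[a + 1, b + 1] <- cnt[a + 1, b + 1] + 1
    cnt[b + 1, a + 1] <- cnt[b + 1, a + 1] + 1
  }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# direct Haralick formula evaluation with explicit loops, levels 1..ng
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  asm <- ctr <- idm <- ent <- 0
  mux <- muy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    ctr <- ctr + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    mux <- mux + i * p
    muy <- muy + j * p
  }
  sdx <- sdy <- 0; corr_num <- 0; ssq <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    sdx <- sdx + (i - mux)^2 * p
    sdy <- sdy + (j - muy)^2 * p
    corr_num <- corr_num + i * j * p
    ssq <- ssq + (i - mux)^2 * p
  }
  corr <- if (sdx > 0 && sdy > 0)
    (corr_num - mux * muy) / sqrt(sdx * sdy) else 0
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  savg <- sum((1:(2 * ng)) * psum)
  svar <- sum(((1:(2 * ng)) - savg)^2 * psum)
  sent <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  dmu <- sum((0:(ng - 1)) * pdif)
  dvar <- sum(((0:(ng - 1)) - dmu)^2 * pdif)
  dent <- -sum(pdif[pdif > 0] * log(pdif[pdif > 0]))
  c(AngScMom = asm, Contrast = ctr, Correlation = corr, SumOfSqs = ssq,
    InvDfMom = idm, SumAverg = savg, SumVarnc = svar, SumEntrp = sent,
    Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

# run enumeration by explicit walking along a direction
oracle_runs <- function(L, angle) {
  step <- switch(as.character(angle),
                 `0` = c(0, 1), `90` = c(1, 0),
                 `45` = c(-1, 1), `135` = c(1, 1))
  h <- nrow(L); w <- ncol(L)
  inb <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w
  runs <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    # scanline start: no predecessor
    if (inb(r - step[1], c - step[2])) next
    rr <- r; cc <- c
    cur <- NA; len <- 0
    while (inb(rr, cc)) {
      v <- L[rr, cc]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      if (is.na(v)) cur <- NA
      rr <- rr + step[1]; cc <- cc + step[2]
    }
    if (!is.na(cur) && len > 0) runs[[length(runs) + 1]] <- c(cur, len)
  }
  if (length(runs) == 0)
    return(data.frame(level = integer(), length = integer()))
  m <- do.call(rbind, runs)
  data.frame(level = m[, 1], length = m[, 2])
}

oracle_glrlm_features <- function(runs, npix) {
  n <- nrow(runs)
  per_level <- tapply(rep(1, n), runs$level, sum)
  per_length <- tapply(rep(1, n), runs$length, sum)
  c(RLNonUni = sum(per_length^2) / n,
    GLevNonU = sum(per_level^2) / n,
    ShrtREmp = sum(1 / runs$length^2) / n,
    LngREmph = sum(runs$length^2) / n,
    Fraction = n / npix)
}

# step-up BH by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- min(1, prev)
  }
  adj
}

# random masked level matrix for oracle-equivalence tests
random_qroi <- function(seed) {
  set.seed(seed)
  h <- sample(2:8, 1); w <- sample(2:8, 1)
  ng <- sample(c(4L, 8L), 1)
  L <- matrix(sample(0:(ng - 1), h * w, replace = TRUE), h, w)
  if (runif(1) < 0.7) {
    drop <- runif(h * w) < 0.3
    if (sum(!drop) < 2) drop[seq_len(2)] <- FALSE
    L[drop] <- NA
  }
  make_qroi(L, n_gray = ng)
}
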