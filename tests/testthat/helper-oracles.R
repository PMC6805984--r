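# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# All-pairs physical-distance contraction: retain a member voxel iff no
# in-grid complement voxel center lies within `d` mm of its center.
bruteContract <- function(mask, d) {
  v <- voxels(mask)
  sp <- gridSpacing(mask)
  idx <- which(v | !v, arr.ind = TRUE)  # all voxels
  pts <- sweep(idx, 2, sp, "*")
  member <- as.vector(v)
  keep <- member
  compPts <- pts[!member, , drop = FALSE]
  if (nrow(compPts)) {
    for (i in which(member)) {
      dd <- sqrt(colSums((t(compPts) - pts[i, ])^2))
      if (any(dd <= d)) keep[i] <- FALSE
    }
  }
  binaryMask(array(keep, dim(v)), grid = mask@grid)
}

# All-pairs expansion: add a complement voxel iff some member center is
# within `d` mm.
bruteExpand <- function(mask, d) {
  v <- voxels(mask)
  sp <- gridSpacing(mask)
  idx <- which(v | !v, arr.ind = TRUE)
  pts <- sweep(idx, 2, sp, "*")
  member <- as.vector(v)
  out <- member
  memPts <- pts[member, , drop = FALSE]
  if (nrow(memPts)) {
    for (i in which(!member)) {
      dd <- sqrt(colSums((t(memPts) - pts[i, ])^2))
      if (any(dd <= d)) out[i] <- TRUE
    }
  }
  binaryMask(array(out, dim(v)), grid = mask@grid)
}

# Pairwise win-fraction AUC (ties count one half).
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over candidate cutoffs at the observed scores;
# applies the tie-break (higher sensitivity, then lower cutoff).
bruteYouden <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    se <- mean(scores[labels == 1] >= t)
    sp <- mean(scores[labels == 0] < t)
    j <- se + sp - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (se > best$se + 1e-12 ||
          (abs(se - best$se) <= 1e-12 && t < best$t)))) {
      best <- list(t = t, j = j, se = se, sp = sp)
    }
  }
  best
}

# Random mask whose members stay `margin` physical mm away from the
# grid boundary, so expansions up to `margin` cannot clip.
randomMask <- function(shape, p = 0.4, spacing = rep(1, 3), margin = 0) {
  pad <- ceiling(margin / spacing)
  full <- as.integer(shape + 2 * pad)
  v <- array(FALSE, full)
  inner <- array(runif(prod(shape)) < p, shape)
  v[pad[1] + seq_len(shape[1]), pad[2] + seq_len(shape[2]),
    pad[3] + seq_len(shape[3])] <- inner
  binaryMask(v, grid = imageGrid(full, spacing))
}

smallCohortSpec <- function(n = 30L) cohortSpec(nPatients = as.integer(n))
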