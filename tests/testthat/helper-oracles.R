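## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the superposition oracle uses Horn's
## quaternion eigenvector method instead of SVD, and the assignment oracle
## re-steps the sequential pseudocode directly over a profile table.

## Optimal rigid superposition RMSD via Horn's quaternion method.
quaternion_rmsd <- function(model, target) {
  n <- nrow(model)
  a <- sweep(model, 2, colMeans(model))
  b <- sweep(target, 2, colMeans(target))
  m <- crossprod(a, b)  # sum a_i b_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,        -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(a * a) + sum(b * b) - 2 * lam
  sqrt(max(e2, 0) / n)
}

## A random, valid (non-degenerate) C-alpha quadruple: a helix with random
## parameters, random rigid placement and small coordinate jitter.
random_quad <- function(seed) {
  set.seed(seed)
  r <- runif(1, 1.2, 3.0)
  p <- runif(1, 0.8, 2.5)
  t <- runif(1, 60, 140)
  cur <- helical_curve(r, p, t, origin = rnorm(3, sd = 5),
                      rotation = random_rotation(seed + 10000))
  curve_point(cur, 0:3) + matrix(rnorm(12, sd = 0.03), 4, 3)
}

## Random proper rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  rot
}

## Fabricate a helix_profile from explicit per-residue vectors, to exercise
## assignment pseudocode paths without geometry.
stub_profile <- function(h = NULL, g = NULL, pi_s = NULL, a = NULL,
                         sd = NULL, n = NULL, handedness = "right") {
  n <- if (is.null(n)) max(lengths(list(h, g, pi_s, a, sd))) else n
  fill <- function(v) {
    out <- rep(NA_real_, n)
    if (!is.null(v)) out[seq_along(v)] <- v
    out
  }
  structure(list(
    profile = data.frame(index = seq_len(n), r = NA_real_, p = NA_real_,
                         t = NA_real_, delta = NA_real_, a = fill(a),
                         small_delta = fill(sd), h = fill(h), g = fill(g),
                         pi = fill(pi_s)),
    fits = list(), handedness = handedness, n = n),
    class = "helix_profile")
}

## Hand-stepped re-derivation of the sequential pi -> 3-10 -> alpha
## pseudocode over one profile table, starting from assigned flags b0.
## Returns list(out = data.frame(start, end, type), b = final flags).
## Written independently of the package's pass functions (one function,
## explicit flag vector, iterative merge).
trace_assignment <- function(pr, n, th = threshold_config(),
                             b0 = rep(FALSE, n)) {
  ok <- function(x, thr) !is.na(x) && x < thr
  oke <- function(x, thr) !is.na(x) && x <= thr
  at <- function(v, i) if (i >= 1 && i <= n) v[i] else NA_real_
  b <- b0
  out <- data.frame(start = integer(), end = integer(),
                    type = character(), stringsAsFactors = FALSE)
  add <- function(s, e, ty) rbind(out, data.frame(start = s, end = e,
                                                  type = ty,
                                                  stringsAsFactors = FALSE))
  ## pi pass
  i <- 1
  while (i <= n) {
    if (!b[i] && ok(pr$pi[i], th$pi_T) && ok(at(pr$a, i), th$a_I) &&
        ok(at(pr$a, i + 1), th$a_I) && ok(at(pr$a, i + 2), th$a_I)) {
      s <- i; b[i] <- TRUE; i <- i + 1
      while (i <= n - 3 && !b[i] && ok(pr$pi[i], th$pi_T)) {
        b[i] <- TRUE; i <- i + 1
      }
      e <- i - 1
      j <- i
      while (j <= min(i + 3, n) && !b[j]) { b[j] <- TRUE; e <- j; j <- j + 1 }
      if (e - s + 1 >= 5) out <- add(s, e, "pi") else b[s:e] <- FALSE
      i <- e + 1
    } else i <- i + 1
  }
  ## 3-10 pass
  i <- 1
  while (i <= n) {
    if (!b[i] && ok(pr$g[i], th$g_T) && ok(at(pr$a, i), th$a_G)) {
      s <- i; b[i] <- TRUE; i <- i + 1
      while (i <= n && !b[i] && ok(pr$g[i], th$g_T)) {
        b[i] <- TRUE; i <- i + 1
      }
      e <- i - 1
      if (ok(at(pr$small_delta, i), th$delta_G) &&
          ok(at(pr$small_delta, i + 1), th$delta_G)) {
        j <- i
        while (j <= min(i + 1, n) && !b[j]) { b[j] <- TRUE; e <- j; j <- j + 1 }
      }
      if (e - s + 1 >= 3) out <- add(s, e, "310") else b[s:e] <- FALSE
      i <- e + 1
    } else i <- i + 1
  }
  ## alpha pass
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!b[i] && ok(pr$h[i], th$h_T) && ok(at(pr$a, i), th$a_T) &&
        ok(at(pr$h, i + 1), th$h_T)) {
      s <- i; b[i] <- TRUE; i <- i + 1
      while (i <= n && !b[i] && ok(pr$h[i], th$h_T)) {
        b[i] <- TRUE; i <- i + 1
      }
      runs[[length(runs) + 1]] <- c(s, i - 1)
    } else i <- i + 1
  }
  ## merge (left to right, cascading)
  k <- 1
  while (k < length(runs)) {
    cur <- runs[[k]]; nxt <- runs[[k + 1]]
    gapn <- nxt[1] - cur[2] - 1
    gap <- if (gapn > 0) (cur[2] + 1):(nxt[1] - 1) else integer()
    mergeable <- gapn < 4 && all(vapply(gap, function(ii)
      !b[ii] && oke(pr$a[ii], th$a_max) && ok(pr$h[ii], th$h_max) &&
        ok(pr$small_delta[ii], th$delta_max), logical(1)))
    if (mergeable) {
      b[gap] <- TRUE
      runs[[k]] <- c(cur[1], nxt[2])
      runs[[k + 1]] <- NULL
    } else k <- k + 1
  }
  ## extend C-termini
  for (k in seq_along(runs)) {
    j <- runs[[k]][2] + 1
    if (j <= n && !b[j] && ok(pr$h[j], th$h_max) && ok(pr$a[j], th$a_max)) {
      b[j] <- TRUE; runs[[k]][2] <- j
      if (j + 1 <= n && !b[j + 1]) { b[j + 1] <- TRUE; runs[[k]][2] <- j + 1 }
    }
  }
  for (r in runs) {
    if (r[2] - r[1] + 1 >= 4) out <- add(r[1], r[2], "alpha")
    else b[r[1]:r[2]] <- FALSE
  }
  list(out = out, b = b)
}

## Hand-trace of the full two-handedness orchestration over one segment.
## Profile numbers come from the package (shared input); the pass logic is
## the independently re-derived part.
trace_segment <- function(xyz, th = threshold_config()) {
  n <- nrow(xyz)
  res <- data.frame(start = integer(), end = integer(), type = character(),
                    handedness = character(), stringsAsFactors = FALSE)
  b <- rep(FALSE, n)
  for (hand in c("right", "left")) {
    pr <- profile_segment(xyz, handedness = hand)$profile
    tr <- trace_assignment(pr, n, th, b)
    b <- tr$b
    if (nrow(tr$out))
      res <- rbind(res, cbind(tr$out, handedness = hand,
                              stringsAsFactors = FALSE))
  }
  res[order(res$start), , drop = FALSE]
}
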