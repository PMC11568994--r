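# Contrastive objectives over cosine similarities of L2-normalized
# descriptors: the supervised contrastive loss (SupCon), a multi-positive
# InfoNCE (MP-InfoNCE), and a triplet baseline.
#
# Index conventions follow the multiviewed batch: z[i, k, ] is the unit-norm
# descriptor of keypoint k in view i, i in 1..N+1 (view 1 = original image),
# k in 1..K.  Cosine similarity of unit vectors is their dot product.

#' Multiview descriptor tensor
#'
#' @param z numeric array (N+1) x K x D of descriptors; every (i, k) row
#'   must have unit Euclidean norm to within 1e-5.
#' @param tau temperature, > 0 (default 0.1).
#' @return an object of class `multiview_descriptor_tensor`.
#' @export
multiview_descriptor_tensor <- function(z, tau = 0.1) {
  stopifnot(length(dim(z)) == 3, tau > 0)
  n <- sqrt(apply(z^2, c(1, 2), sum))
  if (any(abs(n - 1) > 1e-5)) {
    stopf("fundusreg_invalid_argument",
          "descriptors must be unit-norm (max deviation %.2e)",
          max(abs(n - 1)))
  }
  structure(list(z = z, tau = tau), class = "multiview_descriptor_tensor")
}

#' Cosine similarity of two unit-norm descriptors
#'
#' For L2-normalized descriptors the cosine similarity is the plain dot
#' product; inputs deviating from unit norm by more than 1e-3 are a contract
#' violation.
#' @param a,b numeric unit vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
similarity <- function(a, b) {
  if (abs(sqrt(sum(a^2)) - 1) > 1e-3 || abs(sqrt(sum(b^2)) - 1) > 1e-3) {
    stopf("fundusreg_invalid_argument",
          "similarity() requires unit-norm descriptors")
  }
  sum(a * b)
}

# Flatten (V, K, D) -> (V*K, D) with view-major row order: row (i-1)*K + k.
flatten_tensor <- function(z) {
  d <- dim(z)
  matrix(aperm(z, c(2, 1, 3)), d[1] * d[2], d[3])
}

check_tensor <- function(t) {
  stopifnot(inherits(t, "multiview_descriptor_tensor"))
  d <- dim(t$z)
  if (d[2] < 2) {
    stopf("fundusreg_invalid_argument",
          "loss evaluation needs K >= 2 keypoints (got K = %d)", d[2])
  }
  if (d[1] < 2) {
    stopf("fundusreg_invalid_argument",
          "loss evaluation needs N >= 1 augmented views")
  }
  d
}

#' Supervised contrastive (SupCon) loss
#'
#' For every ordered pair of views (i, j), i != j, and every keypoint k, the
#' anchor z_ik is pulled towards its positive z_jk against all other samples:
#' the denominator sums exp(z_ik . z_ic / tau) over the anchor's own view
#' (c != k) and exp(z_ik . z_lc / tau) over every other view l != i and all
#' c.  The sum of -log ratios is scaled by 1/N.  Each log-ratio is
#' stabilized by max-subtraction.
#'
#' @param t a [multiview_descriptor_tensor()].
#' @return scalar loss, >= 0.
#' @export
supcon_loss <- function(t) supcon_core(t)$loss

#' Multi-positive InfoNCE (MP-InfoNCE) loss
#'
#' For every unordered view pair (i, j), j > i, and keypoint k, the anchor
#' z_ik is contrasted only within the pair: the denominator sums
#' exp(z_ik . z_ic / tau) over c != k in the anchor's view plus
#' exp(z_ik . z_jc / tau) over all c in view j.  The sum of -log ratios is
#' normalized by choose(N+1, 2) * K.
#'
#' @inheritParams supcon_loss
#' @return scalar loss, >= 0.
#' @export
mp_infonce_loss <- function(t) mp_infonce_core(t)$loss

# Shared machinery: both losses are sums over anchors of
# logsumexp(denominator set) - positive similarity; the gradient w.r.t. the
# similarity matrix is softmax weights minus indicators, chained through
# s = Z Z^T / tau.
supcon_core <- function(t, grad = FALSE) {
  d <- check_tensor(t)
  V <- d[1]; K <- d[2]; N <- V - 1
  Z <- flatten_tensor(t$z)
  S <- Z %*% t(Z) / t$tau
  M <- V * K
  loss <- 0
  G <- if (grad) matrix(0, M, M) else NULL
  for (i in seq_len(V)) {
    for (k in seq_len(K)) {
      a <- (i - 1) * K + k
      sa <- S[a, ]
      sa[a] <- -Inf                        # denominator = all samples but self
      m <- max(sa)
      w <- exp(sa - m)
      lse <- m + log(sum(w))
      pos <- ((setdiff(seq_len(V), i)) - 1) * K + k
      loss <- loss + (N * lse - sum(S[a, pos])) / N
      if (grad) {
        G[a, ] <- G[a, ] + w / sum(w)      # (1/N) * N * softmax
        G[a, pos] <- G[a, pos] - 1 / N
      }
    }
  }
  out <- list(loss = loss)
  if (grad) out$gZ <- tensor_grad_from_S(G, Z, t$tau, d)
  out
}

mp_infonce_core <- function(t, grad = FALSE) {
  d <- check_tensor(t)
  V <- d[1]; K <- d[2]
  Z <- flatten_tensor(t$z)
  S <- Z %*% t(Z) / t$tau
  M <- V * K
  norm <- choose(V, 2) * K
  loss <- 0
  G <- if (grad) matrix(0, M, M) else NULL
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      for (k in seq_len(K)) {
        a <- (i - 1) * K + k
        own <- (i - 1) * K + setdiff(seq_len(K), k)
        other <- (j - 1) * K + seq_len(K)
        den <- c(own, other)
        sden <- S[a, den]
        m <- max(sden)
        w <- exp(sden - m)
        lse <- m + log(sum(w))
        p <- (j - 1) * K + k
        loss <- loss + (lse - S[a, p]) / norm
        if (grad) {
          G[a, den] <- G[a, den] + (w / sum(w)) / norm
          G[a, p] <- G[a, p] - 1 / norm
        }
      }
    }
  }
  out <- list(loss = loss)
  if (grad) out$gZ <- tensor_grad_from_S(G, Z, t$tau, d)
  out
}

# dL/dZ for s_ab = z_a . z_b / tau given dL/ds in G (rows = anchors).
tensor_grad_from_S <- function(G, Z, tau, d) {
  gZ <- (G + t(G)) %*% Z / tau
  aperm(array(gZ, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Triplet loss on cosine similarities
#'
#' The baseline single-positive single-negative objective:
#' `max(0, margin - s_ap + s_an)`, a hinge on the cosine distances
#' (1 - s) of the anchor-positive and anchor-negative pairs.
#'
#' @param s_ap anchor-positive cosine similarity in [-1, 1].
#' @param s_an anchor-negative cosine similarity in [-1, 1].
#' @param margin hinge margin, > 0 (default 0.05).
#' @return scalar loss, >= 0 (vectorized over inputs).
#' @export
triplet_loss <- function(s_ap, s_an, margin = 0.05) {
  stopifnot(margin > 0, all(abs(s_ap) <= 1 + 1e-9), all(abs(s_an) <= 1 + 1e-9))
  pmax(0, margin - s_ap + s_an)
}

# Triplet objective over a full tensor, for training: for every anchor
# (i, k) draw one positive view and one uniformly random non-matching
# keypoint (any view) as negative; returns mean hinge and gradient.
triplet_core <- function(t, grad = FALSE, margin = 0.05) {
  d <- check_tensor(t)
  V <- d[1]; K <- d[2]
  Z <- flatten_tensor(t$z)
  S <- Z %*% t(Z)
  M <- V * K
  loss <- 0
  G <- if (grad) matrix(0, M, M) else NULL
  cnt <- 0
  for (i in seq_len(V)) {
    for (k in seq_len(K)) {
      a <- (i - 1) * K + k
      j <- sample(setdiff(seq_len(V), i), 1)
      p <- (j - 1) * K + k
      # negative: any sample with a different keypoint index
      repeat {
        nv <- sample.int(V, 1); nk <- sample.int(K, 1)
        if (nk != k) break
      }
      n <- (nv - 1) * K + nk
      h <- margin - S[a, p] + S[a, n]
      cnt <- cnt + 1
      if (h > 0) {
        loss <- loss + h
        if (grad) {
          G[a, p] <- G[a, p] - 1
          G[a, n] <- G[a, n] + 1
        }
      }
    }
  }
  out <- list(loss = loss / cnt)
  if (grad) {
    out$gZ <- tensor_grad_from_S(G / cnt, Z, 1, d)
  }
  out
}
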