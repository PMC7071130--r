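# Independent brute-force reference implementations used as oracles.
# These deliberately use plain scalar loops and share no code with the
# package's vectorized / compiled paths.

# SAME-padded stride-1 2-D convolution of a multi-channel image with one
# kernel group; weights laid out as the package stores them
# (row n = kernel n; column index (c-1)*kh*kw + (di-1)*kw + dj).
oracle_conv <- function(x, W, b, kh, kw) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  n_k <- nrow(W)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  out <- array(0, c(H, Wd, n_k))
  for (n in seq_len(n_k)) {
    for (i in seq_len(H)) {
      for (j in seq_len(Wd)) {
        acc <- b[n]
        for (c in seq_len(C)) {
          for (di in seq_len(kh)) {
            for (dj in seq_len(kw)) {
              ii <- i + di - 1 - ph
              jj <- j + dj - 1 - pw
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
                wcol <- (c - 1) * kh * kw + (di - 1) * kw + dj
                acc <- acc + W[n, wcol] * x[ii, jj, c]
              }
            }
          }
        }
        out[i, j, n] <- acc
      }
    }
  }
  out
}

# Valid 2x2 max pooling with stride 1.
oracle_pool <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H - 1, W - 1, C))
  for (c in seq_len(C)) {
    for (i in seq_len(H - 1)) {
      for (j in seq_len(W - 1)) {
        out[i, j, c] <- max(x[i, j, c], x[i + 1, j, c],
                            x[i, j + 1, c], x[i + 1, j + 1, c])
      }
    }
  }
  out
}

# Attention pooling (scores w' tanh(W V' + b), softmax, weighted sum),
# computed with scalar loops.
oracle_attention <- function(V, W, b, w) {
  N <- nrow(V); a <- length(b)
  scores <- numeric(N)
  for (n in seq_len(N)) {
    s <- 0
    for (k in seq_len(a)) {
      z <- b[k]
      for (d in seq_len(ncol(V))) z <- z + W[k, d] * V[n, d]
      s <- s + w[k] * tanh(z)
    }
    scores[n] <- s
  }
  e <- exp(scores - max(scores))
  alpha <- e / sum(e)
  out <- numeric(ncol(V))
  for (d in seq_len(ncol(V))) out[d] <- sum(alpha * V[, d])
  list(alpha = alpha, out = out)
}

# One GRU step, scalar loops.
oracle_gru_step <- function(xt, h_prev, p, use_bh = FALSE) {
  h <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  z <- r <- hc <- ht <- numeric(h)
  for (i in seq_len(h)) {
    z[i] <- sig(sum(p$Wxz[i, ] * xt) + sum(p$Whz[i, ] * h_prev) + p$bz[i])
    r[i] <- sig(sum(p$Wxr[i, ] * xt) + sum(p$Whr[i, ] * h_prev) + p$br[i])
  }
  for (i in seq_len(h)) {
    acc <- sum(p$Wxh[i, ] * xt) + sum(p$W[i, ] * (r * h_prev))
    if (use_bh) acc <- acc + p$bh[i]
    hc[i] <- tanh(acc)
    ht[i] <- (1 - z[i]) * h_prev[i] + z[i] * hc[i]
  }
  ht
}

# Small clean test records.
clean_patient <- function(hr = 60, noise = 0, wander = 0, id = "P001") {
  patient_profile(patient_id = id, heart_rate = hr, noise_sd = noise,
                  wander_amp = wander)
}

# A quick beat dataset of random short beats for training plumbing tests.
random_beats <- function(n, len = 64, classes = c("HC", "MI"),
                         n_patients = 4, seed = 1, signal = 0.5) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    labels <- rep_len(classes, n)
    beats <- array(rnorm(12 * len * n, sd = 0.1), c(12, len, n))
    # a separable class signature on three leads
    for (i in which(labels == classes[2])) {
      beats[2:4, seq(10, min(30, len)), i] <-
        beats[2:4, seq(10, min(30, len)), i] + signal
    }
    beat_dataset(pmin(pmax(beats, -1), 1), labels,
                 rep_len(sprintf("P%02d", seq_len(n_patients)), n))
  })
}
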