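# Independent double-precision reference implementation of the backbone
# forward pass, written directly from the layer definitions (plain R, no
# shared code with the compiled engine). Used to verify the engine's forward
# values and, through numerical differentiation, its gradients on tiny
# configurations.

ref_im2col <- function(A, H, W) {
  # A: (H*W) x C, pixel p = i + H*j (0-based)
  C <- ncol(A)
  cols <- matrix(0, H * W, 9 * C)
  for (cc in seq_len(C)) {
    ch <- matrix(A[, cc], H, W)
    pad <- matrix(0, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- ch
    for (b in -1:1) for (a in -1:1) {
      q <- (a + 1) + 3 * (b + 1) + 9 * (cc - 1) + 1
      cols[, q] <- as.vector(pad[(2 + a):(H + 1 + a), (2 + b):(W + 1 + b)])
    }
  }
  cols
}

ref_lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)

# conv + bias + affine instance norm (population moments, eps 1e-5) + leaky ReLU
ref_block <- function(A, w, H, W) {
  k <- dim(w$W)[1]
  Wm <- matrix(w$W, k * k * dim(w$W)[3], dim(w$W)[4])
  X <- if (k == 1) A else ref_im2col(A, H, W)
  Y <- sweep(X %*% Wm, 2, w$b, "+")
  for (cc in seq_len(ncol(Y))) {
    mu <- mean(Y[, cc])
    v <- mean((Y[, cc] - mu)^2)
    Y[, cc] <- w$gamma[cc] * (Y[, cc] - mu) / sqrt(v + 1e-5) + w$beta[cc]
  }
  ref_lrelu(Y)
}

# split the flat weight list back into per-conv groups
ref_groups <- function(weights) {
  groups <- list(); i <- 1
  while (i <= length(weights)) {
    g <- list(W = weights[[i]], b = weights[[i + 1]])
    nm <- names(weights)[i]
    gname <- sub("_W$", "", nm)
    if (i + 2 <= length(weights) &&
        identical(names(weights)[i + 2], paste0(gname, "_gamma"))) {
      g$gamma <- weights[[i + 2]]; g$beta <- weights[[i + 3]]
      i <- i + 4
    } else i <- i + 2
    groups[[length(groups) + 1]] <- g
  }
  groups
}

ref_forward <- function(weights, x, cfg) {
  d <- cfg$depth; nconv <- cfg$convs
  gs <- ref_groups(weights)
  H <- cfg$side; W <- cfg$side
  A <- matrix(as.vector(x), H * W, 1)
  li <- 1; skips <- list()
  for (l in 1:d) {
    for (rep in seq_len(nconv)) { A <- ref_block(A, gs[[li]], H, W); li <- li + 1 }
    skips[[l]] <- A
    C <- ncol(A); Ho <- H / 2; Wo <- W / 2
    P <- matrix(0, Ho * Wo, C)
    for (cc in seq_len(C)) {
      ch <- matrix(A[, cc], H, W)
      P[, cc] <- as.vector(pmax(ch[seq(1, H, 2), seq(1, W, 2)],
                                ch[seq(2, H, 2), seq(1, W, 2)],
                                ch[seq(1, H, 2), seq(2, W, 2)],
                                ch[seq(2, H, 2), seq(2, W, 2)]))
    }
    A <- P; H <- Ho; W <- Wo
  }
  for (rep in seq_len(nconv)) { A <- ref_block(A, gs[[li]], H, W); li <- li + 1 }
  for (l in d:1) {
    C <- ncol(A); Hn <- 2 * H; Wn <- 2 * W
    U <- matrix(0, Hn * Wn, C)
    for (cc in seq_len(C)) {
      ch <- matrix(A[, cc], H, W)
      U[, cc] <- as.vector(ch[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2)])
    }
    A <- U; H <- Hn; W <- Wn
    A <- ref_block(A, gs[[li]], H, W); li <- li + 1   # 1x1 reduce
    A <- cbind(skips[[l]], A)
    for (rep in seq_len(nconv)) { A <- ref_block(A, gs[[li]], H, W); li <- li + 1 }
  }
  # head: 1x1 conv + sigmoid, no norm
  w <- gs[[li]]
  Wm <- matrix(w$W, dim(w$W)[3], dim(w$W)[4])
  z <- sweep(A %*% Wm, 2, w$b, "+")
  matrix(1 / (1 + exp(-z)), cfg$side, cfg$side)
}

# numerical gradient of sum((p - g)^2) wrt one weight entry, double precision
ref_num_grad <- function(weights, x, g, cfg, li, idx, h = 1e-6) {
  f <- function(w) sum((ref_forward(w, x, cfg) - g)^2)
  w2 <- weights; w2[[li]][idx] <- w2[[li]][idx] + h
  w3 <- weights; w3[[li]][idx] <- w3[[li]][idx] - h
  (f(w2) - f(w3)) / (2 * h)
}
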