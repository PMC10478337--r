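#' Backbone configuration
#'
#' Describes the encoder-decoder (U-Net style) backbone shared by the two
#' branches: input side length, base channel width, number of
#' down/up-sampling levels, and convolutions per block. The network maps a
#' `side x side` grayscale slice to a per-pixel foreground probability
#' through `depth` encoder levels (`convs_per_block` 3x3 convolutions, each
#' followed by affine instance normalization and a leaky ReLU, then 2x2
#' max-pooling), a bottleneck block, symmetric decoder levels
#' (nearest-neighbour upsampling, a 1x1 channel-reduction convolution,
#' concatenation with the skip connection, `convs_per_block` 3x3
#' convolutions) and a sigmoid 1x1 output head.
#'
#' @param side input side length in pixels; must be divisible by `2^depth`.
#' @param width base channel width of the first level (doubles per level).
#' @param depth number of down/up-sampling levels (at least 2).
#' @param convs_per_block number of 3x3 convolutions per encoder/decoder
#'   block (1 gives a compact backbone, 2 the classic layout).
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(side = 64L, width = 8L, depth = 3L,
                            convs_per_block = 1L) {
  side <- as.integer(side); width <- as.integer(width); depth <- as.integer(depth)
  convs_per_block <- as.integer(convs_per_block)
  if (depth < 2L) stop("depth must be >= 2")
  if (width < 1L) stop("width must be >= 1")
  if (convs_per_block < 1L) stop("convs_per_block must be >= 1")
  if (side %% (2L^depth) != 0L)
    stop("side (", side, ") must be divisible by 2^depth (", 2L^depth, ")")
  structure(list(side = side, width = width, depth = depth,
                 convs = convs_per_block),
            class = "backbone_config")
}

# channel plan: list of c(k, Cin, Cout) per convolution, in forward order
conv_plan <- function(cfg) {
  w <- cfg$width; d <- cfg$depth; n <- cfg$convs
  plan <- list()
  block <- function(cin, cout) {
    out <- list(c(3L, cin, cout))
    if (n > 1L) for (r in 2:n) out[[r]] <- c(3L, cout, cout)
    out
  }
  for (l in 0:(d - 1)) {
    cin <- if (l == 0) 1L else w * 2L^(l - 1L)
    plan <- c(plan, block(cin, w * 2L^l))
  }
  plan <- c(plan, block(w * 2L^(d - 1L), w * 2L^d))
  for (l in (d - 1):0) {
    plan[[length(plan) + 1L]] <- c(1L, w * 2L^(l + 1L), w * 2L^l)  # reduce
    plan <- c(plan, block(2L * w * 2L^l, w * 2L^l))                # after concat
  }
  plan[[length(plan) + 1L]] <- c(1L, w, 1L)  # sigmoid head
  plan
}

#' Build and initialize a backbone
#'
#' He-style initialization (`N(0, sqrt(2 / fan_in))`) driven by the R RNG so
#' that a given seed yields bitwise-identical weights. The clean and noisy
#' branches of the dual-branch trainer are both initialized from the same
#' call, so they start structurally and numerically identical.
#'
#' @param cfg a [backbone_config()].
#' @param seed integer RNG seed for the initialization.
#' @return an object of class `branch_weights`: a flat ordered list of kernel
#'   arrays (`dim = c(k, k, Cin, Cout)`) interleaved with bias vectors, plus
#'   the config as an attribute.
#' @export
build_backbone <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  plan <- conv_plan(cfg)
  weights <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (i in seq_along(plan)) {
    k <- plan[[i]][1]; cin <- plan[[i]][2]; cout <- plan[[i]][3]
    fan_in <- k * k * cin
    nm <- sprintf("conv%02d", i)
    weights[[paste0(nm, "_W")]] <-
      array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
            dim = c(k, k, cin, cout))
    weights[[paste0(nm, "_b")]] <- numeric(cout)
    if (i < length(plan)) {  # affine instance norm on all but the head
      weights[[paste0(nm, "_gamma")]] <- rep(1, cout)
      weights[[paste0(nm, "_beta")]] <- numeric(cout)
    }
  }
  structure(weights, cfg = cfg, class = "branch_weights")
}

#' Create a reusable engine context
#'
#' A context owns the engine-side buffers (im2col matrices, cached
#' activations). Reusing one context per branch across training steps keeps
#' buffer sizes constant and avoids repeated large allocations.
#'
#' @return an opaque context handle.
#' @export
net_context <- function() .unet_ctx_new()

#' Forward pass of the backbone
#'
#' @param weights a `branch_weights` object.
#' @param x slice batch, array `side x side x n`, values in `[0, 1]`.
#' @param keep_cache retain intermediates for a following [net_backward()].
#' @param ctx a [net_context()]; created on the fly when `NULL`.
#' @return list with `prob` (array `side x side x n` of foreground
#'   probabilities) and the context handle `cache` to pass to
#'   [net_backward()].
#' @export
net_forward <- function(weights, x, keep_cache = FALSE, ctx = NULL) {
  cfg <- attr(weights, "cfg")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (is.null(ctx)) ctx <- .unet_ctx_new()
  prob <- .unet_forward_cpp(ctx, unclass(weights), x, cfg$side, cfg$depth,
                            cfg$width, cfg$convs, keep_cache)
  list(prob = prob, cache = ctx)
}

#' Backward pass of the backbone
#'
#' @param cache the context returned by [net_forward()] with
#'   `keep_cache = TRUE`.
#' @param dLdz gradient of the scalar loss with respect to the output
#'   logits (pre-sigmoid), same shape as the forward output. Losses supply
#'   this via their analytic composition through the sigmoid, which keeps
#'   cross-entropy gradients exact under saturation.
#' @return list of gradients matching the weight list structure.
#' @export
net_backward <- function(cache, dLdz) {
  if (length(dim(dLdz)) == 2L) dim(dLdz) <- c(dim(dLdz), 1L)
  .unet_backward_cpp(cache, dLdz)
}

#' @export
print.branch_weights <- function(x, ...) {
  cfg <- attr(x, "cfg")
  np <- sum(vapply(x, length, integer(1)))
  cat(sprintf("<branch_weights> side=%d width=%d depth=%d, %d parameters\n",
              cfg$side, cfg$width, cfg$depth, np))
  invisible(x)
}
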