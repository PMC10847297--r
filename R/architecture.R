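#' Pathway width derivation by shrinkage ratio
#'
#' Successive layer widths along an encoder pathway. In `"shrink"` mode
#' every step multiplies by the ratio (`w1 = floor(input * ratio)`,
#' `wk = floor(w(k-1) * ratio)`); in `"expand_first"` mode the first step
#' divides by the ratio (dimensionality expansion) and subsequent steps
#' shrink. With a 512-sample input the low-ratio pathway (0.45) starts at
#' 230 and the high-ratio pathway (0.75) starts at 682.
#'
#' @param input_len input width in samples.
#' @param ratio shrinkage ratio in (0, 1).
#' @param depth number of layers.
#' @param direction `"shrink"` or `"expand_first"`.
#' @return Integer vector of `depth` widths.
#' @export
derive_path_widths <- function(input_len, ratio, depth = 3L,
                               direction = c("shrink", "expand_first")) {
  direction <- match.arg(direction)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("'ratio' must lie strictly between 0 and 1")
  if (depth < 1L) stop("'depth' must be at least 1")
  w <- integer(depth)
  w[1] <- if (direction == "shrink") floor(input_len * ratio)
          else floor(input_len / ratio)
  if (depth > 1L)
    for (k in 2:depth) w[k] <- floor(w[k - 1] * ratio)
  w
}

# Layer description helper. Trainable kinds get SeLU by default; the
# output layer is linear so amplitudes are recoverable.
lyr <- function(name, kind, inputs = character(), width = NULL,
                kernel = NULL, stride = NULL, channels = NULL,
                units = NULL, activation = NULL) {
  if (is.null(activation))
    activation <- if (kind %in% c("dense", "conv", "gru")) "selu" else "none"
  list(name = name, kind = kind, inputs = inputs, width = width,
       kernel = kernel, stride = stride, channels = channels,
       units = units, activation = activation)
}

new_arch <- function(input_len, backbone, layers, ratios = c(0.45, 0.75),
                     use_fusion = TRUE, use_residual = TRUE) {
  names(layers) <- vapply(layers, function(l) l$name, character(1))
  spec <- structure(list(input_len = as.integer(input_len),
                         backbone = backbone, ratios = ratios,
                         use_fusion = use_fusion,
                         use_residual = use_residual,
                         layers = layers),
                    class = "dpae_arch")
  validate_arch(spec)
  spec
}

#' Per-layer output shapes of an architecture
#'
#' Computes (and validates) the output shape of every layer: vector
#' layers report `width`; sequence layers (convolution/GRU stages)
#' report `len` and `ch`.
#'
#' @param spec a `dpae_arch`.
#' @return Named list, one entry per layer, each a list with `width` or
#'   `len`/`ch`.
#' @export
arch_shapes <- function(spec) {
  shapes <- list()
  for (l in spec$layers) {
    ins <- lapply(l$inputs, function(nm) {
      if (is.null(shapes[[nm]]))
        stop("layer '", l$name, "' consumes undefined layer '", nm, "'")
      shapes[[nm]]
    })
    shapes[[l$name]] <- switch(
      l$kind,
      input = if (spec$backbone == "mlp")
        list(width = spec$input_len)
      else list(len = spec$input_len, ch = 1L),
      dense = ,
      output = {
        if (is.null(ins[[1]]$width))
          stop("layer '", l$name, "' needs a vector input; add a flatten/last stage")
        if (is.null(l$width) || l$width < 1L)
          stop("layer '", l$name, "' has degenerate width ",
               l$width %||% "NULL", "; the input length is too small for ",
               "this shrinkage depth")
        list(width = l$width)
      },
      conv = {
        L_in <- ins[[1]]$len
        L_out <- floor((L_in - l$kernel) / l$stride) + 1L
        if (L_out < 1L)
          stop("layer '", l$name, "': kernel/stride exhaust the sequence length")
        list(len = L_out, ch = l$channels)
      },
      gru = list(len = ins[[1]]$len, ch = l$units),
      last = list(width = ins[[1]]$ch),
      flatten = list(width = ins[[1]]$len * ins[[1]]$ch),
      concat = {
        w <- vapply(ins, function(s) s$width, numeric(1))
        if (!is.null(l$width) && l$width != sum(w))
          stop("layer '", l$name, "': declared width ", l$width,
               " != sum of input widths ", sum(w))
        list(width = sum(w))
      },
      add = {
        w <- vapply(ins, function(s) s$width, numeric(1))
        if (length(unique(w)) != 1L)
          stop("layer '", l$name, "': add requires equal input widths, got ",
               paste(w, collapse = ", "))
        list(width = w[1])
      },
      batchnorm = ins[[1]],
      stop("unknown layer kind '", l$kind, "' at layer '", l$name, "'")
    )
  }
  shapes
}

validate_arch <- function(spec) {
  shapes <- arch_shapes(spec)
  out <- spec$layers[[length(spec$layers)]]
  if (out$kind != "output")
    stop("the final layer must have kind 'output'")
  if (shapes[[out$name]]$width != spec$input_len)
    stop("output width ", shapes[[out$name]]$width,
         " != input length ", spec$input_len)
  invisible(spec)
}

#' @export
print.dpae_arch <- function(x, ...) {
  cat(sprintf("<dpae_arch> backbone=%s, input_len=%d, %d layers (fusion=%s, residual=%s)\n",
              x$backbone, x$input_len, length(x$layers),
              x$use_fusion, x$use_residual))
  cat(sprintf("  trainable hidden layers: %d; params: %s; FLOPs/forward: %s\n",
              n_hidden_layers(x), format(count_params(x), big.mark = ","),
              format(count_flops(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable hidden layers
#'
#' Counts dense/convolution/GRU layers between input and output (the
#' output projection itself is not counted).
#'
#' @param spec a `dpae_arch`.
#' @return Integer count.
#' @export
n_hidden_layers <- function(spec) {
  sum(vapply(spec$layers,
             function(l) l$kind %in% c("dense", "conv", "gru"), logical(1)))
}

# Shared topology: dual encoder pathways -> concat -> BN -> symmetric
# fusion block -> per-pathway projection (+ residual add with the
# pathway's last encoder layer) -> per-pathway compression -> concat ->
# BN -> decoder -> linear output. `p1_tail`/`p2_tail` name the layers the
# residual connections add to (the fusion-block inputs).
dual_path_tail <- function(layers, input_len, p1_tail, p2_tail,
                           w1, w2, fusion_widths, post1, post2,
                           decoder_width, use_fusion, use_residual) {
  layers <- c(layers, list(
    lyr("concat1", "concat", c(p1_tail, p2_tail), width = w1 + w2),
    lyr("bn1", "batchnorm", "concat1")))
  fusion_out <- "bn1"
  if (use_fusion) {
    f <- fusion_widths
    layers <- c(layers, list(
      lyr("fusion_enc1", "dense", "bn1", width = f[1]),
      lyr("fusion_enc2", "dense", "fusion_enc1", width = f[2]),
      lyr("fusion_feature", "dense", "fusion_enc2", width = f[3]),
      lyr("fusion_dec1", "dense", "fusion_feature", width = f[2]),
      lyr("fusion_dec2", "dense", "fusion_dec1", width = f[1])))
    fusion_out <- "fusion_dec2"
  }
  layers <- c(layers, list(lyr("p1_proj", "dense", fusion_out, width = w1)))
  p1_src <- "p1_proj"
  if (use_residual) {
    layers <- c(layers, list(lyr("p1_add", "add", c(p1_tail, "p1_proj"))))
    p1_src <- "p1_add"
  }
  layers <- c(layers, list(
    lyr("p1_out", "dense", p1_src, width = post1),
    lyr("p2_proj", "dense", fusion_out, width = w2)))
  p2_src <- "p2_proj"
  if (use_residual) {
    layers <- c(layers, list(lyr("p2_add", "add", c(p2_tail, "p2_proj"))))
    p2_src <- "p2_add"
  }
  c(layers, list(
    lyr("p2_out", "dense", p2_src, width = post2),
    lyr("concat2", "concat", c("p1_out", "p2_out"), width = post1 + post2),
    lyr("bn2", "batchnorm", "concat2"),
    lyr("decoder", "dense", "bn2", width = decoder_width),
    lyr("output", "output", "decoder", width = input_len,
        activation = "linear")))
}

#' Reference dual-pathway MLP architecture for 512-sample inputs
#'
#' The published layer table of the 512-input dense model, hard-coded:
#' pathway 1 shrinks 230 -> 103 -> 46 (ratio 0.45), pathway 2 expands to
#' 680 then shrinks 511 -> 383 (ratio 0.75); the concatenated features
#' (429) are batch-normalized and pass the symmetric fusion block
#' 193 -> 86 -> 39 -> 86 -> 193; per-pathway projections (46, 383) are
#' residually added to the last encoder layers, compressed to 20 and 287,
#' concatenated (307), batch-normalized, decoded through 256 and
#' projected linearly back to 512. Sixteen trainable hidden layers in
#' total. The printed widths are not all reproducible by one rounding
#' rule (680 vs the formula's 682; 39 vs floor(86*0.45) = 38), so this
#' table is kept verbatim rather than derived; [dpae_spec] is the
#' formula-faithful generic builder.
#'
#' @param use_fusion keep the fusion block (set `FALSE` for the ablation
#'   variant in which the batch-normalized concatenation feeds the
#'   pathway projections directly).
#' @param use_residual keep the two residual additions.
#' @return A `dpae_arch`.
#' @export
dpae_mlp_canonical <- function(use_fusion = TRUE, use_residual = TRUE) {
  layers <- list(
    lyr("input", "input", width = 512L),
    lyr("p1_enc1", "dense", "input", width = 230L),
    lyr("p1_enc2", "dense", "p1_enc1", width = 103L),
    lyr("p1_enc3", "dense", "p1_enc2", width = 46L),
    lyr("p2_enc1", "dense", "input", width = 680L),
    lyr("p2_enc2", "dense", "p2_enc1", width = 511L),
    lyr("p2_enc3", "dense", "p2_enc2", width = 383L))
  layers <- dual_path_tail(layers, 512L, "p1_enc3", "p2_enc3",
                           w1 = 46L, w2 = 383L,
                           fusion_widths = c(193L, 86L, 39L),
                           post1 = 20L, post2 = 287L, decoder_width = 256L,
                           use_fusion = use_fusion,
                           use_residual = use_residual)
  new_arch(512L, "mlp", layers, use_fusion = use_fusion,
           use_residual = use_residual)
}

#' Build a dual-pathway architecture for a given backbone
#'
#' Derives a full architecture from the input length and backbone kind.
#' All backbones share the fusion/residual/decoder topology; they differ
#' in the encoder pathways:
#' \describe{
#'   \item{mlp}{dense pathways with shrinkage ratios 0.45 (all-shrink)
#'     and 0.75 (expand first), widths from [derive_path_widths].}
#'   \item{cnn}{1-D convolution pathways: kernel 3 / stride 2 vs kernel
#'     5 / stride 4, channel progression `channels` (default 16, 32,
#'     64), flattened before the dense fusion block.}
#'   \item{rnn}{stacked GRU pathways whose unit counts follow the same
#'     floor chains as the MLP; the final hidden state feeds the fusion
#'     block.}
#' }
#'
#' @param input_len segment length in samples.
#' @param backbone `"mlp"`, `"cnn"` or `"rnn"`.
#' @param ratios low/high shrinkage ratios (default 0.45, 0.75).
#' @param depth encoder layers per pathway (default 3).
#' @param channels convolution channel progression for the CNN backbone.
#' @param use_fusion,use_residual ablation switches.
#' @return A `dpae_arch`.
#' @export
dpae_spec <- function(input_len, backbone = c("mlp", "cnn", "rnn"),
                      ratios = c(0.45, 0.75), depth = 3L,
                      channels = c(16L, 32L, 64L),
                      use_fusion = TRUE, use_residual = TRUE) {
  backbone <- match.arg(backbone)
  input_len <- as.integer(input_len)
  if (input_len < 16L) stop("'input_len' too small for the dual-pathway topology")
  rl <- ratios[1]; rh <- ratios[2]
  if (backbone == "mlp") {
    p1 <- derive_path_widths(input_len, rl, depth, "shrink")
    p2 <- derive_path_widths(input_len, rh, depth, "expand_first")
    layers <- list(lyr("input", "input", width = input_len))
    prev <- "input"
    for (k in seq_len(depth)) {
      nm <- sprintf("p1_enc%d", k)
      layers <- c(layers, list(lyr(nm, "dense", prev, width = p1[k])))
      prev <- nm
    }
    prev <- "input"
    for (k in seq_len(depth)) {
      nm <- sprintf("p2_enc%d", k)
      layers <- c(layers, list(lyr(nm, "dense", prev, width = p2[k])))
      prev <- nm
    }
    tails <- c("p1_enc" , "p2_enc")
    w1 <- p1[depth]; w2 <- p2[depth]
    p1_tail <- sprintf("p1_enc%d", depth); p2_tail <- sprintf("p2_enc%d", depth)
  } else if (backbone == "cnn") {
    if (length(channels) != depth)
      stop("'channels' must supply one channel count per encoder layer")
    layers <- list(lyr("input", "input"))
    prev <- "input"
    for (k in seq_len(depth)) {
      nm <- sprintf("p1_conv%d", k)
      layers <- c(layers, list(lyr(nm, "conv", prev, kernel = 3L, stride = 2L,
                                   channels = as.integer(channels[k]))))
      prev <- nm
    }
    layers <- c(layers, list(lyr("p1_flat", "flatten", prev)))
    prev <- "input"
    for (k in seq_len(depth)) {
      nm <- sprintf("p2_conv%d", k)
      layers <- c(layers, list(lyr(nm, "conv", prev, kernel = 5L, stride = 4L,
                                   channels = as.integer(channels[k]))))
      prev <- nm
    }
    layers <- c(layers, list(lyr("p2_flat", "flatten", prev)))
    # flattened widths from the conv geometry
    len1 <- input_len; len2 <- input_len
    for (k in seq_len(depth)) {
      len1 <- floor((len1 - 3L) / 2L) + 1L
      len2 <- floor((len2 - 5L) / 4L) + 1L
    }
    if (len1 < 1L || len2 < 1L)
      stop("'input_len' too short for the convolutional pathway depth")
    w1 <- len1 * channels[depth]; w2 <- len2 * channels[depth]
    p1_tail <- "p1_flat"; p2_tail <- "p2_flat"
  } else {
    u1 <- derive_path_widths(input_len, rl, depth, "shrink")
    u2 <- derive_path_widths(input_len, rh, depth, "expand_first")
    layers <- list(lyr("input", "input"))
    prev <- "input"
    for (k in seq_len(depth)) {
      nm <- sprintf("p1_gru%d", k)
      layers <- c(layers, list(lyr(nm, "gru", prev, units = u1[k])))
      prev <- nm
    }
    layers <- c(layers, list(lyr("p1_last", "last", prev)))
    prev <- "input"
    for (k in seq_len(depth)) {
      nm <- sprintf("p2_gru%d", k)
      layers <- c(layers, list(lyr(nm, "gru", prev, units = u2[k])))
      prev <- nm
    }
    layers <- c(layers, list(lyr("p2_last", "last", prev)))
    w1 <- u1[depth]; w2 <- u2[depth]
    p1_tail <- "p1_last"; p2_tail <- "p2_last"
  }
  cw <- w1 + w2
  f1 <- floor(cw * rl); f2 <- floor(f1 * rl); feat <- floor(f2 * rl)
  layers <- dual_path_tail(layers, input_len, p1_tail, p2_tail,
                           w1 = w1, w2 = w2,
                           fusion_widths = c(f1, f2, feat),
                           post1 = floor(w1 * rl), post2 = floor(w2 * rh),
                           decoder_width = floor(input_len * 0.5),
                           use_fusion = use_fusion,
                           use_residual = use_residual)
  new_arch(input_len, backbone, layers, ratios = ratios,
           use_fusion = use_fusion, use_residual = use_residual)
}

#' Minimal fully connected baseline architecture
#'
#' A plain stack of equal-width dense SeLU layers with a linear output
#' projection; included only as a relative comparison point for the
#' dual-pathway models.
#'
#' @param input_len segment length in samples.
#' @param width hidden width (default equals `input_len`).
#' @param depth number of hidden layers (default 4).
#' @return A `dpae_arch` with backbone `"mlp"` and no fusion/residual
#'   structure.
#' @export
fcnn_spec <- function(input_len, width = input_len, depth = 4L) {
  layers <- list(lyr("input", "input", width = as.integer(input_len)))
  prev <- "input"
  for (k in seq_len(depth)) {
    nm <- sprintf("hidden%d", k)
    layers <- c(layers, list(lyr(nm, "dense", prev, width = as.integer(width))))
    prev <- nm
  }
  layers <- c(layers, list(lyr("output", "output", prev,
                               width = as.integer(input_len),
                               activation = "linear")))
  new_arch(as.integer(input_len), "mlp", layers,
           use_fusion = FALSE, use_residual = FALSE)
}

#' Trainable parameter count of an architecture
#'
#' Dense layers contribute `in * out + out`; batch normalization `2 *
#' width` (scale and shift); 1-D convolutions `kernel * in_ch * out_ch +
#' out_ch`; GRU layers `3 * (in * h + h * h + 2 * h)` (input and hidden
#' projections for the three gates, with separate input/hidden biases).
#'
#' @param spec a `dpae_arch`.
#' @return Total parameter count.
#' @export
count_params <- function(spec) {
  shapes <- arch_shapes(spec)
  total <- 0
  for (l in spec$layers) {
    if (l$kind %in% c("dense", "output")) {
      w_in <- shapes[[l$inputs[1]]]$width
      total <- total + w_in * l$width + l$width
    } else if (l$kind == "batchnorm") {
      total <- total + 2 * shapes[[l$name]]$width
    } else if (l$kind == "conv") {
      cin <- shapes[[l$inputs[1]]]$ch
      total <- total + l$kernel * cin * l$channels + l$channels
    } else if (l$kind == "gru") {
      f <- shapes[[l$inputs[1]]]$ch; h <- l$units
      total <- total + 3 * (f * h + h * h + 2 * h)
    }
  }
  total
}

#' Forward-pass FLOP count of an architecture
#'
#' Multiply-accumulate convention: a dense layer with `in` inputs and
#' `out` outputs contributes `2 * in * out` floating-point operations; a
#' convolution `2 * kernel * in_ch * out_ch * out_len`; a GRU
#' `T * (6 * (in * h + h * h) + 12 * h)`; batch normalization `4 *
#' width`; residual adds `width`. Activations are not counted.
#'
#' @param spec a `dpae_arch`.
#' @return Total FLOPs for one forward pass on one segment.
#' @export
count_flops <- function(spec) {
  shapes <- arch_shapes(spec)
  total <- 0
  for (l in spec$layers) {
    if (l$kind %in% c("dense", "output")) {
      total <- total + 2 * shapes[[l$inputs[1]]]$width * l$width
    } else if (l$kind == "batchnorm") {
      total <- total + 4 * shapes[[l$name]]$width
    } else if (l$kind == "add") {
      total <- total + shapes[[l$name]]$width
    } else if (l$kind == "conv") {
      cin <- shapes[[l$inputs[1]]]$ch
      total <- total + 2 * l$kernel * cin * l$channels * shapes[[l$name]]$len
    } else if (l$kind == "gru") {
      f <- shapes[[l$inputs[1]]]$ch; h <- l$units
      total <- total + shapes[[l$name]]$len * (6 * (f * h + h * h) + 12 * h)
    }
  }
  total
}

#' Write an architecture to a YAML config file
#' @param spec a `dpae_arch`.
#' @param path output file path.
#' @export
write_architecture <- function(spec, path) {
  obj <- unclass(spec)
  obj$layers <- lapply(obj$layers, function(l) Filter(Negate(is.null), l))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an architecture from a YAML config file
#' @param path file path written by [write_architecture].
#' @return A `dpae_arch`.
#' @export
read_architecture <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(l)
    lyr(l$name, l$kind, inputs = as.character(l$inputs %||% character()),
        width = l$width, kernel = l$kernel, stride = l$stride,
        channels = l$channels, units = l$units, activation = l$activation))
  new_arch(obj$input_len, obj$backbone, layers,
           ratios = as.numeric(obj$ratios),
           use_fusion = obj$use_fusion, use_residual = obj$use_residual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
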