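test_that("pathway widths follow the floor chains", {
  expect_equal(derive_path_widths(512, 0.45, 1, "shrink"), 230)
  expect_equal(derive_path_widths(512, 0.75, 1, "expand_first"), 682)
  expect_equal(derive_path_widths(300, 0.45, 2, "shrink"), c(135, 60))
  expect_equal(derive_path_widths(512, 0.45, 3, "shrink"), c(230, 103, 46))
  expect_error(derive_path_widths(512, 1.0, 1), "ratio")
})

canonical_widths <- c(
  p1_enc1 = 230, p1_enc2 = 103, p1_enc3 = 46,
  p2_enc1 = 680, p2_enc2 = 511, p2_enc3 = 383,
  concat1 = 429, bn1 = 429,
  fusion_enc1 = 193, fusion_enc2 = 86, fusion_feature = 39,
  fusion_dec1 = 86, fusion_dec2 = 193,
  p1_proj = 46, p1_add = 46, p1_out = 20,
  p2_proj = 383, p2_add = 383, p2_out = 287,
  concat2 = 307, bn2 = 307, decoder = 256, output = 512)

test_that("the canonical 512-input MLP reproduces every published width", {
  spec <- dpae_mlp_canonical()
  shapes <- arch_shapes(spec)
  for (nm in names(canonical_widths))
    expect_equal(shapes[[nm]]$width, unname(canonical_widths[nm]),
                 label = paste("width of", nm))
  expect_equal(n_hidden_layers(spec), 16)
  expect_equal(spec$layers$fusion_feature$width, 39)
  expect_equal(shapes$concat1$width, 429)
})

test_that("parameter and FLOP counts match independent per-layer sums", {
  # one hidden dense layer 10 -> 5 plus the 5 -> 10 output projection
  tiny <- fcnn_spec(10, width = 5, depth = 1)
  expect_equal(count_params(tiny), (10 * 5 + 5) + (5 * 10 + 10))
  expect_equal(count_flops(tiny), 2 * 10 * 5 + 2 * 5 * 10)

  # canonical spec: hand-summed arithmetic over the width table
  dense_io <- list(c(512, 230), c(230, 103), c(103, 46),
                   c(512, 680), c(680, 511), c(511, 383),
                   c(429, 193), c(193, 86), c(86, 39), c(39, 86), c(86, 193),
                   c(193, 46), c(46, 20), c(193, 383), c(383, 287),
                   c(307, 256), c(256, 512))
  hand_params <- sum(vapply(dense_io, function(p) p[1] * p[2] + p[2],
                            numeric(1))) + 2 * 429 + 2 * 307
  hand_flops <- sum(vapply(dense_io, function(p) 2 * p[1] * p[2],
                           numeric(1))) + 4 * 429 + 4 * 307 + 46 + 383
  spec <- dpae_mlp_canonical()
  expect_equal(count_params(spec), hand_params)
  expect_equal(count_flops(spec), hand_flops)

  # FLOPs >= params for all-dense specs (2*in*out >= in*out + out, in >= 2)
  expect_gte(count_flops(spec), count_params(spec))
  # removing the fusion block strictly decreases the parameter count
  expect_lt(count_params(dpae_mlp_canonical(use_fusion = FALSE)),
            count_params(spec))
})

test_that("backbone variants share the fusion topology and output width", {
  cnn <- dpae_spec(512, "cnn")
  p1 <- Filter(function(l) l$kind == "conv" && grepl("^p1", l$name),
               cnn$layers)
  p2 <- Filter(function(l) l$kind == "conv" && grepl("^p2", l$name),
               cnn$layers)
  expect_true(all(vapply(p1, function(l) l$kernel == 3 && l$stride == 2,
                         logical(1))))
  expect_true(all(vapply(p2, function(l) l$kernel == 5 && l$stride == 4,
                         logical(1))))

  rnn <- dpae_spec(512, "rnn")
  units1 <- vapply(sprintf("p1_gru%d", 1:3),
                   function(nm) rnn$layers[[nm]]$units, numeric(1))
  units2 <- vapply(sprintf("p2_gru%d", 1:3),
                   function(nm) rnn$layers[[nm]]$units, numeric(1))
  expect_equal(unname(units1), derive_path_widths(512, 0.45, 3, "shrink"))
  expect_equal(unname(units2), derive_path_widths(512, 0.75, 3, "expand_first"))

  for (spec in list(dpae_spec(512, "mlp"), cnn, rnn)) {
    shapes <- arch_shapes(spec)
    expect_equal(shapes$output$width, 512)
    expect_true(spec$layers$output$activation == "linear")
  }
  for (L in c(256, 512, 1024))
    expect_equal(arch_shapes(dpae_spec(L, "mlp"))$output$width, L)
  expect_error(dpae_spec(512, "transformer"))
})

test_that("structural validation names the offending layer", {
  layers <- list(
    dpae:::lyr("input", "input", width = 8L),
    dpae:::lyr("a", "dense", "input", width = 4L),
    dpae:::lyr("b", "dense", "input", width = 5L),
    dpae:::lyr("bad_add", "add", c("a", "b")),
    dpae:::lyr("output", "output", "bad_add", width = 8L,
               activation = "linear"))
  expect_error(dpae:::new_arch(8L, "mlp", layers), "bad_add")

  layers2 <- list(
    dpae:::lyr("input", "input", width = 8L),
    dpae:::lyr("a", "dense", "input", width = 4L),
    dpae:::lyr("bad_cat", "concat", c("a", "input"), width = 99L),
    dpae:::lyr("output", "output", "bad_cat", width = 8L,
               activation = "linear"))
  expect_error(dpae:::new_arch(8L, "mlp", layers2), "bad_cat")
})

test_that("architectures round-trip through YAML configs", {
  spec <- dpae_mlp_canonical()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_architecture(spec, path)
  back <- read_architecture(path)
  expect_equal(arch_shapes(back), arch_shapes(spec))
  expect_equal(count_params(back), count_params(spec))
  expect_equal(back$backbone, spec$backbone)
})
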