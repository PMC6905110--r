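test_that("receptive-field recursion reproduces the canonical geometry", {
  geo <- receptive_field(canonical_spec("tasselnetv2"))
  tot <- attr(geo, "totals")
  expect_identical(tot$rf, 94)
  expect_identical(tot$stride, 16)
  expect_identical(tot$padding, 15)
  # rf never shrinks; jump is the running stride product
  expect_true(all(diff(geo$receptive_field) >= 0))
  expect_equal(geo$jump, cumprod(vapply(canonical_spec("tasselnetv2")$layers,
                                        `[[`, integer(1), "stride")))

  one <- network_spec(list(layer_spec("c", "conv", 3, 1, 0, 3, 8)))
  t1 <- geometry_totals(one)
  expect_equal(unlist(t1), c(rf = 3, stride = 1, padding = 0))

  # stripping padding changes coverage, not the receptive field or capacity
  for (v in c("tasselnet", "tasselnetv2")) {
    spec <- canonical_spec(v)
    stripped <- strip_padding(spec)
    expect_equal(geometry_totals(stripped)$rf, geometry_totals(spec)$rf)
    expect_equal(count_parameters(stripped), count_parameters(spec))
    expect_equal(geometry_totals(stripped)$padding, 0)
  }
})

test_that("gradient-support oracle agrees with the recursion on random stacks", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      st <- rand_conv_stack(sample(1:4, 1))
      layers <- lapply(seq_along(st$kernels), function(l)
        layer_spec(paste0("c", l), "conv", st$kernels[l], st$strides[l], 0,
                   in_channels = 1, out_channels = 1))
      spec <- network_spec(layers, input_channels = 1)
      rf <- geometry_totals(spec)$rf
      expect_equal(oracle_rf_support(st$kernels, st$strides), rf,
                   info = paste("kernels", paste(st$kernels, collapse = ","),
                                "strides", paste(st$strides, collapse = ",")))
    }
  })
})

test_that("output shapes follow floor arithmetic and compose layer by layer", {
  spec <- canonical_spec("tasselnetv2")
  expect_equal(output_shape(spec, c(912, 1216)), c(54, 73))
  expect_equal(output_shape(strip_padding(spec), c(94, 94)), c(1, 1))
  pool <- network_spec(list(layer_spec("p", "maxpool", 2, 2)),
                       input_channels = 1)
  expect_equal(output_shape(pool, c(8, 8)), c(4, 4))

  # whole-spec result equals folding over one-layer specs
  hw <- c(300, 411)
  step <- hw
  for (l in seq_along(spec$layers)) {
    sub <- spec
    sub$layers <- spec$layers[l]
    step <- output_shape(sub, step)
  }
  expect_equal(output_shape(spec, hw), step)

  expect_error(output_shape(spec, c(40, 40)), "conv6")
})

test_that("multiplication counts reproduce the published per-layer figures", {
  fl <- count_mult_flops(canonical_spec("tasselnetv2"), c(912, 1216))
  m <- setNames(fl$multiplications, fl$layer)
  expect_equal(signif(m[["conv1"]], 3), 4.79e8)
  expect_equal(signif(m[["conv6"]], 3), 2.07e9)
  expect_equal(signif(m[["conv7"]], 3), 6.46e7)
  expect_equal(signif(m[["conv8"]], 3), 5.05e5)
  expect_equal(signif(attr(fl, "total"), 3), 1.03e10)
  expect_identical(attr(fl, "total"), sum(fl$multiplications))

  one <- network_spec(list(layer_spec("c", "conv", 1, 1, 0, 1, 1)),
                      input_channels = 1)
  expect_equal(attr(count_mult_flops(one, c(10, 10)), "total"), 100)

  # patch-mode accounting scales linearly with the caller-supplied count
  p <- count_mult_flops(canonical_spec("tasselnet"), c(64, 64),
                        n_patches = 266)
  p1 <- count_mult_flops(canonical_spec("tasselnet"), c(64, 64))
  expect_equal(attr(p, "total"), 266 * attr(p1, "total"))
})

test_that("multiplication counts equal the loop-nest oracle on small inputs", {
  for (v in c("tasselnet", "tasselnet_ctx", "tasselnetv2")) {
    spec <- canonical_spec(v)
    spec$layers <- spec$layers[1:4]   # deeper layers need > 12 px input
    expect_identical(attr(count_mult_flops(spec, c(12, 12)), "total"),
                     oracle_flops(spec, c(12, 12)))
  }
  withr::with_seed(17, {
    for (rep in 1:5) {
      k <- sample(c(1L, 3L), 2, replace = TRUE)
      layers <- lapply(1:2, function(l)
        layer_spec(paste0("c", l), "conv", k[l], sample(1:2, 1),
                   sample(0:1, 1), in_channels = c(3, 4)[l],
                   out_channels = c(4, 2)[l]))
      spec <- network_spec(layers)
      expect_identical(attr(count_mult_flops(spec, c(12, 12)), "total"),
                       oracle_flops(spec, c(12, 12)))
    }
  })
})

test_that("weight-only parameter counts match the published capacity", {
  expect_equal(count_parameters(canonical_spec("tasselnetv2")), 638000)
  expect_equal(count_parameters(canonical_spec("tasselnet")),
               count_parameters(canonical_spec("tasselnetv2")))
  one <- network_spec(list(layer_spec("c", "conv", 3, 1, 0, 3, 16)))
  expect_equal(count_parameters(one), 432)
  withpool <- network_spec(list(layer_spec("c", "conv", 3, 1, 0, 3, 16),
                                layer_spec("p", "maxpool", 2, 2)))
  expect_equal(count_parameters(withpool), 432)
})

test_that("layer validation rejects impossible geometry", {
  expect_error(layer_spec("c", "conv", 0, 1, 0, 3, 8), "kernel")
  expect_error(layer_spec("c", "conv", 3, 0, 0, 3, 8), "stride")
  expect_error(layer_spec("c", "conv", 3, 1, -1, 3, 8), "padding")
  expect_error(layer_spec("c", "conv", 3, 1, 0), "channels")
  expect_error(network_spec(list(
    layer_spec("a", "conv", 3, 1, 0, 3, 8),
    layer_spec("b", "conv", 3, 1, 0, 16, 8))), "channels")
})

test_that("network specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  spec <- canonical_spec("tasselnetv2")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(back, spec)
  expect_equal(geometry_totals(back), geometry_totals(spec))
})
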