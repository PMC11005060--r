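# Network assembly, variants, profilers, checkpoints, heatmaps.
# Tests use a reduced 64x64 input with narrow widths so full forward and
# backward passes stay fast; the complexity contracts are size-agnostic.

small_cfg <- function(...) model_config(input_size = 64L,
                                        stage_widths = c(3L, 4L, 6L, 8L, 12L),
                                        n_partitions = 2L, shift_size = 3L,
                                        ...)

test_that("build_model forward pass produces probabilities of the right shape", {
  m <- build_model(small_cfg(), seed = 1)
  x <- rfm(2, 3, 64, 64); x <- (x - min(x)) / diff(range(x))
  p <- forward_pass(m, x)
  expect_equal(dim(p), c(2, 1, 64, 64))
  expect_true(all(p > 0 & p < 1))
  # eval determinism: double call is bitwise identical
  expect_identical(p, forward_pass(m, x))
  # wrong spatial size errors with a resize hint
  expect_error(forward_pass(m, rfm(1, 3, 32, 32)), "resize|crop")
  expect_error(forward_pass(m, rfm(1, 5, 64, 64)), "channels")
})

test_that("same config and seed build identical models", {
  cfg <- small_cfg()
  m1 <- build_model(cfg, seed = 42)
  m2 <- build_model(cfg, seed = 42)
  expect_equal(mdunet:::param_checksum(m1), mdunet:::param_checksum(m2))
  m3 <- build_model(cfg, seed = 43)
  expect_false(isTRUE(all.equal(mdunet:::param_checksum(m1),
                                mdunet:::param_checksum(m3))))
})

test_that("build_variant toggles modules and orders complexity correctly", {
  cfg <- small_cfg()
  ms <- lapply(c("baseline", "baseline_mfe", "baseline_da", "full"),
               build_variant, config = cfg)
  p <- sapply(ms, count_parameters)
  f <- sapply(ms, function(m) count_flops(m))
  # params and flops strictly increase from baseline to full
  expect_true(p[1] < p[2] && p[2] < p[4])
  expect_true(p[1] < p[3] && p[3] < p[4])
  expect_true(all(f[1] < f[2:4]))
  expect_true(all(f[2:3] < f[4]))
  # module costs are architecturally independent (exact additivity)
  expect_equal(p[4] - p[1], (p[2] - p[1]) + (p[3] - p[1]), tolerance = 1e-12)
  expect_equal(f[4] - f[1], (f[2] - f[1]) + (f[3] - f[1]), tolerance = 1e-12)
  # full equals build_model on the same config
  expect_equal(count_parameters(ms[[4]]), count_parameters(build_model(cfg)))
  expect_error(build_variant("nope", cfg), "baseline")
})

test_that("count_parameters matches closed forms and the built model", {
  # single 3x3 conv 3 -> 16 with bias
  conv <- mdunet:::layer_conv2d("c", 3, 16, 3)
  expect_equal(mdunet:::module_n_params(conv), 3 * 3 * 3 * 16 + 16)
  # depthwise 3x3 on C channels with bias: 10 C elements
  dw <- mdunet:::layer_conv2d("d", 7, 7, 3, groups = 7)
  expect_equal(mdunet:::module_n_params(dw), 10 * 7)
  # analytic per-layer profile equals the built model's parameter count
  m <- build_model(small_cfg())
  rep <- complexity_report(m)
  expect_equal(rep$params_millions, count_parameters(m), tolerance = 1e-12)
  expect_equal(rep$params_millions, sum(rep$breakdown$params) / 1e6)
})

test_that("analytic FLOPs match closed forms and the runtime meter", {
  # 1x1 conv: H W cin cout MACs (+ bias adds)
  r1 <- mdunet:::prof_conv("x", 8, 4, 1, 1, 16)
  expect_equal(r1$flops, 16 * 16 * 4 * (8 + 1))
  # cross-check: analytic total vs hook-based runtime profiler within 1%
  for (variant in c("baseline", "full")) {
    m <- build_variant(variant, small_cfg())
    fa <- count_flops(m)
    fr <- profile_flops_runtime(m)
    expect_lt(abs(fa - fr) / fa, 0.01, label = variant)
  }
  # report totals are invariant to batch size (per-image metering)
  m <- build_variant("full", small_cfg())
  x2 <- array(0, c(2, 3, 64, 64))
  mdunet:::ag_profile_start()
  invisible(forward_pass(m, x2))
  f2 <- mdunet:::ag_profile_stop() / 1e9
  expect_equal(f2 / 2, count_flops(m), tolerance = 1e-9)
})

test_that("complexity profile covers every parameter-bearing layer", {
  m <- build_variant("full", small_cfg())
  br <- complexity_report(m)$breakdown
  expect_false(any(is.na(br$params)))
  expect_false(any(is.na(br$flops)))
  # every named parameter group appears in the breakdown prefix set
  prm <- names(mdunet:::model_params(m))
  tops <- unique(sub("\\..*$", "", br$name))
  expect_true(all(sub("\\..*$", "", prm) %in% tops))
})

test_that("no trainable parameter sits on a detached branch", {
  # architectural dead-branch detector.  A parameter on a path that is
  # disconnected from the loss gets zero gradient under EVERY weight
  # initialization; a transiently dead ReLU unit does not.  So the test
  # re-initializes the model several times and requires each parameter to
  # receive gradient under at least one init.
  set.seed(55)
  seen <- NULL
  for (init in 1:8) {
    m <- build_model(small_cfg(se_ratio = 2L), seed = init)
    ps <- mdunet:::model_params(m)
    if (is.null(seen)) seen <- setNames(rep(FALSE, length(ps)), names(ps))
    x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
    y <- (array(runif(64 * 64 * 2), c(64, 64, 1, 2)) > 0.5) * 1
    out <- mdunet:::model_forward_ag(m, mdunet:::ag_var(x))
    loss <- mdunet:::ag_combined_loss(y, out)
    mdunet:::ag_backward(loss)
    for (nm in names(ps)) {
      g <- ps[[nm]]$grad
      if (!is.null(g) && max(abs(g)) > 0) seen[nm] <- TRUE
    }
    if (all(seen)) break
  }
  expect_length(names(seen)[!seen], 0)
})

test_that("model config round-trips through YAML and JSON losslessly", {
  cfg <- small_cfg(use_da = TRUE, da_int_mult = 2.5, da_gate_pool = 1L,
                   mfe_levels = c(2L, 3L), fusion_mode = "add")
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_model_config(cfg, path)
    back <- read_model_config(path)
    expect_equal(back, cfg)
  }
})

test_that("checkpoints restore weights and predictions exactly", {
  m <- build_model(small_cfg(), seed = 9)
  x <- rfm(1, 3, 64, 64); x <- (x - min(x)) / diff(range(x))
  p1 <- forward_pass(m, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(forward_pass(m2, x), p1)
})

test_that("activation heatmaps are written at input resolution", {
  m <- build_model(small_cfg(), seed = 2)
  cfg <- tiny_nuclei_cfg(seed = 4, size = 64L)
  s <- generate_nuclei_sample(cfg)
  out <- tempfile(fileext = ".png")
  hm <- export_activation_heatmap(m, s, "head", out)
  expect_true(file.exists(out))
  img <- png::readPNG(out)
  expect_equal(dim(img)[1:2], c(64, 64))
  expect_true(all(hm >= 0 & hm <= 1))
  # constant activation map: degenerate normalization maps to 0 (head of a
  # zeroed model is constant)
  m0 <- build_model(small_cfg(), seed = 2)
  zero_params(m0$head)
  hm0 <- export_activation_heatmap(m0, s, "head", tempfile(fileext = ".png"))
  expect_true(all(hm0 == 0))
  expect_error(export_activation_heatmap(m, s, "bogus", out), "registered")
})
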