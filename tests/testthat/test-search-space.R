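test_that("default space matches the nine printed hyperparameter grids", {
  sp <- default_seagrass_space()
  expect_equal(sp$d, 9L)
  nm <- vapply(sp$specs, `[[`, character(1L), "name")
  spec_of <- function(n) sp$specs[[match(n, nm)]]

  expect_equal(spec_of("n_conv_layers")$categories, 1:20)
  expect_equal(spec_of("kernel_size")$categories, 1:30)
  expect_equal(spec_of("n_filters")$categories, 1:500)
  expect_equal(spec_of("n_epochs")$categories, 1:400)
  expect_equal(spec_of("batch_size")$categories, seq(10L, 200L, by = 10L))
  expect_equal(spec_of("pool_size")$categories, 1:20)

  dr <- spec_of("dropout")$categories
  expect_equal(dr[1L], 0.20)
  expect_equal(dr[length(dr)], 0.65)
  expect_equal(diff(dr), rep(0.05, length(dr) - 1L))

  lr <- spec_of("learning_rate")$categories
  expect_equal(lr[1:2], c(0.001, 0.006))
  expect_equal(lr[length(lr)], 0.1)

  mr <- spec_of("momentum")$categories
  expect_equal(range(mr), c(0.05, 0.95))
})

test_that("uniform sampling respects bounds and the unit embedding", {
  sp <- search_space(hp_continuous("x", 10, 200), hp_discrete("k", 1:7))
  set.seed(1)
  pos <- sample_uniform(sp, 5000)
  expect_true(all(pos[, 1L] >= 10 & pos[, 1L] <= 200))
  expect_true(all(pos[, 2L] >= 0 & pos[, 2L] <= 1))
  # affine form lower + u * (upper - lower): endpoints are attainable
  # limits; check via the repaired decode of forced endpoint coordinates
  expect_equal(repair(sp, c(10, 0)), c(10, 0))
  expect_equal(repair(sp, c(200, 1)), c(200, 1))
  expect_error(sample_uniform(sp, 0), "positive")

  set.seed(42)
  a <- sample_uniform(sp, 10)
  set.seed(42)
  b <- sample_uniform(sp, 10)
  expect_identical(a, b)
})

test_that("discretization maps endpoints and midpoints as specified", {
  K5 <- paste0("K", 1:5)
  expect_identical(discretize(0, K5), "K1")
  expect_identical(discretize(1, K5), "K5")
  expect_identical(discretize(0.5, paste0("K", 1:4)), "K3")
  expect_error(discretize(-0.1, K5), "\\[0, 1\\]")
  expect_error(discretize(1.1, K5), "\\[0, 1\\]")
  # single category is total
  expect_identical(discretize(c(0, 0.5, 1), "only"), rep("only", 3L))
})

test_that("discretization never escapes the category list", {
  set.seed(3)
  for (n in c(1L, 2L, 7L, 20L, 500L)) {
    cats <- seq_len(n)
    r <- c(0, 1, stats::runif(500))
    expect_true(all(discretize(r, cats) %in% cats))
  }
})

test_that("uniform R induces uniform categories", {
  set.seed(4)
  n <- 7L
  draws <- discretize(stats::runif(20000), seq_len(n))
  tab <- table(factor(draws, levels = seq_len(n)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("decode passes continuous through and discretizes the rest", {
  sp <- search_space(hp_continuous("x", -1, 1), hp_discrete("k", 5:9),
                     hp_discrete("z", c("a", "b")))
  expect_identical(decode(sp, c(0.25, 0, 0)), list(x = 0.25, k = 5L, z = "a"))
  expect_identical(decode(sp, c(0.25, 1, 1)), list(x = 0.25, k = 9L, z = "b"))
  expect_error(decode(sp, c(1, 2)), "dimensions")

  # closure + determinism on the default space
  sp9 <- default_seagrass_space()
  set.seed(5)
  pos <- sample_uniform(sp9, 50)
  for (i in seq_len(nrow(pos))) {
    a <- decode(sp9, pos[i, ])
    expect_identical(a, decode(sp9, pos[i, ]))
    for (j in seq_len(sp9$d)) {
      expect_true(a[[j]] %in% sp9$specs[[j]]$categories)
    }
  }
})

test_that("repair clamps, is idempotent, and decode after repair is total", {
  sp <- search_space(hp_continuous("lr", 0.001, 0.1), hp_discrete("k", 1:5))
  expect_equal(repair(sp, c(-5, 1.7)), c(0.001, 1))
  expect_equal(repair(sp, c(0.05, 0.3)), c(0.05, 0.3))
  set.seed(6)
  for (i in 1:50) {
    p <- stats::rcauchy(2) * 10
    r <- repair(sp, p)
    expect_identical(repair(sp, r), r)
    a <- decode(sp, r)
    expect_true(a$lr >= 0.001 && a$lr <= 0.1)
    expect_true(a$k %in% 1:5)
  }
})

test_that("search spaces serialize to config lists and back", {
  sp <- search_space(hp_continuous("x", -2, 3), hp_discrete("k", c(1L, 5L, 9L)))
  rt <- space_from_config(space_to_config(sp))
  expect_equal(rt, sp)
  # through YAML as the config file would store it
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(space_to_config(sp), f)
  rt2 <- space_from_config(yaml::read_yaml(f))
  expect_equal(rt2$d, 2L)
  expect_equal(rt2$specs[[2L]]$categories, c(1L, 5L, 9L))
})
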