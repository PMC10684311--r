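# brute-force oracle: all candidate cells sorted by wrapped distance
brute_kth_distance <- function(x, y, L, k) {
  cc <- expand.grid(cx = 0:(L - 1), cy = 0:(L - 1))
  cc <- cc[!(cc$cx == x & cc$cy == y), ]
  d2 <- torus_dist2(x, y, cc$cx, cc$cy, L)
  sort(d2)[k]
}

test_that("periodic nearest neighbours: unique shells, wrapping, brute-force cut radius", {
  set.seed(1)
  nb <- periodic_nearest(5, 5, L = 20, k = 4)
  expect_equal(nrow(nb), 4)
  expect_setequal(paste(nb$x, nb$y),
                  c("4 5", "6 5", "5 4", "5 6"))

  # corner cell reaches the same shell via wrapping
  nb0 <- periodic_nearest(0, 0, L = 20, k = 4)
  expect_setequal(paste(nb0$x, nb0$y),
                  c("19 0", "1 0", "0 19", "0 1"))

  # k = 40: max selected distance equals the exhaustive k-th distance
  for (cell in list(c(0, 0), c(7, 13))) {
    nb40 <- periodic_nearest(cell[1], cell[2], L = 20, k = 40)
    got <- max(torus_dist2(cell[1], cell[2], nb40$x, nb40$y, 20))
    expect_equal(got, brute_kth_distance(cell[1], cell[2], 20, 40))
  }
  expect_error(periodic_nearest(0, 0, L = 20, k = 400), "k must be")
})

test_that("module topology satisfies the degree and weight invariants", {
  set.seed(42)
  top <- build_module()
  # out-degrees
  expect_true(all(table(top$ee$src) == 40))
  expect_true(all(table(top$ei$src) == 10))
  expect_true(all(table(top$ie$src) == 400))
  expect_true(all(table(top$ii$src) == 99))   # no self-inhibition
  expect_false(any(top$ii$src == top$ii$dst))
  expect_false(any(top$ee$src == top$ee$dst))
  # weights exactly as printed
  expect_true(all(top$ee$w == 0.01))
  expect_true(all(top$ei$w == 0.05))
  expect_true(all(top$ii$w == 0.04))
  expect_true(all(top$ie$w == 0.04))
  # 100 I cells out of 500 = 20%
  n_i <- length(unique(top$ie$src))
  expect_equal(n_i / (n_i + length(unique(top$ee$src))), 0.2)
})

test_that("wiring is reproducible from the seed", {
  set.seed(7)
  a <- build_module()
  set.seed(7)
  b <- build_module()
  expect_identical(a, b)
  set.seed(7)
  w1 <- build_intermodule("random", 40)
  set.seed(7)
  w2 <- build_intermodule("random", 40)
  expect_identical(w1, w2)
})

test_that("random inter-module wiring has the exact in-degree and initial weight", {
  set.seed(3)
  w <- build_intermodule("random", in_degree = 40)
  for (dir in c("w12", "w21")) {
    expect_equal(unname(table(w[[dir]]$dst)), rep(40L, 400),
                 ignore_attr = TRUE)
    expect_true(all(w[[dir]]$w == 0.005))
  }
  expect_error(build_intermodule("random", in_degree = 0))
})

test_that("topographic wiring aligns overlaid lattices", {
  set.seed(5)
  w1 <- build_intermodule("topographic", in_degree = 1)
  # nearest cell under overlay is the aligned counterpart (distance 0)
  expect_true(all(w1$w12$src == w1$w12$dst))
  expect_true(all(w1$w21$src == w1$w21$dst))

  # in_degree = 5 neighbour sets match exhaustive enumeration (the aligned
  # cell plus the four axis neighbours: distances 0,1,1,1,1)
  set.seed(5)
  w5 <- build_intermodule("topographic", in_degree = 5)
  cc <- data.frame(x = rep(0:19, each = 20), y = rep(0:19, times = 20))
  for (src in c(1, 25, 400)) {
    d2 <- torus_dist2(cc$x[src], cc$y[src],
                      cc$x[w5$w12$dst[w5$w12$src == src]],
                      cc$y[w5$w12$dst[w5$w12$src == src]], 20)
    expect_true(all(sort(d2) == c(0, 1, 1, 1, 1)))
  }
  # symmetry of the construction gives constant in-degree too
  expect_true(all(table(w5$w12$dst) == 5))
})

test_that("topographic wiring is translation-covariant on the torus", {
  # shifting the query point by (a, b) shifts its neighbour set
  set.seed(11)
  base <- periodic_nearest(3, 4, 20, 8)
  shifted <- periodic_nearest((3 + 6) %% 20, (4 + 9) %% 20, 20, 8)
  expect_setequal(paste((base$x + 6) %% 20, (base$y + 9) %% 20),
                  paste(shifted$x, shifted$y))
})

test_that("display indices follow the column-major raster scheme", {
  expect_equal(display_index(2, "E", 0, 0), 1L)
  expect_equal(display_index(2, "E", 1, 2), 23L)
  expect_equal(display_index(2, "E", 19, 19), 400L)
  expect_equal(display_index(2, "I", 0, 0), 401L)
  expect_equal(display_index(1, "E", 0, 0), 501L)
  expect_equal(display_index(1, "I", 9, 9), 1000L)
})

test_that("edge lists and weight matrices round-trip through text formats", {
  set.seed(2)
  w <- build_intermodule("random", in_degree = 5)
  path <- tempfile(fileext = ".tsv")
  write_edges(w$w12, path)
  back <- read_edges(path)
  expect_equal(back$src, w$w12$src)
  expect_equal(back$w, w$w12$w)

  mtx <- tempfile(fileext = ".mtx")
  write_weights_mtx(w$w12, mtx)
  m <- as.matrix(Matrix::readMM(mtx))
  expect_equal(sum(m > 0), nrow(w$w12))
  expect_equal(sum(m), sum(w$w12$w), tolerance = 1e-12)
})
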