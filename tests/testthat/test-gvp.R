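make_gvp_inputs <- function(n = 6, si = 5, vi = 3, seed = 31) {
  set.seed(seed)
  list(s = matrix(rnorm(n * si), n, si),
       V = matrix(rnorm(3 * n * vi), 3 * n, vi))
}

rotate_stacked <- function(V, R) {
  n <- nrow(V) %/% 3L
  out <- V
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    out[rows, ] <- t(R) %*% V[rows, , drop = FALSE]
  }
  out
}

test_that("one GVP matches an independently coded plain implementation", {
  set.seed(32)
  p <- ribodesign:::gvp_init(5L, 3L, 4L, 2L)
  inp <- make_gvp_inputs()
  got <- ribodesign:::gvp_forward(p, inp$s, inp$V, act = TRUE)
  want <- gvp_plain(p, inp$s, inp$V, act = TRUE)
  expect_equal(got$s, want$s, tolerance = 1e-12)
  expect_equal(got$V, want$V, tolerance = 1e-12)
})

test_that("GVP is O(3)-equivariant: scalars invariant, vectors rotate", {
  set.seed(33)
  p <- ribodesign:::gvp_init(5L, 3L, 4L, 2L)
  inp <- make_gvp_inputs()
  base <- ribodesign:::gvp_forward(p, inp$s, inp$V, act = TRUE)
  for (R in list(random_rotation(1), diag(c(1, 1, -1)) %*% random_rotation(2))) {
    rot <- ribodesign:::gvp_forward(p, inp$s, rotate_stacked(inp$V, R), act = TRUE)
    expect_equal(rot$s, base$s, tolerance = 1e-10)          # improper included
    expect_equal(rot$V, rotate_stacked(base$V, R), tolerance = 1e-10)
  }
})

test_that("zero input vectors give zero output vectors and finite scalars", {
  p <- ribodesign:::gvp_init(5L, 3L, 4L, 2L)
  inp <- make_gvp_inputs()
  out <- ribodesign:::gvp_forward(p, inp$s, inp$V * 0, act = TRUE)
  expect_equal(out$V, out$V * 0)
  expect_true(all(is.finite(out$s)))
})

test_that("relational layer with one populated type equals a plain single-type layer bit-for-bit", {
  set.seed(34)
  n <- 7; sd <- 6L; vd <- 2L; se <- 4L; ve <- 1L
  lp3 <- ribodesign:::relational_layer_init(sd, vd, se, ve,
                                            c("primary", "secondary", "spatial"))
  lp1 <- list(msg = list(all = lp3$msg$primary),
              w = list(all = matrix(1, 1, 1)),
              ff = lp3$ff)
  s <- matrix(rnorm(n * sd), n, sd)
  V <- matrix(rnorm(3 * n * vd), 3 * n, vd)
  E <- rbind(c(1L, 2L), c(2L, 1L), c(3L, 6L), c(6L, 3L), c(5L, 4L))
  ef <- list(s = matrix(rnorm(nrow(E) * se), nrow(E), se),
             V = matrix(rnorm(3 * nrow(E) * ve), 3 * nrow(E), ve))
  empty <- list(E = matrix(integer(0), 0, 2),
                ef = list(s = matrix(0, 0, se), V = matrix(0, 0, ve)))
  gf3 <- list(primary = list(E = E, ef = ef), secondary = empty, spatial = empty)
  gf1 <- list(all = list(E = E, ef = ef))
  out3 <- ribodesign:::relational_layer_forward(lp3, s, V, gf3, n)
  out1 <- ribodesign:::relational_layer_forward(lp1, s, V, gf1, n)
  expect_identical(out3$s, out1$s)
  expect_identical(out3$V, out1$V)
})

test_that("relational layer matches the brute-force per-edge oracle", {
  set.seed(35)
  n <- 7; sd <- 6L; vd <- 2L; se <- 4L; ve <- 1L
  lp <- ribodesign:::relational_layer_init(sd, vd, se, ve, "primary")
  lp$w$primary <- matrix(1.37, 1, 1)
  s <- matrix(rnorm(n * sd), n, sd)
  V <- matrix(rnorm(3 * n * vd), 3 * n, vd)
  E <- rbind(c(1L, 2L), c(1L, 3L), c(4L, 2L), c(7L, 6L), c(2L, 1L))
  ef <- list(s = matrix(rnorm(nrow(E) * se), nrow(E), se),
             V = matrix(rnorm(3 * nrow(E) * ve), 3 * nrow(E), ve))
  got <- ribodesign:::relational_layer_forward(
    lp, s, V, list(primary = list(E = E, ef = ef)), n)
  want <- plain_layer_oracle(lp$msg$primary, 1.37, lp$ff, s, V, E, ef$s, ef$V)
  expect_equal(got$s, want$s, tolerance = 1e-10)
  expect_equal(got$V, want$V, tolerance = 1e-10)
})

test_that("learned edge-type weights scale their component's contribution", {
  set.seed(36)
  n <- 5; sd <- 4L; vd <- 1L; se <- 3L; ve <- 1L
  lp <- ribodesign:::relational_layer_init(sd, vd, se, ve, c("primary", "secondary"))
  s <- matrix(rnorm(n * sd), n, sd)
  V <- matrix(rnorm(3 * n * vd), 3 * n, vd)
  E <- rbind(c(1L, 2L), c(3L, 4L))
  ef <- list(s = matrix(rnorm(2 * se), 2, se), V = matrix(rnorm(6 * ve), 6, ve))
  empty <- list(E = matrix(integer(0), 0, 2),
                ef = list(s = matrix(0, 0, se), V = matrix(0, 0, ve)))
  gf <- list(primary = list(E = E, ef = ef), secondary = empty)
  out1 <- ribodesign:::relational_layer_forward(lp, s, V, gf, n)
  lp0 <- lp; lp0$w$primary <- matrix(0, 1, 1)
  out0 <- ribodesign:::relational_layer_forward(lp0, s, V, gf, n)
  # with the only populated component weighted 0, the layer sees no messages
  gf_none <- list(primary = empty, secondary = empty)
  outn <- ribodesign:::relational_layer_forward(lp, s, V, gf_none, n)
  expect_equal(out0$s, outn$s, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out1$s, out0$s)))
})

test_that("message aggregation sums over incoming edges per receiver", {
  set.seed(37)
  sd <- 3L; vd <- 1L; se <- 2L; ve <- 1L
  mp <- ribodesign:::msg_init(sd, vd, se, ve)
  n <- 4
  s <- matrix(rnorm(n * sd), n, sd)
  V <- matrix(rnorm(3 * n * vd), 3 * n, vd)
  E2 <- rbind(c(1L, 2L), c(1L, 3L))      # node 1 receives from 2 and 3
  ef2 <- list(s = matrix(rnorm(2 * se), 2, se), V = matrix(rnorm(6), 6, ve))
  both <- ribodesign:::gvp_component_messages(mp, s, V, E2, ef2, n)
  one <- ribodesign:::gvp_component_messages(
    mp, s, V, E2[1, , drop = FALSE],
    list(s = ef2$s[1, , drop = FALSE], V = ef2$V[1:3, , drop = FALSE]), n)
  two <- ribodesign:::gvp_component_messages(
    mp, s, V, E2[2, , drop = FALSE],
    list(s = ef2$s[2, , drop = FALSE], V = ef2$V[4:6, , drop = FALSE]), n)
  expect_equal(both$s, one$s + two$s, tolerance = 1e-12)
  expect_equal(both$V, one$V + two$V, tolerance = 1e-12)
  expect_equal(both$s[4, ], rep(0, sd))  # node with no incoming edges
})
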