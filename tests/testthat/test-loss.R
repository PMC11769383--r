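# Boundary extraction, distance maps, gradient fields and the three
# loss components against brute-force / closed-form oracles.

test_that("boundary extraction follows the inner 4-neighbour rule", {
  expect_equal(max(extract_boundary(matrix(0, 8, 8))), 0)

  m <- matrix(0, 5, 5); m[3, 3] <- 1
  b <- extract_boundary(m)
  expect_equal(which(b != 0), which(m != 0))

  # solid 3x3 square centred in 7x7: 8 perimeter pixels, centre excluded
  sq <- matrix(0, 7, 7); sq[3:5, 3:5] <- 1
  b <- extract_boundary(sq)
  expect_equal(sum(b), 8)
  expect_equal(b[4, 4], 0)
  expect_equal(b, brute_boundary(sq))

  # all-foreground mask: no label change inside the image
  expect_equal(max(extract_boundary(matrix(1, 6, 6))), 0)

  expect_error(extract_boundary(matrix(0.5, 4, 4)), "binary")
})

test_that("boundary extraction agrees with brute force on random masks", {
  set.seed(301)
  for (rep in 1:25) {
    m <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10, 10)
    expect_equal(extract_boundary(m), brute_boundary(m))
  }
})

test_that("distance map is the exact minimum over boundary pixels", {
  b <- matrix(0, 5, 5); b[3, 3] <- 1
  D <- distance_map(b)
  expect_equal(D[3, 3], 0)
  expect_equal(D[1, 1], 2 * sqrt(2), tolerance = 1e-12)

  expect_equal(distance_map(matrix(0, 6, 6)), matrix(0, 6, 6))

  set.seed(302)
  for (rep in 1:100) {
    m <- matrix(rbinom(256, 1, runif(1, 0.05, 0.6)), 16, 16)
    b <- extract_boundary(m)
    expect_equal(distance_map(b), brute_distance(b), tolerance = 1e-12)
  }
})

test_that("distance map is translation-equivariant away from edges", {
  set.seed(303)
  base <- matrix(0, 16, 16)
  base[5:8, 4:7] <- 1
  base[6, 9] <- 1
  D0 <- distance_map(extract_boundary(base))
  shifted <- matrix(0, 16, 16)
  shifted[2 + (5:8), 3 + (4:7)] <- 1
  shifted[2 + 6, 3 + 9] <- 1
  D1 <- distance_map(extract_boundary(shifted))
  # compare on the interior window the object occupies in both frames
  expect_equal(D1[(3:16), (4:16)], D0[1:14, 1:13], tolerance = 1e-12)
})

test_that("gradient magnitude matches its defining scheme", {
  expect_equal(gradient_magnitude(matrix(3.7, 6, 8)), matrix(0, 6, 8))

  W <- 7
  ramp <- matrix(rep((0:(W - 1)) / (W - 1), each = 5), 5, W)
  gm <- gradient_magnitude(ramp)
  expect_equal(gm[, 1:(W - 1)], matrix(1 / (W - 1), 5, W - 1),
               tolerance = 1e-12)
  expect_equal(gm[, W], rep(0, 5))

  set.seed(304)
  p <- matrix(rnorm(36), 6, 6)
  expect_lt(max(abs(gradient_magnitude(p) - loop_grad_mag(p))), 1e-7)
})

test_that("bce loss reproduces closed-form values and stays finite", {
  G <- rand_mask(1, 4, 4)
  expect_equal(bce_loss(array(0, c(1, 1, 4, 4)), G), log(2),
               tolerance = 1e-9)

  G1 <- array(1, c(1, 1, 4, 4))
  expect_lt(bce_loss(array(20, c(1, 1, 4, 4)), G1), 1e-8)

  # worked 2x2 example, term by term
  P <- array(c(0, -2, 2, 0), c(1, 1, 2, 2))   # [[0,2],[-2,0]] row-major
  G <- array(c(0, 1, 1, 0), c(1, 1, 2, 2))
  manual <- -mean(c(log(1 - sigm(0)), log(sigm(-2)), log(sigm(2)),
                    log(1 - sigm(0))))
  expect_equal(bce_loss(P, G), manual, tolerance = 1e-12)

  # extreme logits of both signs never produce non-finite values
  Pb <- array(c(500, -500, 300, -300), c(1, 1, 2, 2))
  expect_true(is.finite(bce_loss(Pb, G)))
  expect_error(bce_loss(array(0, c(1, 1, 3, 3)), rand_mask(1, 4, 4)),
               "shape mismatch")
})

test_that("dice loss covers perfect, empty and disjoint cases", {
  set.seed(305)
  G <- rand_mask(2, 8, 8, 0.4)
  hard <- (2 * G - 1) * 20
  expect_lt(dice_loss(hard, G, xi = 1e-6), 1e-3)

  # empty mask, near-empty prediction: the smoothing term keeps the
  # 0/0 case finite; exact value is S/(S + xi) with S the residual
  # probability mass, which vanishes once saturation beats xi
  G0 <- array(0, c(1, 1, 8, 8))
  S <- 64 * sigm(-20)
  expect_equal(dice_loss(array(-20, c(1, 1, 8, 8)), G0, xi = 1e-6),
               S / (S + 1e-6), tolerance = 1e-9)
  expect_lt(dice_loss(array(-40, c(1, 1, 8, 8)), G0, xi = 1e-6), 1e-3)

  Gl <- array(0, c(1, 1, 8, 8)); Gl[, , , 1:4] <- 1
  Pr <- array(-20, c(1, 1, 8, 8)); Pr[, , , 5:8] <- 20
  expect_gt(dice_loss(Pr, Gl, xi = 1e-6), 0.999)

  expect_error(dice_loss(G, G, xi = 0), "xi")
  expect_error(dice_loss(G, G, xi = -1), "xi")
})

test_that("boundary loss vanishes where it must and composes the oracles", {
  set.seed(306)
  G <- rand_mask(1, 6, 6, 0.4)
  expect_equal(boundary_loss(array(1.3, c(1, 1, 6, 6)), G), 0)
  P <- array(rnorm(36), c(1, 1, 6, 6))
  expect_equal(boundary_loss(P, array(0, c(1, 1, 6, 6))), 0)

  # 4x4 derived case: vertical logit step against a left-half mask
  P4 <- array(0, c(1, 1, 4, 4))
  P4[1, 1, , 1:2] <- 6
  P4[1, 1, , 3:4] <- -6
  G4 <- array(0, c(1, 1, 4, 4)); G4[1, 1, , 1:2] <- 1
  D <- brute_distance(brute_boundary(matrix(G4[1, 1, , ], 4)))
  gm <- loop_grad_mag(sigm(matrix(P4[1, 1, , ], 4)))
  expect_equal(boundary_loss(P4, G4), mean(gm * D), tolerance = 1e-12)

  expect_gte(boundary_loss(P, G), 0)
})

test_that("boundary loss grows as a sharp edge moves off the true boundary", {
  # 16x16, true mask = left 8 columns; predicted sharp sigmoid edge
  # displaced by k columns: loss must not decrease with k
  H <- 16
  G <- array(0, c(1, 1, H, H)); G[1, 1, , 1:8] <- 1
  loss_at <- function(k) {
    P <- array(-12, c(1, 1, H, H))
    P[1, 1, , 1:(8 + k)] <- 12
    boundary_loss(P, G)
  }
  ls <- vapply(0:3, loss_at, numeric(1))
  expect_true(all(diff(ls) >= 0))
  expect_gt(ls[4], ls[1])
})

test_that("bce and dice are pixel-permutation invariant; boundary is not", {
  set.seed(307)
  P <- array(rnorm(64), c(1, 1, 8, 8))
  G <- rand_mask(1, 8, 8, 0.4)
  perm <- sample(64)
  Pp <- array(as.numeric(P)[perm], dim(P))
  Gp <- array(as.numeric(G)[perm], dim(G))
  expect_equal(bce_loss(P, G), bce_loss(Pp, Gp), tolerance = 1e-12)
  expect_equal(dice_loss(P, G), dice_loss(Pp, Gp), tolerance = 1e-12)

  # counterexample: scrambling pixels changes the boundary geometry
  Pc <- array(0, c(1, 1, 8, 8)); Pc[1, 1, , 1:4] <- 8; Pc[1, 1, , 5:8] <- -8
  Gc <- array(0, c(1, 1, 8, 8)); Gc[1, 1, , 1:4] <- 1
  set.seed(308)
  perm <- sample(64)
  Pcp <- array(as.numeric(Pc)[perm], dim(Pc))
  Gcp <- array(as.numeric(Gc)[perm], dim(Gc))
  expect_gt(abs(boundary_loss(Pcp, Gcp) - boundary_loss(Pc, Gc)), 1e-6)
})

test_that("aflm total is the stated linear combination of its parts", {
  set.seed(309)
  P <- array(rnorm(2 * 64), c(2, 1, 8, 8))
  G <- rand_mask(2, 8, 8, 0.35)

  res <- aflm_total(P, G)
  w <- loss_weights()
  expect_equal(res$total,
               w$alpha * res$bce + w$beta * res$dice + w$gamma * res$boundary,
               tolerance = 1e-12)
  expect_equal(res$bce, bce_loss(P, G), tolerance = 1e-12)
  expect_equal(res$dice, dice_loss(P, G, w$xi), tolerance = 1e-12)
  expect_equal(res$boundary, boundary_loss(P, G), tolerance = 1e-12)

  # default coefficients
  expect_equal(w$alpha, sqrt(2) / 2)
  expect_equal(w$beta, 1 + sqrt(2) / 2)
  expect_equal(w$gamma, 1 + sqrt(2) / 2)

  # scaling one weight scales exactly that contribution
  w2 <- loss_weights(alpha = 3 * w$alpha, beta = w$beta, gamma = w$gamma)
  res2 <- aflm_total(P, G, w2)
  expect_equal(res2$total - res$total, 2 * w$alpha * res$bce,
               tolerance = 1e-12)

  expect_error(loss_weights(alpha = -1), "non-negative")
})

test_that("differentiable total matches finite differences for all schemes", {
  set.seed(310)
  P <- array(rnorm(64), c(1, 1, 8, 8))
  G <- rand_mask(1, 8, 8, 0.4)
  w <- loss_weights()
  for (scheme in c("forward", "central", "sobel")) {
    pn <- ag_leaf(P)
    l <- with_grad(afnnet:::ag_aflm(pn, G, w, scheme = scheme))
    expect_equal(l$value, aflm_total(P, G, w, scheme = scheme)$total,
                 tolerance = 1e-12)
    ag_backward(l)
    for (i in sample(64, 6)) {
      pp <- P; pp[i] <- P[i] + 1e-6
      pm <- P; pm[i] <- P[i] - 1e-6
      fdg <- (aflm_total(pp, G, w, scheme = scheme)$total -
                aflm_total(pm, G, w, scheme = scheme)$total) / 2e-6
      expect_lt(abs(pn$grad[i] - fdg) / max(abs(fdg), 1e-8), 1e-3)
    }
  }
})
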