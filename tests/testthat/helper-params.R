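# Random valid kinetic parameter sets: rates satisfy the per-step bounds
# (total pre-mRNA loss, mRNA loss and protein loss each below 1) and the
# contraction factors a, b, c are kept pairwise separated so that the
# closed-form solution with three distinct geometric modes applies.
random_params <- function(min_gap = 0.02) {
  repeat {
    s1 <- runif(1, 0.05, 0.95)           # C + mu_PR
    uc <- runif(1, 0.1, 0.9)
    s2 <- runif(1, 0.05, 0.95)           # mu_R + P
    ur <- runif(1, 0.1, 0.9)
    mu_P <- runif(1, 0.05, 0.95)
    fac <- c(1 - s1, 1 - s2 * ur, 1 - mu_P)
    if (min(dist(fac)) < min_gap) next
    return(kinetic_params(R = runif(1, 0.1, 5), C = s1 * uc,
                          P = s2 * (1 - ur), mu_PR = s1 * (1 - uc),
                          mu_R = s2 * ur, mu_P = mu_P))
  }
}

random_box_state <- function(params) {
  w <- fixed_point_w(params)
  runif(3) * w
}

# Independent closed-form flow of the reduced (diagonal) system:
# each coordinate relaxes geometrically to v_k * i.
reduced_flow_oracle <- function(reduced, t, x, i) {
  l <- c(reduced$a, reduced$b, reduced$c)
  v <- v_vector(reduced)
  l^t * (x - v * i) + v * i
}

expect_close <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)) / (1 + max(abs(expected))), tol)
}
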