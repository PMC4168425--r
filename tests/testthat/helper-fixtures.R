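# shared fixtures: the two reference mixture curves and a quadratic
# evaluation shorthand used across test files

curve_te <- function() {
  interaction_curve(c(1.73, -2.13, 1.40),
                    components = c("toluene", "ethylbenzene"),
                    axis_component = "ethylbenzene", label = "T+E")
}

curve_eox <- function() {
  interaction_curve(c(1.88, -2.10, 1.30),
                    components = c("ethylbenzene", "o-xylene"),
                    axis_component = "ethylbenzene", label = "E+OX")
}

curve_bt <- function() {
  interaction_curve(c(1.93, -2.09, 1.39),
                    components = c("benzene", "toluene"),
                    axis_component = "benzene", label = "B+T")
}

quad <- function(co, x) co[1] * x^2 + co[2] * x + co[3]

# independent normal-equations quadratic fit (brute-force oracle)
quad_normal_equations <- function(x, y) {
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(a2 = beta[3], a1 = beta[2], a0 = beta[1])
}

random_mixture_df <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    odorant_a = "alpha", odorant_b = "beta",
    ln_oav_a = runif(n, 0.5, 5), ln_oav_b = runif(n, 0.5, 5),
    oi = runif(n, 1, 7)
  )
}
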