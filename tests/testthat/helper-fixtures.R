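# Shared fixtures and independent oracles for the test suite.

# O(n^2) all-pairs neighbor counting: the brute-force oracle the
# production grid-bucket index is checked against.
brute_count_within <- function(qx, qy, tx, ty, radius) {
  vapply(seq_along(qx), function(i) {
    sum((tx - qx[i])^2 + (ty - qy[i])^2 <= radius^2)
  }, integer(1))
}

# closed-form AUC of 1 - exp(-a s^2) on [0, r], a = p_y * pi,
# via the error function (erf(x) = 2 pnorm(x sqrt(2)) - 1)
gcross_auc_closed_form <- function(p_y, r = 50) {
  a <- p_y * pi
  if (a == 0) return(0)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  r - 0.5 * sqrt(pi / a) * erf(sqrt(a) * r)
}

# reference R implementation of one explicit FVM diffusion step
# (boundary neighbor replaced by the cell itself = zero-flux face)
diffuse_ref <- function(field, D, decay, sources, dt, h) {
  d <- dim(field)
  nb <- array(0, d)
  if (d[1] > 1) nb <- nb + field[c(2:d[1], d[1]), , , drop = FALSE] +
      field[c(1, 1:(d[1] - 1)), , , drop = FALSE]
  else nb <- nb + 2 * field
  if (d[2] > 1) nb <- nb + field[, c(2:d[2], d[2]), , drop = FALSE] +
      field[, c(1, 1:(d[2] - 1)), , drop = FALSE]
  else nb <- nb + 2 * field
  if (d[3] > 1) nb <- nb + field[, , c(2:d[3], d[3]), drop = FALSE] +
      field[, , c(1, 1:(d[3] - 1)), drop = FALSE]
  else nb <- nb + 2 * field
  field + dt * ((D / h^2) * (nb - 6 * field) - decay * field + sources)
}

# quick cell_map from coordinate vectors
make_map <- function(x, y, type, pad = 100) {
  cell_map(data.frame(id = seq_along(x), x = x, y = y, cell_type = type),
           bounds(range(x) + c(-pad, pad), range(y) + c(-pad, pad)))
}

expect_no_na <- function(x) expect_false(anyNA(x))
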