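# fixtures built in code: random physical polarization states and directions

random_stokes <- function(n = 1, dop_min = 0, dop_max = 1) {
  lapply(seq_len(n), function(i) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, dop_min, dop_max)
    s0 <- stats::runif(1, 0.2, 5)
    stokes(s0, s0 * v[1], s0 * v[2], s0 * v[3])
  })
}

random_unit_rows <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# a direction matrix plus valid perpendicular reference vectors
random_packet_frames <- function(n) {
  u <- random_unit_rows(n)
  helper <- random_unit_rows(n)
  bad <- abs(rowSums(u * helper)) > 0.99
  helper[bad, ] <- matrix(rep(c(0.3, 0.9, 0.1) / sqrt(0.91), sum(bad)),
                          ncol = 3, byrow = TRUE)
  r <- cbind(u[, 2] * helper[, 3] - u[, 3] * helper[, 2],
             u[, 3] * helper[, 1] - u[, 1] * helper[, 3],
             u[, 1] * helper[, 2] - u[, 2] * helper[, 1])
  r <- r / sqrt(rowSums(r^2))
  list(u = u, r = r)
}

dop_of <- function(s) sqrt(sum(as.numeric(s)[2:4]^2)) / as.numeric(s)[1]
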