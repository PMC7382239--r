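# Independent oracles, kept deliberately naive: plain loops and direct
# formula transcriptions against which the package implementations are
# checked.

# weighted nematic resultant by explicit accumulation loop
s2_oracle <- function(angle_deg, weight) {
  sc <- 0; ss <- 0; sw <- 0
  for (i in seq_along(angle_deg)) {
    sc <- sc + weight[i] * cos(2 * angle_deg[i] * pi / 180)
    ss <- ss + weight[i] * sin(2 * angle_deg[i] * pi / 180)
    sw <- sw + weight[i]
  }
  c2 <- sc / sw; s2 <- ss / sw
  theta <- atan2(s2, c2) / 2 * 180 / pi
  theta <- (theta + 90) %% 180 - 90
  if (theta == -90) theta <- 90
  list(S2 = sqrt(c2^2 + s2^2), theta = theta)
}

# ECDF-scan oracles: evaluate both empirical CDFs at every pooled data value
ks_oracle <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  d <- 0
  for (x in xs) {
    fa <- mean(a <= x); fb <- mean(b <= x)
    d <- max(d, abs(fa - fb))
  }
  d
}

kuiper_oracle <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  dplus <- 0; dminus <- 0
  for (x in xs) {
    diff <- mean(a <= x) - mean(b <= x)
    dplus <- max(dplus, diff)
    dminus <- max(dminus, -diff)
  }
  dplus + dminus
}

# total polymer length of a state, in um
total_length <- function(state) {
  sum(vapply(state$mts, function(m) {
    v <- m$vertices
    sum(sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
  }, numeric(1)))
}

element_lengths <- function(state) {
  unlist(lapply(state$mts, function(m) {
    v <- m$vertices
    sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  }))
}

all_vertices <- function(state) {
  do.call(rbind, lapply(state$mts, `[[`, "vertices"))
}

quiet_params <- function(...) {
  args <- list(p_spont_cat = 0, p_rescue = 0, p_cat = 0, p_cross = 0,
               k_nuc = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_params, args)
}

# shift nematic angles (degrees) around the 180-degree circle
wrap_shift <- function(theta, s) ((theta + s + 90) %% 180) - 90
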