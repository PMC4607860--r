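# Independent oracles used to freeze expected values.

# Exhaustive grid evaluation of the single-condition least-squares surface.
# For every (beta, delta) grid pair the SSE over the lambda grid is expanded
# algebraically (sum(obs^2) - 2*lambda*sum(obs*E) + lambda^2*sum(E^2), with
# E the unit-asymptote curve), which evaluates the identical SSE at every
# grid point without a triple loop.
grid_search_sse <- function(obs, tt, lambda_grid, beta_grid, delta_grid) {
  c0 <- sum(obs^2)
  best <- Inf
  best_par <- c(lambda = NA_real_, beta = NA_real_, delta = NA_real_)
  for (de in delta_grid) {
    dt <- tt - de
    E <- 1 - exp(-outer(beta_grid, pmax(dt, 0)))
    E[, dt <= 0] <- 0
    b1 <- as.vector(E %*% obs)        # per beta: sum(obs * E)
    a2 <- rowSums(E * E)              # per beta: sum(E^2)
    sse <- c0 - 2 * outer(b1, lambda_grid) +
      outer(a2, lambda_grid^2)
    i <- arrayInd(which.min(sse), dim(sse))
    if (sse[i] < best) {
      best <- sse[i]
      best_par <- c(lambda = lambda_grid[i[2]], beta = beta_grid[i[1]],
                    delta = de)
    }
  }
  list(sse = best, par = best_par)
}

# Plain per-point loop computing the least-squares objective of a model
# spec, resolving the group maps row by row.
sse_loop <- function(theta, spec, curves) {
  total <- 0
  for (i in seq_len(nrow(curves))) {
    ci <- match(curves$construction[i], spec$conditions)
    lam <- theta[spec$lambda_map[ci]]
    bet <- theta[spec$n_lambda + spec$beta_map[ci]]
    del <- theta[spec$n_lambda + spec$n_beta + spec$delta_map[ci]]
    t1 <- curves$lag_time[i]
    pred <- if (t1 > del) lam * (1 - exp(-bet * (t1 - del))) else 0
    total <- total + (curves$dprime[i] - pred)^2
  }
  total
}
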