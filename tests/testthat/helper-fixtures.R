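# Shared fixtures and independent oracles.

small_config <- function(...) {
  base <- list(n_agents = 3, width_cm = 100, height_cm = 100, n_patches = 2,
               patch_radius_cm = 8, patch_capacity = 3, max_steps = 200)
  args <- utils::modifyList(base, list(...))
  do.call(make_scenario, c(list("noncompetitive"), args))
}

# deep-copy a world (the RNG stream is an environment and must be cloned)
clone_world <- function(world) {
  w2 <- world
  s2 <- rng_stream(world$stream$seed, "clone")
  s2$seed <- world$stream$seed
  s2$name <- world$stream$name
  s2$state <- world$stream$state
  w2$stream <- s2
  w2
}

# brute-force point-dipole field (independent of the C++ kernel)
oracle_dipole_field <- function(points, sources, kappa = 1, r_min = 1) {
  out <- matrix(0, nrow(points), 2)
  for (i in seq_len(nrow(points))) {
    for (j in seq_len(nrow(sources))) {
      rv <- c(points[i, 1] - sources$x[j], points[i, 2] - sources$y[j])
      r <- sqrt(sum(rv^2))
      p <- c(sources$mx[j], sources$my[j])
      reff <- max(r, r_min)
      if (r > 0) {
        u <- rv / r
        out[i, ] <- out[i, ] + kappa * (3 * sum(p * u) * u - p) / reff^3
      } else {
        out[i, ] <- out[i, ] - kappa * p / reff^3
      }
    }
  }
  out
}

# O(T^2) brute-force GAE (double sum over future TD residuals)
oracle_gae <- function(rewards, values, dones, gamma, lambda) {
  T_ <- length(rewards)
  delta <- numeric(T_)
  for (t in seq_len(T_))
    delta[t] <- rewards[t] + gamma * values[t + 1] * (1 - dones[t]) - values[t]
  adv <- numeric(T_)
  for (t in seq_len(T_)) {
    acc <- 0; w <- 1
    for (k in t:T_) {
      acc <- acc + w * delta[k]
      if (dones[k] == 1) break
      w <- w * gamma * lambda
    }
    adv[t] <- acc
  }
  list(advantages = adv, returns = adv + values[seq_len(T_)])
}

# exhaustive pairwise motif enumeration (independent of mine_social_motifs)
oracle_motifs <- function(trace, dist_thresh = 15, min_len = 4,
                          motif_len = 4) {
  st <- trace$states
  ac <- trace$actions
  agents <- sort(unique(st$agent_id))
  T_ <- trace$n_steps
  pos <- lapply(agents, function(i) {
    s <- st[st$agent_id == i, ]; s <- s[order(s$step), ]
    cbind(s$x, s$y)
  })
  eod <- lapply(agents, function(i) {
    a <- ac[ac$agent_id == i, ]; a <- a[order(a$step), ]
    a$eod
  })
  counts <- list()
  for (ii in seq_along(agents)) for (jj in seq_along(agents)) {
    if (jj <= ii) next
    close_ <- sqrt(rowSums((pos[[ii]] - pos[[jj]])^2)) <= dist_thresh
    # maximal runs
    t <- 1
    while (t <= T_) {
      if (close_[t]) {
        e <- t
        while (e < T_ && close_[e + 1]) e <- e + 1
        if (e - t + 1 >= min_len && e - t + 1 >= motif_len) {
          for (t0 in t:(e - motif_len + 1)) {
            sa <- paste(eod[[ii]][t0:(t0 + motif_len - 1)], collapse = "")
            sb <- paste(eod[[jj]][t0:(t0 + motif_len - 1)], collapse = "")
            key <- if (sa <= sb) paste(sa, sb, sep = "|")
                   else paste(sb, sa, sep = "|")
            counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          }
        }
        t <- e + 1
      } else t <- t + 1
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Theil formula (loop form)
oracle_theil <- function(x) {
  mu <- sum(x) / length(x)
  tot <- 0
  for (xi in x) if (xi > 0) tot <- tot + (xi / mu) * log(xi / mu)
  tot / length(x)
}
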