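# Independent reference implementations used as oracles.

# Reference dive-bout segmentation: a direct recursive transcription of the
# rules.  Takes depths and inter-dive surface gaps (minutes) for one seal and
# returns the per-dive class labels.
ref_segment_classes <- function(depths, gaps_min, tol = 0.15, min_ref = 2,
                                rep_min = 5, rest_gap = 10) {
  n <- length(depths)
  if (!n) return(character(0))
  seg_id <- cumsum(c(1, as.numeric(gaps_min > rest_gap)))
  cls <- rep(NA_character_, n)
  for (seg in split(seq_len(n), seg_id)) {
    d <- depths[seg]
    runs <- ref_runs(d, tol, min_ref)
    for (run in runs) {
      n_reg <- sum(run$reg)
      cls[seg[run$members]] <- if (n_reg >= rep_min) "repetitive" else "mixed"
    }
  }
  cls
}

# Recursively grow runs from the left: a dive is consistent when within `tol`
# of either of the two immediately preceding dives of the run (reference depth
# at least `min_ref`); one interposed inconsistent dive is tolerated, a second
# consecutive one closes the run before the first and restarts from it, and a
# trailing tolerated deviant is expelled from the run.
ref_runs <- function(d, tol, min_ref) {
  n <- length(d)
  if (!n) return(list())
  members <- 1L
  reg <- TRUE
  pending <- NA_integer_
  k <- 2L
  while (k <= n) {
    m <- length(members)
    refs <- d[members[max(1L, m - 1L):m]]
    ok <- any(refs >= min_ref & abs(d[k] - refs) / refs <= tol)
    if (ok) {
      members <- c(members, k); reg <- c(reg, TRUE); pending <- NA_integer_
    } else if (is.na(pending)) {
      members <- c(members, k); reg <- c(reg, FALSE); pending <- k
    } else {
      keep <- members != pending
      run <- list(members = members[keep], reg = reg[keep])
      rest <- ref_runs(d[pending:n], tol, min_ref)
      rest <- lapply(rest, function(r) {
        r$members <- r$members + pending - 1L
        r
      })
      return(c(list(run), rest))
    }
    k <- k + 1L
  }
  if (!is.na(pending)) {
    keep <- members != pending
    return(list(list(members = members[keep], reg = reg[keep]),
                list(members = pending, reg = TRUE)))
  }
  list(list(members = members, reg = reg))
}

# Brute-force signed ice-edge distance: igraph connected components over the
# 8-neighbour adjacency of qualifying cells, then a full scan over every
# periphery cell.
ref_ice_edge <- function(ice, lon, lat, conc_min = 15, min_pixels = 10) {
  ny <- nrow(ice$values); nx <- ncol(ice$values)
  qual <- !is.na(ice$values) & ice$values >= conc_min & !ice$land
  idx <- which(qual)
  if (!length(idx)) return(NA_real_)
  id_of <- match(seq_len(ny * nx), idx)
  from <- integer(0); to <- integer(0)
  for (cell in idx) {
    i <- (cell - 1L) %% ny + 1L
    j <- (cell - 1L) %/% ny + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
      nb <- (jj - 1L) * ny + ii
      if (nb > cell && qual[nb]) {
        from <- c(from, id_of[cell]); to <- c(to, id_of[nb])
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  big <- as.integer(names(which(table(memb) >= min_pixels)))
  if (!length(big)) return(NA_real_)
  member_cells <- idx[memb %in% big]
  member_mask <- rep(FALSE, ny * nx)
  member_mask[member_cells] <- TRUE
  open_sea <- !qual & !ice$land
  peri <- c()
  for (cell in member_cells) {
    i <- (cell - 1L) %% ny + 1L
    j <- (cell - 1L) %/% ny + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx &&
          open_sea[(jj - 1L) * ny + ii]) {
        peri <- c(peri, cell)
      }
    }
  }
  peri <- unique(peri)
  if (!length(peri)) return(NA_real_)
  pi_ <- (peri - 1L) %% ny + 1L
  pj <- (peri - 1L) %/% ny + 1L
  xy <- cbind(ice$x0 + (pj - 1) * ice$dx, ice$y0 + (pi_ - 1) * ice$dy)
  ll <- laea_inverse(xy[, 1], xy[, 2], ice$center)
  d <- min(gc_dist_km(lon, lat, ll$lon, ll$lat))
  pxy <- laea_project(lon, lat, ice$center)
  i0 <- as.integer(round((pxy$y - ice$y0) / ice$dy)) + 1L
  j0 <- as.integer(round((pxy$x - ice$x0) / ice$dx)) + 1L
  inside <- i0 >= 1 && i0 <= ny && j0 >= 1 && j0 <= nx &&
    member_mask[(j0 - 1L) * ny + i0]
  if (inside) -d else d
}

# Direct generalised-least-squares posterior means for a 3-observation toy
# problem of the integrated-OU model, replicating the filter's diffuse prior
# at the first fix.
ref_gls_smoother <- function(t_hr, y, err_var, beta, sigma) {
  Tm <- function(dt) matrix(c(1, 0, (1 - exp(-beta * dt)) / beta,
                              exp(-beta * dt)), 2, 2)
  Qm <- function(dt) {
    phi <- exp(-beta * dt); s2 <- sigma^2
    matrix(c(s2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta)),
             s2 * (1 - phi)^2 / (2 * beta^2),
             s2 * (1 - phi)^2 / (2 * beta^2),
             s2 * (1 - phi^2) / (2 * beta)), 2, 2)
  }
  P0 <- diag(c(1e6, sigma^2 / (2 * beta)))
  T21 <- Tm(t_hr[2] - t_hr[1]); T32 <- Tm(t_hr[3] - t_hr[2])
  Q21 <- Qm(t_hr[2] - t_hr[1]); Q32 <- Qm(t_hr[3] - t_hr[2])
  mu1 <- c(y[1], 0)
  mu <- c(mu1, T21 %*% mu1, T32 %*% T21 %*% mu1)
  S11 <- P0
  S22 <- T21 %*% P0 %*% t(T21) + Q21
  S33 <- T32 %*% S22 %*% t(T32) + Q32
  S12 <- P0 %*% t(T21)
  S13 <- S12 %*% t(T32)
  S23 <- S22 %*% t(T32)
  Sig <- rbind(cbind(S11, S12, S13),
               cbind(t(S12), S22, S23),
               cbind(t(S13), t(S23), S33))
  H <- matrix(0, 3, 6)
  H[1, 1] <- H[2, 3] <- H[3, 5] <- 1
  R <- diag(pmax(err_var, 1e-10))
  K <- Sig %*% t(H) %*% solve(H %*% Sig %*% t(H) + R)
  post <- mu + K %*% (y - H %*% mu)
  post[c(1, 3, 5)]  # position means at the three times
}
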