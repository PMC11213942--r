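# Independent brute-force oracles, written loop-wise on purpose so they do
# not share code paths with the package implementation.

# mean distance of each point to its k nearest neighbours, O(n^2)
bf_knn_mean_dist <- function(x, y, z, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2 + (z - z[i])^2)
    out[i] <- mean(sort(d[-i])[seq_len(k)])
  }
  out
}

# per-cell maximum height oracle for rasterization (labels as in the cloud)
bf_cell_max <- function(cloud, res, extent) {
  x0 <- extent[1]; y0 <- extent[2]
  nc <- max(1, ceiling((extent[3] - x0) / res))
  nr <- max(1, ceiling((extent[4] - y0) / res))
  v <- matrix(NA_real_, nr, nc)
  lab <- if (is.null(cloud$label)) rep("ABOVE_GROUND", n_points(cloud)) else cloud$label
  for (p in seq_len(n_points(cloud))) {
    j <- min(nc - 1, floor((cloud$x[p] - x0) / res))
    i <- min(nr - 1, floor((cloud$y[p] - y0) / res))
    if (j < 0 || i < 0) next
    cur <- v[i + 1, j + 1]
    val <- if (lab[p] == "GROUND") 0 else cloud$z[p]
    if (lab[p] == "UNCLASSIFIED" || lab[p] == "NOISE") next
    v[i + 1, j + 1] <- if (is.na(cur)) val else max(cur, val)
  }
  v
}

# windowed local-maxima scan oracle for the variable window filter
bf_crown_tops <- function(values, res, rmin, slope, min_height) {
  nr <- nrow(values); nc <- ncol(values)
  tops <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- values[i, j]
    if (is.na(v) || v < min_height) next
    r <- max(rmin, slope * v)
    rc <- floor(r / res)
    is_top <- TRUE
    for (di in -rc:rc) for (dj in -rc:rc) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if ((di^2 + dj^2) * res^2 > r^2) next
      u <- values[ii, jj]
      if (is.na(u)) next
      if (u > v || (u == v && (ii < i || (ii == i && jj < j)))) {
        is_top <- FALSE
        break
      }
    }
    if (is_top) tops <- rbind(tops, c(i, j))
  }
  tops
}

# element-wise scalar loop oracle for one LSTM step (no matrix ops)
bf_lstm_step <- function(x, h_prev, c_prev, p) {
  H <- length(h_prev)
  D <- length(x)
  sig <- function(z) 1 / (1 + exp(-z))
  pre <- function(Tm, Wm, bv, j) {
    s <- bv[j]
    for (d in seq_len(D)) s <- s + x[d] * Tm[d, j]
    for (m in seq_len(H)) s <- s + h_prev[m] * Wm[m, j]
    s
  }
  h <- c_new <- numeric(H)
  for (j in seq_len(H)) {
    i_g <- sig(pre(p$T_y, p$W_y, p$b_y, j))
    f_g <- sig(pre(p$T_f, p$W_f, p$b_f, j))
    o_g <- sig(pre(p$T_p, p$W_p, p$b_p, j))
    g_c <- tanh(pre(p$T_g, p$W_g, p$b_g, j))
    c_new[j] <- f_g * c_prev[j] + i_g * g_c
    h[j] <- o_g * tanh(c_new[j])
  }
  list(h = h, c = c_new)
}

# element-wise scalar loop oracle for one GRU step
bf_gru_step <- function(x, d_prev, p) {
  H <- length(d_prev)
  D <- length(x)
  sig <- function(z) 1 / (1 + exp(-z))
  d_new <- numeric(H)
  for (j in seq_len(H)) {
    pre_u <- p$b_u[j]; pre_s <- p$b_s[j]
    for (d in seq_len(D)) {
      pre_u <- pre_u + x[d] * p$T_u[d, j]
      pre_s <- pre_s + x[d] * p$T_s[d, j]
    }
    for (m in seq_len(H)) {
      pre_u <- pre_u + d_prev[m] * p$W_u[m, j]
      pre_s <- pre_s + d_prev[m] * p$W_s[m, j]
    }
    u <- sig(pre_u)
    s_all <- numeric(H)
    for (m in seq_len(H)) {
      pre_sm <- p$b_s[m]
      for (d in seq_len(D)) pre_sm <- pre_sm + x[d] * p$T_s[d, m]
      for (q in seq_len(H)) pre_sm <- pre_sm + d_prev[q] * p$W_s[q, m]
      s_all[m] <- sig(pre_sm)
    }
    pre_d <- p$b_d[j]
    for (d in seq_len(D)) pre_d <- pre_d + x[d] * p$T_d[d, j]
    for (m in seq_len(H)) pre_d <- pre_d + s_all[m] * d_prev[m] * p$W_d[m, j]
    dt <- tanh(pre_d)
    d_new[j] <- (1 - u) * d_prev[j] + u * dt
  }
  d_new
}

# random small cell parameter sets
rand_lstm_params <- function(D, H) {
  p <- list()
  for (g in c("y", "f", "p", "g")) {
    p[[paste0("T_", g)]] <- matrix(stats::rnorm(D * H, sd = 0.7), D, H)
    p[[paste0("W_", g)]] <- matrix(stats::rnorm(H * H, sd = 0.7), H, H)
    p[[paste0("b_", g)]] <- stats::rnorm(H, sd = 0.5)
  }
  p
}

rand_gru_params <- function(D, H) {
  p <- list()
  for (g in c("u", "s", "d")) {
    p[[paste0("T_", g)]] <- matrix(stats::rnorm(D * H, sd = 0.7), D, H)
    p[[paste0("W_", g)]] <- matrix(stats::rnorm(H * H, sd = 0.7), H, H)
    p[[paste0("b_", g)]] <- stats::rnorm(H, sd = 0.5)
  }
  p
}

# set every trainable parameter of a hybrid model to zero
zero_model <- function(model) {
  zap <- function(x) if (is.list(x)) lapply(x, zap) else x * 0
  model$params <- zap(model$params)
  model
}

# scalar 1-unit parameter lists with all weights w and zero biases
unit_lstm_params <- function(w = 1, D = 1) {
  Tm <- matrix(w, D, 1)
  list(T_y = Tm, T_f = Tm, T_p = Tm, T_g = Tm,
       W_y = matrix(w), W_f = matrix(w), W_p = matrix(w), W_g = matrix(w),
       b_y = 0, b_f = 0, b_p = 0, b_g = 0)
}

unit_gru_params <- function(w = 1, D = 1) {
  Tm <- matrix(w, D, 1)
  list(T_u = Tm, T_s = Tm, T_d = Tm,
       W_u = matrix(w), W_s = matrix(w), W_d = matrix(w),
       b_u = 0, b_s = 0, b_d = 0)
}
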