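# Hybrid network internals: initialization, batched forward pass,
# backpropagation through time and the adaptive-moment optimizer.
# All of this operates on scaled inputs/targets in [0, 1].

.init_mat <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)

.init_lstm_params <- function(input_dim, hidden) {
  a_in <- sqrt(6 / (input_dim + hidden))
  a_rec <- sqrt(6 / (2 * hidden))
  p <- list()
  for (g in c("y", "f", "p", "g")) {
    p[[paste0("T_", g)]] <- .init_mat(input_dim, hidden, a_in)
    p[[paste0("W_", g)]] <- .init_mat(hidden, hidden, a_rec)
    p[[paste0("b_", g)]] <- rep(0, hidden)
  }
  p$b_f <- rep(1, hidden)  # open forget gate at init: standard carry bias
  p
}

.init_gru_params <- function(input_dim, hidden) {
  a_in <- sqrt(6 / (input_dim + hidden))
  a_rec <- sqrt(6 / (2 * hidden))
  p <- list()
  for (g in c("u", "s", "d")) {
    p[[paste0("T_", g)]] <- .init_mat(input_dim, hidden, a_in)
    p[[paste0("W_", g)]] <- .init_mat(hidden, hidden, a_rec)
    p[[paste0("b_", g)]] <- rep(0, hidden)
  }
  p
}

#' Initialize a hybrid stacked LSTM-GRU model
#'
#' Weights are drawn from a scaled-uniform (Glorot) scheme,
#' `U(-sqrt(6/(fan_in+fan_out)), +...)`; biases start at zero except the
#' LSTM forget bias (1). The same seed yields bit-identical parameters.
#' Input/output min-max scalers start as identities and are fitted by
#' [train_model()].
#'
#' @param input_dim Features per time step (2: height, crown area).
#' @param output_dim Predicted parameters (2).
#' @param hidden Units per recurrent layer (default 50).
#' @param lstm_layers,gru_layers Stack depths (default 2 each).
#' @param fcn_units Units of each branch's fully connected head.
#' @param branches `"both"`, `"lstm"` or `"gru"` (single-branch ablations).
#' @param seed Optional RNG seed.
#' @return An object of class `hybrid_model`.
#' @export
init_model <- function(input_dim = 2, output_dim = 2, hidden = 50,
                       lstm_layers = 2, gru_layers = 2, fcn_units = 50,
                       branches = c("both", "lstm", "gru"), seed = NULL) {
  branches <- match.arg(branches)
  stopifnot(input_dim >= 1, output_dim >= 1, hidden >= 1,
            lstm_layers >= 1, gru_layers >= 1, fcn_units >= 1)
  if (!is.null(seed)) set.seed(seed)
  a_f <- sqrt(6 / (hidden + fcn_units))
  params <- list()
  if (branches %in% c("both", "lstm")) {
    params$lstm <- lapply(seq_len(lstm_layers), function(l)
      .init_lstm_params(if (l == 1) input_dim else hidden, hidden))
    params$fcn_l <- list(W = .init_mat(hidden, fcn_units, a_f), b = rep(0, fcn_units))
  }
  if (branches %in% c("both", "gru")) {
    params$gru <- lapply(seq_len(gru_layers), function(l)
      .init_gru_params(if (l == 1) input_dim else hidden, hidden))
    params$fcn_g <- list(W = .init_mat(hidden, fcn_units, a_f), b = rep(0, fcn_units))
  }
  concat_dim <- fcn_units * (if (branches == "both") 2 else 1)
  params$final <- list(W = .init_mat(concat_dim, output_dim,
                                     sqrt(6 / (concat_dim + output_dim))),
                       b = rep(0, output_dim))
  structure(list(params = params, branches = branches, activation = "relu",
                 input_dim = input_dim, output_dim = output_dim,
                 hidden = hidden, fcn_units = fcn_units,
                 lstm_layers = if (is.null(params$lstm)) 0L else lstm_layers,
                 gru_layers = if (is.null(params$gru)) 0L else gru_layers,
                 input_stages = NULL,
                 scaler_x = list(min = rep(0, input_dim), max = rep(1, input_dim)),
                 scaler_y = list(min = rep(0, output_dim), max = rep(1, output_dim))),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("hybrid_model: branches = %s, hidden = %d (L = %d LSTM, G = %d GRU), fcn = %d\n",
              x$branches, x$hidden, x$lstm_layers, x$gru_layers, x$fcn_units))
  invisible(x)
}

.relu <- function(z) pmax(z, 0)

# forward pass over a batch; Xlist = list over time of B x D scaled inputs
.forward_hybrid_batch <- function(model, Xlist, cache = FALSE) {
  p <- model$params
  B <- nrow(Xlist[[1]])
  parts <- list(); cc <- list()
  if (!is.null(p$lstm)) {
    fw <- .stack_forward_batch(Xlist, p$lstm, "lstm", cache = cache)
    zl <- sweep(fw$h_last %*% p$fcn_l$W, 2, p$fcn_l$b, "+")
    yl <- .relu(zl)
    parts$lstm <- yl
    if (cache) cc$lstm <- list(stack = fw, h_last = fw$h_last, y = yl)
  }
  if (!is.null(p$gru)) {
    fw <- .stack_forward_batch(Xlist, p$gru, "gru", cache = cache)
    zg <- sweep(fw$h_last %*% p$fcn_g$W, 2, p$fcn_g$b, "+")
    yg <- .relu(zg)
    parts$gru <- yg
    if (cache) cc$gru <- list(stack = fw, h_last = fw$h_last, y = yg)
  }
  ycat <- do.call(cbind, unname(parts))
  yhat <- sweep(ycat %*% p$final$W, 2, p$final$b, "+")
  if (cache) list(yhat = yhat, ycat = ycat, cc = cc) else list(yhat = yhat)
}

# BPTT through one stacked branch. inj: list over time of B x H gradients
# injected into the TOP layer's hidden states. Returns per-layer grads.
.stack_backward_batch <- function(stack, caches, kind, inj) {
  Tn <- length(inj)
  grads <- vector("list", length(stack))
  for (l in rev(seq_along(stack))) {
    p <- stack[[l]]
    g <- lapply(p, function(m) m * 0)
    ch <- caches[[l]]
    B <- nrow(inj[[1]])
    Hd <- ncol(p$W_u %||% p$W_y)
    dh_rec <- matrix(0, B, Hd)
    dc_rec <- matrix(0, B, Hd)
    dX <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      ct <- ch[[t]]
      dh <- inj[[t]] + dh_rec
      if (kind == "lstm") {
        do_ <- dh * ct$tanhc
        dc <- dc_rec + dh * ct$o * (1 - ct$tanhc^2)
        df <- dc * ct$c_prev
        di <- dc * ct$g
        dg <- dc * ct$i
        dc_rec <- dc * ct$f
        dai <- di * ct$i * (1 - ct$i)
        daf <- df * ct$f * (1 - ct$f)
        dao <- do_ * ct$o * (1 - ct$o)
        dag <- dg * (1 - ct$g^2)
        g$T_y <- g$T_y + crossprod(ct$x, dai)
        g$T_f <- g$T_f + crossprod(ct$x, daf)
        g$T_p <- g$T_p + crossprod(ct$x, dao)
        g$T_g <- g$T_g + crossprod(ct$x, dag)
        g$W_y <- g$W_y + crossprod(ct$h_prev, dai)
        g$W_f <- g$W_f + crossprod(ct$h_prev, daf)
        g$W_p <- g$W_p + crossprod(ct$h_prev, dao)
        g$W_g <- g$W_g + crossprod(ct$h_prev, dag)
        g$b_y <- g$b_y + colSums(dai)
        g$b_f <- g$b_f + colSums(daf)
        g$b_p <- g$b_p + colSums(dao)
        g$b_g <- g$b_g + colSums(dag)
        dX[[t]] <- dai %*% t(p$T_y) + daf %*% t(p$T_f) +
                   dao %*% t(p$T_p) + dag %*% t(p$T_g)
        dh_rec <- dai %*% t(p$W_y) + daf %*% t(p$W_f) +
                  dao %*% t(p$W_p) + dag %*% t(p$W_g)
      } else {
        du <- dh * (ct$dt - ct$d_prev)
        ddt <- dh * ct$u
        dd_prev <- dh * (1 - ct$u)
        dad <- ddt * (1 - ct$dt^2)
        dsd <- dad %*% t(p$W_d)          # grad w.r.t. (s * d_prev)
        ds <- dsd * ct$d_prev
        dd_prev <- dd_prev + dsd * ct$s
        dau <- du * ct$u * (1 - ct$u)
        das <- ds * ct$s * (1 - ct$s)
        g$T_u <- g$T_u + crossprod(ct$x, dau)
        g$T_s <- g$T_s + crossprod(ct$x, das)
        g$T_d <- g$T_d + crossprod(ct$x, dad)
        g$W_u <- g$W_u + crossprod(ct$d_prev, dau)
        g$W_s <- g$W_s + crossprod(ct$d_prev, das)
        g$W_d <- g$W_d + crossprod(ct$s * ct$d_prev, dad)
        g$b_u <- g$b_u + colSums(dau)
        g$b_s <- g$b_s + colSums(das)
        g$b_d <- g$b_d + colSums(dad)
        dX[[t]] <- dau %*% t(p$T_u) + das %*% t(p$T_s) + dad %*% t(p$T_d)
        dh_rec <- dau %*% t(p$W_u) + das %*% t(p$W_s) + dd_prev
      }
    }
    grads[[l]] <- g
    inj <- dX  # gradients flowing into the layer below's hidden sequence
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full backward pass; dy: B x output_dim gradient of the loss w.r.t. yhat
.backward_hybrid_batch <- function(model, fw, dy, Tn) {
  p <- model$params
  g <- list()
  g$final <- list(W = crossprod(fw$ycat, dy), b = colSums(dy))
  dycat <- dy %*% t(p$final$W)
  off <- 0
  B <- nrow(dy)
  zero_inj <- function() {
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) out[[t]] <- matrix(0, B, model$hidden)
    out
  }
  for (br in c("lstm", "gru")) {
    if (is.null(fw$cc[[br]])) next
    Fd <- model$fcn_units
    dyb <- dycat[, off + seq_len(Fd), drop = FALSE]
    off <- off + Fd
    da <- dyb * (fw$cc[[br]]$y > 0)
    fcn_name <- if (br == "lstm") "fcn_l" else "fcn_g"
    g[[fcn_name]] <- list(W = crossprod(fw$cc[[br]]$h_last, da), b = colSums(da))
    dHL <- da %*% t(p[[fcn_name]]$W)
    inj <- zero_inj()
    inj[[Tn]] <- dHL
    g[[br]] <- .stack_backward_batch(p[[br]], fw$cc[[br]]$stack$caches, br, inj)
  }
  g
}

# recursive adaptive-moment update over the nested parameter list
.adam_step <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    for (nm in names(p)) {
      r <- .adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, b1, b2, eps, t)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

.zeros_like <- function(p) if (is.list(p)) lapply(p, .zeros_like) else p * 0

.mse <- function(a, b) mean((a - b)^2)

# core training loop on scaled arrays. Xtr: list over time of n x D.
.train_network <- function(model, Xtr, Ytr, Xval = NULL, Yval = NULL,
                           epochs = 400, batch_size = 50, lr = 1e-3) {
  n <- nrow(Ytr)
  mm <- .zeros_like(model$params)
  vv <- .zeros_like(model$params)
  tstep <- 0
  hist_tr <- hist_val <- rep(NA_real_, epochs)
  best_val <- Inf
  best_params <- model$params
  Tn <- length(Xtr)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    losses <- c(); sizes <- c()
    for (b0 in seq(1, n, by = batch_size)) {
      take <- perm[b0:min(b0 + batch_size - 1, n)]
      Xb <- lapply(Xtr, function(m) m[take, , drop = FALSE])
      Yb <- Ytr[take, , drop = FALSE]
      fw <- .forward_hybrid_batch(model, Xb, cache = TRUE)
      loss <- .mse(fw$yhat, Yb)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; lower the learning rate")
      losses <- c(losses, loss); sizes <- c(sizes, length(take))
      dy <- 2 * (fw$yhat - Yb) / length(Yb)
      g <- .backward_hybrid_batch(model, fw, dy, Tn)
      tstep <- tstep + 1
      upd <- .adam_step(model$params, g, mm, vv, lr, 0.9, 0.999, 1e-8, tstep)
      model$params <- upd$p; mm <- upd$m; vv <- upd$v
    }
    hist_tr[ep] <- sum(losses * sizes) / sum(sizes)
    if (!is.null(Xval) && nrow(Yval) > 0) {
      fv <- .forward_hybrid_batch(model, Xval)
      hist_val[ep] <- .mse(fv$yhat, Yval)
      if (hist_val[ep] < best_val) {
        best_val <- hist_val[ep]
        best_params <- model$params
      }
    }
  }
  if (is.finite(best_val)) model$params <- best_params
  list(model = model,
       history = data.frame(epoch = seq_len(epochs), train_loss = hist_tr,
                            val_loss = hist_val))
}

# ---- scaling helpers ----

.fit_scaler <- function(m) {
  mn <- apply(m, 2, min); mx <- apply(m, 2, max)
  same <- mx - mn < 1e-12
  mx[same] <- mn[same] + 1
  list(min = mn, max = mx)
}

.scale_mat <- function(m, s) sweep(sweep(m, 2, s$min, "-"), 2, s$max - s$min, "/")
.unscale_mat <- function(m, s) sweep(sweep(m, 2, s$max - s$min, "*"), 2, s$min, "+")

#' Forward pass of the hybrid model on one scaled sequence
#'
#' The stacked LSTM and GRU branches each summarize the sequence into their
#' top layer's final hidden state, pass it through a ReLU fully connected
#' head, the head outputs are concatenated and a final linear layer
#' predicts the targets, which are inverse-scaled to physical units.
#'
#' @param seq A `T x input_dim` matrix already scaled by the model's input
#'   scaler (all values finite).
#' @param model A `hybrid_model`.
#' @return Numeric vector of predictions in physical units.
#' @export
hybrid_forward <- function(seq, model) {
  stopifnot(inherits(model, "hybrid_model"))
  if (!is.matrix(seq)) seq <- matrix(seq, ncol = model$input_dim)
  if (anyNA(seq) || any(!is.finite(seq)))
    stop("sequence contains non-finite values; scale inputs first")
  Xlist <- lapply(seq_len(nrow(seq)), function(t) seq[t, , drop = FALSE])
  fw <- .forward_hybrid_batch(model, Xlist)
  drop(.unscale_mat(fw$yhat, model$scaler_y))
}
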