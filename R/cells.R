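# LSTM and GRU cell steps. The canonical gated cells are used: per-gate
# input weights T (input_dim x hidden), recurrent weights W (hidden x
# hidden) and additive biases b. Inputs are row vectors (or row-stacked
# batches); all gate activations are logistic, candidates are tanh.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

.check_lstm_params <- function(p) {
  need <- c("T_y", "T_f", "T_p", "T_g", "W_y", "W_f", "W_p", "W_g",
            "b_y", "b_f", "b_p", "b_g")
  if (!all(need %in% names(p))) stop("malformed LSTM parameter list")
  invisible(p)
}

.check_gru_params <- function(p) {
  need <- c("T_u", "T_s", "T_d", "W_u", "W_s", "W_d", "b_u", "b_s", "b_d")
  if (!all(need %in% names(p))) stop("malformed GRU parameter list")
  invisible(p)
}

# batched LSTM step; X: B x D, H/C: B x hidden
.lstm_step_batch <- function(X, H, C, p, cache = FALSE) {
  i <- .sigmoid(sweep(X %*% p$T_y + H %*% p$W_y, 2, p$b_y, "+"))   # input gate
  f <- .sigmoid(sweep(X %*% p$T_f + H %*% p$W_f, 2, p$b_f, "+"))   # forget gate
  o <- .sigmoid(sweep(X %*% p$T_p + H %*% p$W_p, 2, p$b_p, "+"))   # output gate
  g <- tanh(sweep(X %*% p$T_g + H %*% p$W_g, 2, p$b_g, "+"))       # candidate
  c_new <- f * C + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  out <- list(h = h_new, c = c_new)
  if (cache)
    out$cache <- list(x = X, h_prev = H, c_prev = C, i = i, f = f, o = o,
                      g = g, c = c_new, tanhc = tc)
  out
}

# batched GRU step; X: B x D, D_prev: B x hidden
.gru_step_batch <- function(X, D_prev, p, cache = FALSE) {
  u <- .sigmoid(sweep(X %*% p$T_u + D_prev %*% p$W_u, 2, p$b_u, "+"))  # update
  s <- .sigmoid(sweep(X %*% p$T_s + D_prev %*% p$W_s, 2, p$b_s, "+"))  # reset
  dt <- tanh(sweep(X %*% p$T_d + (s * D_prev) %*% p$W_d, 2, p$b_d, "+"))
  d_new <- (1 - u) * D_prev + u * dt
  out <- list(d = d_new)
  if (cache)
    out$cache <- list(x = X, d_prev = D_prev, u = u, s = s, dt = dt)
  out
}

#' One LSTM cell step
#'
#' Computes the canonical gated update: input gate
#' `y = sigma(x T^y + h W^y + b^y)`, forget gate `f`, output gate `p`,
#' candidate `C~ = tanh(x T^g + h W^g + b^g)`, cell state
#' `c = f * c_prev + y * C~` and hidden state `h = p * tanh(c)`.
#'
#' @param x Input vector (length `input_dim`) or batch matrix.
#' @param h_prev,c_prev Previous hidden and cell state (length `hidden`).
#' @param params LSTM parameter list (`T_*`, `W_*`, `b_*` per gate).
#' @return A list with `h` and `c`.
#' @export
lstm_step <- function(x, h_prev, c_prev, params) {
  .check_lstm_params(params)
  vec <- !is.matrix(x)
  X <- .as_row(x); H <- .as_row(h_prev); C <- .as_row(c_prev)
  if (ncol(X) != nrow(params$T_y) || ncol(H) != nrow(params$W_y))
    stop("shape mismatch between inputs and LSTM parameters")
  st <- .lstm_step_batch(X, H, C, params)
  if (vec) list(h = drop(st$h), c = drop(st$c)) else list(h = st$h, c = st$c)
}

#' One GRU cell step
#'
#' Update gate `u = sigma(x T^u + d W^u + b^u)`, reset gate `s`, candidate
#' `d~ = tanh(x T^d + (s * d) W^d + b^d)`, new state
#' `d = (1 - u) * d_prev + u * d~`.
#'
#' @param x Input vector or batch matrix.
#' @param d_prev Previous hidden state.
#' @param params GRU parameter list (`T_*`, `W_*`, `b_*` per gate).
#' @return The new hidden state `d`.
#' @export
gru_step <- function(x, d_prev, params) {
  .check_gru_params(params)
  vec <- !is.matrix(x)
  X <- .as_row(x); D_prev <- .as_row(d_prev)
  if (ncol(X) != nrow(params$T_u) || ncol(D_prev) != nrow(params$W_u))
    stop("shape mismatch between inputs and GRU parameters")
  st <- .gru_step_batch(X, D_prev, params)
  if (vec) drop(st$d) else st$d
}

# run a whole stack over a batched sequence
# Xlist: list over time of B x D matrices. Returns per-layer hidden
# sequences and (if cache) everything backprop needs.
.stack_forward_batch <- function(Xlist, stack, kind, cache = FALSE) {
  B <- nrow(Xlist[[1]])
  Tn <- length(Xlist)
  layer_seqs <- vector("list", length(stack))
  caches <- if (cache) vector("list", length(stack))
  inp <- Xlist
  for (l in seq_along(stack)) {
    p <- stack[[l]]
    Hd <- length(p[[grep("^b_", names(p))[1]]])
    H <- matrix(0, B, Hd)
    C <- matrix(0, B, Hd)
    hs <- vector("list", Tn)
    cc <- if (cache) vector("list", Tn)
    for (t in seq_len(Tn)) {
      if (kind == "lstm") {
        st <- .lstm_step_batch(inp[[t]], H, C, p, cache = cache)
        H <- st$h; C <- st$c
      } else {
        st <- .gru_step_batch(inp[[t]], H, p, cache = cache)
        H <- st$d
      }
      hs[[t]] <- H
      if (cache) cc[[t]] <- st$cache
    }
    layer_seqs[[l]] <- hs
    if (cache) caches[[l]] <- cc
    inp <- hs
  }
  list(layers = layer_seqs, h_last = layer_seqs[[length(stack)]][[Tn]],
       caches = caches)
}

#' Run a stacked recurrent branch over a sequence
#'
#' Layer 1 consumes the input sequence; each further layer consumes the
#' full hidden sequence of the layer below. Initial states are zero.
#'
#' @param seq A `T x input_dim` matrix (rows are time steps).
#' @param stack A list of per-layer parameter lists.
#' @param cell_kind `"lstm"` or `"gru"`.
#' @return A list with `final` (top layer's hidden state at the last step)
#'   and `layers` (per-layer `T x hidden` hidden-state matrices).
#' @export
stacked_forward <- function(seq, stack, cell_kind = c("lstm", "gru")) {
  cell_kind <- match.arg(cell_kind)
  if (!is.matrix(seq)) seq <- matrix(seq, ncol = 1)
  if (nrow(seq) < 1) stop("sequence must have at least one time step")
  if (cell_kind == "lstm") lapply(stack, .check_lstm_params)
  else lapply(stack, .check_gru_params)
  Xlist <- lapply(seq_len(nrow(seq)), function(t) seq[t, , drop = FALSE])
  fw <- .stack_forward_batch(Xlist, stack, cell_kind)
  list(final = drop(fw$h_last),
       layers = lapply(fw$layers, function(hs) do.call(rbind, hs)))
}
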