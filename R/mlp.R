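#' Train the learned summary regressor (ABC-DL-lite)
#'
#' A small feed-forward network (two tanh hidden layers, linear output)
#' mapping summary statistics to demographic parameters, trained by
#' full-batch gradient descent with backtracking line search on the mean
#' squared error of standardized inputs and outputs. The backtracking step
#' makes the recorded loss trace non-increasing by construction. Constant
#' (zero-variance) summary columns are dropped with a warning. The fitted
#' mapping is used to project observed and simulated summaries into
#' parameter space before ABC rejection, playing the role of the learned
#' (DNN) summaries of ABC-DL at desk scale.
#'
#' @param x n x p matrix of summary vectors (n >= 200)
#' @param y n x q matrix of true parameters
#' @param hidden sizes of the two hidden layers
#' @param epochs training epochs
#' @param lr initial learning rate
#' @param seed seed for the weight initialization
#' @return object of class `pp_regressor` with `$loss_trace`
#' @export
train_summary_regressor <- function(x, y, hidden = c(32, 32), epochs = 300,
                                    lr = 0.05, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < 200)
    stop_pp("need >= 200 training simulations", "pyrenpop_validation_error")
  sdx <- apply(x, 2, sd)
  keep <- sdx > 0
  if (any(!keep))
    warning(sprintf("dropping %d constant summary column(s)", sum(!keep)))
  x <- x[, keep, drop = FALSE]
  mx <- colMeans(x); sx <- apply(x, 2, sd)
  my <- colMeans(y); sy <- apply(y, 2, sd); sy[sy == 0] <- 1
  X <- sweep(sweep(x, 2, mx), 2, sx, "/")
  Y <- sweep(sweep(y, 2, my), 2, sy, "/")
  p <- ncol(X); q <- ncol(Y)
  h1 <- hidden[1]; h2 <- hidden[2]
  set.seed(seed)
  par <- list(W1 = matrix(rnorm(p * h1, 0, sqrt(1 / p)), p, h1),
              b1 = numeric(h1),
              W2 = matrix(rnorm(h1 * h2, 0, sqrt(1 / h1)), h1, h2),
              b2 = numeric(h2),
              W3 = matrix(rnorm(h2 * q, 0, sqrt(1 / h2)), h2, q),
              b3 = numeric(q))
  fwd <- function(par, X) {
    A1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
    A2 <- tanh(sweep(A1 %*% par$W2, 2, par$b2, "+"))
    list(A1 = A1, A2 = A2,
         Yhat = sweep(A2 %*% par$W3, 2, par$b3, "+"))
  }
  loss_of <- function(par) mean((fwd(par, X)$Yhat - Y)^2)
  grad_of <- function(par) {
    f <- fwd(par, X)
    n <- nrow(X)
    dY <- 2 * (f$Yhat - Y) / (n * q)
    dA2 <- dY %*% t(par$W3) * (1 - f$A2^2)
    dA1 <- dA2 %*% t(par$W2) * (1 - f$A1^2)
    list(W1 = t(X) %*% dA1, b1 = colSums(dA1),
         W2 = t(f$A1) %*% dA2, b2 = colSums(dA2),
         W3 = t(f$A2) %*% dY, b3 = colSums(dY))
  }
  trace <- numeric(epochs)
  cur <- loss_of(par)
  step <- lr
  for (ep in seq_len(epochs)) {
    g <- grad_of(par)
    repeat {
      cand <- Map(function(w, gw) w - step * gw, par, g)
      new <- loss_of(cand)
      if (new <= cur || step < 1e-12) break
      step <- step / 2
    }
    if (new <= cur) { par <- cand; cur <- new; step <- step * 1.2 }
    trace[ep] <- cur
  }
  structure(list(par = par, keep = keep, mx = mx, sx = sx, my = my, sy = sy,
                 loss_trace = trace, hidden = hidden,
                 param_names = colnames(y)),
            class = "pp_regressor")
}

#' Predict demographic parameters from summary vectors
#' @param object a `pp_regressor`
#' @param newdata matrix (or vector) of summary statistics
#' @param ... unused
#' @return matrix of predicted parameters (original scale)
#' @export
predict.pp_regressor <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1)
  X <- sweep(sweep(newdata[, object$keep, drop = FALSE], 2, object$mx),
             2, object$sx, "/")
  A1 <- tanh(sweep(X %*% object$par$W1, 2, object$par$b1, "+"))
  A2 <- tanh(sweep(A1 %*% object$par$W2, 2, object$par$b2, "+"))
  Z <- sweep(A2 %*% object$par$W3, 2, object$par$b3, "+")
  out <- sweep(sweep(Z, 2, object$sy, "*"), 2, object$my, "+")
  colnames(out) <- object$param_names
  out
}
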