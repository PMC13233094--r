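#' Initialize a parsimonious two-layer ReLU network
#'
#' The network computes \eqn{f(x) = \sum_k w_{2,k}\,\mathrm{relu}(W_{1,k} \cdot x)}
#' with no bias terms in either layer. `K = 4` hidden units is the minimal
#' width that can represent the XOR solution. All weights are drawn i.i.d.
#' Gaussian with mean 0 and standard deviation `init_std`.
#'
#' Because there are no biases, an input on which every hidden unit is
#' inactive yields a logit of exactly zero: the network abstains (see
#' [forward()]), which is why abstention is a structural outcome of this
#' architecture rather than a thresholding choice.
#'
#' @param K Number of hidden units.
#' @param d Input dimension.
#' @param init_std Initialization standard deviation (> 0).
#' @param seed Integer seed.
#' @return An object of class `"xor_net"`: list with `W1` (`K x d`), `w2`
#'   (length `K`), `K`, `d`.
#' @export
init_network <- function(K = 4L, d, init_std = 0.05, seed = 1L) {
  if (K < 1) stop("K must be >= 1")
  if (d < 2) stop("d must be >= 2")
  if (!is.numeric(init_std) || init_std <= 0) stop("init_std must be positive")
  local_seed(seed)
  structure(list(W1 = matrix(stats::rnorm(K * d, 0, init_std), K, d),
                 w2 = stats::rnorm(K, 0, init_std),
                 K = as.integer(K), d = as.integer(d)),
            class = "xor_net")
}

#' Hand-constructed XOR solution network
#'
#' Rows aligned with \eqn{\pm\mu_1} read out positively and rows aligned with
#' \eqn{\pm\mu_0} negatively, so the logit equals
#' \eqn{scale\,(|x\cdot\mu_1| - |x\cdot\mu_0|)} -- the Bayes decision rule for
#' the task.
#'
#' @param task An `"xor_task"`.
#' @param scale Positive scaling of the readout weights.
#' @return An `"xor_net"`.
#' @export
xor_solution <- function(task, scale = 1) {
  structure(list(W1 = rbind(task$mu1, -task$mu1, task$mu0, -task$mu0),
                 w2 = scale * c(1, 1, -1, -1),
                 K = 4L, d = task$d),
            class = "xor_net")
}

#' @export
print.xor_net <- function(x, ...) {
  cat(sprintf("two-layer ReLU network: K = %d hidden units, d = %d, no biases\n",
              x$K, x$d))
  invisible(x)
}

#' @export
coef.xor_net <- function(object, ...) list(W1 = object$W1, w2 = object$w2)

#' Forward pass with three-outcome decision
#'
#' Returns the logit and the decision: label 1 for a positive logit, label 0
#' for a negative one, and `"abstain"` when the logit is exactly zero (all
#' ReLU units inactive -- the bias-free network cannot produce an answer).
#' Abstentions count as errors in [accuracy()], which puts the chance level
#' of an untrained network slightly below 50%.
#'
#' @param net An `"xor_net"`.
#' @param x Input vector of length `d`.
#' @return List with `logit` (numeric) and `decision` (`"label0"`,
#'   `"label1"`, or `"abstain"`).
#' @export
forward <- function(net, x) {
  if (length(x) != net$d) stop("input length does not match network dimension")
  h <- pmax(drop(net$W1 %*% x), 0)
  logit <- sum(net$w2 * h)
  decision <- if (logit > 0) "label1" else if (logit < 0) "label0" else "abstain"
  list(logit = logit, decision = decision)
}

# vectorized logits for an n x d stimulus matrix
net_logits <- function(net, X) {
  pre <- X %*% t(net$W1)
  drop(pmax(pre, 0) %*% net$w2)
}

#' Predict labels for a batch of stimuli
#'
#' @param object An `"xor_net"`.
#' @param newdata An `n x d` matrix or a `"labeled_batch"`.
#' @param ... Unused.
#' @return Integer vector with 1/0 decisions and `NA` for abstentions.
#' @export
predict.xor_net <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_batch")) newdata$inputs else as.matrix(newdata)
  f <- net_logits(object, X)
  ifelse(f > 0, 1L, ifelse(f < 0, 0L, NA_integer_))
}

#' One online SGD step on the binary cross-entropy loss
#'
#' With \eqn{p = sigmoid(f(x))} and \eqn{\delta = p - y}, both layers are
#' updated with the same per-step learning rate:
#' \deqn{w_2 \leftarrow w_2 - \eta\,\delta\,h, \qquad
#'       W_{1,k} \leftarrow W_{1,k} - \eta\,\delta\,w_{2,k}\,[W_{1,k}\cdot x > 0]\,x}
#' where \eqn{h_k = \mathrm{relu}(W_{1,k}\cdot x)} and all right-hand sides use
#' the pre-update weights (simultaneous gradient).
#'
#' @param net An `"xor_net"`.
#' @param x Input vector.
#' @param y Label in \{0, 1\}.
#' @param eta_step Per-step learning rate (> 0). Under the time convention
#'   `time = steps / d` a nominal rate `eta` corresponds to
#'   `eta_step = eta / d`.
#' @param freeze_w2 If `TRUE` only the first layer is trained.
#' @return The updated `"xor_net"`.
#' @export
sgd_step <- function(net, x, y, eta_step, freeze_w2 = FALSE) {
  if (!y %in% c(0, 1)) stop("y must be 0 or 1")
  if (eta_step <= 0) stop("eta_step must be positive")
  pre <- drop(net$W1 %*% x)
  h <- pmax(pre, 0)
  f <- sum(net$w2 * h)
  delta <- 1 / (1 + exp(-f)) - y
  gate <- as.numeric(pre > 0)
  net$W1 <- net$W1 - (eta_step * delta * net$w2 * gate) %o% x
  if (!freeze_w2) net$w2 <- net$w2 - eta_step * delta * h
  net
}

#' Binary cross-entropy of a network on one stimulus
#' @keywords internal
bce_loss <- function(net, x, y) {
  f <- forward(net, x)$logit
  # numerically stable: log(1 + exp(-|f|)) + max(0, (1-2y) f)
  log1p(exp(-abs(f))) + max(0, (1 - 2 * y) * f)
}

#' Classification accuracy with abstentions counted incorrect
#'
#' @param net An `"xor_net"`.
#' @param batch A non-empty `"labeled_batch"`.
#' @return Fraction of trials whose decision equals the label.
#' @export
accuracy <- function(net, batch) {
  stopifnot(inherits(batch, "labeled_batch"))
  n <- length(batch$labels)
  if (n < 1) stop("batch is empty")
  f <- net_logits(net, batch$inputs)
  dec <- ifelse(f > 0, 1L, ifelse(f < 0, 0L, -1L))
  mean(dec == batch$labels)
}

#' Save / load network weights as JSON
#'
#' Flat checkpoint of the two weight matrices for replay.
#'
#' @param net An `"xor_net"`.
#' @param path File path.
#' @return `write_network_json` returns `path` invisibly; `read_network_json`
#'   returns an `"xor_net"`.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(K = net$K, d = net$d, W1 = net$W1, w2 = net$w2),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = matrix(obj$W1, obj$K, obj$d), w2 = as.numeric(obj$w2),
                 K = as.integer(obj$K), d = as.integer(obj$d)),
            class = "xor_net")
}
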