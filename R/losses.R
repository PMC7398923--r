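#' Training losses: categorical cross-entropy, focal, smooth-L1
#'
#' The three branches of the network are trained with (i) categorical
#' cross-entropy `-log(p)` on the probability assigned to the true class of
#' an anchor, (ii) a per-pixel focal loss `-(1 - p)^gamma * log(p)` on the
#' mask branch, which down-weights well-classified (mostly background)
#' pixels so that rare foreground pixels -- thin legs above all -- keep a
#' meaningful share of the gradient, and (iii) a smooth-L1 penalty on the
#' four box-delta components for anchor tightening.
#'
#' Probabilities are clamped below at `probability_floor` before the log.
#' All loss functions are vectorised and return the elementwise values;
#' `reduce = "mean"` averages over the batch.
#'
#' @param gamma Focusing exponent, `>= 0`; `gamma = 0` recovers plain
#'   cross-entropy. The model default is 2.
#' @param probability_floor Clamp applied to probabilities before `log`.
#' @return An object of class `focal_params`.
#' @export
focal_params <- function(gamma = 2, probability_floor = 1e-7) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (probability_floor <= 0 || probability_floor >= 1e-3)
    stop("probability_floor must be in (0, 1e-3)")
  structure(list(gamma = gamma, probability_floor = probability_floor),
            class = "focal_params")
}

#' @param p Probability assigned to the true class, in `(0, 1]` (values below
#'   the floor are clamped).
#' @param reduce `"none"` for elementwise values, `"mean"` for the batch mean.
#' @rdname focal_params
#' @export
cce_loss <- function(p, probability_floor = 1e-7, reduce = c("none", "mean")) {
  reduce <- match.arg(reduce)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  v <- -log(pmax(p, probability_floor))
  if (reduce == "mean") mean(v) else v
}

#' @param params A [focal_params()] object.
#' @rdname focal_params
#' @export
focal_loss <- function(p, params = focal_params(), reduce = c("none", "mean")) {
  reduce <- match.arg(reduce)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  pc <- pmax(p, params$probability_floor)
  v <- -(1 - pc)^params$gamma * log(pc)
  if (reduce == "mean") mean(v) else v
}

#' @param x Real input (typically a delta residual).
#' @rdname focal_params
#' @export
smooth_l1 <- function(x) {
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

#' @param pred,target Box-delta data frames (columns `tx`, `ty`, `tw`, `th`)
#'   with matching row counts.
#' @rdname focal_params
#' @export
reg_loss <- function(pred, target, reduce = c("none", "mean")) {
  reduce <- match.arg(reduce)
  d <- as.matrix(target[, c("tx", "ty", "tw", "th")]) -
    as.matrix(pred[, c("tx", "ty", "tw", "th")])
  v <- rowSums(smooth_l1(d))
  if (reduce == "mean") mean(v) else v
}

#' @param cls,mask,reg Non-negative branch losses.
#' @param weights Length-3 non-negative weights, default `c(1, 1, 1)`.
#' @rdname focal_params
#' @export
total_loss <- function(cls, mask, reg, weights = c(1, 1, 1)) {
  if (any(weights < 0)) stop("loss weights must be non-negative")
  if (any(c(cls, mask, reg) < 0)) stop("loss components must be non-negative")
  sum(weights * c(cls, mask, reg))
}

# --- internal gradients ------------------------------------------------------

# d/dz of the binary focal loss at logit z with target y in {0,1}.
# p = sigmoid(z), q = p_t = y*p + (1-y)*(1-p); FL = -(1-q)^g log q.
# dFL/dz = [g (1-q)^(g-1) log q - (1-q)^g / q] * s * q(1-q), s = +-1.
focal_grad_logit <- function(z, y, gamma, floor = 1e-7) {
  p <- 1 / (1 + exp(-z))
  q <- ifelse(y > 0, p, 1 - p)
  qc <- pmax(q, floor)
  s <- ifelse(y > 0, 1, -1)
  lt <- if (gamma > 0) gamma * (1 - qc)^(gamma - 1) * log(qc) else 0
  (lt - (1 - qc)^gamma / qc) * s * qc * (1 - qc)
}

# Elementwise focal loss at logit z with binary target y.
focal_loss_logit <- function(z, y, gamma, floor = 1e-7) {
  p <- 1 / (1 + exp(-z))
  q <- pmax(ifelse(y > 0, p, 1 - p), floor)
  -(1 - q)^gamma * log(q)
}

# d smooth_l1(t* - t) / d t  (gradient w.r.t. the prediction).
smooth_l1_grad_pred <- function(pred, target) {
  d <- target - pred
  -clamp(d, -1, 1)
}
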