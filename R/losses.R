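# Hybrid segmentation loss: soft Jaccard + class-balanced focal term,
# summed over deeply supervised stages with fixed stage weights.
#
# All losses accept either plain numeric arrays (returning a numeric
# scalar) or autodiff nodes (returning a scalar node that supports
# backpropagation); the same code path computes both.

#' Loss hyperparameters
#'
#' Defaults are the published operating point: focal balance
#' `alpha = 0.2`, focusing exponent `gamma = 1`, Jaccard weight
#' `lambda_j = 1`, focal weight `eta_f = 0.1`, stage weights
#' `{0.8, 0.9, 1.0}` for the two auxiliary signals and the final
#' output.  `eps` is a numerical floor protecting the Jaccard ratio on
#' empty masks and the focal logs near 0/1.
#'
#' @param alpha focal balance factor in (0, 1); weight of the positive
#'   class.
#' @param gamma focusing exponent (>= 0) down-weighting easy voxels.
#' @param lambda_j weight of the Jaccard term in the signal loss.
#' @param eta_f weight of the focal term in the signal loss.
#' @param stage_weights named vector `c(w2, w3, wf)` for the stage-wise
#'   deeply supervised sum.
#' @param eps numerical floor.
#' @return a `LossConfig` list.
#' @export
lossConfig <- function(alpha = 0.2, gamma = 1, lambda_j = 1, eta_f = 0.1,
                       stage_weights = c(w2 = 0.8, w3 = 0.9, wf = 1.0),
                       eps = 1e-7) {
  stopifnot(alpha > 0, alpha < 1, gamma >= 0, lambda_j >= 0, eta_f >= 0,
            all(stage_weights >= 0))
  structure(list(alpha = alpha, gamma = gamma, lambda_j = lambda_j,
                 eta_f = eta_f, stage_weights = stage_weights, eps = eps),
            class = "LossConfig")
}

checkPQ <- function(p, q) {
  pv <- agValue(p)
  if (length(pv) != length(q))
    stop("prediction and ground truth differ in length (",
         length(pv), " vs ", length(q), ")")
  if (!all(q %in% c(0, 1))) stop("ground truth must be strictly binary")
  invisible(NULL)
}

maybeValue <- function(node, was_node) if (was_node) node else agValue(node)

#' Soft Jaccard loss
#'
#' `1 - sum(q p) / (sum(q^2) + sum(p^2) - sum(q p) + eps)`: one minus a
#' differentiable intersection-over-union, 0 for a perfect binary
#' prediction and 1 for a total miss.
#'
#' @param p probability map (values in \[0, 1\]), array or autodiff
#'   node.
#' @param q binary ground-truth mask of the same length.
#' @param eps numerical floor added to the denominator.
#' @return scalar loss (numeric, or a node if `p` is a node).
#' @export
#' @examples
#' jaccardLoss(c(0.5, 0.5), c(1, 0))  # 0.5
jaccardLoss <- function(p, q, eps = 1e-7) {
  checkPQ(p, q)
  was_node <- isNode(p)
  p <- asNode(p)
  qn <- agLeaf(array(as.numeric(q), dim = dimOf(agValue(p))))
  s_qp <- ag_sum(ag_mul(p, qn))
  s_p2 <- ag_sum(ag_mul(p, p))
  s_q2 <- sum(q)                        # q binary: sum(q^2) = sum(q)
  denom <- ag_addc(ag_sub(s_p2, s_qp), s_q2 + eps)
  out <- ag_addc(ag_scale(ag_div(s_qp, denom), -1), 1)
  maybeValue(out, was_node)
}

#' Focal loss
#'
#' Mean over voxels of
#' `-[alpha q (1-p)^gamma log p + (1-alpha)(1-q) p^gamma log(1-p)]`
#' (natural logarithm), with `p` clamped to `[eps, 1-eps]`.
#'
#' @inheritParams jaccardLoss
#' @param cfg a [lossConfig()].
#' @return scalar loss.
#' @export
#' @examples
#' focalLoss(0.5, 1)   # -0.2 * 0.5 * log(0.5) = 0.0693
focalLoss <- function(p, q, cfg = lossConfig()) {
  checkPQ(p, q)
  was_node <- isNode(p)
  p <- ag_clamp(asNode(p), cfg$eps, 1 - cfg$eps)
  a <- cfg$alpha; g <- cfg$gamma
  qn <- agLeaf(array(as.numeric(q), dim = dimOf(agValue(p))))
  one_m_p <- ag_addc(ag_scale(p, -1), 1)
  one_m_q <- 1 - as.numeric(q)
  pos <- ag_mul(ag_mul(qn, ag_powc(one_m_p, g)), ag_log(p))
  neg <- ag_mul(ag_mul(agLeaf(array(one_m_q, dim = dimOf(agValue(p)))),
                       ag_powc(p, g)), ag_log(one_m_p))
  out <- ag_scale(ag_mean(ag_add(ag_scale(pos, a), ag_scale(neg, 1 - a))), -1)
  maybeValue(out, was_node)
}

#' Supervised-signal loss
#'
#' Weighted sum `lambda_j * Jaccard + eta_f * focal` applied to one
#' probability map.
#'
#' @inheritParams focalLoss
#' @return scalar loss.
#' @export
signalLoss <- function(p, q, cfg = lossConfig()) {
  was_node <- isNode(p)
  p <- asNode(p)
  out <- ag_add(ag_scale(jaccardLoss(p, q, cfg$eps), cfg$lambda_j),
                ag_scale(focalLoss(p, q, cfg), cfg$eta_f))
  maybeValue(out, was_node)
}

#' Stage-wise deeply supervised loss
#'
#' `w2 L(p_s2) + w3 L(p_s3) + wf L(p_f)` with `L` the signal loss and
#' default stage weights `{0.8, 0.9, 1.0}`.  Setting `w2 = w3 = 0`
#' recovers single-output training on the final map.
#'
#' @param preds list with full-resolution probability maps `p_s2`,
#'   `p_s3` and `p_f` (arrays or nodes).
#' @inheritParams focalLoss
#' @return scalar loss.
#' @export
sdsLoss <- function(preds, q, cfg = lossConfig()) {
  w <- cfg$stage_weights
  was_node <- any(vapply(preds[c("p_s2", "p_s3", "p_f")], isNode, logical(1)))
  terms <- list(ag_scale(asNode(signalLoss(asNode(preds$p_s2), q, cfg)), w[["w2"]]),
                ag_scale(asNode(signalLoss(asNode(preds$p_s3), q, cfg)), w[["w3"]]),
                ag_scale(asNode(signalLoss(asNode(preds$p_f), q, cfg)), w[["wf"]]))
  out <- ag_add(ag_add(terms[[1]], terms[[2]]), terms[[3]])
  maybeValue(out, was_node)
}
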