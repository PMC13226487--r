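#' Region-weighted combined L1 segmentation loss
#'
#' The loss between a predicted probability map and its ground truth is the
#' sum of four mean-absolute-error terms: a global term over all N voxels,
#' two terms restricted to the ground-truth regions S1 (`gt > t1`) and S2
#' (`gt > t2`), and one restricted to the predicted foreground S2*
#' (`pred > t2`), which penalises false-positive segmentation.  A term over
#' an empty region is defined as 0.
#'
#' @param pred,gt [vb_volume()]s or arrays of equal shape with values in
#'   \[0, 1\].
#' @param t1,t2 normalized intensity thresholds defining the regions.
#' @param weights optional nonnegative weights for the four terms
#'   (global, S1, S2, S2*); the canonical loss is the unweighted sum.
#' @return list of class `loss_breakdown`: `term_global`, `term_S1`,
#'   `term_S2`, `term_S2star`, `total`, and region sizes `N`, `n_S1`,
#'   `n_S2`, `n_S2star`.
#' @export
combined_loss <- function(pred, gt, t1 = 0.012, t2 = 0.404,
                          weights = c(1, 1, 1, 1)) {
  p <- if (inherits(pred, "vb_volume")) pred$data else pred
  g <- if (inherits(gt, "vb_volume")) gt$data else gt
  if (!identical(dim(p), dim(g))) stop("shape mismatch between pred and gt")
  stopifnot(length(weights) == 4, all(weights >= 0))
  ad <- abs(p - g)
  S1 <- g > t1; S2 <- g > t2; S2s <- p > t2
  term <- function(mask) if (any(mask)) sum(ad[mask]) / sum(mask) else 0
  tg <- mean(ad)
  t1v <- term(S1); t2v <- term(S2); tsv <- term(S2s)
  structure(list(term_global = weights[1] * tg,
                 term_S1 = weights[2] * t1v,
                 term_S2 = weights[3] * t2v,
                 term_S2star = weights[4] * tsv,
                 total = weights[1] * tg + weights[2] * t1v +
                         weights[3] * t2v + weights[4] * tsv,
                 N = length(ad), n_S1 = sum(S1), n_S2 = sum(S2),
                 n_S2star = sum(S2s)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss: total %.6g = global %.6g + S1 %.6g + S2 %.6g + S2* %.6g (N=%d, #S1=%d, #S2=%d, #S2*=%d)>\n",
    x$total, x$term_global, x$term_S1, x$term_S2, x$term_S2star,
    x$N, x$n_S1, x$n_S2, x$n_S2star))
  invisible(x)
}
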