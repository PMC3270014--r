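# ---------------------------------------------------------------------------
# PWM comparison: mean per-position Kullback-Leibler divergence and
# empirical p-values from randomized matrices
# ---------------------------------------------------------------------------

# Floor all entries at epsilon and renormalize columns (rows of the L x 4
# matrix).  Prevents infinite divergences on zero-probability bases.
floor_pwm_matrix <- function(m, epsilon) {
  m <- pmax(unclass(m), epsilon)
  m / rowSums(m)
}

#' Mean per-position Kullback-Leibler divergence between two PWMs
#'
#' `psi = (1/L) * sum_j sum_i q_ij * ln(q_ij / p_ij)` with `q` the
#' annotated and `p` the predicted matrix (both floored at `epsilon` and
#' renormalized), natural logarithm.  0 means identical matrices; larger is
#' worse.  The KL direction treats the annotated PWM as the truth
#' (`"ann_pred"`, default); `"pred_ann"` and the symmetrized mean are
#' available.
#'
#' @param pred,ann [pwm()] objects of equal length.
#' @param epsilon probability floor (default 1e-3).
#' @param direction `"ann_pred"`, `"pred_ann"` or `"symmetric"`.
#' @return Nonnegative scalar.
#' @export
psi_score <- function(pred, ann, epsilon = 1e-3,
                      direction = c("ann_pred", "pred_ann", "symmetric")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pred, "pwm"), inherits(ann, "pwm"))
  if (nrow(pred) != nrow(ann))
    stop("PWM lengths differ (", nrow(pred), " vs ", nrow(ann),
         "); align them first with align_pwms()")
  p <- floor_pwm_matrix(pred, epsilon)
  q <- floor_pwm_matrix(ann, epsilon)
  kl <- function(a, b) sum(a * log(a / b)) / nrow(a)
  switch(direction,
         ann_pred = kl(q, p),
         pred_ann = kl(p, q),
         symmetric = (kl(q, p) + kl(p, q)) / 2)
}

#' Align two PWMs over offsets and strands and score the best placement
#'
#' Predicted PWMs are typically shorter than annotated ones.  The shorter
#' matrix is slid across every offset that places it fully inside the
#' longer, on both the forward and reverse-complement orientation of the
#' predicted matrix, and the placement minimizing the psi score is
#' returned.  Ties break toward the smaller offset, forward strand first.
#'
#' @param pred,ann non-empty [pwm()] objects.
#' @param epsilon probability floor passed to [psi_score()].
#' @param direction KL direction passed to [psi_score()].
#' @return Object of class `psi_result`: `psi`, `offset` (0-based shift of
#'   the shorter matrix within the longer), `strand` (`"forward"` or
#'   `"revcomp"`), `L_overlap`, `p_value` (`NA` until [psi_pvalue()]).
#' @export
align_pwms <- function(pred, ann, epsilon = 1e-3,
                       direction = "ann_pred") {
  stopifnot(inherits(pred, "pwm"), inherits(ann, "pwm"))
  Lp <- nrow(pred); La <- nrow(ann)
  best <- NULL
  for (strand in c("forward", "revcomp")) {
    p_or <- if (strand == "forward") pred else revcomp_pwm(pred)
    n_off <- abs(La - Lp) + 1L
    for (off in 0:(n_off - 1L)) {
      if (Lp <= La) {
        a_slice <- pwm(unclass(ann)[off + seq_len(Lp), , drop = FALSE])
        p_slice <- p_or
      } else {
        a_slice <- ann
        p_slice <- pwm(unclass(p_or)[off + seq_len(La), , drop = FALSE])
      }
      psi <- psi_score(p_slice, a_slice, epsilon = epsilon,
                       direction = direction)
      if (is.null(best) || psi < best$psi - 1e-15) {
        best <- list(psi = psi, offset = off, strand = strand,
                     L_overlap = min(Lp, La), p_value = NA_real_)
      }
    }
  }
  structure(best, class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("<psi_result> psi = %.4f at offset %d (%s), L = %d",
              x$psi, x$offset, x$strand, x$L_overlap))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

# Best psi of each random matrix against ann, mirroring align_pwms: every
# full-containment offset, forward and reverse-complement orientation.
# logp: n x L x 4 array of log probabilities (already floored).
null_best_psi <- function(logp, ann_f, epsilon) {
  n <- dim(logp)[1]; L <- dim(logp)[2]; La <- nrow(ann_f)
  q <- floor_pwm_matrix(ann_f, epsilon)
  best <- rep(Inf, n)
  # reverse-complement orientation of the random matrix = reversed
  # positions with A<->T, C<->G swapped
  orients <- list(forward = list(pos = seq_len(L), base = 1:4),
                  revcomp = list(pos = rev(seq_len(L)), base = c(4, 3, 2, 1)))
  for (o in orients) {
    lp <- logp[, o$pos, o$base, drop = FALSE]
    lpm <- matrix(lp, nrow = n)            # n x (L*4), position-major
    for (off in 0:(abs(La - L))) {
      if (L <= La) {
        qs <- q[off + seq_len(L), , drop = FALSE]
        cross <- lpm %*% as.vector(qs)
        ent <- sum(qs * log(qs))
        psi <- (ent - cross) / L
      } else {
        sel <- as.vector(outer(off + seq_len(La), (0:3) * L, "+"))
        cross <- lpm[, sel, drop = FALSE] %*% as.vector(q)
        ent <- sum(q * log(q))
        psi <- (ent - cross) / La
      }
      best <- pmin(best, as.vector(psi))
    }
  }
  best
}

#' Empirical p-value of a psi score from a randomized-PWM null
#'
#' Generates `n` random PWMs of length `L` (each column drawn uniformly
#' from the probability simplex, i.e. a flat Dirichlet), aligns each to the
#' annotated PWM exactly as the prediction was aligned, and returns the
#' add-one estimate `(1 + #(psi_null <= psi)) / (n + 1)`, which is never 0.
#'
#' @param psi the observed psi score to test.
#' @param ann annotated [pwm()].
#' @param L length of the random matrices (use the predicted PWM's length).
#' @param n number of random matrices (default 100000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param epsilon probability floor used in scoring.
#' @return p-value in (0, 1].
#' @export
psi_pvalue <- function(psi, ann, L, n = 100000L, seed = 1L,
                       epsilon = 1e-3) {
  stopifnot(inherits(ann, "pwm"), n >= 1, L >= 1)
  null_psi <- with_seed(seed, {
    # flat Dirichlet columns via normalized Exp(1) draws, then the same
    # epsilon flooring applied to any scored PWM
    g <- array(stats::rexp(n * L * 4), dim = c(n, L, 4))
    tot <- g[, , 1] + g[, , 2] + g[, , 3] + g[, , 4]
    for (b in 1:4) g[, , b] <- pmax(g[, , b] / tot, epsilon)
    tot <- g[, , 1] + g[, , 2] + g[, , 3] + g[, , 4]
    for (b in 1:4) g[, , b] <- log(g[, , b] / tot)
    null_best_psi(g, ann, epsilon)
  })
  unname((1 + sum(null_psi <= psi)) / (n + 1))
}

#' Score a prediction against an annotated PWM, with p-value
#'
#' Convenience wrapper: aligns, scores, and attaches the empirical
#' p-value.
#'
#' @param pred,ann [pwm()] objects.
#' @param n,seed,epsilon see [psi_pvalue()].
#' @return A `psi_result` with `p_value` filled in.
#' @export
evaluate_pwm <- function(pred, ann, n = 100000L, seed = 1L,
                         epsilon = 1e-3) {
  res <- align_pwms(pred, ann, epsilon = epsilon)
  res$p_value <- psi_pvalue(res$psi, ann, L = nrow(pred), n = n,
                            seed = seed, epsilon = epsilon)
  res$n_null <- n
  res$seed <- seed
  res
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
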